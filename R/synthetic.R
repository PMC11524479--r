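# Synthetic wingbeat and environmental-noise generator. A mosquito flight
# tone is modeled as a quasi-harmonic series: a fundamental near the
# species/sex wingbeat rate (female Ae. aegypti around 512 Hz), a few
# harmonics with geometric roll-off, a slow bounded random walk of the
# fundamental, and slow amplitude modulation. Environmental noise comes
# in four characters: impulsive (clicks), harmonic (tonal complex at a
# non-wingbeat fundamental), broadband (filtered noise), and fan (steady
# tonal plus broadband), mirroring trap-side recording conditions.

#' Species/sex tone profile
#'
#' @param label integer class index (see [class_index()]).
#' @param f0_mean mean fundamental frequency, Hz.
#' @param f0_jitter bound on the slow random walk of the fundamental, Hz.
#' @param n_harmonics number of harmonics (fundamental included).
#' @param harmonic_rolloff geometric amplitude decay per harmonic.
#' @param am_depth depth of the slow amplitude modulation, 0..1.
#' @param fs sample rate the profile targets (aliasing check), Hz.
#' @return An object of class `wb_species_profile`.
#' @export
species_profile <- function(label, f0_mean, f0_jitter = 10, n_harmonics = 3L,
                            harmonic_rolloff = 0.55, am_depth = 0.2,
                            fs = 8000L) {
  stopifnot(f0_mean > 0, f0_jitter >= 0, n_harmonics >= 1,
            harmonic_rolloff > 0, am_depth >= 0, am_depth < 1)
  if ((f0_mean + f0_jitter) * n_harmonics >= fs / 2)
    stop("profile error: harmonic ", n_harmonics, " of ", f0_mean,
         " Hz aliases at fs = ", fs)
  structure(list(label = as.integer(label), f0_mean = f0_mean,
                 f0_jitter = f0_jitter, n_harmonics = as.integer(n_harmonics),
                 harmonic_rolloff = harmonic_rolloff, am_depth = am_depth),
            class = "wb_species_profile")
}

#' Default eight-class profile bank
#'
#' Fundamentals span roughly 350-750 Hz with sex modeled as an upward
#' offset within each species (males beat faster) and deliberate overlap
#' between adjacent species, so classes are separable but not trivially
#' so. Only the female Ae. aegypti fundamental (512 Hz) is anchored to a
#' published observation; the others are modeling choices.
#'
#' @param num_class 8 (species and sex), 4 (species only, females), or 2
#'   (a well-separated toy pair).
#' @return A list of [species_profile()]s with labels `0..num_class-1`.
#' @export
default_profiles <- function(num_class = 8L) {
  f0 <- switch(as.character(num_class),
    "8" = c(512, 660, 545, 700, 380, 470, 420, 580),
    "4" = c(512, 545, 380, 420),
    "2" = c(400, 700),
    stop("default_profiles supports num_class 2, 4 or 8"))
  lapply(seq_along(f0), function(i)
    species_profile(label = i - 1L, f0_mean = f0[i]))
}

#' Synthesize a wingbeat recording
#'
#' Sum of `n_harmonics` sinusoids at `k * f0(t)` with amplitudes
#' proportional to `harmonic_rolloff^(k-1)`, where the fundamental
#' follows a bounded slow random walk around `f0_mean`; slow sinusoidal
#' amplitude modulation of depth `am_depth`; peak-normalized to 0.9.
#'
#' @param p a [species_profile()].
#' @param duration seconds.
#' @param fs sample rate, Hz (default 8000).
#' @param species,sex,source_id,recorded_at metadata passed to the
#'   returned [wb_recording()].
#' @return A [wb_recording()] with the profile's label derivable from its
#'   species/sex metadata when supplied.
#' @export
synth_wingbeat <- function(p, duration = 1, fs = 8000L,
                           species = NA_character_, sex = NA_character_,
                           source_id = "synth", recorded_at = 0) {
  n <- round(duration * fs)
  t <- seq_len(n)
  # slow mean-reverting wander of f0 (AR(1), ~50 ms time constant),
  # clamped to +/- jitter around the species mean
  rho <- exp(-1 / (0.05 * fs))
  innov <- rnorm(n, 0, (p$f0_jitter / 2) * sqrt(1 - rho^2))
  walk <- as.numeric(stats::filter(innov, rho, method = "recursive"))
  f0 <- p$f0_mean + pmin(p$f0_jitter, pmax(-p$f0_jitter, walk))
  phase <- 2 * pi * cumsum(f0) / fs
  x <- numeric(n)
  for (k in seq_len(p$n_harmonics))
    x <- x + p$harmonic_rolloff^(k - 1) * sin(k * phase)
  if (p$am_depth > 0) {
    f_am <- runif(1, 0.5, 2)
    x <- x * (1 + p$am_depth * sin(2 * pi * f_am * t / fs + runif(1, 0, 2 * pi)))
  }
  x <- 0.9 * x / max(abs(x))
  wb_recording(x, fs, species = species, sex = sex, source_id = source_id,
               recorded_at = recorded_at)
}

#' Synthesize an environmental noise recording
#'
#' @param kind `"impulsive"` (sparse clicks with decay tails),
#'   `"harmonic"` (tonal complex at a low, non-wingbeat fundamental),
#'   `"broadband"` (smoothed white noise), or `"fan"` (steady low tonal
#'   complex plus broadband floor).
#' @param duration seconds.
#' @param fs sample rate, Hz.
#' @param source_id identifier for the returned recording.
#' @return A [wb_recording()], peak-normalized to 0.9, unlabeled.
#' @export
synth_noise <- function(kind = c("impulsive", "harmonic", "broadband", "fan"),
                        duration = 1, fs = 8000L, source_id = "noise") {
  kind <- match.arg(kind)
  n <- round(duration * fs)
  t <- seq_len(n)
  x <- switch(kind,
    impulsive = {
      y <- numeric(n)
      n_clicks <- max(1L, stats::rpois(1, duration * 8))
      pos <- sample.int(n, min(n_clicks, n))
      tail_len <- min(n, round(0.004 * fs))
      decay <- exp(-seq_len(tail_len) / (0.001 * fs))
      for (s in pos) {
        e <- min(n, s + tail_len - 1L)
        y[s:e] <- y[s:e] + runif(1, 0.3, 1) * sample(c(-1, 1), 1) * decay[seq_len(e - s + 1L)]
      }
      y + 0.01 * rnorm(n)
    },
    harmonic = {
      f0 <- runif(1, 90, 260)
      y <- numeric(n)
      for (k in 1:5) y <- y + 0.6^(k - 1) * sin(2 * pi * k * f0 * t / fs + runif(1, 0, 2 * pi))
      y
    },
    broadband = {
      y <- rnorm(n)
      as.numeric(stats::filter(y, rep(1 / 4, 4), sides = 2, circular = TRUE))
    },
    fan = {
      f0 <- runif(1, 50, 150)
      y <- numeric(n)
      for (k in 1:4) y <- y + 0.7^(k - 1) * sin(2 * pi * k * f0 * t / fs + runif(1, 0, 2 * pi))
      y + 0.5 * as.numeric(stats::filter(rnorm(n), rep(1 / 6, 6), sides = 2, circular = TRUE))
    })
  x <- 0.9 * x / max(abs(x))
  wb_recording(x, fs, source_id = source_id)
}

#' Generate a labeled synthetic dataset with a manifest
#'
#' Produces `n_per_class` recordings per profile with synthetic
#' timestamps that increase monotonically within each class, so
#' chronological fold splitting is well defined. Species/sex metadata is
#' attached when the profile labels fall in the standard 8-class space.
#'
#' @param profiles list of [species_profile()]s with distinct labels.
#' @param n_per_class recordings per profile.
#' @param duration seconds per recording.
#' @param fs sample rate, Hz.
#' @param dir optional directory; when given, WAVs and `manifest.csv` are
#'   written there in the standard ingestion schema.
#' @return `list(recordings, manifest)`; recordings are standardized
#'   (16-bit-quantized) [wb_recording()]s.
#' @export
make_dataset <- function(profiles, n_per_class = 10L, duration = 1,
                         fs = 8000L, dir = NULL) {
  labs <- vapply(profiles, `[[`, 0L, "label")
  if (anyDuplicated(labs)) stop("config error: duplicate profile labels")
  eight <- length(profiles) == 8L && setequal(labs, 0:7)
  recs <- list(); rows <- list()
  for (p in profiles) {
    species <- if (eight) WB_SPECIES[p$label %/% 2L + 1L] else NA_character_
    sex <- if (eight) WB_SEXES[p$label %% 2L + 1L] else NA_character_
    for (i in seq_len(n_per_class)) {
      sid <- sprintf("class%d_rec%03d", p$label, i)
      r <- synth_wingbeat(p, duration, fs, species = species, sex = sex,
                          source_id = sid, recorded_at = i)
      r$samples <- quantize16(r$samples)
      recs[[length(recs) + 1L]] <- r
      rows[[length(rows) + 1L]] <- data.frame(
        path = paste0(sid, ".wav"), species = species, sex = sex,
        source_id = sid, recorded_at = i, label = p$label)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (r in recs) write_wav(r, file.path(dir, paste0(r$source_id, ".wav")))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(recordings = recs, manifest = manifest)
}

#' Build a synthetic noise pool
#'
#' Convenience wrapper generating `n_per_kind` recordings of each noise
#' character and assembling them into a [noise_pool()].
#'
#' @param n_per_kind recordings per noise kind.
#' @param duration seconds per recording.
#' @param partition_tag pool partition (`"train"`, `"val"`, `"test"`).
#' @param kinds noise kinds to include.
#' @param fs sample rate, Hz.
#' @return A [noise_pool()].
#' @export
make_noise_pool <- function(n_per_kind = 3L, duration = 1,
                            partition_tag = "train",
                            kinds = c("impulsive", "harmonic", "broadband", "fan"),
                            fs = 8000L) {
  recs <- list(); cats <- character(0)
  for (k in kinds) for (i in seq_len(n_per_kind)) {
    r <- synth_noise(k, duration, fs,
                     source_id = sprintf("%s_%s_%02d", partition_tag, k, i))
    r$samples <- quantize16(r$samples)
    recs[[length(recs) + 1L]] <- r
    cats <- c(cats, k)
  }
  noise_pool(recs, cats, partition_tag)
}

#' Generate a labeled synthetic epoch set ready for training
#'
#' Runs [make_dataset()] and [segment_epochs()] end to end, returning
#' labeled standardized epochs. `n_per_class` here counts epochs, not
#' recordings: each 1.05-s recording yields 6 epochs of 300 ms with
#' 150 ms overlap (epoch count per recording is configurable through
#' `duration`).
#'
#' @param profiles list of [species_profile()]s.
#' @param n_per_class target epochs per class.
#' @param duration seconds per underlying recording.
#' @return A labeled [wb_epochs()] with about `n_per_class` epochs per
#'   class (exactly, when `n_per_class` is a multiple of the per-recording
#'   epoch yield).
#' @export
make_epoch_dataset <- function(profiles, n_per_class = 200L, duration = 1.05) {
  per_rec <- max(1L, (round(duration * 8000) - 2400L) %/% 1200L + 1L)
  n_rec <- ceiling(n_per_class / per_rec)
  ds <- make_dataset(profiles, n_per_class = n_rec, duration = duration)
  sets <- lapply(ds$recordings, segment_epochs)
  eps <- do.call(bind_epochs, sets)
  # attach labels for non-standard (toy) label spaces
  if (anyNA(eps$info$label)) {
    lab_by_src <- setNames(ds$manifest$label, ds$manifest$source_id)
    eps$info$label <- as.integer(lab_by_src[eps$info$source_id])
  }
  # trim per class to the target count, keeping chronological order
  keep <- unlist(lapply(split(seq_len(n_epochs(eps)), eps$info$label),
                        function(i) head(i, n_per_class)))
  eps[sort(keep)]
}
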