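# Training-time augmentation. Fresh stochastic variants of every training
# example are generated on each training pass: circular time shift, a
# wingbeat gain drawn from [1, 2] applied before environmental-noise
# overlay (90% of examples; 10% stay clean), additive Gaussian sensor
# noise, and an overall amplitude factor of 1/4..4 drawn log-uniformly so
# its dB offset is symmetric (about -12..+12 dB).

#' Augmentation configuration
#'
#' Collects every stochastic augmentation parameter with its default.
#'
#' @param p_clean probability that an epoch skips the environmental-noise
#'   overlay and stays clean (default 0.10, so 90% of each training pass
#'   carries background noise).
#' @param gain_range range of the wingbeat gain factor G applied before
#'   noise addition (default `c(1, 2)`).
#' @param gaussian_factor_range range of the multiplier on standard-normal
#'   sensor noise (default `c(0.001, 0.01)`).
#' @param shift_fraction maximum circular time shift as a fraction of the
#'   epoch (default 0.10, i.e. +/-240 samples of 2400).
#' @param amplitude_range range of the overall amplitude factor, drawn
#'   log-uniformly (default `c(0.25, 4)`, about -12..+12 dB).
#' @param enable named logical vector switching individual operators
#'   (`shift`, `env_noise`, `gaussian`, `amplitude`).
#' @param seed integer seed anchoring the per-(pass, example) streams.
#' @return An object of class `wb_aug_config`.
#' @export
aug_config <- function(p_clean = 0.10, gain_range = c(1, 2),
                       gaussian_factor_range = c(0.001, 0.01),
                       shift_fraction = 0.10, amplitude_range = c(0.25, 4),
                       enable = c(shift = TRUE, env_noise = TRUE,
                                  gaussian = TRUE, amplitude = TRUE),
                       seed = 1L) {
  stopifnot(p_clean >= 0, p_clean <= 1,
            length(gain_range) == 2L, gain_range[1] <= gain_range[2], gain_range[1] > 0,
            length(gaussian_factor_range) == 2L,
            gaussian_factor_range[1] <= gaussian_factor_range[2],
            gaussian_factor_range[1] >= 0,
            shift_fraction >= 0, shift_fraction <= 1,
            length(amplitude_range) == 2L, amplitude_range[1] > 0,
            amplitude_range[1] <= amplitude_range[2])
  full <- c(shift = TRUE, env_noise = TRUE, gaussian = TRUE, amplitude = TRUE)
  full[names(enable)] <- enable
  structure(list(p_clean = p_clean, gain_range = gain_range,
                 gaussian_factor_range = gaussian_factor_range,
                 shift_fraction = shift_fraction,
                 amplitude_range = amplitude_range,
                 enable = full, seed = as.integer(seed)),
            class = "wb_aug_config")
}

#' Draw a wingbeat gain factor
#'
#' G is uniform on `gain_range` (default `[1, 2]`) and multiplies the
#' wingbeat signal strictly before environmental noise is added, modeling
#' the mosquito's varying distance from the microphone.
#'
#' @param cfg an [aug_config()].
#' @return A single numeric gain.
#' @export
vary_wingbeat_volume <- function(cfg) {
  runif(1, cfg$gain_range[1], cfg$gain_range[2])
}

#' Environmental-noise augmentation
#'
#' With probability `p_clean` the epoch is returned unchanged (marked
#' clean); otherwise a random noise epoch is sampled from the pool and the
#' result is `G * x + noise` with G from [vary_wingbeat_volume()]. Random
#' draws occur in the fixed order: clean/noisy decision, gain, noise
#' recording, noise offset.
#'
#' @param x a [wb_epochs()] (each row augmented independently).
#' @param pool a [noise_pool()]; may be `NULL` only when `p_clean == 1`.
#' @param cfg an [aug_config()].
#' @return A [wb_epochs()] with labels unchanged.
#' @export
env_noise_augment <- function(x, pool, cfg) {
  n <- n_epochs(x)
  out <- x
  for (i in seq_len(n)) {
    if (runif(1) < cfg$p_clean) {
      out$info$is_noisy[i] <- FALSE
      out$info$gain[i] <- NA_real_
    } else {
      if (is.null(pool)) stop("empty noise pool with p_clean < 1")
      g <- vary_wingbeat_volume(cfg)
      nz <- sample_noise_epoch(pool, 1L)
      out$samples[i, ] <- g * x$samples[i, ] + nz$samples[1L, ]
      out$info$is_noisy[i] <- TRUE
      out$info$gain[i] <- g
    }
  }
  out
}

#' Additive Gaussian sensor noise
#'
#' Adds `f * z` per epoch, where `z` is i.i.d. standard normal per sample
#' and `f` is uniform on `gaussian_factor_range`.
#'
#' @inheritParams env_noise_augment
#' @return A [wb_epochs()].
#' @export
add_gaussian_noise <- function(x, cfg) {
  out <- x
  W <- ncol(x$samples)
  for (i in seq_len(n_epochs(x))) {
    f <- runif(1, cfg$gaussian_factor_range[1], cfg$gaussian_factor_range[2])
    out$samples[i, ] <- x$samples[i, ] + f * rnorm(W)
  }
  out
}

#' Random circular time shift
#'
#' Shifts each epoch circularly by `k` samples, `k` uniform on the
#' integers in `[-round(shift_fraction * W), +round(shift_fraction * W)]`
#' (+/-240 at the defaults). The circular fill preserves the sample
#' multiset and hence the waveform energy.
#'
#' @inheritParams env_noise_augment
#' @return A [wb_epochs()].
#' @export
time_shift <- function(x, cfg) {
  out <- x
  W <- ncol(x$samples)
  K <- round(cfg$shift_fraction * W)
  for (i in seq_len(n_epochs(x))) {
    k <- sample.int(2L * K + 1L, 1L) - K - 1L
    if (k != 0L) {
      idx <- ((seq_len(W) - 1L - k) %% W) + 1L
      out$samples[i, ] <- x$samples[i, idx]
    }
  }
  out
}

#' Random amplitude variation
#'
#' Multiplies each epoch by a factor drawn log-uniformly on
#' `amplitude_range`, so the dB offset `20*log10(a)` is uniform on a
#' symmetric interval (about -12..+12 dB at the default 1/4..4).
#'
#' @inheritParams env_noise_augment
#' @return A [wb_epochs()].
#' @export
vary_amplitude <- function(x, cfg) {
  out <- x
  lo <- log(cfg$amplitude_range[1]); hi <- log(cfg$amplitude_range[2])
  for (i in seq_len(n_epochs(x))) {
    a <- exp(runif(1, lo, hi))
    out$samples[i, ] <- a * x$samples[i, ]
  }
  out
}

# deterministic per-(seed, pass, example) stream seed; stays below 2^31
aug_stream_seed <- function(seed, pass, index) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(pass) * 40503 +
                as.numeric(index) * 9973) %% 2147483646) + 1L
}

#' Compose the full augmentation pipeline on one epoch
#'
#' Applies, in order: circular time shift, then the environmental-noise
#' overlay with its wingbeat gain (skipped with probability `p_clean`),
#' then Gaussian sensor noise, then the overall amplitude factor on the
#' mix. Labels are never changed. When `pass` and `index` are supplied the
#' draw stream is seeded from `(cfg$seed, pass, index)` so each example
#' gets a fresh but reproducible variant on every training pass.
#'
#' @param x a single-row [wb_epochs()].
#' @param pool a [noise_pool()] or `NULL`.
#' @param cfg an [aug_config()].
#' @param pass,index optional training-pass and example indices selecting
#'   a deterministic draw stream.
#' @return A single-row [wb_epochs()].
#' @export
compose_augmentations <- function(x, pool, cfg, pass = NULL, index = NULL) {
  stopifnot(n_epochs(x) == 1L)
  if (!is.null(pass) && !is.null(index))
    set.seed(aug_stream_seed(cfg$seed, pass, index))
  en <- cfg$enable
  if (en[["shift"]]) x <- time_shift(x, cfg)
  if (en[["env_noise"]]) x <- env_noise_augment(x, pool, cfg)
  if (en[["gaussian"]]) x <- add_gaussian_noise(x, cfg)
  if (en[["amplitude"]]) x <- vary_amplitude(x, cfg)
  x
}

#' Augment a whole training set for one training pass
#'
#' Runs [compose_augmentations()] on every epoch with stream
#' `(cfg$seed, pass, i)`, regenerating the training set afresh for the
#' given pass.
#'
#' @param x a [wb_epochs()] training set.
#' @param pool a [noise_pool()] or `NULL`.
#' @param cfg an [aug_config()].
#' @param pass training-pass index (1-based).
#' @return A [wb_epochs()] of the same size and labels.
#' @export
augment_set <- function(x, pool, cfg, pass = 1L) {
  out <- x
  for (i in seq_len(n_epochs(x))) {
    a <- compose_augmentations(x[i], pool, cfg, pass = pass, index = i)
    out$samples[i, ] <- a$samples[1L, ]
    out$info$is_noisy[i] <- a$info$is_noisy[1L]
    out$info$gain[i] <- a$info$gain[1L]
  }
  out
}
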