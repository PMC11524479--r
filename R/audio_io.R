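#' @useDynLib wingbeatr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft rnorm runif sd
#' @importFrom utils read.csv write.csv head
"_PACKAGE"

# Species / sex label space. Class indices are fixed alphabetically by
# species, female before male, and never change between runs.
WB_SPECIES <- c("Ae_aegypti", "Ae_albopictus", "An_dirus", "Cx_quinquefasciatus")
WB_SEXES <- c("F", "M")

#' Fixed class index for a species/sex pair
#'
#' Classes are indexed 0..7 alphabetically by species with female before
#' male: Ae. aegypti F=0, M=1; Ae. albopictus F=2, M=3; An. dirus F=4, M=5;
#' Cx. quinquefasciatus F=6, M=7.
#'
#' @param species character vector drawn from
#'   `c("Ae_aegypti", "Ae_albopictus", "An_dirus", "Cx_quinquefasciatus")`.
#' @param sex character vector of `"F"` or `"M"`.
#' @return Integer class indices in 0..7.
#' @export
class_index <- function(species, sex) {
  si <- match(species, WB_SPECIES)
  xi <- match(sex, WB_SEXES)
  if (anyNA(si)) stop("unknown species: ", paste(setdiff(species, WB_SPECIES), collapse = ", "))
  if (anyNA(xi)) stop("unknown sex: ", paste(setdiff(sex, WB_SEXES), collapse = ", "))
  as.integer((si - 1L) * 2L + (xi - 1L))
}

#' Construct an audio recording
#'
#' A mono, real-valued waveform with its sample rate and the metadata used
#' downstream for labeling and chronological fold splitting.
#'
#' @param samples numeric vector of amplitudes, nominally in `[-1, 1]`.
#' @param sample_rate positive integer, Hz.
#' @param species,sex optional labels (see [class_index()]); `NA` for noise.
#' @param source_id opaque identifier of the source recording.
#' @param recorded_at timestamp or monotone ordinal used for chronological
#'   ordering; ties are broken by `source_id`.
#' @return An object of class `wb_recording`.
#' @export
wb_recording <- function(samples, sample_rate, species = NA_character_,
                         sex = NA_character_, source_id = "rec",
                         recorded_at = 0) {
  stopifnot(is.numeric(samples), length(sample_rate) == 1L, sample_rate > 0)
  if (!is.null(dim(samples))) stop("samples must be a mono (one-dimensional) vector")
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.integer(sample_rate),
                 species = species, sex = sex,
                 source_id = as.character(source_id),
                 recorded_at = as.numeric(recorded_at)),
            class = "wb_recording")
}

#' @export
print.wb_recording <- function(x, ...) {
  cat(sprintf("<wb_recording> %s: %d samples @ %d Hz (%.2f s), species=%s sex=%s\n",
              x$source_id, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              x$species, x$sex))
  invisible(x)
}

# ---- WAV I/O (RIFF PCM; 16/24-bit read, 16-bit write) -----------------------

#' Read a PCM WAV file
#'
#' Reads a mono RIFF PCM WAV file (16- or 24-bit integer) and scales samples
#' to `[-1, 1]` by the format's full-scale value. Stereo or multi-channel
#' files are rejected rather than downmixed, since all supported recording
#' setups are single-microphone and silent downmixing would hide data errors.
#'
#' @param path path to a `.wav` file.
#' @return A [wb_recording()] with metadata unset (populate from a manifest).
#' @export
load_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz + (sz %% 2L))
      fmt <- list(
        audio_format = sum(as.integer(raw[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(raw[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + (sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("corrupt WAV (missing fmt/data chunk): ", path)
  if (fmt$audio_format != 1L) stop("only PCM WAV supported (format tag ", fmt$audio_format, ")")
  if (fmt$n_channels != 1L)
    stop("multi-channel WAV not supported (", fmt$n_channels, " channels); no silent downmix")
  if (fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n = length(data_raw) %/% 2L, size = 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$bits == 24L) {
    b <- as.integer(data_raw)
    n <- length(b) %/% 3L
    b <- b[seq_len(n * 3L)]
    v <- b[seq(1, by = 3, length.out = n)] +
         b[seq(2, by = 3, length.out = n)] * 256 +
         b[seq(3, by = 3, length.out = n)] * 65536
    v[v >= 8388608] <- v[v >= 8388608] - 16777216
    x <- v / 8388608
  } else stop("unsupported bit depth: ", fmt$bits)
  wb_recording(x, fmt$sample_rate, source_id = basename(path))
}

#' Write a recording (or raw vector) as 16-bit PCM WAV
#'
#' Samples outside `[-1, 1]` are clipped before quantization; 16-bit export
#' cannot represent values beyond full scale.
#'
#' @param x a [wb_recording()] or numeric vector.
#' @param path output path.
#' @param sample_rate sample rate when `x` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sample_rate = 8000L) {
  if (inherits(x, "wb_recording")) { sample_rate <- x$sample_rate; x <- x$samples }
  x <- pmin(1 - 2^-15, pmax(-1, x))
  pcm <- as.integer(round(x * 32768))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16L), con, size = 4, endian = "little")
  writeBin(as.integer(c(1L, 1L)), con, size = 2, endian = "little")  # PCM, mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(as.integer(c(2L, 16L)), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

# ---- Standardization --------------------------------------------------------

#' Quantize amplitudes to the 16-bit grid (step 2^-15), keeping real storage
#' @param x numeric vector.
#' @return numeric vector rounded to multiples of 2^-15.
#' @export
quantize16 <- function(x) round(x * 32768) / 32768

#' Standardize a recording to the model sample rate
#'
#' Downsamples to `target_rate` with polyphase anti-aliased resampling and
#' simulates 16-bit depth by rounding amplitudes to a `2^-15` grid (stored
#' as reals). A recording already at `target_rate` is only quantized.
#' Upsampling is refused.
#'
#' @param rec a [wb_recording()].
#' @param target_rate target sample rate in Hz (default 8000).
#' @return A standardized [wb_recording()].
#' @export
standardize <- function(rec, target_rate = 8000L) {
  stopifnot(inherits(rec, "wb_recording"))
  if (rec$sample_rate < target_rate)
    stop("upsampling not supported (", rec$sample_rate, " -> ", target_rate, " Hz)")
  if (rec$sample_rate == target_rate) {
    rec$samples <- quantize16(rec$samples)
    return(rec)
  }
  n_out <- round(length(rec$samples) * target_rate / rec$sample_rate)
  g <- gcd_int(target_rate, rec$sample_rate)
  y <- signal::resample(rec$samples, target_rate / g, rec$sample_rate / g)
  # polyphase output length can differ by a sample; enforce the exact ratio
  if (length(y) >= n_out) y <- y[seq_len(n_out)] else y <- c(y, numeric(n_out - length(y)))
  rec$samples <- quantize16(y)
  rec$sample_rate <- as.integer(target_rate)
  rec
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Group-wise peak normalization
#'
#' Divides every sample by the maximum absolute amplitude of its group so
#' the full 16-bit range can be used without clipping. With
#' `scope = "global"` the group is the whole list (one recording setup);
#' with `scope = "per_species"` each species is normalized by its own peak
#' (heterogeneous collections).
#'
#' @param recs list of [wb_recording()].
#' @param scope `"global"` or `"per_species"`.
#' @return The list with samples rescaled; each group's max |amplitude| is 1.
#' @export
normalize_group <- function(recs, scope = c("global", "per_species")) {
  scope <- match.arg(scope)
  stopifnot(length(recs) > 0, all(vapply(recs, inherits, TRUE, "wb_recording")))
  keys <- if (scope == "global") rep("all", length(recs))
          else vapply(recs, function(r) as.character(r$species), "")
  for (k in unique(keys)) {
    idx <- which(keys == k)
    peak <- max(vapply(recs[idx], function(r) max(abs(r$samples), 0), 0))
    if (peak == 0) stop("degenerate group (all-zero samples): ", k)
    for (i in idx) recs[[i]]$samples <- recs[[i]]$samples / peak
  }
  recs
}

# ---- Epoch container --------------------------------------------------------

#' Construct an epoch set
#'
#' Fixed-length raw-waveform windows stored as the rows of a matrix, with a
#' parallel metadata frame. This is the unit the classifier consumes: at the
#' defaults (0.3 s at 8000 Hz) each row has exactly 2400 samples.
#'
#' @param samples numeric matrix, one epoch per row.
#' @param label integer class per epoch (0-based) or `NA`.
#' @param is_noisy logical per epoch; has a noise overlay been applied?
#' @param gain gain factor applied to the wingbeat component, or `NA`.
#' @param source_id,offset,recorded_at provenance columns.
#' @return An object of class `wb_epochs`.
#' @export
wb_epochs <- function(samples, label = NA_integer_, is_noisy = FALSE,
                      gain = NA_real_, source_id = NA_character_,
                      offset = NA_integer_, recorded_at = NA_real_) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1L)
  n <- nrow(samples)
  info <- data.frame(label = rep_len(as.integer(label), n),
                     is_noisy = rep_len(is_noisy, n),
                     gain = rep_len(as.numeric(gain), n),
                     source_id = rep_len(as.character(source_id), n),
                     offset = rep_len(as.integer(offset), n),
                     recorded_at = rep_len(as.numeric(recorded_at), n))
  structure(list(samples = samples, info = info), class = "wb_epochs")
}

#' Number of epochs in a set
#' @param x a `wb_epochs` object.
#' @return integer count.
#' @export
n_epochs <- function(x) nrow(x$samples)

#' @export
print.wb_epochs <- function(x, ...) {
  cat(sprintf("<wb_epochs> %d epochs x %d samples; %d labeled, %d noisy\n",
              n_epochs(x), ncol(x$samples), sum(!is.na(x$info$label)),
              sum(x$info$is_noisy)))
  invisible(x)
}

#' Subset an epoch set
#' @param x a `wb_epochs` object.
#' @param i row (epoch) indices.
#' @param ... unused.
#' @return A `wb_epochs` with the selected epochs.
#' @export
`[.wb_epochs` <- function(x, i, ...) {
  structure(list(samples = x$samples[i, , drop = FALSE],
                 info = x$info[i, , drop = FALSE]),
            class = "wb_epochs")
}

#' Concatenate epoch sets
#' @param ... `wb_epochs` objects with equal epoch length.
#' @return A single `wb_epochs`.
#' @export
bind_epochs <- function(...) {
  xs <- list(...)
  xs <- xs[vapply(xs, n_epochs, 0L) > 0L]
  if (length(xs) == 0L) return(wb_epochs(matrix(numeric(0), 0, 0)))
  structure(list(samples = do.call(rbind, lapply(xs, `[[`, "samples")),
                 info = do.call(rbind, lapply(xs, `[[`, "info"))),
            class = "wb_epochs")
}

#' Segment a standardized recording into fixed-length epochs
#'
#' Slides a window of `epoch_s` seconds with hop `epoch_s - overlap_s` over
#' the recording. Epoch `i` covers samples `[i*hop, i*hop + W)`; a trailing
#' partial window is dropped because the classifier requires a fixed input
#' length. Labels and provenance are inherited from the recording.
#'
#' @param rec a [wb_recording()] standardized to 8000 Hz.
#' @param epoch_s window length in seconds (default 0.3).
#' @param overlap_s overlap between consecutive windows in seconds
#'   (default 0.15); must satisfy `0 < overlap_s < epoch_s`.
#' @return A [wb_epochs()] (possibly with zero rows for short recordings).
#' @export
segment_epochs <- function(rec, epoch_s = 0.3, overlap_s = 0.15) {
  stopifnot(inherits(rec, "wb_recording"), overlap_s > 0, overlap_s < epoch_s)
  fs <- rec$sample_rate
  W <- round(epoch_s * fs)
  hop <- round((epoch_s - overlap_s) * fs)
  n <- length(rec$samples)
  count <- if (n >= W) (n - W) %/% hop + 1L else 0L
  if (count == 0L)
    return(wb_epochs(matrix(numeric(0), 0L, W)))
  starts <- (seq_len(count) - 1L) * hop
  m <- t(vapply(starts, function(s) rec$samples[(s + 1L):(s + W)], numeric(W)))
  lab <- if (!is.na(rec$species) && !is.na(rec$sex) && rec$sex %in% WB_SEXES)
    class_index(rec$species, rec$sex) else NA_integer_
  wb_epochs(m, label = lab, source_id = rec$source_id, offset = starts,
            recorded_at = rec$recorded_at)
}

# ---- Manifests --------------------------------------------------------------

#' Read a recording manifest
#'
#' The manifest CSV has columns `path, species, sex, source_id, recorded_at`
#' (UTF-8, header required). Paths are resolved relative to the manifest's
#' directory unless absolute.
#'
#' @param path manifest CSV path.
#' @param load if `TRUE`, load each WAV and attach metadata.
#' @return If `load`, a list of [wb_recording()]; otherwise the manifest
#'   data frame.
#' @export
read_manifest <- function(path, load = TRUE) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "species", "sex", "source_id", "recorded_at")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (!load) return(man)
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    rec <- load_wav(p)
    rec$species <- man$species[i]
    rec$sex <- man$sex[i]
    rec$source_id <- man$source_id[i]
    rec$recorded_at <- as.numeric(man$recorded_at[i])
    rec
  })
}
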