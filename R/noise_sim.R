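# Additive noise-overlay simulation: a noisy wingbeat epoch is
# g * wingbeat + noise, where g (the gain factor) models the distance of
# the mosquito from the microphone. Output is deliberately NOT clipped to
# [-1, 1]: the overlay is pure addition and clipping would distort the
# training distribution. Clip only when exporting to 16-bit WAV.

#' Build a noise pool
#'
#' An indexed collection of environmental noise recordings (fan, vehicles,
#' animals, human activity, ...) from which overlay segments are drawn.
#' All recordings must be standardized to 8000 Hz and at least one epoch
#' window long to be eligible; they carry no species/sex labels.
#'
#' @param recordings list of [wb_recording()] noise recordings.
#' @param category character vector, one free-form category per recording.
#' @param partition_tag `"train"`, `"val"` or `"test"`; pools for different
#'   partitions must not share source recordings.
#' @param window_len epoch window length in samples (default 2400).
#' @return An object of class `wb_noise_pool`.
#' @export
noise_pool <- function(recordings, category = "unknown",
                       partition_tag = c("train", "val", "test"),
                       window_len = 2400L) {
  partition_tag <- match.arg(partition_tag)
  stopifnot(all(vapply(recordings, inherits, TRUE, "wb_recording")))
  rates <- vapply(recordings, `[[`, 0L, "sample_rate")
  if (any(rates != 8000L)) stop("noise pool recordings must be standardized to 8000 Hz")
  structure(list(recordings = recordings,
                 category = rep_len(as.character(category), length(recordings)),
                 partition_tag = partition_tag,
                 window_len = as.integer(window_len)),
            class = "wb_noise_pool")
}

pool_eligible <- function(pool) {
  which(vapply(pool$recordings, function(r) length(r$samples), 0L) >= pool$window_len)
}

#' @export
print.wb_noise_pool <- function(x, ...) {
  cat(sprintf("<wb_noise_pool> %d recordings (%d eligible), partition=%s\n",
              length(x$recordings), length(pool_eligible(x)), x$partition_tag))
  invisible(x)
}

#' Overlay noise onto a wingbeat epoch
#'
#' Computes `g * x_w + x_n` elementwise. The label is inherited from the
#' wingbeat epoch; the result is marked noisy and records the gain. No
#' clipping is applied, so values may leave `[-1, 1]`.
#'
#' @param x_w wingbeat epoch set ([wb_epochs()]) or numeric vector/matrix.
#' @param x_n noise epoch(s) of identical shape.
#' @param g positive gain factor applied to the wingbeat before addition.
#' @return An object matching `x_w`'s type with the mixed samples.
#' @export
overlay <- function(x_w, x_n, g = 1) {
  stopifnot(g > 0)
  ns <- if (inherits(x_n, "wb_epochs")) x_n$samples else x_n
  ws <- if (inherits(x_w, "wb_epochs")) x_w$samples else x_w
  if (is.null(dim(ws))) ws <- matrix(ws, nrow = 1L)
  if (is.null(dim(ns))) ns <- matrix(ns, nrow = 1L)
  if (!identical(dim(ws), dim(ns)))
    stop("shape mismatch between wingbeat and noise epochs")
  mixed <- g * ws + ns
  if (inherits(x_w, "wb_epochs")) {
    out <- x_w
    out$samples <- mixed
    out$info$is_noisy <- TRUE
    out$info$gain <- g
    return(out)
  }
  if (is.null(dim(x_w))) drop(mixed) else mixed
}

#' Sample one noise epoch from a pool
#'
#' Draws a contiguous window from a uniformly chosen eligible recording at
#' a uniformly chosen valid start offset. Reproducible under a fixed R
#' random seed.
#'
#' @param pool a [noise_pool()].
#' @param n number of epochs to draw (with replacement across draws).
#' @return A [wb_epochs()] with `n` rows of pure noise.
#' @export
sample_noise_epoch <- function(pool, n = 1L) {
  el <- pool_eligible(pool)
  if (length(el) == 0L)
    stop("empty or ineligible noise pool (no recording >= ", pool$window_len, " samples)")
  W <- pool$window_len
  ri <- el[sample.int(length(el), n, replace = TRUE)]
  m <- matrix(0, n, W)
  starts <- integer(n); src <- character(n)
  for (j in seq_len(n)) {
    r <- pool$recordings[[ri[j]]]
    s <- sample.int(length(r$samples) - W + 1L, 1L) - 1L
    m[j, ] <- r$samples[(s + 1L):(s + W)]
    starts[j] <- s; src[j] <- r$source_id
  }
  wb_epochs(m, is_noisy = TRUE, source_id = src, offset = starts)
}

#' Build a noisy evaluation set at a fixed gain
#'
#' For each input epoch, emits one noise-overlaid copy (`g * x + noise`)
#' and, when `keep_clean` is `TRUE`, also the unmodified original, so the
#' evaluation set contains wingbeats both with and without background
#' noise (doubling the set size). Noise segments are drawn without
#' replacement from the pool's window-aligned segments when the pool is
#' large enough; otherwise with replacement and a warning.
#'
#' @param epochs labeled [wb_epochs()] to evaluate on.
#' @param pool a [noise_pool()]; its `partition_tag` should match the
#'   evaluation split so train and test noise never overlap.
#' @param g gain factor (the protocol uses 1, 1.5 and 2).
#' @param keep_clean keep the clean originals alongside the noisy copies.
#' @return A [wb_epochs()] with `2n` (or `n`) rows.
#' @export
build_noisy_eval_set <- function(epochs, pool, g = 1, keep_clean = TRUE) {
  n <- n_epochs(epochs)
  if (n == 0L) return(epochs)
  W <- pool$window_len
  el <- pool_eligible(pool)
  if (length(el) == 0L)
    stop("empty or ineligible noise pool (no recording >= ", W, " samples)")
  # enumerate window-aligned segments for without-replacement sampling
  seg_rec <- integer(0); seg_start <- integer(0)
  for (i in el) {
    k <- length(pool$recordings[[i]]$samples) %/% W
    seg_rec <- c(seg_rec, rep(i, k))
    seg_start <- c(seg_start, (seq_len(k) - 1L) * W)
  }
  if (length(seg_rec) >= n) {
    pick <- sample.int(length(seg_rec), n)
    m <- matrix(0, n, W)
    for (j in seq_len(n)) {
      r <- pool$recordings[[seg_rec[pick[j]]]]
      s <- seg_start[pick[j]]
      m[j, ] <- r$samples[(s + 1L):(s + W)]
    }
    noise <- wb_epochs(m, is_noisy = TRUE)
  } else {
    warning("noise pool smaller than evaluation set; sampling noise with replacement")
    noise <- sample_noise_epoch(pool, n)
  }
  noisy <- epochs
  noisy$samples <- g * epochs$samples + noise$samples
  noisy$info$is_noisy <- TRUE
  noisy$info$gain <- g
  if (keep_clean) bind_epochs(epochs, noisy) else noisy
}

#' Export an evaluation set as 16-bit WAV epochs plus a CSV index
#'
#' Each epoch is written as one WAV file (clipped to full scale, as 16-bit
#' export requires) and indexed by `epoch_id, label, is_noisy, gain`.
#'
#' @param epochs a [wb_epochs()].
#' @param dir output directory (created if needed).
#' @param sample_rate sample rate written to the WAV headers.
#' @return The index data frame, invisibly.
#' @export
export_eval_set <- function(epochs, dir, sample_rate = 8000L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_epochs(epochs)
  ids <- sprintf("epoch_%05d", seq_len(n))
  for (i in seq_len(n))
    write_wav(epochs$samples[i, ], file.path(dir, paste0(ids[i], ".wav")), sample_rate)
  idx <- data.frame(epoch_id = ids, label = epochs$info$label,
                    is_noisy = epochs$info$is_noisy, gain = epochs$info$gain)
  write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(idx)
}

#' Read a noise-pool manifest
#'
#' CSV columns: `path, category, partition_tag`. All recordings are loaded,
#' standardized to 8000 Hz and assembled into one pool per partition tag.
#'
#' @param path manifest CSV path.
#' @param window_len epoch window length in samples.
#' @return A named list of [noise_pool()]s, one per partition tag present.
#' @export
read_noise_manifest <- function(path, window_len = 2400L) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "category", "partition_tag")
  if (!all(need %in% names(man)))
    stop("noise manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(path)
  recs <- lapply(man$path, function(p) {
    if (!file.exists(p)) p <- file.path(base, p)
    standardize(load_wav(p))
  })
  out <- list()
  for (tag in unique(man$partition_tag)) {
    i <- man$partition_tag == tag
    out[[tag]] <- noise_pool(recs[i], man$category[i], tag, window_len)
  }
  out
}
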