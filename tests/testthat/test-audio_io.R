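test_that("WAV round trip preserves samples to within one quantization step", {
  # zero signal at an arbitrary rate
  p <- write_pcm16(integer(4800), 96000)
  rec <- load_wav(p)
  expect_s3_class(rec, "wb_recording")
  expect_length(rec$samples, 4800)
  expect_identical(rec$sample_rate, 96000L)
  expect_true(all(rec$samples == 0))

  # full-scale positive samples map to ~1.0
  p <- write_pcm16(rep(32767L, 100), 8000)
  rec <- load_wav(p)
  expect_true(all(abs(rec$samples - 32767 / 32768) < 1e-12))

  # arbitrary quantized signal survives write/read exactly
  x <- quantize16(runif(2400, -0.9, 0.9))
  p <- tempfile(fileext = ".wav")
  write_wav(x, p, 8000)
  expect_true(max(abs(load_wav(p)$samples - x)) <= 2^-15)
})

test_that("stereo WAV is rejected rather than downmixed", {
  # build a 2-channel WAV by hand
  p <- tempfile(fileext = ".wav")
  con <- file(p, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + 8L, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 2L), con, size = 2, endian = "little")
  writeBin(8000L, con, size = 4, endian = "little")
  writeBin(32000L, con, size = 4, endian = "little")
  writeBin(c(4L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(8L, con, size = 4, endian = "little")
  writeBin(integer(4), con, size = 2, endian = "little")
  close(con)
  expect_error(load_wav(p), "multi-channel")
  expect_error(load_wav(tempfile()), "not found")
})

test_that("standardize resamples to 8 kHz with the exact length ratio", {
  set.seed(11)
  rec <- wb_recording(rnorm(96000) / 5, 96000)
  out <- standardize(rec)
  expect_identical(out$sample_rate, 8000L)
  expect_length(out$samples, round(96000 * 8000 / 96000))

  # non-integer ratio (44.1 kHz) also honors round(n * target / rate)
  rec2 <- wb_recording(rnorm(44100) / 5, 44100)
  out2 <- standardize(rec2)
  expect_length(out2$samples, round(44100 * 8000 / 44100))

  # identity rate: only quantization
  rec3 <- wb_recording(runif(100, -0.5, 0.5), 8000)
  out3 <- standardize(rec3)
  expect_identical(out3$samples, quantize16(rec3$samples))

  expect_error(standardize(wb_recording(rnorm(10), 4000)), "upsampling")
})

test_that("a 512 Hz tone survives 96 kHz -> 8 kHz downsampling", {
  t <- (0:95999) / 96000
  rec <- wb_recording(0.8 * sin(2 * pi * 512 * t), 96000)
  out <- standardize(rec)
  spec <- abs(fft(out$samples))[1:4000]
  peak_hz <- (which.max(spec) - 1) * 8000 / length(out$samples)
  expect_lt(abs(peak_hz - 512), 5)
})

test_that("standardize is idempotent in rate and length", {
  set.seed(12)
  rec <- standardize(wb_recording(rnorm(48000) / 4, 48000))
  again <- standardize(rec)
  expect_identical(again$sample_rate, rec$sample_rate)
  expect_length(again$samples, length(rec$samples))
  expect_identical(again$samples, rec$samples)  # quantization is idempotent too
})

test_that("normalize_group scales each scope group to unit peak", {
  r1 <- wb_recording(c(0.5, -0.25), 8000, species = "Ae_aegypti", sex = "F")
  r2 <- wb_recording(c(0.1, 0.4), 8000, species = "Ae_aegypti", sex = "F")
  out <- normalize_group(list(r1, r2), "global")
  expect_equal(max(abs(unlist(lapply(out, `[[`, "samples")))), 1.0)
  expect_equal(out[[1]]$samples, c(1, -0.5))  # everything doubled

  # per-species: A peak 0.5 -> x2, B peak 0.25 -> x4
  a <- wb_recording(c(0.5, 0.1), 8000, species = "Ae_aegypti", sex = "F")
  b <- wb_recording(c(0.25, 0.05), 8000, species = "An_dirus", sex = "F")
  out2 <- normalize_group(list(a, b), "per_species")
  expect_equal(out2[[1]]$samples, c(1, 0.2))
  expect_equal(out2[[2]]$samples, c(1, 0.2))

  # idempotence
  out3 <- normalize_group(out2, "per_species")
  expect_identical(lapply(out3, `[[`, "samples"), lapply(out2, `[[`, "samples"))

  expect_error(normalize_group(list(wb_recording(numeric(5), 8000)), "global"),
               "degenerate")
})

test_that("segmentation matches the count law and a brute-force enumerator", {
  # spec'd cases
  rec <- wb_recording(quantize16(runif(4800, -0.5, 0.5)), 8000)
  eps <- segment_epochs(rec)
  expect_identical(n_epochs(eps), 3L)
  expect_identical(eps$info$offset, c(0L, 1200L, 2400L))
  expect_identical(ncol(eps$samples), 2400L)

  expect_identical(n_epochs(segment_epochs(wb_recording(runif(2400), 8000))), 1L)
  expect_identical(n_epochs(segment_epochs(wb_recording(runif(2399), 8000))), 0L)

  # property: count and contents match a sliding-window enumerator for many n
  brute <- function(x, W, hop) {
    out <- list(); s <- 0L
    while (s + W <= length(x)) { out[[length(out) + 1L]] <- x[(s + 1):(s + W)]; s <- s + hop }
    out
  }
  set.seed(21)
  for (n in c(0L, 1L, 2399L, 2400L, 2401L, 3600L, 4800L, 7201L, sample(5000:20000, 4))) {
    x <- quantize16(runif(n, -0.5, 0.5))
    eps <- segment_epochs(wb_recording(x, 8000))
    ref <- brute(x, 2400L, 1200L)
    expect_identical(n_epochs(eps), length(ref))
    for (j in seq_along(ref)) expect_equal(eps$samples[j, ], ref[[j]])
  }
})

test_that("epochs inherit the fixed alphabetical class indexing", {
  expect_identical(class_index("Ae_aegypti", "F"), 0L)
  expect_identical(class_index("Cx_quinquefasciatus", "M"), 7L)
  expect_identical(class_index(c("Ae_albopictus", "An_dirus"), c("M", "F")), c(3L, 4L))
  expect_error(class_index("Ae_aegypti", "X"), "unknown sex")
  rec <- wb_recording(runif(2400), 8000, species = "An_dirus", sex = "M")
  expect_identical(segment_epochs(rec)$info$label, 5L)
})

test_that("manifest CSV round trips recordings with metadata", {
  dir <- tempfile(); dir.create(dir)
  x <- quantize16(runif(2400, -0.5, 0.5))
  write_wav(x, file.path(dir, "a.wav"), 8000)
  write.csv(data.frame(path = "a.wav", species = "Ae_aegypti", sex = "F",
                       source_id = "a", recorded_at = 3),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  recs <- read_manifest(file.path(dir, "manifest.csv"))
  expect_length(recs, 1)
  expect_identical(recs[[1]]$species, "Ae_aegypti")
  expect_identical(recs[[1]]$recorded_at, 3)
  expect_error(read_manifest({
    f <- tempfile(fileext = ".csv")
    write.csv(data.frame(path = "a.wav"), f, row.names = FALSE)
    f
  }), "columns")
})
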