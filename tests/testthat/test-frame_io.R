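test_that("MRC reader round-trips fixture files bit-exactly", {
  set.seed(11)
  frames <- lapply(1:3, function(i) matrix(sample(-5:10, 24, TRUE), 4, 6))
  path <- withr::local_tempfile(fileext = ".mrc")
  oracle_write_mrc(frames, path, mode = 1L)
  st <- read_mrc_stack(path)
  expect_equal(st$n_frames, 3L)
  expect_equal(st$frame_shape, c(4L, 6L))
  for (i in 1:3) expect_equal(get_frame(st, i), frames[[i]] + 0)

  # extended header of junk bytes is skipped per NSYMBT
  path2 <- withr::local_tempfile(fileext = ".mrc")
  oracle_write_mrc(frames, path2, mode = 1L, nsymbt = 128L)
  st2 <- read_mrc_stack(path2)
  expect_identical(st2$pixels, st$pixels)

  # float mode preserves non-integral and negative values
  fr <- list(matrix(c(-1.5, 0.25, 3.75, 2), 2, 2))
  path3 <- withr::local_tempfile(fileext = ".mrc")
  oracle_write_mrc(fr, path3, mode = 2L)
  expect_equal(get_frame(read_mrc_stack(path3), 1), fr[[1]])
})

test_that("MRC reader rejects malformed input", {
  empty <- withr::local_tempfile(fileext = ".mrc")
  file.create(empty)
  expect_error(read_mrc_stack(empty), "header")
  bad <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw(2048), bad)
  expect_error(read_mrc_stack(bad), "MAP")
  # unsupported mode named in the error
  path <- withr::local_tempfile(fileext = ".mrc")
  oracle_write_mrc(list(matrix(0L, 2, 2)), path, mode = 1L)
  r <- readBin(path, "raw", file.size(path))
  r[13:16] <- writeBin(12L, raw(), size = 4L, endian = "little")
  writeBin(r, path)
  expect_error(read_mrc_stack(path), "mode 12")
})

test_that("package MRC writer agrees with the independent reader path", {
  set.seed(12)
  px <- array(sample(-100:100, 4 * 6 * 2, TRUE), dim = c(4, 6, 2))
  path <- withr::local_tempfile(fileext = ".mrc")
  write_mrc_stack(frame_stack(px), path)
  expect_equal(read_mrc_stack(path)$pixels, px + 0)
  # non-integral data falls back to float32
  pxf <- px + 0.5
  write_mrc_stack(frame_stack(pxf), path)
  expect_equal(read_mrc_stack(path)$pixels, pxf, tolerance = 1e-6)
})

test_that("SER reader round-trips oracle-written series", {
  f1 <- matrix(c(-5L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L), 3, 4)
  f2 <- f1 + 100L
  path <- withr::local_tempfile(fileext = ".ser")
  oracle_write_ser(list(f1, f2), path, dtype = 5L)
  st <- read_ser_series(path)
  expect_equal(st$n_frames, 2L)
  expect_equal(get_frame(st, 1), f1 + 0)
  expect_equal(get_frame(st, 2), f2 + 0)

  # float32 payload preserves -1.5
  ff <- matrix(c(-1.5, 0, 2.25, 7), 2, 2)
  oracle_write_ser(list(ff), path, dtype = 7L)
  expect_equal(get_frame(read_ser_series(path), 1), ff, tolerance = 1e-7)
})

test_that("SER reader rejects corrupt input instead of short-reading", {
  f1 <- matrix(1:16, 4, 4)
  path <- withr::local_tempfile(fileext = ".ser")
  oracle_write_ser(list(f1), path)
  r <- readBin(path, "raw", file.size(path))
  writeBin(r[1:80], path)                       # truncate inside the payload
  expect_error(read_ser_series(path), "truncat|corrupt")
  bad <- withr::local_tempfile(fileext = ".ser")
  writeBin(raw(64), bad)
  expect_error(read_ser_series(bad), "magic")
})

test_that("reader equivalence: the same frame through MRC and SER", {
  set.seed(13)
  fr <- matrix(sample(-20:500, 35, TRUE), 5, 7)
  p1 <- withr::local_tempfile(fileext = ".mrc")
  p2 <- withr::local_tempfile(fileext = ".ser")
  oracle_write_mrc(list(fr), p1)
  oracle_write_ser(list(fr), p2)
  expect_identical(read_mrc_stack(p1)$pixels, read_ser_series(p2)$pixels)
})

test_that("pedestal policy clips and accounts per the examples", {
  st <- frame_stack(matrix(c(-3, 0, 5), 1, 3))
  res <- apply_pedestal(st, 8)
  expect_equal(as.vector(res$stack$pixels), c(5, 8, 13))
  expect_equal(res$clipped_fractions, 0)

  st2 <- frame_stack(matrix(c(-10, -8, 7), 1, 3))
  res2 <- apply_pedestal(st2, 8)
  expect_equal(as.vector(res2$stack$pixels), c(0, 0, 15))
  expect_equal(res2$clipped_fractions, 2 / 3)

  expect_error(apply_pedestal(st, -1), ">= 0")
})

test_that("pedestal properties: conservation, monotonicity, brute-force count", {
  set.seed(14)
  px <- array(rnorm(32 * 32 * 4, mean = 5, sd = 6), dim = c(32, 32, 4))
  st <- frame_stack(px)
  for (ped in c(0, 2, 8, 20)) {
    res <- apply_pedestal(st, ped)
    oracle <- apply(px <= -ped, 3, mean)        # elementwise scan
    expect_equal(res$clipped_fractions, as.numeric(oracle))
    expect_true(all(res$stack$pixels >= 0))
  }
  # monotone: larger pedestal never clips more
  cf <- sapply(c(0, 2, 8, 20), function(p) max(apply_pedestal(st, p)$clipped_fractions))
  expect_true(all(diff(cf) <= 0))
  # conservation when nothing clips
  big <- ceiling(-min(px)) + 1
  res <- apply_pedestal(st, big)
  expect_equal(sum(res$stack$pixels), sum(px) + big * length(px))
})

test_that("SMV header derivation follows the geometry", {
  geom <- falcon_geom()
  cfg <- conversion_config(pedestal = 8, distance_mm = 2380,
                           oscillation_start_deg = -30,
                           oscillation_per_frame_deg = 0.45)
  h0 <- build_smv_header(geom, cfg, 0L)
  expect_equal(as.numeric(h0[["WAVELENGTH"]]), 0.025079, tolerance = 1e-4)
  expect_equal(as.numeric(h0[["OSC_START"]]), -30)
  expect_equal(as.numeric(h0[["OSC_RANGE"]]), 0.45)
  expect_equal(as.numeric(h0[["PIXEL_SIZE"]]), 0.028)
  h5 <- build_smv_header(geom, cfg, 5L)
  expect_equal(as.numeric(h5[["OSC_START"]]), -30 + 5 * 0.45)
  # user overrides win
  cfg2 <- conversion_config(pedestal = 8, distance_mm = 2380,
                            user_overrides = list(DISTANCE = "999.5"))
  expect_equal(build_smv_header(geom, cfg2, 0L)[["DISTANCE"]], "999.5")
  # missing distance instructs the user to supply it
  expect_error(build_smv_header(geom, conversion_config(pedestal = 8), 0L),
               "specified by the user")
})

test_that("SMV write/read round-trips with clamping, property-style", {
  geom <- toy_geom(8)
  cfg <- conversion_config(pedestal = 0, distance_mm = 650)
  header <- build_smv_header(geom, cfg, 0L)
  path <- withr::local_tempfile(fileext = ".img")

  fr <- matrix(c(0, 65535, 1, 2), 2, 2)
  write_smv(fr, header, path)
  rt <- read_smv(path)
  expect_equal(rt$frame, fr)
  expect_equal(file.size(path), 512 + 2 * 4)
  # header block is exactly HEADER_BYTES and starts with "{"
  expect_equal(as.integer(rt$header[["HEADER_BYTES"]]), 512L)
  expect_equal(rawToChar(readBin(path, "raw", 1)), "{")

  res <- write_smv(matrix(c(70000, 1, 2, 3), 2, 2), header, path)
  expect_equal(res$saturated_count, 1)
  expect_equal(read_smv(path)$frame[1, 1], 65535)

  expect_error(write_smv(matrix(c(-1, 0, 1, 2), 2, 2), header, path),
               "non-negative")

  set.seed(15)
  for (rep in 1:5) {
    nr <- sample(2:9, 1); nc <- sample(2:9, 1)
    fr <- matrix(sample(0:65535, nr * nc, TRUE), nr, nc)
    g <- acquisition_geometry(200, 650, frame_shape = c(nr, nc))
    write_smv(fr, build_smv_header(g, cfg, 0L), path)
    rt <- read_smv(path)
    expect_identical(rt$frame, fr + 0)
    expect_equal(as.integer(rt$header[["SIZE1"]]), nc)
    expect_equal(as.integer(rt$header[["SIZE2"]]), nr)
  }
})

test_that("convert_dataset writes one SMV per frame, deterministically", {
  set.seed(16)
  frames <- lapply(1:3, function(i) matrix(sample(-10:100, 64, TRUE), 8, 8))
  mrc <- withr::local_tempfile(fileext = ".mrc")
  oracle_write_mrc(frames, mrc)
  geom <- toy_geom(8)
  cfg <- conversion_config(pedestal = 8, distance_mm = 650,
                           oscillation_start_deg = 30,
                           oscillation_per_frame_deg = -0.45)
  out1 <- withr::local_tempdir()
  rep1 <- convert_dataset(mrc, geom, cfg, out1)
  expect_equal(rep1$frames_written, 3L)
  expect_equal(basename(rep1$paths), sprintf("frame_%03d.img", 1:3))
  expect_true(all(file.exists(rep1$paths)))
  expect_length(rep1$clipped_fraction_per_frame, 3L)
  # pedestal-policy equivalence with apply_pedestal on the same stack
  ap <- apply_pedestal(read_mrc_stack(mrc), 8)
  expect_equal(rep1$clipped_fraction_per_frame, ap$clipped_fractions)
  expect_equal(read_smv(rep1$paths[2])$frame, get_frame(ap$stack, 2))
  # OSC_START decreases for negative per-frame oscillation
  osc <- sapply(rep1$paths, function(p) as.numeric(read_smv(p)$header[["OSC_START"]]))
  expect_equal(unname(osc), c(30, 29.55, 29.1))
  # byte-identical on re-conversion
  out2 <- withr::local_tempdir()
  rep2 <- convert_dataset(mrc, geom, cfg, out2)
  for (i in 1:3)
    expect_identical(readBin(rep1$paths[i], "raw", file.size(rep1$paths[i])),
                     readBin(rep2$paths[i], "raw", file.size(rep2$paths[i])))
})
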