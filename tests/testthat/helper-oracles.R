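# Independent byte-level writers used as oracles for the package readers.
# These are written directly from the published file layouts and share no
# code with the package's I/O paths.

# Minimal MRC2014 writer: 1024-byte header, optional extended header of
# junk bytes, X-fastest payload. mode 1 = int16, mode 2 = float32.
oracle_write_mrc <- function(frames, path, mode = 1L, nsymbt = 0L) {
  # frames: list of matrices (slow x fast), all same shape
  ny <- nrow(frames[[1]]); nx <- ncol(frames[[1]]); nz <- length(frames)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- raw(1024)
  put_i32 <- function(word, value) {
    b <- writeBin(as.integer(value), raw(), size = 4L, endian = "little")
    header[((word - 1) * 4 + 1):((word - 1) * 4 + 4)] <<- b
  }
  put_f32 <- function(word, value) {
    b <- writeBin(as.numeric(value), raw(), size = 4L, endian = "little")
    header[((word - 1) * 4 + 1):((word - 1) * 4 + 4)] <<- b
  }
  put_i32(1, nx); put_i32(2, ny); put_i32(3, nz); put_i32(4, mode)
  put_i32(8, nx); put_i32(9, ny); put_i32(10, nz)
  put_f32(11, nx); put_f32(12, ny); put_f32(13, nz)
  put_f32(14, 90); put_f32(15, 90); put_f32(16, 90)
  put_i32(17, 1); put_i32(18, 2); put_i32(19, 3)
  put_i32(23, 1)               # ISPG
  put_i32(24, nsymbt)
  header[209:212] <- charToRaw("MAP ")
  header[213:214] <- as.raw(c(0x44, 0x44))
  writeBin(header, con)
  if (nsymbt > 0) writeBin(as.raw(seq_len(nsymbt) %% 256), con)
  vals <- unlist(lapply(frames, function(f) as.vector(t(f))), use.names = FALSE)
  if (mode == 1L) writeBin(as.integer(vals), con, size = 2L, endian = "little")
  else writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  invisible(path)
}

# TIA/SER writer, series version 0x0210 (32-bit offsets), one time
# dimension, 2-D image elements. dtype 5 = int16, 7 = float32.
oracle_write_ser <- function(frames, path, dtype = 5L) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(frames)
  elem_size <- function(f) {
    bytes <- if (dtype == 5L) 2L else 4L
    50L + bytes * length(f)
  }
  head_len <- 6L + 4L * 5L                    # 3 int16 + 5 int32 (incl. OAO)
  dim_len <- 4L + 16L + 4L + 4L + 1L + 4L + 1L
  data_start <- head_len + 4L + dim_len       # + NumberDimensions int32
  sizes <- vapply(frames, elem_size, integer(1))
  offs <- data_start + cumsum(c(0L, sizes[-n]))
  oao <- data_start + sum(sizes)              # offset array after the data
  writeBin(c(0x4949L, 0x0197L, 0x0210L), con, size = 2L, endian = "little")
  writeBin(c(0x4122L, 0x4152L, n, n), con, size = 4L, endian = "little")
  writeBin(as.integer(oao), con, size = 4L, endian = "little")
  writeBin(1L, con, size = 4L, endian = "little")          # NumberDimensions
  writeBin(as.integer(n), con, size = 4L, endian = "little")
  writeBin(c(0, 1), con, size = 8L, endian = "little")     # dim calibration
  writeBin(0L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 4L, endian = "little"); writeBin(charToRaw("t"), con)
  writeBin(1L, con, size = 4L, endian = "little"); writeBin(charToRaw("s"), con)
  for (f in frames) {
    writeBin(c(0, 1), con, size = 8L, endian = "little")   # X calibration
    writeBin(0L, con, size = 4L, endian = "little")
    writeBin(c(0, 1), con, size = 8L, endian = "little")   # Y calibration
    writeBin(0L, con, size = 4L, endian = "little")
    writeBin(as.integer(dtype), con, size = 2L, endian = "little")
    writeBin(c(ncol(f), nrow(f)), con, size = 4L, endian = "little")
    vals <- as.vector(t(f))                                # X fastest
    if (dtype == 5L) writeBin(as.integer(vals), con, size = 2L, endian = "little")
    else writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  }
  writeBin(as.integer(offs), con, size = 4L, endian = "little")
  writeBin(integer(n), con, size = 4L, endian = "little")  # tag offsets
  invisible(path)
}

# Independent orbit oracle: the 16 tetragonal Laue operations written out
# as (swap h/k, sign flips) tuples, separate from the package's matrix
# representation.
oracle_orbit_4mmm <- function(h, k, l) {
  out <- matrix(NA_integer_, 16, 3)
  i <- 0
  for (sw in 0:1) for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
    u <- if (sw) c(k, h) else c(h, k)
    i <- i + 1
    out[i, ] <- c(s1 * u[1], s2 * u[2], s3 * l)
  }
  unique(out)
}
oracle_canonical <- function(orbit) {
  ord <- order(orbit[, 1], orbit[, 2], orbit[, 3], decreasing = TRUE)
  orbit[ord[1], ]
}

# Standard camera geometries used across tests.
falcon_geom <- function(distance_mm = 2380) {
  acquisition_geometry(voltage_kv = 200, distance_mm = distance_mm,
                       physical_pixel_um = 14, binning = 2,
                       frame_shape = c(2048L, 2048L),
                       rotation_speed_deg_s = 0.45, exposure_time_s = 1,
                       exposure_rate = 0.01)
}

toy_geom <- function(n = 64L, distance_mm = 650) {
  acquisition_geometry(voltage_kv = 200, distance_mm = distance_mm,
                       physical_pixel_um = 14, binning = 2,
                       frame_shape = c(n, n),
                       rotation_speed_deg_s = 0.45, exposure_time_s = 1,
                       exposure_rate = 0.01)
}
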