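# Movie-stack I/O: MRC2014 and TIA/SER readers, the pedestal/clipping
# policy, and the SMV diffraction-image writer with derived headers.
#
# Frame stacks hold pixels as a numeric array dim c(rows, cols, n_frames)
# (slow, fast, frame). Negative pixel values are legal before the pedestal
# is applied: integrating detectors retain readout-noise excursions below
# zero in their native output.

#' Construct a frame stack
#'
#' @param pixels Numeric array `dim = c(rows, cols, n_frames)`, or a matrix
#'   for a single frame. May contain negative values.
#' @param source_format One of `"MRC"`, `"SER"`, `"SYNTHETIC"`.
#' @param per_frame_time Exposure time per frame in seconds.
#' @return A `frame_stack` object with fields `pixels`, `n_frames`,
#'   `frame_shape`, `source_format`, `per_frame_time`.
#' @export
frame_stack <- function(pixels, source_format = "SYNTHETIC", per_frame_time = NA_real_) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  d <- dim(pixels)
  if (any(d < 1L)) stop("frame dimensions and frame count must be >= 1", call. = FALSE)
  source_format <- match.arg(source_format, c("MRC", "SER", "SYNTHETIC"))
  structure(list(pixels = pixels,
                 n_frames = d[3L],
                 frame_shape = d[1:2],
                 source_format = source_format,
                 per_frame_time = per_frame_time),
            class = "frame_stack")
}

#' Extract one frame from a stack as a matrix
#' @param stack A [frame_stack()].
#' @param i Frame index, 1-based.
#' @export
get_frame <- function(stack, i) {
  stopifnot(inherits(stack, "frame_stack"))
  i <- as.integer(i)
  if (i < 1L || i > stack$n_frames) stop("frame index out of range", call. = FALSE)
  stack$pixels[, , i]
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("Frame stack (%s): %d frame(s) of %dx%d, range [%g, %g]\n",
              x$source_format, x$n_frames, x$frame_shape[1], x$frame_shape[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

.read_u64le <- function(con) {
  w <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  lo <- as.numeric(w[1]); hi <- as.numeric(w[2])
  if (lo < 0) lo <- lo + 2^32
  if (hi < 0) hi <- hi + 2^32
  lo + hi * 2^32
}

#' Read an MRC2014 movie stack
#'
#' Supports modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16); signed
#' modes preserve negative pixel values exactly. Any extended header is
#' skipped according to `NSYMBT`. The stack is returned in the canonical
#' (slow, fast, frame) layout; no MAPC/MAPR/MAPS axis permutation is
#' honoured, since diffraction movies are written canonically.
#'
#' @param path Path to a `.mrc` file.
#' @return A [frame_stack()] with `n_frames = NZ`, `frame_shape = c(NY, NX)`.
#' @export
read_mrc_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) < 1024)
    stop("not an MRC file (shorter than the 1024-byte header): ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  nxyz <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  mode <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  seek(con, 92)
  nsymbt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  seek(con, 208)
  map_tag <- rawToChar(readBin(con, "raw", n = 4L))
  if (map_tag != "MAP ")
    stop("malformed MRC file (missing 'MAP ' tag): ", path, call. = FALSE)
  nx <- nxyz[1]; ny <- nxyz[2]; nz <- nxyz[3]
  if (any(nxyz < 1L)) stop("malformed MRC file (non-positive dimensions)", call. = FALSE)
  seek(con, 1024 + nsymbt)
  n <- as.numeric(nx) * ny * nz
  vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1L, signed = TRUE),
    "1" = readBin(con, "integer", n = n, size = 2L, signed = TRUE, endian = "little"),
    "2" = readBin(con, "double", n = n, size = 4L, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = "little"),
    stop("unsupported MRC mode ", mode,
         " (supported: 0, 1, 2, 6)", call. = FALSE))
  if (length(vals) < n)
    stop("truncated MRC payload: expected ", n, " values, got ", length(vals),
         call. = FALSE)
  # stored X-fastest: (fast, slow, frame) -> canonical (slow, fast, frame)
  px <- aperm(array(as.numeric(vals), dim = c(nx, ny, nz)), c(2L, 1L, 3L))
  frame_stack(px, source_format = "MRC")
}

#' Write a movie stack as MRC2014
#'
#' Writes mode 1 (int16) when all values are integral and fit, otherwise
#' mode 2 (float32). Companion to [read_mrc_stack()]; used by the simulator
#' to produce standard movie files.
#'
#' @param stack A [frame_stack()] or 3-D array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mrc_stack <- function(stack, path) {
  if (inherits(stack, "frame_stack")) px <- stack$pixels else px <- stack
  stopifnot(is.array(px), length(dim(px)) == 3L)
  d <- dim(px)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  integral <- all(px == round(px)) && min(px) >= -32768 && max(px) <= 32767
  mode <- if (integral) 1L else 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(nx, ny, nz, mode, 0L, 0L, 0L, nx, ny, nz)), con,
           size = 4L, endian = "little")
  writeBin(as.numeric(c(nx, ny, nz, 90, 90, 90)), con, size = 4L, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4L, endian = "little")  # MAPC/R/S
  writeBin(as.numeric(c(min(px), max(px), mean(px))), con, size = 4L, endian = "little")
  writeBin(as.integer(c(1L, 0L)), con, size = 4L, endian = "little")      # ISPG, NSYMBT
  writeBin(raw(100), con)                                                 # EXTRA 25 words
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4L, endian = "little")     # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)                        # MACHST LE
  writeBin(as.numeric(stats::sd(px)), con, size = 4L, endian = "little")
  writeBin(0L, con, size = 4L, endian = "little")                         # NLABL
  writeBin(raw(800), con)
  vals <- as.vector(aperm(px, c(2L, 1L, 3L)))                             # X fastest
  if (mode == 1L) {
    writeBin(as.integer(vals), con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  }
  invisible(path)
}

# TIA/SER data-type tags -> (what, size, signed)
.ser_types <- list(
  `1` = list(what = "integer", size = 1L, signed = FALSE),
  `2` = list(what = "integer", size = 2L, signed = FALSE),
  `3` = list(what = "integer", size = 4L, signed = NA),     # uint32, special
  `4` = list(what = "integer", size = 1L, signed = TRUE),
  `5` = list(what = "integer", size = 2L, signed = TRUE),
  `6` = list(what = "integer", size = 4L, signed = TRUE),
  `7` = list(what = "double",  size = 4L, signed = NA),
  `8` = list(what = "double",  size = 8L, signed = NA))

#' Read a TIA/SER image series
#'
#' Parses the FEI/TIA "ES Vision" SER container: little-endian header,
#' dimension arrays, a data-offset array (32-bit for series version
#' `0x0210`, 64-bit for `0x0220`), and per-element 2-D data records. All
#' 2-D elements are returned as frames in file order, widened losslessly
#' to numeric.
#'
#' @param path Path to a `.ser` file.
#' @return A [frame_stack()].
#' @export
read_ser_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sz <- file.size(path)
  if (sz < 30) stop("not a SER file (truncated header): ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  byte_order <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                        endian = "little")
  series_id <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                       endian = "little")
  if (byte_order != 0x4949 || series_id != 0x0197)
    stop("not a SER file (bad magic): ", path, call. = FALSE)
  version <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                     endian = "little")
  data_type_id <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  readBin(con, "integer", n = 1L, size = 4L, endian = "little")  # tag type id
  total_n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  valid_n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (data_type_id != 0x4122)
    stop("unsupported SER data type id 0x", sprintf("%x", data_type_id),
         " (only 2-D image series, 0x4122, are supported)", call. = FALSE)
  if (valid_n < 1L) stop("empty SER series (no valid elements)", call. = FALSE)
  wide_offsets <- version >= 0x0220
  offset_array_offset <- if (wide_offsets) .read_u64le(con) else
    readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  n_dims <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  for (d in seq_len(n_dims)) {  # dimension arrays: skipped, sizes come per element
    readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    readBin(con, "double", n = 2L, size = 8L, endian = "little")
    readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    dl <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (dl > 0) readBin(con, "raw", n = dl)
    ul <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (ul > 0) readBin(con, "raw", n = ul)
  }
  seek(con, offset_array_offset)
  offs <- if (wide_offsets) vapply(seq_len(valid_n), function(i) .read_u64le(con),
                                   numeric(1))
  else as.numeric(readBin(con, "integer", n = valid_n, size = 4L,
                          endian = "little"))
  if (length(offs) < valid_n || any(!is.finite(offs)))
    stop("truncated SER file: offset array is incomplete", call. = FALSE)
  frames <- vector("list", valid_n)
  for (i in seq_len(valid_n)) {
    if (offs[i] <= 0 || offs[i] >= sz)
      stop("truncated or corrupt SER file: element offset out of range", call. = FALSE)
    seek(con, offs[i])
    readBin(con, "double", n = 2L, size = 8L, endian = "little")  # X calibration
    readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    readBin(con, "double", n = 2L, size = 8L, endian = "little")  # Y calibration
    readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    dtype <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                     endian = "little")
    asx <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    asy <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    spec <- .ser_types[[as.character(dtype)]]
    if (is.null(spec))
      stop("unsupported SER element data type tag ", dtype, call. = FALSE)
    n <- as.numeric(asx) * asy
    need <- n * spec$size
    if (offs[i] + 50 + need > sz)
      stop("truncated SER payload: element ", i, " needs ", need,
           " bytes past offset", call. = FALSE)
    vals <- if (spec$what == "double") {
      readBin(con, "double", n = n, size = spec$size, endian = "little")
    } else if (is.na(spec$signed)) {  # uint32: read signed, fix wrap
      v <- as.numeric(readBin(con, "integer", n = n, size = 4L, endian = "little"))
      ifelse(v < 0, v + 2^32, v)
    } else {
      readBin(con, "integer", n = n, size = spec$size, signed = spec$signed,
              endian = "little")
    }
    if (length(vals) < n)
      stop("truncated SER payload in element ", i, call. = FALSE)
    # stored X fastest -> (slow, fast) matrix
    frames[[i]] <- t(matrix(as.numeric(vals), nrow = asx, ncol = asy))
  }
  shp <- dim(frames[[1]])
  px <- array(NA_real_, dim = c(shp, valid_n))
  for (i in seq_len(valid_n)) px[, , i] <- frames[[i]]
  frame_stack(px, source_format = "SER")
}

#' Apply the pedestal/clipping policy
#'
#' Adds a non-negative constant to every pixel so that readout-noise
#' excursions below zero remain representable in an unsigned output format.
#' Pixels still negative after the addition (raw value < -pedestal) are set
#' to zero; the zeroed fraction is reported per frame so the conversion can
#' be audited (on real Falcon III / CetaD data these fractions are of order
#' 1e-4 or below).
#'
#' @param stack A [frame_stack()].
#' @param pedestal Constant in ADU (>= 0).
#' @return A list with `stack` (all values >= 0) and `clipped_fractions`
#'   (one fraction in \[0, 1\] per frame).
#' @export
apply_pedestal <- function(stack, pedestal) {
  stopifnot(inherits(stack, "frame_stack"))
  if (length(pedestal) != 1L || is.na(pedestal) || pedestal < 0)
    stop("pedestal must be a single value >= 0", call. = FALSE)
  px <- stack$pixels + pedestal
  clipped <- px <= 0  # raw <= -pedestal: zeroed (a no-op at exactly 0) and counted
  px[px < 0] <- 0
  per_frame <- apply(clipped, 3L, mean)
  out <- stack
  out$pixels <- px
  list(stack = out, clipped_fractions = as.numeric(per_frame))
}

#' Conversion configuration
#'
#' @param pedestal Per-data-set pedestal in ADU (>= 0); typical values are
#'   8 for Falcon III and 128 for CetaD movies.
#' @param distance_mm Virtual sample-to-detector distance in mm; must be
#'   supplied by the user (it is not recorded in the native movie formats).
#' @param beam_center Beam centre `c(x, y)` in mm on the detector.
#' @param oscillation_start_deg Rotation angle at the start of frame 1.
#' @param oscillation_per_frame_deg Signed rotation per frame; negative for
#'   stages rotated from high towards zero tilt.
#' @param saturation_cap Largest representable output value (default 65535).
#' @param user_overrides Named list of header keys applied last, overriding
#'   any derived value.
#' @return A `conversion_config` object.
#' @export
conversion_config <- function(pedestal = 0L, distance_mm = NA_real_,
                              beam_center = NULL,
                              oscillation_start_deg = 0,
                              oscillation_per_frame_deg = 0,
                              saturation_cap = 65535L,
                              user_overrides = list()) {
  if (pedestal < 0) stop("pedestal must be >= 0", call. = FALSE)
  structure(list(pedestal = pedestal,
                 distance_mm = distance_mm,
                 beam_center = beam_center,
                 oscillation_start_deg = oscillation_start_deg,
                 oscillation_per_frame_deg = oscillation_per_frame_deg,
                 saturation_cap = as.integer(saturation_cap),
                 user_overrides = user_overrides),
            class = "conversion_config")
}

#' Build the SMV header for one frame
#'
#' Derives as much of the diffraction geometry as possible from the
#' acquisition parameters: WAVELENGTH from the acceleration voltage via
#' [electron_wavelength()], OSC_START from the frame index and per-frame
#' oscillation, PIXEL_SIZE from the physical pixel and binning. Keys in
#' `config$user_overrides` are applied last. The virtual detector distance
#' cannot be derived and must be present in `config` or the overrides.
#'
#' @param geom An [acquisition_geometry()].
#' @param config A [conversion_config()].
#' @param frame_index 0-based frame index used for OSC_START arithmetic.
#' @return An `smv_header`: an ordered named character vector.
#' @export
build_smv_header <- function(geom, config, frame_index = 0L) {
  stopifnot(inherits(geom, "acquisition_geometry"),
            inherits(config, "conversion_config"))
  distance <- config$distance_mm
  if ((is.null(distance) || is.na(distance)) &&
      is.null(config$user_overrides[["DISTANCE"]]))
    stop(paste("the virtual sample-to-detector distance is not recorded in the",
               "native movie metadata and must be specified by the user",
               "(conversion_config(distance_mm = ...))"), call. = FALSE)
  wavelength <- electron_wavelength(geom$voltage_kv)
  pixel_mm <- geom$physical_pixel_um * geom$binning / 1000
  osc_range <- abs(config$oscillation_per_frame_deg)
  osc_start <- config$oscillation_start_deg +
    frame_index * config$oscillation_per_frame_deg
  bc <- config$beam_center
  if (is.null(bc)) bc <- rev(geom$frame_shape) / 2 * pixel_mm  # (x, y) mm
  h <- c(
    HEADER_BYTES = "512",
    DIM = "2",
    SIZE1 = as.character(geom$frame_shape[2]),
    SIZE2 = as.character(geom$frame_shape[1]),
    TYPE = "unsigned_short",
    BYTE_ORDER = "little_endian",
    PIXEL_SIZE = sprintf("%.6g", pixel_mm),
    DISTANCE = sprintf("%.6g", distance),
    WAVELENGTH = sprintf("%.6g", wavelength),
    OSC_START = sprintf("%.6g", osc_start),
    OSC_RANGE = sprintf("%.6g", osc_range),
    PHI = sprintf("%.6g", osc_start),
    TIME = sprintf("%.6g", geom$exposure_time_s),
    BEAM_CENTER_X = sprintf("%.6g", bc[1]),
    BEAM_CENTER_Y = sprintf("%.6g", bc[2]),
    BIN = sprintf("%dx%d", geom$binning, geom$binning)
  )
  for (k in names(config$user_overrides))
    h[[k]] <- as.character(config$user_overrides[[k]])
  structure(h, class = "smv_header")
}

.serialize_smv_header <- function(header) {
  body <- paste0("{\n",
                 paste0(names(header), "=", unname(header), ";\n",
                        collapse = ""),
                 "}\n")
  hb <- as.integer(header[["HEADER_BYTES"]])
  need <- 512L * ceiling((nchar(body, type = "bytes")) / 512)
  if (is.na(hb) || hb < need) hb <- need
  header[["HEADER_BYTES"]] <- as.character(hb)
  body <- paste0("{\n",
                 paste0(names(header), "=", unname(header), ";\n",
                        collapse = ""),
                 "}\n")
  pad <- hb - nchar(body, type = "bytes")
  c(charToRaw(body), rep(as.raw(0x20), pad))
}

#' Write one SMV diffraction image
#'
#' Serializes the header into an ASCII block padded to a 512-byte multiple,
#' followed by row-major unsigned 16-bit little-endian pixel data. Values
#' above the saturation cap (65535) are clamped and counted.
#'
#' @param frame Non-negative numeric matrix (rows = slow, cols = fast).
#' @param header An `smv_header` from [build_smv_header()].
#' @param path Output path (conventionally `.img`).
#' @return Invisibly, a list with `saturated_count`.
#' @export
write_smv <- function(frame, header, path) {
  stopifnot(is.matrix(frame), inherits(header, "smv_header"))
  if (min(frame) < 0)
    stop("SMV frames must be non-negative; apply the pedestal first", call. = FALSE)
  v <- round(as.vector(t(frame)))  # row-major
  saturated <- sum(v > 65535)
  v[v > 65535] <- 65535
  header[["SIZE1"]] <- as.character(ncol(frame))
  header[["SIZE2"]] <- as.character(nrow(frame))
  hdr <- .serialize_smv_header(header)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  v <- as.integer(v)
  r <- raw(2L * length(v))
  r[seq(1L, length(r), 2L)] <- as.raw(v %% 256L)
  r[seq(2L, length(r), 2L)] <- as.raw(v %/% 256L)
  writeBin(r, con)
  invisible(list(saturated_count = saturated))
}

#' Read an SMV diffraction image
#'
#' Inverse of [write_smv()]; used for round-trip validation and inspection.
#'
#' @param path Path to a `.img` file.
#' @return A list with `header` (named character vector) and `frame`
#'   (numeric matrix, rows = slow).
#' @export
read_smv <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head1 <- rawToChar(readBin(con, "raw", n = 512L))
  m <- regmatches(head1, regexec("HEADER_BYTES=\\s*([0-9]+)\\s*;", head1))[[1]]
  if (length(m) < 2) stop("not an SMV file (no HEADER_BYTES): ", path, call. = FALSE)
  hb <- as.integer(m[2])
  seek(con, 0)
  txt <- rawToChar(readBin(con, "raw", n = hb))
  entries <- regmatches(txt, gregexpr("[A-Za-z0-9_]+=[^;]*;", txt))[[1]]
  keys <- sub("=.*", "", entries)
  vals <- sub(";$", "", sub("^[A-Za-z0-9_]+=", "", entries))
  header <- stats::setNames(trimws(vals), keys)
  s1 <- as.integer(header[["SIZE1"]]); s2 <- as.integer(header[["SIZE2"]])
  v <- readBin(con, "integer", n = s1 * s2, size = 2L, signed = FALSE,
               endian = "little")
  list(header = header, frame = matrix(as.numeric(v), nrow = s2, byrow = TRUE))
}

#' Convert a movie stack to per-frame SMV images
#'
#' Reads the input (MRC or SER by extension, or an in-memory
#' [frame_stack()]), applies the pedestal policy, and writes one SMV file
#' per frame named `<prefix>_NNN.img` with 1-based zero-padded numbers.
#' OSC_START advances by the signed per-frame oscillation using 0-based
#' frame arithmetic. No dark-current or flat-field correction is applied.
#'
#' @param input Path to a `.mrc`/`.ser` file, or a [frame_stack()].
#' @param geom An [acquisition_geometry()].
#' @param config A [conversion_config()].
#' @param out_dir Output directory (created if missing).
#' @param prefix Filename prefix (default `"frame"`).
#' @return A `conversion_report` with `frames_written`,
#'   `clipped_fraction_per_frame`, `saturated_count_per_frame`,
#'   `pedestal_used` and `paths`.
#' @export
convert_dataset <- function(input, geom, config, out_dir, prefix = "frame") {
  stack <- if (inherits(input, "frame_stack")) input
  else if (grepl("\\.mrc$", input, ignore.case = TRUE)) read_mrc_stack(input)
  else if (grepl("\\.ser$", input, ignore.case = TRUE)) read_ser_series(input)
  else stop("cannot infer input format from extension: ", input, call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ped <- apply_pedestal(stack, config$pedestal)
  width <- max(3L, nchar(as.character(stack$n_frames)))
  saturated <- integer(stack$n_frames)
  paths <- character(stack$n_frames)
  for (i in seq_len(stack$n_frames)) {
    header <- build_smv_header(geom, config, frame_index = i - 1L)
    paths[i] <- file.path(out_dir, sprintf("%s_%0*d.img", prefix, width, i))
    res <- write_smv(get_frame(ped$stack, i), header, paths[i])
    saturated[i] <- res$saturated_count
  }
  structure(list(frames_written = stack$n_frames,
                 clipped_fraction_per_frame = ped$clipped_fractions,
                 saturated_count_per_frame = saturated,
                 pedestal_used = config$pedestal,
                 paths = paths),
            class = "conversion_report")
}

#' @export
print.conversion_report <- function(x, ...) {
  cat(sprintf("Converted %d frame(s), pedestal %g ADU\n",
              x$frames_written, x$pedestal_used))
  cat(sprintf("  clipped fraction: max %.3g%%; saturated pixels: %d total\n",
              100 * max(x$clipped_fraction_per_frame),
              sum(x$saturated_count_per_frame)))
  invisible(x)
}
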