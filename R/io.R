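# File formats.  Phantom images are written either as uncompressed baseline
# grayscale TIFF (8- or 16-bit, single strip, little-endian; the subset
# every scientific TIFF reader understands) or as plain-text PGM (P2).
# Pixel size and wall geometry travel in a sidecar JSON.  Traces, profiles
# and response tables are plain CSV.

# ---- TIFF (baseline grayscale, uncompressed) --------------------------------

u16_raw <- function(v) {
  v <- as.integer(v)
  as.raw(rbind(v %% 256L, v %/% 256L))
}
u32_raw <- function(v) {
  v <- as.numeric(v)
  as.raw(rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256, (v %/% 16777216) %% 256))
}

tiff_entry <- function(tag, type, count, value_raw4) {
  c(u16_raw(tag), u16_raw(type), u32_raw(count), value_raw4)
}

#' Write grayscale images as an uncompressed TIFF
#'
#' Baseline little-endian TIFF, one strip per page, photometric
#' BlackIsZero; multiple matrices become a multi-page file.
#'
#' @param images a numeric matrix or list of matrices (rows = y); values
#'   are rounded and clipped to the sample range.
#' @param path output file.
#' @param bits 8 or 16 bits per sample.
#' @return `path`, invisibly.
#' @export
write_tiff_gray <- function(images, path, bits = 8) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(bits %in% c(8L, 16L), length(images) >= 1L)
  maxval <- 2^bits - 1
  con <- file(path, "wb")
  on.exit(close(con))
  n_entries <- 9L
  ifd_len <- 2 + n_entries * 12 + 4
  blocks <- lapply(images, function(m) {
    v <- as.integer(pmin(pmax(round(t(m)), 0), maxval))  # row-major scan order
    data <- if (bits == 8L) as.raw(v) else u16_raw(v)
    if (length(data) %% 2 == 1) data <- c(data, as.raw(0))  # word alignment
    data
  })
  # layout: header | data1 | IFD1 | data2 | IFD2 | ...
  data_off <- 8 + cumsum(c(0, utils::head(lengths(blocks), -1) + ifd_len))
  ifd_offs <- data_off + lengths(blocks)
  out <- c(charToRaw("II"), u16_raw(42L), u32_raw(ifd_offs[1]))
  for (p in seq_along(images)) {
    m <- images[[p]]
    nbytes <- nrow(m) * ncol(m) * (bits %/% 8L)
    next_off <- if (p < length(images)) ifd_offs[p + 1] else 0
    ifd <- c(
      u16_raw(n_entries),
      tiff_entry(256L, 3L, 1L, c(u16_raw(ncol(m)), u16_raw(0L))),
      tiff_entry(257L, 3L, 1L, c(u16_raw(nrow(m)), u16_raw(0L))),
      tiff_entry(258L, 3L, 1L, c(u16_raw(bits), u16_raw(0L))),
      tiff_entry(259L, 3L, 1L, c(u16_raw(1L), u16_raw(0L))),   # no compression
      tiff_entry(262L, 3L, 1L, c(u16_raw(1L), u16_raw(0L))),   # BlackIsZero
      tiff_entry(273L, 4L, 1L, u32_raw(data_off[p])),
      tiff_entry(277L, 3L, 1L, c(u16_raw(1L), u16_raw(0L))),
      tiff_entry(278L, 4L, 1L, u32_raw(nrow(m))),
      tiff_entry(279L, 4L, 1L, u32_raw(nbytes)),
      u32_raw(next_off))
    out <- c(out, blocks[[p]], ifd)
  }
  writeBin(out, con)
  invisible(path)
}

rd_int <- function(raw, little) {
  v <- as.integer(raw)
  if (!little) v <- rev(v)
  sum(v * 256^(seq_along(v) - 1))
}

#' Read a grayscale TIFF written by this package (or any baseline
#' uncompressed grayscale TIFF, either endianness)
#'
#' @param path TIFF file.
#' @return list of numeric matrices (one per page).
#' @export
read_tiff_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  little <- raw[1] == charToRaw("I")
  if (rd_int(raw[3:4], little) != 42L) stop("read_tiff_gray: not a TIFF file")
  ifd_off <- rd_int(raw[5:8], little)
  pages <- list()
  while (ifd_off > 0) {
    n <- rd_int(raw[ifd_off + 1:2], little)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd_off + 2 + (i - 1) * 12
      tag <- rd_int(raw[e + 1:2], little)
      type <- rd_int(raw[e + 3:4], little)
      count <- rd_int(raw[e + 5:8], little)
      vraw <- raw[e + 9:12]
      val <- if (type == 3L && count == 1L) rd_int(vraw[1:2], little)
             else rd_int(vraw, little)
      tags[[as.character(tag)]] <- list(type = type, count = count, value = val,
                                        raw = vraw)
    }
    need <- function(t) {
      x <- tags[[as.character(t)]]
      if (is.null(x)) stop(sprintf("read_tiff_gray: missing tag %d", t))
      x
    }
    w <- need(256L)$value; h <- need(257L)$value
    bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]]$value
    comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]]$value
    if (comp != 1L) stop("read_tiff_gray: compressed TIFF not supported")
    so <- need(273L); sc <- need(279L)
    get_longs <- function(x) {
      if (x$count == 1L) return(x$value)
      off <- x$value
      sz <- if (x$type == 3L) 2L else 4L
      vapply(seq_len(x$count), function(i)
        rd_int(raw[off + (i - 1) * sz + seq_len(sz)], little), 0)
    }
    offs <- get_longs(so); cnts <- get_longs(sc)
    bytes <- unlist(lapply(seq_along(offs), function(i) raw[offs[i] + seq_len(cnts[i])]))
    if (bits == 8L) {
      v <- as.integer(bytes)
    } else if (bits == 16L) {
      ints <- as.integer(bytes)
      lo <- ints[seq(1, length(ints), by = 2)]
      hi <- ints[seq(2, length(ints), by = 2)]
      v <- if (little) lo + 256L * hi else hi + 256L * lo
    } else stop("read_tiff_gray: only 8/16-bit grayscale supported")
    pages[[length(pages) + 1L]] <- t(matrix(v, nrow = w, ncol = h))
    ifd_off <- rd_int(raw[ifd_off + 2 + n * 12 + 1:4], little)
  }
  pages
}

# ---- PGM (plain text) -------------------------------------------------------

#' Write a matrix as a plain-text PGM (P2) image
#' @param m numeric matrix (rows = y).
#' @param path output file.
#' @param maxval maximum gray value.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(m, path, maxval = 255) {
  v <- pmin(pmax(round(m), 0), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)), as.character(maxval)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a plain-text PGM (P2) image
#' @param path PGM file.
#' @return numeric matrix.
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("read_pgm: only plain (P2) PGM supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("read_pgm: truncated pixel data")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

# ---- patch images with sidecar ---------------------------------------------

#' Write a patch image plus sidecar metadata
#'
#' The image goes to `<path>` (format by extension: `.tif`/`.tiff` or
#' `.pgm`) and pixel size, wall lines, and any ground truth to
#' `<path>.json`.
#'
#' @param image a `patch_image`.
#' @param path output image path.
#' @param bits TIFF bit depth.
#' @return `path`, invisibly.
#' @export
write_patch_image <- function(image, path, bits = 8) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_tiff_gray(image$intensities, path, bits = bits)
  } else if (ext == "pgm") {
    write_pgm(image$intensities, path)
  } else stop("write_patch_image: unsupported extension ", ext)
  meta <- list(pixel_size_um = image$pixel_size,
               wall_lines = image$wall_lines,
               truth = if (!is.null(image$truth))
                 image$truth[setdiff(names(image$truth), "arc_um")] else NULL)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = 10, null = "null")
  if (!is.null(image$truth)) {
    utils::write.csv(as.data.frame(image$truth$arc_um),
                     paste0(tools::file_path_sans_ext(path), "_arc_truth.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a patch image written by [write_patch_image()]
#'
#' @param path image path (`.tif`/`.tiff`/`.pgm`); `<path>.json` sidecar is
#'   read when present, else `pixel_size` must be given.
#' @param pixel_size um/px override.
#' @return a `patch_image`.
#' @export
read_patch_image <- function(path, pixel_size = NULL) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) read_tiff_gray(path)[[1]] else read_pgm(path)
  side <- paste0(path, ".json")
  walls <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
    pixel_size <- pixel_size %||% meta$pixel_size_um
    if (!is.null(meta$wall_lines) && length(meta$wall_lines) == 2L) {
      walls <- lapply(meta$wall_lines, function(l)
        list(point = as.numeric(l$point), dir = as.numeric(l$dir)))
    }
  }
  if (is.null(pixel_size)) stop("read_patch_image: pixel_size unknown (no sidecar)")
  patch_image(m, pixel_size, wall_lines = walls)
}

# ---- CSV tables -------------------------------------------------------------

#' Write / read a current trace as CSV (time_s, current_pA, pressure_mmHg)
#' @param sweep a `sweep_record`.
#' @param path CSV path.
#' @return `path` (write) or a `sweep_record` (read).
#' @export
write_trace_csv <- function(sweep, path) {
  d <- data.frame(time_s = sweep$time_s, current_pA = sweep$current_pa,
                  pressure_mmHg = sweep$pressure_mmhg)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "current_pA", "pressure_mmHg")
  if (!all(need %in% names(d))) {
    stop("read_trace_csv: expected columns time_s, current_pA, pressure_mmHg")
  }
  rec <- data.frame(time_s = d$time_s, current_pa = d$current_pA,
                    pressure_mmhg = d$pressure_mmHg)
  fs <- 1 / stats::median(diff(d$time_s))
  attr(rec, "sample_rate") <- fs
  # reconstruct the segment table from pressure transitions
  ch <- c(TRUE, diff(d$pressure_mmHg) != 0)
  starts <- which(ch)
  ends <- c(starts[-1] - 1L, nrow(d))
  attr(rec, "segments") <- data.frame(
    amplitude = d$pressure_mmHg[starts],
    start_s = d$time_s[starts],
    end_s = d$time_s[ends] + 1 / fs)
  class(rec) <- c("sweep_record", "data.frame")
  rec
}

#' Write a membrane profile as CSV (frame, x_um, y_um, intensity)
#' @param profile a `membrane_profile`.
#' @param path CSV path.
#' @param frame frame index recorded in the file.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path, frame = 1L) {
  utils::write.csv(data.frame(frame = frame, x_um = profile$x_um,
                              y_um = profile$y_um,
                              intensity = profile$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Serialize a circle fit to JSON
#' @param fit a `circle_fit`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_circle_json <- function(fit, path) {
  jsonlite::write_json(list(
    cx_um = fit$center[1], cy_um = fit$center[2], radius_um = fit$radius,
    rms_um = fit$rms_um, n_points = fit$n_points,
    curvature_sign = sign(fit$signed_curvature), flat = fit$flat),
    path, auto_unbox = TRUE, digits = 10, na = "null")
  invisible(path)
}
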