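# Plain-format I/O: baseline uncompressed TIFF (8/16-bit, grayscale/RGB,
# multi-page) and non-interlaced PNG (8/16-bit gray/RGB, zlib via
# memCompress/memDecompress), written without external imaging libraries.
# Intensities travel as [0, 1] doubles in memory and are quantized to the
# requested bit depth on export.

# --- raw packing helpers ----------------------------------------------------

pack_u16 <- function(v, endian = c("little", "big")) {
  endian <- match.arg(endian)
  v <- as.integer(round(v))
  hi <- as.raw(v %/% 256L); lo <- as.raw(v %% 256L)
  out <- raw(2 * length(v))
  if (endian == "little") {
    out[seq(1, length(out), 2)] <- lo; out[seq(2, length(out), 2)] <- hi
  } else {
    out[seq(1, length(out), 2)] <- hi; out[seq(2, length(out), 2)] <- lo
  }
  out
}

unpack_u16 <- function(r, endian = c("little", "big")) {
  endian <- match.arg(endian)
  a <- as.integer(r[seq(1, length(r), 2)])
  b <- as.integer(r[seq(2, length(r), 2)])
  if (endian == "little") b * 256L + a else a * 256L + b
}

pack_u32 <- function(v, endian = "little") {
  v <- as.numeric(v)
  b0 <- as.raw(v %% 256); b1 <- as.raw((v %/% 256) %% 256)
  b2 <- as.raw((v %/% 65536) %% 256); b3 <- as.raw((v %/% 16777216) %% 256)
  out <- raw(4 * length(v))
  o <- if (endian == "little") list(b0, b1, b2, b3) else list(b3, b2, b1, b0)
  for (k in 1:4) out[seq(k, length(out), 4)] <- o[[k]]
  out
}

unpack_u32 <- function(r, endian = "little") {
  a <- as.numeric(r[seq(1, length(r), 4)])
  b <- as.numeric(r[seq(2, length(r), 4)])
  c <- as.numeric(r[seq(3, length(r), 4)])
  d <- as.numeric(r[seq(4, length(r), 4)])
  if (endian == "little") ((d * 256 + c) * 256 + b) * 256 + a
  else ((a * 256 + b) * 256 + c) * 256 + d
}

# Quantize a [0, 1] raster to integers at `bits` depth; `scale = FALSE`
# takes the values as already-integer (label images).
quantize <- function(m, bits, scale) {
  mx <- 2^bits - 1
  if (scale) round(pmin(pmax(m, 0), 1) * mx) else round(m)
}

# Sample matrix (h x w or h x w x k) -> interleaved row-major sample vector.
interleave_samples <- function(x) {
  if (length(dim(x)) == 2) return(as.vector(t(x)))
  k <- dim(x)[3]
  out <- matrix(0, k, dim(x)[1] * dim(x)[2])
  for (c in seq_len(k)) out[c, ] <- as.vector(t(x[, , c]))
  as.vector(out)
}

deinterleave_samples <- function(v, h, w, k) {
  if (k == 1) return(matrix(v, h, w, byrow = TRUE))
  arr <- array(0, c(h, w, k))
  for (c in seq_len(k))
    arr[, , c] <- matrix(v[seq(c, length(v), k)], h, w, byrow = TRUE)
  arr
}

# --- TIFF -------------------------------------------------------------------

tiff_entry <- function(tag, type, count, value) {
  list(tag = tag, type = type, count = count, value = value)
}

# Serialize one page: returns list(raw_ifd_builder) used by write_tiff.
write_tiff <- function(pages, path, bits, scale, descriptions = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x49), as.raw(0x49), as.raw(42), as.raw(0)), con)
  # offsets are computed page by page; header IFD pointer patched at the end
  chunks <- list()
  pos <- 8
  ifd_offsets <- numeric(length(pages))
  for (p in seq_along(pages)) {
    img <- pages[[p]]
    rgbp <- length(dim(img)) == 3
    h <- dim(img)[1]; w <- dim(img)[2]; k <- if (rgbp) dim(img)[3] else 1L
    q <- quantize(img, bits, scale)
    samples <- interleave_samples(q)
    data <- if (bits == 16) pack_u16(samples, "little") else as.raw(samples)
    desc <- if (!is.null(descriptions)) descriptions[p] else NA
    entries <- list(
      tiff_entry(256, 4, 1, w), tiff_entry(257, 4, 1, h),
      tiff_entry(258, 3, k, rep(bits, k)),
      tiff_entry(259, 3, 1, 1),
      tiff_entry(262, 3, 1, if (rgbp) 2 else 1))
    if (!is.na(desc)) {
      dr <- c(charToRaw(desc), as.raw(0))
      entries <- c(entries, list(tiff_entry(270, 2, length(dr), dr)))
    }
    entries <- c(entries, list(
      tiff_entry(273, 4, 1, NA),  # strip offset, patched below
      tiff_entry(277, 3, 1, k),
      tiff_entry(278, 4, 1, h),
      tiff_entry(279, 4, 1, length(data)),
      tiff_entry(339, 3, 1, 1)))
    entries <- entries[order(vapply(entries, `[[`, numeric(1), "tag"))]
    n <- length(entries)
    ifd_size <- 2 + n * 12 + 4
    # external value area directly after the IFD
    ext <- raw(0)
    ext_off <- pos + ifd_size
    ser <- raw(0)
    type_size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4)
    val_field <- vector("list", n)
    for (e in seq_len(n)) {
      en <- entries[[e]]
      if (en$tag == 273) next  # handled after data offset known
      bytes <- if (en$type == 2) en$value
        else if (en$type == 3) pack_u16(en$value, "little")
        else pack_u32(en$value, "little")
      if (length(bytes) <= 4) {
        val_field[[e]] <- c(bytes, raw(4 - length(bytes)))
      } else {
        val_field[[e]] <- pack_u32(ext_off + length(ext), "little")
        ext <- c(ext, bytes)
      }
    }
    if (length(ext) %% 2 == 1) ext <- c(ext, raw(1))
    data_off <- ext_off + length(ext)
    for (e in seq_len(n))
      if (entries[[e]]$tag == 273)
        val_field[[e]] <- pack_u32(data_off, "little")
    ifd <- pack_u16(n, "little")
    for (e in seq_len(n)) {
      en <- entries[[e]]
      ifd <- c(ifd, pack_u16(en$tag, "little"), pack_u16(en$type, "little"),
               pack_u32(en$count, "little"), val_field[[e]])
    }
    next_off <- if (p < length(pages)) {
      nd <- data_off + length(data)
      if (nd %% 2 == 1) nd <- nd + 1
      nd
    } else 0
    ifd <- c(ifd, pack_u32(next_off, "little"))
    page_raw <- c(ifd, ext, data)
    if (length(page_raw) %% 2 == 1) page_raw <- c(page_raw, raw(1))
    ifd_offsets[p] <- pos
    chunks[[p]] <- page_raw
    pos <- pos + length(page_raw)
  }
  writeBin(pack_u32(ifd_offsets[1], "little"), con)
  seek(con, 8)
  for (ch in chunks) writeBin(ch, con)
  invisible(path)
}

read_tiff <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  endian <- if (raw_all[1] == as.raw(0x49)) "little" else "big"
  if (unpack_u16(raw_all[3:4], endian) != 42)
    stop("not a TIFF file: ", path, call. = FALSE)
  off <- unpack_u32(raw_all[5:8], endian)
  pages <- list(); descs <- character(0)
  while (off != 0) {
    n <- unpack_u16(raw_all[off + 1:2], endian)
    tags <- list()
    for (e in seq_len(n)) {
      base <- off + 2 + (e - 1) * 12
      tag <- unpack_u16(raw_all[base + 1:2], endian)
      type <- unpack_u16(raw_all[base + 3:4], endian)
      count <- unpack_u32(raw_all[base + 5:8], endian)
      vsz <- c(1, 1, 2, 4, 8)[type] * count
      vraw <- if (vsz <= 4) raw_all[base + 9:12]
        else {
          vo <- unpack_u32(raw_all[base + 9:12], endian)
          raw_all[vo + seq_len(vsz)]
        }
      val <- switch(as.character(type),
        `1` = as.integer(vraw[seq_len(count)]),
        `2` = rawToChar(vraw[seq_len(max(count - 1, 0))]),
        `3` = unpack_u16(vraw[seq_len(2 * count)], endian),
        `4` = unpack_u32(vraw[seq_len(4 * count)], endian),
        vraw)
      tags[[as.character(tag)]] <- val
    }
    g <- function(t, default = NULL) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) default else v
    }
    if (g(259, 1) != 1)
      stop("unsupported TIFF compression (only uncompressed is supported)",
           call. = FALSE)
    w <- g(256); h <- g(257)
    bits <- g(258, 1)[1]
    if (!(bits %in% c(8, 16)))
      stop("unsupported TIFF bit depth: ", bits, call. = FALSE)
    k <- g(277, 1)
    offs <- g(273); cnts <- g(279)
    data <- raw(0)
    for (s in seq_along(offs))
      data <- c(data, raw_all[offs[s] + seq_len(cnts[s])])
    v <- if (bits == 16) unpack_u16(data, endian) else as.integer(data)
    img <- deinterleave_samples(v / (2^bits - 1), h, w, k)
    photometric <- g(262, 1)
    if (photometric == 0) img <- 1 - img  # WhiteIsZero
    pages[[length(pages) + 1]] <- img
    descs <- c(descs, g(270, NA_character_))
    nx <- off + 2 + n * 12
    off <- unpack_u32(raw_all[nx + 1:4], endian)
  }
  attr(pages, "descriptions") <- descs
  attr(pages, "bits") <- bits
  pages
}

# --- PNG --------------------------------------------------------------------

PNG_SIG <- as.raw(c(137, 80, 78, 71, 13, 10, 26, 10))

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- cpp_crc32(body)
  c(pack_u32(length(data), "big"), body, pack_u32(crc, "big"))
}

write_png_raster <- function(img, path, bits = 16, scale = TRUE) {
  rgbp <- length(dim(img)) == 3
  h <- dim(img)[1]; w <- dim(img)[2]; k <- if (rgbp) dim(img)[3] else 1L
  q <- quantize(img, bits, scale)
  samples <- interleave_samples(q)
  bytes <- if (bits == 16) pack_u16(samples, "big") else as.raw(samples)
  rowbytes <- w * k * (bits / 8)
  rows <- matrix(bytes, nrow = rowbytes)
  scan <- as.vector(rbind(raw(ncol(rows)), rows))  # filter byte 0 per row
  ihdr <- c(pack_u32(w, "big"), pack_u32(h, "big"), as.raw(bits),
            as.raw(if (rgbp) 2 else 0), as.raw(0), as.raw(0), as.raw(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(PNG_SIG, con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", memCompress(scan, "gzip")), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

read_png_raster <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  if (!identical(raw_all[1:8], PNG_SIG))
    stop("not a PNG file: ", path, call. = FALSE)
  pos <- 8
  idat <- raw(0)
  w <- h <- bits <- ctype <- interlace <- NULL
  while (pos < length(raw_all)) {
    len <- unpack_u32(raw_all[pos + 1:4], "big")
    type <- rawToChar(raw_all[pos + 5:8])
    data <- if (len > 0) raw_all[pos + 8 + seq_len(len)] else raw(0)
    if (type == "IHDR") {
      w <- unpack_u32(data[1:4], "big"); h <- unpack_u32(data[5:8], "big")
      bits <- as.integer(data[9]); ctype <- as.integer(data[10])
      interlace <- as.integer(data[13])
    } else if (type == "IDAT") {
      idat <- c(idat, data)
    } else if (type == "IEND") break
    pos <- pos + 12 + len
  }
  if (!(bits %in% c(8, 16)) || !(ctype %in% c(0, 2, 4, 6)) || interlace != 0)
    stop("unsupported PNG variant (supported: non-interlaced 8/16-bit grayscale or RGB(A))",
         call. = FALSE)
  k <- unname(c(`0` = 1L, `2` = 3L, `4` = 2L, `6` = 4L)[as.character(ctype)])
  scan <- memDecompress(idat, type = "gzip")
  rowbytes <- as.integer(w * k * (bits / 8))
  recon <- cpp_png_unfilter(scan, as.integer(h), rowbytes,
                            as.integer(k * (bits / 8)))
  v <- if (bits == 16) unpack_u16(recon, "big") else as.integer(recon)
  arr <- deinterleave_samples(v / (2^bits - 1), h, w, k)
  if (k == 2) arr <- arr[, , 1]            # gray + alpha -> gray
  if (k == 4) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  arr
}

# --- public API -------------------------------------------------------------

#' Read a raster image (TIFF or PNG)
#'
#' Uncompressed baseline TIFF (8/16-bit, grayscale or RGB, multi-page) and
#' non-interlaced PNG (8/16-bit grayscale or RGB(A)) are supported.
#' Intensities are returned as doubles `value / (2^bits - 1)` in \[0, 1\],
#' preserving the stored integers exactly. Multi-page TIFFs return a named
#' list of rasters, pages in file order; page names come from the
#' ImageDescription tag when present.
#'
#' @param path file path; format chosen by extension (.tif/.tiff/.png)
#' @param scale if `FALSE`, return raw stored integers (label images)
#' @return a raster matrix, an h x w x 3 array (RGB), or a named list of
#'   rasters for multi-page TIFF
#' @export
read_image <- function(path, scale = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  out <- if (ext %in% c("tif", "tiff")) {
    pages <- read_tiff(path)
    bits <- attr(pages, "bits")
    if (!scale) pages <- lapply(pages, function(p) {
      m <- round(p * (2^bits - 1)); storage.mode(m) <- "integer"; m
    })
    descs <- attr(pages, "descriptions")
    attributes(pages) <- NULL
    if (length(pages) == 1) pages[[1]]
    else { names(pages) <- descs; pages }
  } else if (ext == "png") {
    p <- read_png_raster(path)
    if (!scale) { p <- round(p * 65535); storage.mode(p) <- "integer" }
    p
  } else {
    stop("unsupported format '", ext,
         "'; supported formats: tif, tiff, png", call. = FALSE)
  }
  out
}

#' Write a raster image (TIFF or PNG)
#'
#' @param image raster matrix, h x w x 3 array, or named list of rasters
#'   (multi-page TIFF; names stored as page descriptions)
#' @param path output path (.tif/.tiff/.png)
#' @param bits 8 or 16 (default 16, matching 16-bit acquisition)
#' @param scale if `TRUE`, treat values as \[0, 1\] and quantize; if
#'   `FALSE`, store values as integers directly (label images)
#' @return the path, invisibly
#' @export
write_image <- function(image, path, bits = 16, scale = TRUE) {
  stopifnot(bits %in% c(8, 16))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (is.list(image)) write_tiff(image, path, bits, scale,
                                   descriptions = names(image))
    else write_tiff(list(image), path, bits, scale)
  } else if (ext == "png") {
    if (is.list(image))
      stop("PNG does not support multi-page images; use TIFF", call. = FALSE)
    write_png_raster(image, path, bits, scale)
  } else {
    stop("unsupported format '", ext,
         "'; supported formats: tif, tiff, png", call. = FALSE)
  }
  invisible(path)
}

#' Write / read a grid model as JSON
#'
#' Documented schema: fields of [grid_model] (pixels, degrees) plus
#' `units` and `schema` markers.
#'
#' @param grid a [grid_model]
#' @param path JSON path
#' @return `write_grid_json`: the path, invisibly; `read_grid_json`: a
#'   [grid_model]
#' @export
write_grid_json <- function(grid, path) {
  stopifnot(inherits(grid, "grid_model"))
  obj <- c(list(schema = "gridspot.grid_model/1", units = "pixels",
                angle_units = "degrees"),
           unclass(grid))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid_json
#' @export
read_grid_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid_model(obj$rows, obj$cols, obj$origin_x, obj$origin_y,
             obj$pitch_x, obj$pitch_y, obj$rotation_deg, obj$spot_radius)
}

#' Write spot ROIs as CSV
#'
#' Columns: i, j, x_min, y_min, x_max, y_max (half-open pixel ranges).
#'
#' @param rois ROI list from [extract_rois()]
#' @param path CSV path
#' @export
write_rois_csv <- function(rois, path) {
  df <- data.frame(i = vapply(rois, `[[`, numeric(1), "i"),
                   j = vapply(rois, `[[`, numeric(1), "j"),
                   x_min = vapply(rois, `[[`, numeric(1), "x0"),
                   y_min = vapply(rois, `[[`, numeric(1), "y0"),
                   x_max = vapply(rois, `[[`, numeric(1), "x1"),
                   y_max = vapply(rois, `[[`, numeric(1), "y1"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a region feature table as CSV
#'
#' Column order follows the canonical exported feature list: ID, Area,
#' Eccentricity, Mean intensity, Major axis, Minor axis.
#'
#' @param features data.frame from [extract_features()]
#' @param path CSV path
#' @export
write_features_csv <- function(features, path) {
  df <- data.frame(ID = features$id, Area = features$area,
                   Eccentricity = features$eccentricity,
                   `Mean intensity` = features$mean_intensity,
                   `Major axis` = features$major_axis,
                   `Minor axis` = features$minor_axis,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a synthetic scene with its truth bundle
#'
#' Channels as per-channel 16-bit TIFF (RGB as one TIFF), grid truth as
#' JSON, instance truth as 16-bit label TIFF, status/value truth as CSV.
#'
#' @param scene a `gridspot_scene`
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
export_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(scene$images))
    write_image(scene$images[[ch]], file.path(dir, paste0(ch, ".tif")))
  if (!is.null(scene$rgb))
    write_image(scene$rgb, file.path(dir, "rgb.tif"))
  write_grid_json(scene$truth_grid, file.path(dir, "truth_grid.json"))
  for (ch in names(scene$truth_instances))
    write_image(scene$truth_instances[[ch]],
                file.path(dir, paste0("truth_instances_", ch, ".tif")),
                scale = FALSE)
  if (!is.null(scene$truth_status))
    write.csv(scene$truth_status, file.path(dir, "truth_status.csv"),
              row.names = FALSE)
  if (!is.null(scene$truth_values)) {
    tv <- scene$truth_values
    write.csv(data.frame(i = rep(seq_len(nrow(tv)) - 1L, each = ncol(tv)),
                         j = rep(seq_len(ncol(tv)) - 1L, nrow(tv)),
                         value = as.vector(t(tv))),
              file.path(dir, "truth_values.csv"), row.names = FALSE)
  }
  invisible(dir)
}
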