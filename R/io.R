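#' Image volume container
#'
#' A light container for 2D images / 3D stacks: a numeric array with `x` the
#' fastest-varying (first) index, optional physical voxel spacing per axis,
#' and a record of the original intensity range when normalized.
#' Coordinates used throughout the package are 0-based voxel indices with
#' voxel centers at integers.
#'
#' @param data 2D or 3D numeric array, indexed `[x, y]` / `[x, y, z]`.
#' @param spacing Optional positive physical voxel spacing `(x, y[, z])`.
#' @param normalize Min-max scale intensities to `[0, 1]`; a constant image
#'   (degenerate range) maps to all zeros.
#' @return An object of class `image_volume` with fields `data`, `spacing`,
#'   `range` (original min/max before normalization, or `NULL`).
#' @export
image_volume <- function(data, spacing = NULL, normalize = FALSE) {
  stopifnot(is.numeric(data), length(dim(data)) %in% c(2L, 3L))
  if (!is.null(spacing)) {
    stopifnot(length(spacing) == length(dim(data)), all(spacing > 0))
    spacing <- as.numeric(spacing)
  }
  rng <- NULL
  data <- data * 1.0  # force double
  if (normalize) {
    rng <- range(data)
    data <- if (diff(rng) > 0) (data - rng[1]) / diff(rng)
            else array(0, dim(data))
  }
  structure(list(data = data, spacing = spacing, range = rng),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels%s, intensity [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = " x "),
              if (is.null(x$spacing)) ""
              else paste0(", spacing (", paste(x$spacing, collapse = ", "), ")"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

## ---------------------------------------------------------------------------
## Minimal TIFF codec: uncompressed grayscale, 8/16-bit unsigned or 32-bit
## float, single- or multi-page. The writer emits little-endian files; the
## reader accepts both byte orders. (No TIFF library is available in the
## supported dependency set, so the subset needed for microscopy stack
## round-trips is implemented here.)

tiff_tag <- function(con, endian) {
  tag <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
  type <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
  count <- readBin(con, "integer", 1, 4, endian = endian)
  value_raw <- readBin(con, "raw", 4)
  list(tag = tag, type = type, count = count, value_raw = value_raw)
}

tiff_tag_values <- function(con, t, endian) {
  type_size <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)[t$type]
  nbytes <- type_size * t$count
  read_vals <- function(raw_or_con, from_raw) {
    rd <- function(what, size, n, signed = TRUE) {
      if (from_raw) readBin(raw_or_con, what, n, size, signed = signed,
                            endian = endian)
      else readBin(raw_or_con, what, n, size, signed = signed,
                   endian = endian)
    }
    switch(as.character(t$type),
           "1" = rd("integer", 1, t$count, signed = FALSE),
           "3" = rd("integer", 2, t$count, signed = FALSE),
           "4" = rd("integer", 4, t$count),
           "11" = rd("double", 4, t$count),
           NULL)
  }
  if (nbytes <= 4) {
    read_vals(t$value_raw, TRUE)
  } else {
    offset <- readBin(t$value_raw, "integer", 1, 4, endian = endian)
    old <- seek(con, NA)
    seek(con, offset)
    vals <- read_vals(con, FALSE)
    seek(con, old)
    vals
  }
}

read_tiff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  endian <- if (identical(magic, as.raw(c(0x49, 0x49)))) "little"
            else if (identical(magic, as.raw(c(0x4d, 0x4d)))) "big"
            else stop("not a TIFF file: ", path, call. = FALSE)
  fortytwo <- readBin(con, "integer", 1, 2, endian = endian)
  if (fortytwo != 42L) stop("not a TIFF file: ", path, call. = FALSE)
  ifd_offset <- readBin(con, "integer", 1, 4, endian = endian)

  pages <- list()
  while (ifd_offset != 0) {
    seek(con, ifd_offset)
    n_tags <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
    tags <- lapply(seq_len(n_tags), function(i) tiff_tag(con, endian))
    ifd_offset <- readBin(con, "integer", 1, 4, endian = endian)
    names(tags) <- vapply(tags, `[[`, numeric(1), "tag")
    getv <- function(id, default = NULL) {
      t <- tags[[as.character(id)]]
      if (is.null(t)) return(default)
      tiff_tag_values(con, t, endian)
    }
    width <- getv(256)
    height <- getv(257)
    bits <- getv(258, 8L)
    compression <- getv(259, 1L)
    offsets <- getv(273)
    spp <- getv(277, 1L)
    rows_per_strip <- getv(278, height)
    byte_counts <- getv(279)
    sample_format <- getv(339, 1L)
    if (is.null(width) || is.null(height) || is.null(offsets))
      stop("malformed TIFF page", call. = FALSE)
    if (compression != 1L)
      stop("only uncompressed TIFF is supported", call. = FALSE)
    if (spp != 1L)
      stop("RGB/multi-sample TIFF is not supported; convert to grayscale",
           call. = FALSE)
    if (length(bits) > 1) bits <- bits[1]
    bytes_pp <- bits / 8
    if (!bits %in% c(8L, 16L, 32L))
      stop("unsupported bit depth: ", bits, call. = FALSE)
    if (bits == 32L && sample_format != 3L)
      stop("32-bit TIFF must be float (sample format 3)", call. = FALSE)
    if (is.null(byte_counts))
      byte_counts <- rep(rows_per_strip * width * bytes_pp, length(offsets))

    vals <- numeric(0)
    for (s in seq_along(offsets)) {
      seek(con, offsets[s])
      n <- byte_counts[s] / bytes_pp
      v <- if (bits == 32L)
        readBin(con, "double", n, 4, endian = endian)
      else
        readBin(con, "integer", n, bytes_pp, signed = FALSE, endian = endian)
      vals <- c(vals, v)
    }
    # TIFF rows are y-major: value index = x + width * y
    page <- array(vals[seq_len(width * height)], dim = c(width, height))
    pages[[length(pages) + 1]] <- page
  }
  if (!length(pages)) stop("TIFF file has no pages", call. = FALSE)
  if (length(pages) == 1) return(pages[[1]])
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

write_tiff <- function(data, path, bits = 32L) {
  stopifnot(length(dim(data)) %in% c(2L, 3L), bits %in% c(8L, 16L, 32L))
  dims <- dim(data)
  width <- dims[1]
  height <- dims[2]
  n_pages <- if (length(dims) == 3) dims[3] else 1L
  bytes_pp <- bits / 8
  page_bytes <- width * height * bytes_pp
  sample_format <- if (bits == 32L) 3L else 1L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49)), con)  # little-endian
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")  # first IFD at byte 8

  n_tags <- 9L
  ifd_size <- 2 + n_tags * 12 + 4
  offset <- 8
  for (p in seq_len(n_pages)) {
    data_offset <- offset + ifd_size
    next_ifd <- if (p < n_pages) data_offset + page_bytes else 0L
    seek(con, offset)
    writeBin(n_tags, con, size = 2, endian = "little")
    wtag <- function(tag, type, count, value) {
      writeBin(as.integer(tag), con, size = 2, endian = "little")
      writeBin(as.integer(type), con, size = 2, endian = "little")
      writeBin(as.integer(count), con, size = 4, endian = "little")
      if (type == 3) {  # SHORT padded to 4 bytes
        writeBin(as.integer(value), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(value), con, size = 4, endian = "little")
      }
    }
    wtag(256, 4, 1, width)          # ImageWidth
    wtag(257, 4, 1, height)         # ImageLength
    wtag(258, 3, 1, bits)           # BitsPerSample
    wtag(259, 3, 1, 1)              # Compression: none
    wtag(262, 3, 1, 1)              # Photometric: BlackIsZero
    wtag(273, 4, 1, data_offset)    # StripOffsets (single strip)
    wtag(278, 4, 1, height)         # RowsPerStrip
    wtag(279, 4, 1, page_bytes)     # StripByteCounts
    wtag(339, 3, 1, sample_format)  # SampleFormat
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")

    page <- if (length(dims) == 3) data[, , p] else data
    if (bits == 32L) {
      writeBin(as.numeric(page), con, size = 4, endian = "little")
    } else {
      v <- as.integer(round(page))
      if (any(v < 0) || any(v >= 2^bits))
        stop("integer TIFF output out of range for ", bits, " bits",
             call. = FALSE)
      writeBin(v, con, size = bytes_pp, endian = "little")
    }
    offset <- data_offset + page_bytes
  }
  invisible(path)
}

#' Load a grayscale TIFF image or stack
#'
#' Reads a single- or multi-page uncompressed grayscale TIFF (8/16-bit
#' unsigned or 32-bit float), min-max normalizes intensities to `[0, 1]`
#' (recording the original range; a constant image maps to all zeros), and
#' attaches the voxel spacing if given. Multi-page stacks become 3D volumes
#' with the page index as the z axis.
#'
#' @param path Path to a TIFF file.
#' @param spacing Optional physical voxel spacing `(x, y[, z])`.
#' @param normalize Normalize to `[0, 1]` (default `TRUE`).
#' @return An [image_volume()].
#' @export
load_volume <- function(path, spacing = NULL, normalize = TRUE) {
  data <- read_tiff(path)
  image_volume(data, spacing = spacing, normalize = normalize)
}

#' Save an image volume as TIFF
#'
#' Writes a (multi-page) uncompressed grayscale TIFF; 32-bit float by default
#' so intensities round-trip exactly.
#'
#' @param image 2D/3D numeric array or [image_volume()].
#' @param path Output path.
#' @param bits 8, 16 (unsigned integer) or 32 (float).
#' @export
save_volume <- function(image, path, bits = 32L) {
  write_tiff(as_image_data(image), path, bits = as.integer(bits))
}

#' Resample a volume to isotropic voxels
#'
#' Confocal stacks are commonly anisotropic (axial spacing coarser than
#' lateral). This linearly interpolates along the axial (z) axis so the axial
#' spacing matches the lateral one; lateral axes are untouched. The new axial
#' size is `round(nz * spacing_z / spacing_xy)`.
#'
#' @param vol An [image_volume()] with known `spacing`.
#' @return An [image_volume()] with isotropic spacing; unchanged (identical
#'   data) if the input is already isotropic.
#' @export
resample_isotropic <- function(vol) {
  stopifnot(inherits(vol, "image_volume"))
  if (is.null(vol$spacing))
    stop("voxel spacing is required for isotropic resampling", call. = FALSE)
  d <- dim(vol$data)
  if (length(d) == 2 || vol$spacing[3] == vol$spacing[1]) {
    if (length(unique(vol$spacing)) > 1)
      stop("lateral spacings differ; only axial anisotropy is supported",
           call. = FALSE)
    return(vol)
  }
  if (vol$spacing[1] != vol$spacing[2])
    stop("lateral spacings differ; only axial anisotropy is supported",
         call. = FALSE)
  ratio <- vol$spacing[3] / vol$spacing[1]
  nz <- d[3]
  if (nz < 2) return(image_volume(vol$data, spacing = rep(vol$spacing[1], 3)))
  nz_new <- as.integer(round(nz * ratio))
  # new voxel centers in old axial index units
  pos <- (seq_len(nz_new) - 1) / ratio
  pos <- pmin(pos, nz - 1)
  k0 <- pmin(floor(pos), nz - 2)
  w <- pos - k0
  out <- array(0, c(d[1], d[2], nz_new))
  for (j in seq_len(nz_new)) {
    a <- vol$data[, , k0[j] + 1]
    b <- vol$data[, , k0[j] + 2]
    out[, , j] <- (1 - w[j]) * a + w[j] * b
  }
  image_volume(out, spacing = rep(vol$spacing[1], 3))
}
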