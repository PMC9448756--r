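# Volume I/O: multi-page TIFF (baseline, uncompressed, grayscale) and raw
# binary + YAML sidecar. No TIFF package ships with the target image, so a
# minimal reader/writer for the baseline subset is implemented here; it
# round-trips uint8 / uint16 / float32 exactly. TIFF page order is increasing
# z (slow scan), page rows are depth (y), page columns are fast scan (x).

DTYPE_INFO <- list(
  uint8  = list(bits = 8L,  fmt = 1L, bytes = 1L),
  uint16 = list(bits = 16L, fmt = 1L, bytes = 2L),
  float  = list(bits = 32L, fmt = 3L, bytes = 4L)
)

sidecar_path <- function(path) paste0(path, ".yaml")

write_sidecar <- function(path, shape, dtype, spacing) {
  yaml::write_yaml(list(
    shape = as.integer(shape),
    dtype = dtype,
    spacing_mm = c(spacing$dx, spacing$dy, spacing$dz)
  ), sidecar_path(path))
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  yaml::read_yaml(sp)
}

## ---- minimal TIFF ----------------------------------------------------------

u16le <- function(v) {
  v <- as.integer(v)
  as.raw(c(v %% 256L, v %/% 256L))
}
u32le <- function(v) {
  v <- as.numeric(v)
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
           (v %/% 16777216) %% 256))
}

tiff_entry <- function(tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG; value fits inline (count 1)
  val <- if (type == 3L) c(u16le(value), as.raw(c(0, 0))) else u32le(value)
  c(u16le(tag), u16le(type), u32le(count), val)
}

page_payload <- function(slice_vec, dtype) {
  switch(dtype,
    uint8 = as.raw(as.integer(round(slice_vec))),
    uint16 = {
      v <- as.integer(round(slice_vec))
      out <- raw(2L * length(v))
      out[seq(1L, length(out), by = 2L)] <- as.raw(v %% 256L)
      out[seq(2L, length(out), by = 2L)] <- as.raw(v %/% 256L)
      out
    },
    float = writeBin(as.numeric(slice_vec), raw(), size = 4L,
                     endian = "little")
  )
}

write_tiff_stack <- function(data, dtype, path) {
  d <- dim(data)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  info <- DTYPE_INFO[[dtype]]
  strip_bytes <- nx * ny * info$bytes
  con <- file(path, "wb")
  on.exit(close(con))
  # header; first IFD follows all pixel strips
  data_start <- 8
  ifd_start <- data_start + nz * strip_bytes
  writeBin(charToRaw("II"), con)
  writeBin(u16le(42L), con)
  writeBin(u32le(ifd_start), con)
  for (z in seq_len(nz)) {
    writeBin(page_payload(as.vector(data[, , z]), dtype), con)
  }
  n_entries <- 10L
  ifd_size <- 2 + n_entries * 12 + 4
  for (z in seq_len(nz)) {
    strip_off <- data_start + (z - 1) * strip_bytes
    next_ifd <- if (z < nz) ifd_start + z * ifd_size else 0
    writeBin(u16le(n_entries), con)
    writeBin(tiff_entry(256L, 3L, 1L, nx), con)            # ImageWidth
    writeBin(tiff_entry(257L, 3L, 1L, ny), con)            # ImageLength
    writeBin(tiff_entry(258L, 3L, 1L, info$bits), con)     # BitsPerSample
    writeBin(tiff_entry(259L, 3L, 1L, 1L), con)            # Compression: none
    writeBin(tiff_entry(262L, 3L, 1L, 1L), con)            # BlackIsZero
    writeBin(tiff_entry(273L, 4L, 1L, strip_off), con)     # StripOffsets
    writeBin(tiff_entry(277L, 3L, 1L, 1L), con)            # SamplesPerPixel
    writeBin(tiff_entry(278L, 3L, 1L, ny), con)            # RowsPerStrip
    writeBin(tiff_entry(279L, 4L, 1L, strip_bytes), con)   # StripByteCounts
    writeBin(tiff_entry(339L, 3L, 1L, info$fmt), con)      # SampleFormat
    writeBin(u32le(next_ifd), con)
  }
  invisible(path)
}

decode_payload <- function(payload, dtype, n, endian) {
  switch(dtype,
    uint8 = as.numeric(as.integer(payload)),
    uint16 = {
      con <- rawConnection(payload)
      v <- as.numeric(readBin(con, "integer", n = n, size = 2L,
                              signed = FALSE, endian = endian))
      close(con)
      v
    },
    float = {
      con <- rawConnection(payload)
      v <- readBin(con, "double", n = n, size = 4L, endian = endian)
      close(con)
      v
    })
}

rd_u16 <- function(raw, off, endian) {
  b <- as.integer(raw[off + 1:2])
  if (endian == "little") b[1] + 256L * b[2] else b[2] + 256L * b[1]
}
rd_u32 <- function(raw, off, endian) {
  b <- as.numeric(as.integer(raw[off + 1:4]))
  if (endian == "little") sum(b * c(1, 256, 65536, 16777216))
  else sum(rev(b) * c(1, 256, 65536, 16777216))
}

read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  magic <- rawToChar(raw[1:2])
  endian <- switch(magic, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  if (rd_u16(raw, 2, endian) != 42L) stop("bad TIFF magic number in ", path)
  ifd_off <- rd_u32(raw, 4, endian)
  pages <- list()
  while (ifd_off != 0) {
    n <- rd_u16(raw, ifd_off, endian)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd_off + 2 + (i - 1) * 12
      tag <- rd_u16(raw, e, endian)
      type <- rd_u16(raw, e + 2, endian)
      count <- rd_u32(raw, e + 4, endian)
      unit <- switch(as.character(type), `3` = 2L, `4` = 4L, `1` = 1L, NA_integer_)
      if (is.na(unit)) next
      inline <- unit * count <= 4
      voff <- if (inline) e + 8 else rd_u32(raw, e + 8, endian)
      vals <- vapply(seq_len(count), function(k) {
        o <- voff + (k - 1) * unit
        if (unit == 2L) as.numeric(rd_u16(raw, o, endian))
        else if (unit == 4L) rd_u32(raw, o, endian)
        else as.numeric(as.integer(raw[o + 1]))
      }, numeric(1))
      tags[[as.character(tag)]] <- vals
    }
    pages[[length(pages) + 1L]] <- tags
    ifd_off <- rd_u32(raw, ifd_off + 2 + n * 12, endian)
  }
  if (!length(pages)) stop("TIFF file ", path, " contains no pages")
  t1 <- pages[[1]]
  nx <- as.integer(t1[["256"]]); ny <- as.integer(t1[["257"]])
  bits <- as.integer(t1[["258"]][1])
  comp <- if (is.null(t1[["259"]])) 1L else as.integer(t1[["259"]])
  fmt <- if (is.null(t1[["339"]])) 1L else as.integer(t1[["339"]][1])
  if (comp != 1L) stop("unsupported TIFF field Compression=", comp,
                       " (only uncompressed supported)")
  dtype <- if (fmt == 3L && bits == 32L) "float"
           else if (fmt == 1L && bits == 8L) "uint8"
           else if (fmt == 1L && bits == 16L) "uint16"
           else stop("unsupported TIFF dtype: BitsPerSample=", bits,
                     " SampleFormat=", fmt)
  nz <- length(pages)
  out <- array(0, dim = c(nx, ny, nz))
  for (z in seq_len(nz)) {
    tg <- pages[[z]]
    offs <- tg[["273"]]; cnts <- tg[["279"]]
    payload <- unlist(lapply(seq_along(offs), function(s) {
      raw[(offs[s] + 1):(offs[s] + cnts[s])]
    }), use.names = FALSE)
    vals <- decode_payload(payload, dtype, nx * ny, endian)
    if (length(vals) != nx * ny) {
      stop("TIFF page ", z, ": strip byte count inconsistent with shape")
    }
    out[, , z] <- vals
  }
  list(data = out, dtype = dtype)
}

## ---- raw binary ------------------------------------------------------------

write_raw_volume <- function(data, dtype, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(page_payload(as.vector(data), dtype), con)
  invisible(path)
}

read_raw_volume <- function(path, meta) {
  for (f in c("shape", "dtype")) {
    if (is.null(meta[[f]])) {
      stop("raw volume sidecar ", sidecar_path(path), " missing field '", f, "'")
    }
  }
  dtype <- meta$dtype
  if (!dtype %in% names(DTYPE_INFO)) {
    stop("unsupported dtype '", dtype, "' in sidecar field 'dtype'")
  }
  shape <- as.integer(meta$shape)
  n <- prod(shape)
  info <- DTYPE_INFO[[dtype]]
  if (file.size(path) != n * info$bytes) {
    stop("raw volume ", path, ": file size ", file.size(path),
         " does not match sidecar shape ", paste(shape, collapse = "x"),
         " (", n * info$bytes, " bytes expected)")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- switch(dtype,
    uint8 = as.numeric(as.integer(readBin(con, "raw", n = n))),
    uint16 = as.numeric(readBin(con, "integer", n = n, size = 2L,
                                signed = FALSE, endian = "little")),
    float = readBin(con, "double", n = n, size = 4L, endian = "little"))
  list(data = array(vals, dim = shape), dtype = dtype)
}

## ---- public API ------------------------------------------------------------

#' Read a voxel volume from disk
#'
#' Reads either a multi-page TIFF stack (pages = slow-scan z slices, rows =
#' depth y, columns = fast-scan x) or a raw little-endian binary volume with
#' a YAML sidecar `<path>.yaml` giving `shape`, `dtype` and `spacing_mm`.
#' The format is detected from the file's magic bytes, not the extension.
#'
#' @param path file to read.
#' @param spacing_override optional [voxel_spacing()] taking precedence over
#'   sidecar metadata.
#' @param mask if `TRUE`, return a logical volume (`value > 0`), inverting
#'   the `{0, 255}` convention used by [write_volume()] for masks.
#' @param quiet suppress the informational message.
#' @return a [voxel_grid()].
#' @export
read_volume <- function(path, spacing_override = NULL, mask = FALSE,
                        quiet = FALSE) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  head <- readBin(path, "raw", n = 2L)
  is_tiff <- length(head) == 2L && rawToChar(head) %in% c("II", "MM")
  meta <- read_sidecar(path)
  if (is_tiff) {
    vol <- read_tiff_stack(path)
  } else {
    if (is.null(meta)) {
      stop("raw binary volume requires a sidecar file: ", sidecar_path(path))
    }
    vol <- read_raw_volume(path, meta)
  }
  if (!is.null(meta) && !is.null(meta$shape) &&
      !identical(as.integer(meta$shape), as.integer(dim(vol$data)))) {
    stop("sidecar field 'shape' (", paste(meta$shape, collapse = "x"),
         ") does not match stored volume (",
         paste(dim(vol$data), collapse = "x"), ")")
  }
  spacing <- spacing_override
  if (is.null(spacing)) {
    if (!is.null(meta) && !is.null(meta$spacing_mm)) {
      s <- as.numeric(meta$spacing_mm)
      spacing <- voxel_spacing(s[1], s[2], s[3])
    } else {
      spacing <- oct_default_spacing()
      warning("no spacing metadata for ", path,
              "; assuming default ", format(spacing))
    }
  }
  data <- vol$data
  if (mask) data <- array(data > 0, dim = dim(data))
  if (!quiet) {
    message(sprintf("read %s: %s %s, spacing %s",
                    path, paste(dim(data), collapse = "x"), vol$dtype,
                    format(spacing)))
  }
  voxel_grid(data, spacing, vol$dtype)
}

#' Write a voxel volume to disk
#'
#' Writes a TIFF stack (default) or raw binary, always with a YAML sidecar
#' recording shape, dtype and spacing so that [read_volume()] inverts the
#' write exactly. Logical volumes are stored as uint8 `{0, 255}`.
#'
#' @param grid a [voxel_grid()].
#' @param path destination file.
#' @param format `"tiff"` or `"raw"`.
#' @export
write_volume <- function(grid, path, format = c("tiff", "raw")) {
  format <- match.arg(format)
  stopifnot(inherits(grid, "voxel_grid"))
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path))
  }
  data <- grid$data
  dtype <- grid$dtype_tag
  if (is.logical(data)) {
    data <- array(ifelse(data, 255, 0), dim = dim(data))
    dtype <- "uint8"
  }
  rng_max <- c(uint8 = 255, uint16 = 65535)[dtype]
  if (!is.na(rng_max) && (min(data) < 0 || max(data) > rng_max)) {
    stop("data out of range for dtype '", dtype, "'")
  }
  if (format == "tiff") write_tiff_stack(data, dtype, path)
  else write_raw_volume(data, dtype, path)
  write_sidecar(path, dim(data), dtype, grid$spacing)
  invisible(path)
}
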