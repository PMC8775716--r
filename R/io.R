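# Readers and writers: 2-column delimited traces/thermograms, ASCII and
# baseline-TIFF height maps with a JSON pixel-size sidecar.

detect_sep <- function(line) {
  if (grepl(",", line)) "," else if (grepl("\t", line)) "\t" else ""
}

read_two_column <- function(path, min_points) {
  if (!file.exists(path))
    fm_error(sprintf("file not found: %s", path), "fm_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) fm_error(sprintf("empty file: %s", path), "fm_io_error")
  sep <- detect_sep(lines[1])
  split1 <- strsplit(trimws(lines[1]),
                     if (sep == "") "[[:space:]]+" else sep)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(split1))))
  units <- if (has_header) trimws(split1) else NULL
  body <- if (has_header) lines[-1] else lines
  rows <- strsplit(trimws(body), if (sep == "") "[[:space:]]+" else sep)
  bad <- which(lengths(rows) != 2L)
  if (length(bad))
    fm_error(sprintf("line %d of %s does not have 2 columns",
                     bad[1] + has_header, path), "fm_parse_error")
  m <- suppressWarnings(matrix(as.numeric(unlist(rows)), ncol = 2,
                               byrow = TRUE))
  if (any(is.na(m))) {
    bad <- which(apply(is.na(m), 1, any))[1]
    fm_error(sprintf("non-numeric value on line %d of %s",
                     bad + has_header, path), "fm_parse_error")
  }
  if (nrow(m) < min_points)
    fm_error(sprintf("%s has %d rows; need at least %d", path, nrow(m),
                     min_points), "fm_io_error")
  if (!is_strictly_increasing(m[, 1])) {
    fm_warn(sprintf("abscissa in %s not strictly increasing; sorting",
                    basename(path)))
    m <- m[order(m[, 1]), , drop = FALSE]
    m <- m[!duplicated(m[, 1]), , drop = FALSE]
  }
  list(x = m[, 1], y = m[, 2], units = units)
}

#' Read a kinetic trace from a 2-column CSV/TSV file
#'
#' Columns are time (minutes) and signal; an optional header row names
#' the units. A non-increasing time column is sorted with a warning.
#'
#' @param path File path.
#' @return A [kinetic_trace()].
#' @export
read_trace <- function(path) {
  d <- read_two_column(path, min_points = 5L)
  kinetic_trace(d$x, d$y, label = basename(path), units = d$units)
}

#' Read a thermogram from a 2-column CSV/TSV file
#'
#' Columns are temperature (degC) and heat capacity (kJ/mol/degC).
#'
#' @param path File path.
#' @param scan_index Scan number (1 = first heating, 2 = rescan).
#' @return A [thermogram()].
#' @export
read_thermogram <- function(path, scan_index = 1L) {
  d <- read_two_column(path, min_points = 20L)
  thermogram(d$x, d$y, scan_index = scan_index, label = basename(path))
}

#' Write a kinetic trace or thermogram as 2-column CSV
#'
#' @param x A `kinetic_trace` or `thermogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  if (inherits(x, "kinetic_trace")) {
    header <- paste(x$units %||% c("t_min", "signal_au"), collapse = ",")
    body <- paste(format(x$t, digits = 15), format(x$y, digits = 15),
                  sep = ",")
  } else if (inherits(x, "thermogram")) {
    header <- "T_degC,Cp_kJ_mol_degC"
    body <- paste(format(x$T_c, digits = 15), format(x$Cp, digits = 15),
                  sep = ",")
  } else fm_error("unsupported series type", "fm_io_error")
  writeLines(c(header, body), path)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, pixel_size, label = "", scale = NULL) {
  meta <- list(pixel_size_nm = pixel_size, label = label)
  if (!is.null(scale)) meta$scale_nm_per_count <- scale
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a height map
#'
#' `format = "ascii"` writes a whitespace-delimited matrix, one scanline
#' per row; `format = "tiff"` writes a single-strip 32-bit float
#' grayscale baseline TIFF. Either way a JSON sidecar `<path>.json`
#' records the pixel size in nm.
#'
#' @param map A [height_map()].
#' @param path Output path.
#' @param format `"ascii"` or `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_heightmap <- function(map, path, format = c("ascii", "tiff")) {
  stopifnot(inherits(map, "height_map"))
  format <- match.arg(format)
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    utils::write.table(map$heights, con, row.names = FALSE,
                       col.names = FALSE)
  } else {
    write_tiff_float(map$heights, path)
  }
  write_sidecar(path, map$pixel_size, map$label)
  invisible(path)
}

#' Read a height map (ASCII matrix or grayscale TIFF)
#'
#' The pixel size is taken from the JSON sidecar `<path>.json` or the
#' `pixel_size` argument. Integer TIFFs are scaled to nm with the
#' sidecar's `scale_nm_per_count`.
#'
#' @param path File path (`.tif`/`.tiff` for TIFF, anything else is
#'   parsed as an ASCII matrix).
#' @param pixel_size Pixel size in nm/pixel; overrides the sidecar.
#' @return A [height_map()].
#' @export
read_heightmap <- function(path, pixel_size = NULL) {
  if (!file.exists(path))
    fm_error(sprintf("file not found: %s", path), "fm_io_error")
  meta <- read_sidecar(path)
  ps <- pixel_size %||% meta$pixel_size_nm
  if (is.null(ps))
    fm_error(paste0(
      "pixel size unknown: provide a '", sidecar_path(path),
      "' sidecar with pixel_size_nm or pass pixel_size="),
      "fm_io_error")
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  if (is_tiff) {
    tf <- read_tiff(path)
    H <- tf$data
    if (tf$sample_format != 3L) {      # integer counts need a scale
      scale <- meta$scale_nm_per_count
      if (is.null(scale))
        fm_error("integer TIFF requires scale_nm_per_count in the sidecar",
                 "fm_io_error")
      H <- H * scale
    }
  } else {
    rows <- strsplit(trimws(readLines(path, warn = FALSE)), "[[:space:]]+")
    rows <- rows[lengths(rows) > 0]
    if (length(unique(lengths(rows))) != 1L)
      fm_error(sprintf("non-rectangular ASCII matrix in %s", path),
               "fm_parse_error")
    H <- matrix(as.numeric(unlist(rows)), nrow = length(rows),
                byrow = TRUE)
    if (any(is.na(H)))
      fm_error(sprintf("non-numeric value in ASCII matrix %s", path),
               "fm_parse_error")
  }
  height_map(H, ps, label = meta$label %||% basename(path))
}

# --- minimal baseline TIFF (single image, grayscale) ------------------
# Little-endian writer: 32-bit IEEE float, single strip, no compression.
write_tiff_float <- function(H, path) {
  nr <- nrow(H); nc <- ncol(H)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")   # IFD offset
  tags <- list(  # tag, type, count, value
    c(256L, 3L, 1L, nc),        # ImageWidth
    c(257L, 3L, 1L, nr),        # ImageLength
    c(258L, 3L, 1L, 32L),       # BitsPerSample
    c(259L, 3L, 1L, 1L),        # Compression: none
    c(262L, 3L, 1L, 1L),        # Photometric: BlackIsZero
    c(273L, 4L, 1L, NA),        # StripOffsets (patched below)
    c(277L, 3L, 1L, 1L),        # SamplesPerPixel
    c(278L, 3L, 1L, nr),        # RowsPerStrip
    c(279L, 4L, 1L, 4L * nr * nc), # StripByteCounts
    c(339L, 3L, 1L, 3L)         # SampleFormat: IEEE float
  )
  data_offset <- 8L + 2L + 12L * length(tags) + 4L
  tags[[6]][4] <- data_offset
  writeBin(length(tags), con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(tg[1], con, size = 2, endian = "little")
    writeBin(tg[2], con, size = 2, endian = "little")
    writeBin(tg[3], con, size = 4, endian = "little")
    if (tg[2] == 3L) {  # SHORT packed into the low bytes of the value
      writeBin(tg[4], con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(tg[4], con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")   # no next IFD
  # row-major pixel data (scanline by scanline)
  writeBin(as.numeric(t(H)), con, size = 4, endian = "little")
  invisible(path)
}

read_uint <- function(raw, offset, size, endian) {
  bytes <- as.integer(raw[(offset + 1):(offset + size)])
  if (endian == "big") bytes <- rev(bytes)
  sum(bytes * 256^(seq_len(size) - 1))
}

# Reader for baseline grayscale TIFFs: uncompressed, 8/16/32-bit
# unsigned or 32-bit float, one sample per pixel, any strip layout.
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  byte_order <- rawToChar(raw[1:2])
  endian <- if (byte_order == "II") "little"
            else if (byte_order == "MM") "big"
            else fm_error("not a TIFF file", "fm_parse_error")
  ifd_off <- read_uint(raw, 4, 4, endian)
  n_tags <- read_uint(raw, ifd_off, 2, endian)
  tags <- list()
  for (i in seq_len(n_tags)) {
    base <- ifd_off + 2 + (i - 1) * 12
    tag <- read_uint(raw, base, 2, endian)
    type <- read_uint(raw, base + 2, 2, endian)
    count <- read_uint(raw, base + 4, 4, endian)
    type_size <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)[type]
    inline <- count * type_size <= 4
    val_off <- if (inline) base + 8 else read_uint(raw, base + 8, 4, endian)
    vals <- vapply(seq_len(count), function(k)
      read_uint(raw, val_off + (k - 1) * type_size, type_size, endian),
      numeric(1))
    tags[[as.character(tag)]] <- vals
  }
  g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
  nc <- g(256); nr <- g(257)
  bits <- g(258, 8)[1]
  if ((g(259, 1))[1] != 1)
    fm_error("compressed TIFFs are not supported", "fm_parse_error")
  if ((g(277, 1))[1] != 1)
    fm_error("only single-sample grayscale TIFFs are supported",
             "fm_parse_error")
  fmt <- g(339, 1)[1]
  offsets <- g(273)
  counts <- g(279)
  rows_per_strip <- g(278, nr)[1]
  payload <- raw(0)
  for (s in seq_along(offsets))
    payload <- c(payload, raw[(offsets[s] + 1):(offsets[s] + counts[s])])
  n_px <- nr * nc
  vals <- if (fmt == 3L) {
    if (bits != 32) fm_error("only 32-bit float TIFFs supported",
                             "fm_parse_error")
    readBin(payload, "double", n = n_px, size = 4, endian = endian)
  } else {
    readBin(payload, "integer", n = n_px, size = bits / 8,
            signed = bits < 32, endian = endian)
  }
  vals <- as.numeric(vals)
  if (fmt != 3L && bits < 32) vals[vals < 0] <- vals[vals < 0] + 2^bits
  list(data = matrix(vals, nr, nc, byrow = TRUE),
       sample_format = as.integer(fmt), bits = bits)
}
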