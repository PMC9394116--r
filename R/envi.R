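# Minimal ENVI-format cube I/O: enough to read the header + flat binary
# layout produced by line-scan hyperspectral systems (BSQ/BIL/BIP, little or
# big endian, common numeric data types), and to write cubes for round-trip
# tests.

envi_dtypes <- list(
  `1` = list(what = "integer", size = 1L),
  `2` = list(what = "integer", size = 2L),
  `4` = list(what = "numeric", size = 4L),
  `5` = list(what = "numeric", size = 8L),
  `12` = list(what = "integer", size = 2L)
)

parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) next
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- tolower(trimws(parts[1]))
    kv[[key]] <- trimws(paste(parts[-1], collapse = "="))
  }
  kv
}

#' Read an ENVI hyperspectral cube
#'
#' Reads a flat-binary ENVI image given its text header. Supports BSQ, BIL
#' and BIP interleaves and byte/int16/uint16/float32/float64 data types.
#'
#' @param header Path to the `.hdr` text header.
#' @param data Path to the binary image; defaults to `header` minus its
#'   `.hdr` extension.
#' @return Numeric array `lines x samples x bands`, with attribute
#'   `"wavelength"` when the header lists one.
#' @export
read_envi <- function(header, data = sub("\\.hdr$", "", header)) {
  kv <- parse_envi_header(header)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  if (!all(need %in% names(kv))) {
    stop("ENVI header is missing required fields", call. = FALSE)
  }
  ns <- as.integer(kv$samples); nl <- as.integer(kv$lines); nb <- as.integer(kv$bands)
  dt <- envi_dtypes[[kv[["data type"]]]]
  if (is.null(dt)) stop("unsupported ENVI data type ", kv[["data type"]], call. = FALSE)
  endian <- if (identical(kv[["byte order"]], "1")) "big" else "little"
  offset <- as.integer(kv[["header offset"]] %||% "0")
  con <- file(data, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", n = offset)
  vals <- readBin(con, dt$what, n = ns * nl * nb, size = dt$size,
                  endian = endian,
                  signed = !(kv[["data type"]] %in% c("1", "12")))
  vals <- as.numeric(vals)
  cube <- switch(tolower(kv$interleave),
    bsq = aperm(array(vals, c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(vals, c(ns, nb, nl)), c(3, 1, 2)),
    bip = aperm(array(vals, c(nb, ns, nl)), c(3, 2, 1)),
    stop("unsupported interleave ", kv$interleave, call. = FALSE)
  )
  if (!is.null(kv$wavelength)) {
    wl <- as.numeric(strsplit(gsub("[{}]", "", kv$wavelength), ",")[[1]])
    attr(cube, "wavelength") <- wl
  }
  cube
}

#' Write an ENVI cube (float32, BSQ)
#'
#' Companion writer for [read_envi()], mainly for tests and small exports.
#'
#' @param cube Numeric array `lines x samples x bands`.
#' @param path Output path for the binary image; the header is written to
#'   `paste0(path, ".hdr")`.
#' @param wavelength Optional per-band wavelengths recorded in the header.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, wavelength = NULL) {
  stopifnot(length(dim(cube)) == 3)
  nl <- dim(cube)[1]; ns <- dim(cube)[2]; nb <- dim(cube)[3]
  hdr <- c(
    "ENVI",
    paste("samples =", ns),
    paste("lines =", nl),
    paste("bands =", nb),
    "header offset = 0",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0"
  )
  if (!is.null(wavelength)) {
    hdr <- c(hdr, paste0("wavelength = {", paste(wavelength, collapse = ", "), "}"))
  }
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(cube, c(2, 1, 3))), con, size = 4L)
  invisible(path)
}
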