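# ENVI-format cube I/O: a plain-text header (.hdr) plus a band-sequential
# 32-bit float binary (.dat).  Only the subset of the header vocabulary
# needed for reflectance cubes with a wavelength list is supported.

#' Hyperspectral cube container
#'
#' @param values numeric array of reflectance values, rows x cols x bands.
#' @param wavelengths strictly increasing wavelength vector (nm) matching
#'   the band dimension.
#' @return an object of class `hyper_cube`.
#' @export
hyper_cube <- function(values, wavelengths) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("values must be a rows x cols x bands array")
  }
  wavelengths <- as.numeric(wavelengths)
  if (dim(values)[3] != length(wavelengths)) {
    stop("band dimension does not match the wavelength vector")
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (any(!is.finite(values))) stop("cube values must be finite")
  structure(list(values = values, wavelengths = wavelengths),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("hyper_cube: %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$values)

#' Write a cube in ENVI format
#'
#' Writes `<path>.dat` (band-sequential 32-bit little-endian floats, each
#' band stored line by line) and `<path>.hdr` (text header carrying the
#' dimensions and the wavelength list).
#'
#' @param cube a [hyper_cube()].
#' @param path output path without extension.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$values)
  hdr <- c("ENVI",
           "description = {ripenet hyperspectral cube}",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 4",
           "interleave = bsq",
           "byte order = 0",
           "wavelength units = Nanometers",
           paste0("wavelength = {",
                  paste(format(cube$wavelengths, trim = TRUE, digits = 10),
                        collapse = ", "), "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  # BSQ with C line order: transpose each band slice
  for (b in seq_len(d[3])) {
    writeBin(as.numeric(t(cube$values[, , b])), con, size = 4L,
             endian = "little")
  }
  invisible(path)
}

#' Read an ENVI cube
#'
#' @param path path without extension, or the `.hdr`/`.dat` file itself.
#' @return a [hyper_cube()].
#' @export
read_envi <- function(path) {
  path <- sub("\\.(hdr|dat)$", "", path)
  hdr_file <- paste0(path, ".hdr")
  if (!file.exists(hdr_file)) stop("header not found: ", hdr_file)
  txt <- paste(readLines(hdr_file, warn = FALSE), collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(txt, regexpr(paste0(key, "\\s*=\\s*[0-9]+"), txt))
    if (!length(m)) stop("missing header field: ", key)
    as.integer(sub(".*=\\s*", "", m))
  }
  lines <- get_num("lines")
  samples <- get_num("samples")
  bands <- get_num("bands")
  dtype <- get_num("data type")
  if (!dtype %in% c(4L, 5L)) stop("unsupported ENVI data type: ", dtype)
  m <- regmatches(txt, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", txt))
  if (!length(m)) stop("header has no wavelength list")
  wl <- as.numeric(strsplit(gsub(".*\\{|\\}", "", m), ",")[[1]])
  if (length(wl) != bands) stop("wavelength list does not match band count")
  interleave <- regmatches(txt, regexpr("interleave\\s*=\\s*\\w+", txt))
  if (length(interleave) && !grepl("bsq", interleave, ignore.case = TRUE)) {
    stop("only BSQ interleave is supported")
  }
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  n <- lines * samples * bands
  raw <- readBin(con, "numeric", n = n, size = if (dtype == 4L) 4L else 8L,
                 endian = "little")
  if (length(raw) != n) stop("binary payload shorter than the header claims")
  vals <- array(0, c(lines, samples, bands))
  for (b in seq_len(bands)) {
    off <- (b - 1L) * lines * samples
    vals[, , b] <- t(matrix(raw[(off + 1L):(off + lines * samples)],
                            samples, lines))
  }
  hyper_cube(vals, wl)
}
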