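# Minimal NumPy .npy (format 1.0) writer/reader for the spectrogram matrix
# export. Arrays are written C-ordered as little-endian float64 ('<f8') or
# int32 ('<i4'), which numpy.load() reads directly.

npy_magic <- function() c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1L, 0L)))

#' Write a numeric array in NumPy .npy format
#'
#' @param x Numeric vector, matrix or array. Doubles are written as `<f8`,
#'   integers as `<i4`, C-ordered, little-endian (format version 1.0).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path) {
  dims <- dim(x) %||% length(x)
  descr <- if (is.integer(x)) "<i4" else "<f8"
  shape <- paste0("(", paste0(dims, ",", collapse = " "), ")")
  shape <- sub(",\\)$", if (length(dims) == 1L) ",)" else ")", shape)
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    descr, shape)
  total <- 10L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(npy_magic(), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  xv <- if (length(dims) > 1L) as.vector(aperm(x, rev(seq_along(dims)))) else as.vector(x)
  writeBin(xv, con, size = if (is.integer(x)) 4L else 8L, endian = "little")
  invisible(path)
}

#' Read a NumPy .npy file written by [write_npy()]
#'
#' Supports the subset this package writes: version 1.0, `<f8`/`<i4`/`<i8`,
#' C or Fortran order.
#'
#' @param path Input path.
#' @return Numeric vector or array.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, "raw", 8L)
  if (!identical(magic[1:6], npy_magic()[1:6]))
    stop("not an npy file: ", path, call. = FALSE)
  hlen <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
  header <- readChar(con, hlen, useBytes = TRUE)
  descr <- sub(".*'descr': *'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order': *True", header)
  shape_s <- sub(".*'shape': *\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("[ ,]+$", "", shape_s), ",")[[1]])
  n <- prod(dims)
  x <- switch(descr,
              "<f8" = readBin(con, "double", n, size = 8L, endian = "little"),
              "<i4" = readBin(con, "integer", n, size = 4L, endian = "little"),
              "<i8" = as.integer(readBin(con, "double", n, size = 8L, endian = "little")),
              stop("unsupported npy dtype: ", descr, call. = FALSE))
  if (length(dims) <= 1L) return(x)
  if (fortran) array(x, dims) else aperm(array(x, rev(dims)), rev(seq_along(dims)))
}

#' Export a spectrogram power matrix
#'
#' Writes the epochs x frequencies x channels power array and its axes as a
#' directory of uncompressed NumPy `.npy` files plus plain-text sidecars —
#' directly loadable from Python (`numpy.load`) or back into R
#' ([read_npy()]):
#' `power.npy`, `freqs_hz.npy`, `epoch_index_map.npy`, `channels.txt`,
#' `manifest.json`.
#'
#' @param spec A [multitaper_spectrogram()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_spectrogram_matrix <- function(spec, dir) {
  stopifnot(inherits(spec, "spectrogram"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_npy(spec$power, file.path(dir, "power.npy"))
  write_npy(spec$freqs_hz, file.path(dir, "freqs_hz.npy"))
  write_npy(as.integer(spec$epoch_index_map), file.path(dir, "epoch_index_map.npy"))
  writeLines(spec$channel_names, file.path(dir, "channels.txt"))
  manifest <- list(power_dims = dim(spec$power),
                   dim_order = c("epoch", "frequency", "channel"),
                   power_units = "uV^2/Hz",
                   freq_range_hz = range(spec$freqs_hz),
                   fs_hz = spec$fs)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
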