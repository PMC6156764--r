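#' Read a single-plane grayscale TIFF channel
#'
#' Reads an 8- or 16-bit single-plane grayscale TIFF into a numeric matrix
#' scaled to \[0, 1\] (the scale all pipeline stages operate on).
#'
#' @param path path to the TIFF file.
#' @return numeric matrix (rows x cols).
#' @export
read_channel_tiff <- function(path) {
  if (!file.exists(path)) stop("channel file not found: ", path)
  img <- tiff::readTIFF(path, all = FALSE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L)
      stop("expected a single-plane grayscale TIFF: ", path)
    img <- img[, , 1L]
  }
  img
}

#' Write a grayscale channel as 16-bit TIFF
#'
#' Quantizes a \[0, 1\] float image to 16 bit (the typical microscope bit
#' depth) and writes it uncompressed.
#'
#' @param image numeric matrix with values in \[0, 1\].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_channel_tiff <- function(image, path) {
  stopifnot(is.matrix(image))
  q <- round(pmin(pmax(image, 0), 1) * 65535) / 65535
  tiff::writeTIFF(q, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Write / read an integer label map as 16-bit TIFF
#'
#' Label maps (0 = background, labels 1..n) are stored as 16-bit grayscale
#' with the label as the pixel value, the conventional exchange format for
#' segmentation masks.
#'
#' @param labels integer matrix of labels.
#' @param path file path.
#' @return `write_label_tiff` invisibly returns `path`;
#'   `read_label_tiff` returns an integer matrix.
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(is.matrix(labels))
  if (max(labels) > 65535L) stop("more than 65535 labels cannot be stored in 16 bit")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- read_channel_tiff(path)
  storage.mode(m) <- "double"
  lab <- as.integer(round(m * 65535))
  matrix(lab, nrow = nrow(m))
}

#' Plain `key: value` configuration files
#'
#' Minimal flat config format used for simulation and run manifests: one
#' `key: value` pair per line, `#` comments, vectors as comma-separated
#' values. Numbers are parsed as numeric, `true`/`false` as logical.
#'
#' @param x named list of scalars/vectors to write.
#' @param path file path.
#' @return `write_plain_config` invisibly returns `path`;
#'   `read_plain_config` returns a named list.
#' @export
write_plain_config <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)))
  fmt <- function(v) {
    if (is.numeric(v)) paste(format(v, digits = 17, scientific = FALSE,
                                    trim = TRUE), collapse = ", ")
    else if (is.logical(v)) paste(tolower(as.character(v)), collapse = ", ")
    else paste(as.character(v), collapse = ", ")
  }
  lines <- vapply(names(x), function(k) paste0(k, ": ", fmt(x[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_plain_config
#' @export
read_plain_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    sep <- regexpr(":", ln, fixed = TRUE)
    if (sep < 0) stop("malformed config line (expected 'key: value'): ", ln)
    key <- trimws(substr(ln, 1, sep - 1))
    val <- trimws(substr(ln, sep + 1, nchar(ln)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) out[[key]] <- num
    else if (all(tolower(parts) %in% c("true", "false")))
      out[[key]] <- tolower(parts) == "true"
    else out[[key]] <- parts
  }
  out
}

#' Restore a simulation_config from a plain config file
#'
#' @param path path written by [write_plain_config()] (e.g. the
#'   `*_config.txt` emitted by [simulate_to_dir()]).
#' @return a [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  do.call(simulation_config, read_plain_config(path))
}
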