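# Image input/output.
#
# Supported formats: PNG (via the png package), plain ASCII PGM (P2), and CSV
# matrices. TIFF is not supported in this build (no TIFF reader available in
# the target library set); pixel size therefore always comes from the caller.

#' Read a grayscale image
#'
#' Format is chosen by extension: `.png`, `.pgm` (ASCII P2), or `.csv`.
#' Multi-channel PNGs are averaged to one channel.
#'
#' @param path File path.
#' @param pixel_size_um Micrometers per pixel to attach (default 1).
#' @return A [gray_image()] with intensities on their native scale
#'   (0-255 for 8-bit sources).
#' @export
read_gray_image <- function(path, pixel_size_um = 1) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                          c(1, 2), mean)
      a * 255
    },
    pgm = .read_pgm(path),
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    stop("unsupported image format: .", ext))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  gray_image(m, pixel_size_um = pixel_size_um)
}

#' Write a grayscale image
#'
#' `.png` clamps to [0, 255] and writes 8-bit; `.pgm` writes ASCII P2;
#' `.csv` writes the raw matrix.
#'
#' @param img A [gray_image()] or matrix.
#' @param path Output path (extension selects the format).
#' @return Invisibly, `path`.
#' @export
write_gray_image <- function(img, path) {
  m <- unclass(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(pmin(pmax(m / 255, 0), 1), path),
    pgm = .write_pgm(m, path),
    csv = utils::write.table(m, path, sep = ",", row.names = FALSE,
                             col.names = FALSE),
    stop("unsupported image format: .", ext))
  invisible(path)
}

.read_pgm <- function(path) {
  tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (tok[1] != "P2") stop("only ASCII PGM (P2) is supported")
  nc <- as.integer(tok[2]); nr <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != nr * nc) stop("corrupt PGM: wrong pixel count")
  matrix(vals, nr, nc, byrow = TRUE)
}

.write_pgm <- function(m, path) {
  m <- round(pmin(pmax(m, 0), 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
}

#' Write a directionality histogram as CSV
#'
#' Columns: `bin_start_deg`, `bin_end_deg`, `amount`.
#'
#' @param hist A `directionality_histogram`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_histogram_csv <- function(hist, path) {
  utils::write.csv(as.data.frame(hist), path, row.names = FALSE)
  invisible(path)
}
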