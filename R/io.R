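# PNG helpers: 8-bit grayscale in [0, 1]; masks round-trip as 0/255.

#' Read a grayscale PNG as a matrix in `[0, 1]`
#' @param path PNG file path.
#' @export
read_gray_png <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m
}

#' Write a matrix in `[0, 1]` as an 8-bit grayscale PNG
#' @param m Matrix with values in `[0, 1]`.
#' @param path Output path.
#' @export
write_gray_png <- function(m, path) {
  ok <- try(png::writePNG(m, target = path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("failed to write PNG: ", path)
  invisible(path)
}
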