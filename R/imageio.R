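# Frame I/O. Internally every frame is a width x height x 3 array in the
# y-up image coordinate system CS_I (x = column = direction of progression,
# y = 1 at the bottom row). PNG files store rows top-down, so reading and
# writing flips the vertical axis.

#' Write a frame to a PNG file
#' @param rgb width x height x 3 array in `[0, 1]` (y-up orientation).
#' @param path output file.
#' @export
write_frame_png <- function(rgb, path) {
  H <- dim(rgb)[2]
  png::writePNG(aperm(rgb[, H:1, , drop = FALSE], c(2, 1, 3)), path)
  invisible(path)
}

#' Read a frame from a PNG file
#' @param path PNG file.
#' @return width x height x 3 array in `[0, 1]`, y-up orientation.
#' @export
read_frame_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  a <- a[, , 1:3, drop = FALSE]
  arr <- aperm(a, c(2, 1, 3))
  arr[, dim(arr)[2]:1, , drop = FALSE]
}

# HSV planes of a frame (or sub-window). h in degrees [0, 360).
frame_hsv <- function(rgb) {
  d <- dim(rgb)
  m <- grDevices::rgb2hsv(rbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]),
                                as.vector(rgb[, , 3])), maxColorValue = 1)
  list(h_deg = matrix(m[1, ] * 360, d[1], d[2]),
       s = matrix(m[2, ], d[1], d[2]),
       v = matrix(m[3, ], d[1], d[2]))
}
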