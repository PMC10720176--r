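#' Raster helpers
#'
#' Images are held as numeric arrays `[row, col, channel]` with values in
#' `[0, 1]`; masks as logical/integer matrices `[row, col]`. The continuous
#' coordinate of the centre of pixel `(r, c)` (1-indexed) is
#' `(x, y) = (c - 0.5, r - 0.5)`, consistent with the package-wide top-left
#' origin, x = column convention.
#'
#' @name raster-helpers
#' @keywords internal
NULL

#' Rasterize a filled ellipse into a binary mask
#'
#' A pixel belongs to the mask when its centre lies inside the ellipse.
#'
#' @param e an [ellipse()].
#' @param nrow,ncol mask dimensions (px).
#' @return logical matrix `[nrow, ncol]`.
#' @export
rasterize_ellipse <- function(e, nrow, ncol) {
  e <- as_ellipse(e)
  m <- matrix(FALSE, nrow, ncol)
  b <- ellipse_to_bbox(e)
  r0 <- max(1L, floor(b$y_b - b$h_b / 2) + 1L)
  r1 <- min(nrow, ceiling(b$y_b + b$h_b / 2))
  c0 <- max(1L, floor(b$x_b - b$w_b / 2) + 1L)
  c1 <- min(ncol, ceiling(b$x_b + b$w_b / 2))
  if (r0 > r1 || c0 > c1) return(m)
  cc <- (c0:c1) - 0.5
  rr <- (r0:r1) - 0.5
  g <- expand.grid(y = rr, x = cc)
  inside <- in_ellipse(e, g$x, g$y)
  m[r0:r1, c0:c1] <- matrix(inside, nrow = length(rr))
  m
}

#' Read an 8-bit RGB image
#'
#' @param path PNG/JPEG/TIFF file.
#' @return array `[row, col, 3]`, values in `[0, 1]`.
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 2) d <- array(rep(d, 3), dim = c(dim(d), 3))
  if (dim(d)[3] > 3) d <- d[, , 1:3, drop = FALSE]
  aperm(d, c(2, 1, 3)) # EBImage stores [x, y, channel]
}

#' Write an RGB image
#'
#' @param image array `[row, col, 3]` in `[0, 1]`.
#' @param path output file; the extension selects the format.
#' @export
write_image <- function(image, path) {
  EBImage::writeImage(EBImage::Image(aperm(image, c(2, 1, 3)),
                                     colormode = "Color"), path)
  invisible(path)
}

# bilinear sample of one channel matrix at continuous coords (x, y);
# out-of-frame area reads as `fill`.
bilinear_sample <- function(m, x, y, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  # continuous -> fractional pixel index space (pixel r has centre r - 0.5)
  ri <- y + 0.5
  ci <- x + 0.5
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  get <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- rep(fill, length(r))
    v[ok] <- m[cbind(r[ok], c[ok])]
    v
  }
  v00 <- get(r0, c0); v01 <- get(r0, c0 + 1)
  v10 <- get(r0 + 1, c0); v11 <- get(r0 + 1, c0 + 1)
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

# largest connected foreground component of a binary mask (8-connectivity)
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (max(lab) == 0L) return(NULL)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

# sub-pixel contour: midpoints of pixel edges separating foreground from
# background (or from the outside of the mask); returns (x, y) matrix.
mask_contour_points <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  pts <- list()
  idx <- which(core & !pad[2:(nr + 1), 3:(nc + 2)], arr.ind = TRUE) # right
  if (nrow(idx)) pts$r <- cbind(x = idx[, 2], y = idx[, 1] - 0.5)
  idx <- which(core & !pad[2:(nr + 1), 1:nc], arr.ind = TRUE)       # left
  if (nrow(idx)) pts$l <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 0.5)
  idx <- which(core & !pad[3:(nr + 2), 2:(nc + 1)], arr.ind = TRUE) # below
  if (nrow(idx)) pts$d <- cbind(x = idx[, 2] - 0.5, y = idx[, 1])
  idx <- which(core & !pad[1:nr, 2:(nc + 1)], arr.ind = TRUE)       # above
  if (nrow(idx)) pts$u <- cbind(x = idx[, 2] - 0.5, y = idx[, 1] - 1)
  do.call(rbind, pts)
}
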