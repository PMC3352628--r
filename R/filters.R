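#' 2D convolution with a square kernel
#'
#' True convolution (the kernel is flipped), `g = w %*% f` in the mask sense,
#' output the same shape as the input.  Border handling is either half-sample
#' reflection (`"reflect"`, the default: the edge row/column is mirrored
#' including itself) or zero padding (`"zero"`).
#'
#' @param image numeric matrix, at least K x K.
#' @param kernel K x K numeric matrix, K odd.
#' @param border `"reflect"` or `"zero"`.
#' @return numeric matrix, same shape as `image`.
#' @examples
#' im <- matrix(0, 5, 5); im[3, 3] <- 1
#' box <- matrix(1 / 9, 3, 3)
#' convolve2D(im, box, border = "zero")
#' @export
convolve2D <- function(image, kernel, border = c("reflect", "zero")) {
  border <- match.arg(border)
  kernel <- as.matrix(kernel)
  K <- nrow(kernel)
  if (K != ncol(kernel) || K %% 2L == 0L)
    ctsimStop("invalidParameter", "kernel must be square with odd size")
  if (any(!is.finite(kernel)))
    ctsimStop("invalidParameter", "kernel weights must be finite")
  nr <- nrow(image); nc <- ncol(image)
  if (nr < K || nc < K)
    ctsimStop("invalidParameter", "kernel larger than image")
  r <- (K - 1L) %/% 2L
  pad <- .padMatrix(image, r, border)
  w <- kernel[K:1, K:1, drop = FALSE]   # flip: convolution, not correlation
  out <- matrix(0, nr, nc)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    wij <- w[i, j]
    if (wij != 0)
      out <- out + wij * pad[(i:(i + nr - 1L)), (j:(j + nc - 1L))]
  }
  out
}

.padMatrix <- function(m, r, border) {
  if (r == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr + 2L * r, nc + 2L * r)
  out[(r + 1L):(r + nr), (r + 1L):(r + nc)] <- m
  if (border == "reflect") {
    ridx <- c(r:1, seq_len(nr), nr:(nr - r + 1L))
    cidx <- c(r:1, seq_len(nc), nc:(nc - r + 1L))
    out <- m[ridx, cidx, drop = FALSE]
  }
  out
}

#' Box-mean smoothing (low-pass)
#'
#' Convolution with a uniform `kernelSize` x `kernelSize` mean kernel;
#' reduces per-pixel noise variance at the cost of high-frequency detail.
#'
#' @param image numeric matrix.
#' @param kernelSize odd integer >= 1 (1 = identity).
#' @param border passed to [convolve2D()].
#' @return smoothed matrix, same shape.
#' @export
smoothImage <- function(image, kernelSize = 3L, border = "reflect") {
  kernelSize <- as.integer(kernelSize)
  if (kernelSize < 1L || kernelSize %% 2L == 0L)
    ctsimStop("invalidParameter", "kernelSize must be odd and >= 1")
  if (kernelSize == 1L) return(image)
  convolve2D(image, matrix(1 / kernelSize^2, kernelSize, kernelSize),
             border = border)
}

#' Sobel edge magnitude
#'
#' Gradient magnitude `sqrt(Gx^2 + Gy^2)` from the classic unscaled 3 x 3
#' Sobel operator pair.  Only relative magnitudes matter downstream (the
#' map is used to sharpen contour appearance), so no normalisation is
#' applied; an isolated vertical step of height `h` scores `4 h` on the two
#' columns flanking it.
#'
#' @param image numeric matrix, at least 3 x 3.
#' @param border passed to [convolve2D()].
#' @return gradient-magnitude matrix, same shape.
#' @export
sobelEdges <- function(image, border = "reflect") {
  if (nrow(image) < 3L || ncol(image) < 3L)
    ctsimStop("invalidParameter", "image must be at least 3 x 3")
  gx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # d/dx (columns)
  gy <- t(gx)                                               # d/dy (rows)
  sqrt(convolve2D(image, gx, border)^2 + convolve2D(image, gy, border)^2)
}

#' Threshold an image into an object/background mask
#'
#' `mask = 1` where `I >= T` (object), else 0.  With both bounds,
#' `thresholdWindow()` marks `low <= I <= high`.
#'
#' @param image numeric matrix or 3D array.
#' @param threshold scalar threshold T.
#' @param spacing mm spacing recorded on the returned mask (defaults to 1s).
#' @return a [BinaryMask-class] of the same shape.
#' @export
thresholdMask <- function(image, threshold, spacing = NULL) {
  d <- dim(image)
  if (is.null(spacing)) spacing <- rep(1, length(d))
  binaryMask(array(as.integer(image >= threshold), d), spacing = spacing)
}

#' @rdname thresholdMask
#' @param low,high HU window bounds (inclusive).
#' @export
thresholdWindow <- function(image, low, high, spacing = NULL) {
  if (low >= high) ctsimStop("invalidParameter", "window low must be < high")
  d <- dim(image)
  if (is.null(spacing)) spacing <- rep(1, length(d))
  binaryMask(array(as.integer(image >= low & image <= high), d),
             spacing = spacing)
}

#' Histogram-derived threshold within an HU window
#'
#' Builds the intensity histogram restricted to `huWindow`, smooths it with a
#' short moving average, and returns the deepest interior valley (local
#' minimum of the smoothed histogram).  When the windowed histogram has no
#' interior valley — empty, flat or monotone — the window midpoint is
#' returned as a fallback.
#'
#' @param image numeric matrix or array.
#' @param huWindow numeric(2), (low, high) with low < high.
#' @param nbins number of histogram bins over the window (default 64).
#' @return a single threshold T inside the window.
#' @export
histogramThreshold <- function(image, huWindow, nbins = 64L) {
  if (length(huWindow) != 2L || huWindow[1L] >= huWindow[2L])
    ctsimStop("invalidParameter", "huWindow must be (low, high) with low < high")
  lo <- huWindow[1L]; hi <- huWindow[2L]
  mid <- (lo + hi) / 2
  v <- image[image >= lo & image <= hi]
  if (!length(v)) return(mid)
  breaks <- seq(lo, hi, length.out = nbins + 1L)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins)
  ## moving average, width 5, replicated ends
  k <- 5L; half <- k %/% 2L
  padded <- c(rep(counts[1L], half), counts, rep(counts[nbins], half))
  s <- stats::filter(padded, rep(1 / k, k), sides = 2)
  s <- as.numeric(s[(half + 1L):(half + nbins)])
  if (max(s) - min(s) < 1e-12) return(mid)
  centers <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
  ## a valley must lie strictly between occupied histogram mass; a constant
  ## or single-spike image has no interior valley and falls back to the
  ## window midpoint
  occ <- which(counts > 0)
  if (occ[1L] + 1L > occ[length(occ)] - 1L) return(mid)
  interior <- (occ[1L] + 1L):(occ[length(occ)] - 1L)
  interior <- interior[interior >= 2L & interior <= nbins - 1L]
  if (!length(interior)) return(mid)
  isMin <- s[interior] <= s[interior - 1L] & s[interior] <= s[interior + 1L] &
    (s[interior] < s[interior - 1L] | s[interior] < s[interior + 1L])
  cand <- interior[isMin]
  if (!length(cand)) return(mid)
  best <- cand[order(s[cand], centers[cand])][1L]
  centers[best]
}
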