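## Internal helpers: condition classes, connected components, polygon
## rasterisation, small geometry utilities.

ctsimStop <- function(subclass, msg) {
  stop(structure(list(message = msg, call = NULL),
                 class = c(paste0("ctsim_", subclass), "ctsimError",
                           "error", "condition")))
}

#' Dice overlap coefficient between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; 1 for identical non-empty masks.
#'
#' @param a,b [BinaryMask] objects or 0/1 arrays of equal shape.
#' @return the Dice coefficient in [0, 1] (NaN if both masks are empty).
#' @export
diceCoefficient <- function(a, b) {
  if (is(a, "BinaryMask")) a <- a@data
  if (is(b, "BinaryMask")) b <- b@data
  if (!identical(dim(a), dim(b)))
    ctsimStop("invalidParameter", "masks must have identical shape")
  a <- a != 0; b <- b != 0
  2 * sum(a & b) / (sum(a) + sum(b))
}

## 8-connected labelling of a 2D 0/1 matrix.  EBImage::bwlabel is
## 4-connected; diagonal-adjacent labels are merged with union-find.
label8 <- function(m) {
  lab <- EBImage::bwlabel(m != 0)
  lab <- matrix(as.integer(round(lab)), nrow(m), ncol(m))
  k <- max(lab)
  if (k < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal pairs
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal pairs
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (nrow(pairs)) {
    parent <- seq_len(k)
    findRoot <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (r in seq_len(nrow(pairs))) {
      ra <- findRoot(pairs[r, 1L]); rb <- findRoot(pairs[r, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(k), findRoot, integer(1))
    relab <- match(root, sort(unique(root)))
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  lab
}

## 4-neighbour binary dilation of a logical matrix.
dilate4 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-nr, ]
  out[-nr, ] <- out[-nr, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -nc]
  out[, -nc] <- out[, -nc] | m[, -1]
  out
}

## Logical matrix of object pixels whose four axial neighbours are all object
## (strict interior; border pixels of the image are never interior).
interior4 <- function(m) {
  m <- m != 0
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  core <- p[2:(nr + 1L), 2:(nc + 1L)]
  core & p[1:nr, 2:(nc + 1L)] & p[3:(nr + 2L), 2:(nc + 1L)] &
    p[2:(nr + 1L), 1:nc] & p[2:(nr + 1L), 3:(nc + 2L)]
}

## Even-odd point-in-polygon, vectorised over test points.  Points exactly on
## an edge are resolved by a tiny fixed offset of the test points; callers
## that care about on-edge pixels union them explicitly.
pointInPolygon <- function(py, px, polyY, polyX) {
  eps <- c(3.1e-8, 1.7e-8)
  py <- py + eps[1L]; px <- px + eps[2L]
  n <- length(polyY)
  inside <- logical(length(py))
  j <- n
  for (i in seq_len(n)) {
    yi <- polyY[i]; yj <- polyY[j]; xi <- polyX[i]; xj <- polyX[j]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py[crosses] - yi) / (yj - yi) * (xj - xi)
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
    j <- i
  }
  inside
}

## Rasterise a closed polygon given in continuous 1-based pixel coordinates
## (rowCoord, colCoord): pixel centres at integers.  Returns a logical matrix
## of size dims.  Fill rule: pixel centres strictly inside (even-odd), plus
## pixels whose centre coincides with a polygon vertex.  With a raster
## boundary chain as input this reproduces the traced region exactly.
rasterizePolygonPx <- function(rowC, colC, dims) {
  out <- matrix(FALSE, dims[1L], dims[2L])
  r0 <- max(1L, floor(min(rowC))); r1 <- min(dims[1L], ceiling(max(rowC)))
  c0 <- max(1L, floor(min(colC))); c1 <- min(dims[2L], ceiling(max(colC)))
  if (r1 >= r0 && c1 >= c0) {
    rows <- r0:r1; cols <- c0:c1
    grid <- expand.grid(row = rows, col = cols)
    ins <- pointInPolygon(grid$row, grid$col, rowC, colC)
    out[cbind(grid$row[ins], grid$col[ins])] <- TRUE
  }
  vr <- round(rowC); vc <- round(colC)
  onpx <- abs(rowC - vr) < 1e-6 & abs(colC - vc) < 1e-6 &
    vr >= 1 & vr <= dims[1L] & vc >= 1 & vc <= dims[2L]
  if (any(onpx)) out[cbind(vr[onpx], vc[onpx])] <- TRUE
  out
}

## Continuous pixel coordinate of a world mm coordinate along one axis:
## centre of pixel i (1-based) maps to i.
pxFromMm <- function(w, sp, or) (w - or) / sp + 0.5
mmFromPx <- function(i, sp, or) or + (i - 0.5) * sp

## Newell normal of a 3D polygon (n x 3 vertex matrix, any coordinate order).
.polyNormal <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  c(sum((v[, 2] - v[j, 2]) * (v[, 3] + v[j, 3])),
    sum((v[, 3] - v[j, 3]) * (v[, 1] + v[j, 1])),
    sum((v[, 1] - v[j, 1]) * (v[, 2] + v[j, 2])))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) ctsimStop("invalidParameter", "zero-length vector")
  v / n
}

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

## Shoelace signed area of an (y, x) polygon, in the units of the input
## (positive = counter-clockwise in right-handed (x, y) axes).
signedArea <- function(points) {
  y <- points[, 1L]; x <- points[, 2L]
  j <- c(2:length(y), 1L)
  sum(x * y[j] - x[j] * y) / 2
}
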