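## Independent oracles used across the suite.  These deliberately share no
## code with the package implementation.

## Brute-force nested-loop true convolution with zero or half-sample-reflect
## borders.
bruteConvolve <- function(im, kk, border) {
  K <- nrow(kk); r <- (K - 1) / 2
  nr <- nrow(im); nc <- ncol(im)
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    s <- 0
    for (a in -r:r) for (b in -r:r) {
      ii <- i - a; jj <- j - b
      v <- if (border == "zero") {
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) 0 else im[ii, jj]
      } else im[reflect(ii, nr), reflect(jj, nc)]
      s <- s + kk[a + r + 1, b + r + 1] * v
    }
    out[i, j] <- s
  }
  out
}

## Morphological boundary oracle: object pixels removed by a 4-neighbour
## (diamond) erosion.
boundaryOracle <- function(comp) {
  kern <- matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
  er <- EBImage::erode(comp, kern)
  which(comp == 1 & er == 0)
}

## Breadth-first flood-fill oracle for the adjacent-comparison region-growing
## rule (order-independent closure).
floodFillOracle <- function(v, seed, delta) {
  d <- dim(v)
  acc <- array(FALSE, d)
  acc[seed[1], seed[2], seed[3]] <- TRUE
  offs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  repeat {
    cand <- array(FALSE, d)
    idx <- which(acc, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      for (off in offs) {
        q <- idx[r, ] + off
        if (any(q < 1) || any(q > d)) next
        if (!acc[q[1], q[2], q[3]] &&
            abs(v[q[1], q[2], q[3]] - v[idx[r, 1], idx[r, 2], idx[r, 3]]) <= delta)
          cand[q[1], q[2], q[3]] <- TRUE
      }
    }
    if (!any(cand)) break
    acc <- acc | cand
  }
  acc
}

## 6-connected 3D component labelling by repeated dilation (oracle for the
## phantom ground-truth connectivity checks).
connected6 <- function(mask, seedIdx) {
  d <- dim(mask)
  acc <- array(FALSE, d)
  acc[seedIdx[1], seedIdx[2], seedIdx[3]] <- TRUE
  repeat {
    g <- acc
    g[-1, , ] <- g[-1, , ] | acc[-d[1], , ]
    g[-d[1], , ] <- g[-d[1], , ] | acc[-1, , ]
    g[, -1, ] <- g[, -1, ] | acc[, -d[2], ]
    g[, -d[2], ] <- g[, -d[2], ] | acc[, -1, ]
    g[, , -1] <- g[, , -1] | acc[, , -d[3]]
    g[, , -d[3]] <- g[, , -d[3]] | acc[, , -1]
    g <- g & mask
    if (all(g == acc)) break
    acc <- g
  }
  acc
}

## Random hole-free single-component blob mask (union of disks).
randomBlobMask <- function(n = 24) {
  m <- matrix(0L, n, n)
  yg <- matrix(seq_len(n), n, n); xg <- t(yg)
  for (k in seq_len(sample(1:4, 1))) {
    cy <- runif(1, n / 4, 3 * n / 4)
    cx <- runif(1, n / 4, 3 * n / 4)
    r <- runif(1, 2, n / 5)
    m[(yg - cy)^2 + (xg - cx)^2 <= r^2] <- 1L
  }
  lab <- EBImage::bwlabel(m)
  if (max(lab) == 0) return(NULL)
  big <- which.max(tabulate(lab[lab > 0]))
  matrix(as.integer(EBImage::fillHull(matrix(as.integer(lab == big), n, n))),
         n, n)
}
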