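# Independent brute-force oracles used across the test files. These are
# deliberately naive implementations that never share code with the package.

# one step of binary erosion with a 3x3 cross, by explicit shifting
erodeCrossOracle <- function(m) {
  pad <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m)))
      out[i, j] <- pad[i + 1L, j + 1L] && pad[i, j + 1L] && pad[i + 2L, j + 1L] &&
        pad[i + 1L, j] && pad[i + 1L, j + 2L]
  out
}

# iterative-erosion central region: last iterate with area >= fraction * area
centralOracle <- function(mask, fraction) {
  target <- fraction * sum(mask)
  cur <- mask
  repeat {
    er <- erodeCrossOracle(cur)
    if (sum(er) >= target) cur <- er else break
  }
  cur
}

# per-pixel disc membership
circleOracle <- function(center, radiusPx, dims) {
  out <- matrix(FALSE, dims[1L], dims[2L])
  for (i in seq_len(dims[1L]))
    for (j in seq_len(dims[2L]))
      out[i, j] <- (i - center[1L])^2 + (j - center[2L])^2 <= radiusPx^2
  out
}

# grayscale opening (erode-then-dilate min/max filters) with a disc of
# offsets; brute force over every pixel
greyOpeningOracle <- function(img, radiusPx) {
  offs <- which(outer((-radiusPx:radiusPx)^2, (-radiusPx:radiusPx)^2, `+`) <=
                  radiusPx^2, arr.ind = TRUE) - radiusPx - 1L
  filt <- function(x, f, fill) {
    out <- matrix(NA_real_, nrow(x), ncol(x))
    for (i in seq_len(nrow(x)))
      for (j in seq_len(ncol(x))) {
        ri <- i + offs[, 1L]; cj <- j + offs[, 2L]
        ok <- ri >= 1 & ri <= nrow(x) & cj >= 1 & cj <= ncol(x)
        v <- x[cbind(ri[ok], cj[ok])]
        if (any(!ok)) v <- c(v, fill)
        out[i, j] <- f(v)
      }
    out
  }
  filt(filt(img, min, 0), max, 0)
}

# disc raster helper for constructing synthetic masks
diskMat <- function(dims, center, radius) {
  outer(seq_len(dims[1L]), seq_len(dims[2L]),
        function(i, j) (i - center[1L])^2 + (j - center[2L])^2 <= radius^2)
}

# gaussian spot raster
spotMat <- function(dims, center, sigma, amp = 1) {
  outer(seq_len(dims[1L]), seq_len(dims[2L]), function(i, j)
    amp * exp(-((i - center[1L])^2 + (j - center[2L])^2) / (2 * sigma^2)))
}

# match truth cells to pipeline labels through the pipeline cell mask and
# return per-cell (measured ratio, expected ratio) pairs
matchedRecovery <- function(gen, scored, kappa) {
  lab <- labels(attr(scored, "cells"))
  tr <- gen$truth$cells
  out <- NULL
  for (i in seq_len(nrow(tr))) {
    k <- lab[round(tr$row[i]), round(tr$col[i])]
    j <- which(scored$cell_label == k)
    if (length(j) == 1L && !scored$excluded[j])
      out <- rbind(out, c(scored$raw_ratio[j],
                          kappa + (1 - kappa) * tr$a_fraction[i]))
  }
  out
}
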