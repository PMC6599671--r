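# Separable antialiased bicubic resampling.
#
# Catmull-Rom cubic kernel (a = -0.5); when shrinking, the kernel is widened
# by 1/scale so the footprint covers the source pixels that contribute to one
# output pixel (otherwise downscaling aliases).  Edge samples are clamped
# (replicate).  Coordinates are pixel centres: output centre i maps to source
# (i + 0.5)/scale - 0.5 (0-based).

cubic_kernel <- function(x) {
  a <- -0.5
  ax <- abs(x)
  w <- numeric(length(x))
  i1 <- ax <= 1
  i2 <- ax > 1 & ax < 2
  w[i1] <- (a + 2) * ax[i1]^3 - (a + 3) * ax[i1]^2 + 1
  w[i2] <- a * ax[i2]^3 - 5 * a * ax[i2]^2 + 8 * a * ax[i2] - 4 * a
  w
}

# Weight matrix (n_out x n_in) for one dimension.
resample_weights <- function(n_in, n_out) {
  scale <- n_out / n_in
  kscale <- if (scale < 1) scale else 1       # widen kernel when shrinking
  support <- 2 / kscale
  centres <- (seq_len(n_out) - 0.5) / scale - 0.5   # 0-based source coords
  left <- floor(centres - support) + 1
  nw <- ceiling(2 * support) + 2
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    idx <- left[i] + seq_len(nw) - 1          # 0-based source indices
    w <- cubic_kernel((centres[i] - idx) * kscale)
    keep <- w != 0
    idx <- pmin(pmax(idx[keep], 0), n_in - 1) # clamp = replicate border
    w <- w[keep] / sum(w[keep])
    for (j in seq_along(idx)) W[i, idx[j] + 1] <- W[i, idx[j] + 1] + w[j]
  }
  W
}

# Bicubic resize of a numeric matrix to n_rows x n_cols.
resize_bicubic <- function(m, n_rows, n_cols) {
  Wr <- resample_weights(nrow(m), n_rows)
  Wc <- resample_weights(ncol(m), n_cols)
  Wr %*% m %*% t(Wc)
}
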