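#' Multilevel Otsu thresholding
#'
#' Finds the `k` intensity thresholds `TH = [th_1 < ... < th_k]` that
#' partition the `L` discrete grey levels into `k + 1` contiguous classes
#' maximising the between-class variance
#' \deqn{\sigma_B^2 = \sum_j \omega_j (\mu_j - \mu_T)^2,}
#' where \eqn{\omega_j} and \eqn{\mu_j} are the probability and mean of class
#' `j` and \eqn{\mu_T} the global mean.  The sum runs over all `k + 1`
#' classes.  Class `j` contains the levels `th_{j-1} < l <= th_j` (with
#' `th_0 = -1`), and the "maximum class" is every level above `th_k`.
#'
#' The maximum is found exactly by dynamic programming over histogram prefix
#' sums (maximising \eqn{\sum_j \omega_j \mu_j^2}, which differs from
#' \eqn{\sigma_B^2} by the constant \eqn{\mu_T^2}); the result is
#' deterministic and, among ties, the lexicographically smallest threshold
#' vector is returned.
#'
#' @param histogram Integer vector of counts per grey level (length `L`,
#'   level `l` at index `l + 1`).
#' @param k Number of thresholds (`>= 1`).
#' @return List with `TH` (integer thresholds, 0-based levels), `objective`
#'   (the attained \eqn{\sigma_B^2}) and `k`.
#' @examples
#' multi_otsu_thresholds(c(10, 0, 0, 10), k = 1)   # TH = 0, sigma^2 = 2.25
#' @export
multi_otsu_thresholds <- function(histogram, k) {
  k <- as.integer(k)
  stopifnot(k >= 1L, is.numeric(histogram), all(histogram >= 0))
  L <- length(histogram)
  n <- sum(histogram)
  if (n <= 0) abort("empty histogram", class = "od_histogram_error")
  if (sum(histogram > 0) < k + 1L) {
    abort(sprintf("degenerate histogram: %d occupied level(s) < k + 1 = %d",
                  sum(histogram > 0), k + 1L),
          class = "od_histogram_error")
  }
  p <- histogram / n
  lev <- seq_len(L) - 1
  P <- c(0, cumsum(p))
  S <- c(0, cumsum(p * lev))
  mu_T <- S[L + 1L]
  # VAL[a, b] = omega * mu^2 of the class covering levels (a-1)..(b-1)
  VAL <- matrix(0, L, L)
  for (a in seq_len(L)) {
    b <- a:L
    W <- P[b + 1L] - P[a]
    Sg <- S[b + 1L] - S[a]
    v <- numeric(length(b))
    nz <- W > 0
    v[nz] <- Sg[nz]^2 / W[nz]
    VAL[a, b] <- v
  }
  nc <- k + 1L
  # Suffix DP: g[j, s] = best value partitioning levels (s-1)..(L-1) into j classes
  g <- matrix(-Inf, nc, L)
  g[1L, ] <- VAL[cbind(seq_len(L), L)]
  if (nc > 1L) {
    for (j in 2:nc) {
      # class start s..t, remainder t+1.. has j-1 classes => t <= L - (j-1)
      for (s in seq_len(L - j + 1L)) {
        t <- s:(L - j + 1L)
        g[j, s] <- max(VAL[s, t] + g[j - 1L, t + 1L])
      }
    }
  }
  opt <- g[nc, 1L]
  # Front-to-back reconstruction, taking the smallest feasible threshold at
  # each step => lexicographically smallest TH among the maximisers.
  tol <- 1e-11 * max(1, abs(opt))
  TH <- integer(k)
  s <- 1L
  rem <- opt
  for (j in seq_len(k)) {
    t <- s:(L - (nc - j) )
    cand <- VAL[s, t] + g[nc - j, t + 1L]
    pick <- t[which(cand >= rem - tol)[1L]]
    TH[j] <- pick - 1L                     # 0-based level
    rem <- rem - VAL[s, pick]
    s <- pick + 1L
  }
  list(TH = TH, objective = opt - mu_T^2, k = k)
}

# 8-connected labelling: EBImage::bwlabel (4-connected) plus a union-find
# merge of labels adjacent across diagonals.
label8 <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  nlab <- max(lab)
  if (nlab <= 1L) return(matrix(as.integer(lab), nrow(lab), ncol(lab)))
  H <- nrow(lab); W <- ncol(lab)
  d1a <- lab[-H, -W]; d1b <- lab[-1, -1]        # \ diagonal
  d2a <- lab[-1, -W]; d2b <- lab[-H, -1]        # / diagonal
  pa <- c(d1a[d1a > 0 & d1b > 0 & d1a != d1b], d2a[d2a > 0 & d2b > 0 & d2a != d2b])
  pb <- c(d1b[d1a > 0 & d1b > 0 & d1a != d1b], d2b[d2a > 0 & d2b > 0 & d2a != d2b])
  parent <- seq_len(nlab)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_along(pa)) {
    ra <- find(pa[i]); rb <- find(pb[i])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- matrix(0L, H, W)
  nz <- lab > 0
  out[nz] <- relab[lab[nz]]
  out
}
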