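# Fixture builders shared across test files.  Everything is generated in
# code; no binary fixtures on disk.

# A trivially valid FOV covering the whole frame.
full_fov <- function(H, W) {
  structure(list(mask = matrix(TRUE, H, W),
                 circle_centre = c((H - 1) / 2, (W - 1) / 2),
                 circle_radius = sqrt(H^2 + W^2)),
            class = "od_fov")
}

# Wrap a plain [0,1] matrix as a normalised channel on a full-frame FOV.
as_channel <- function(values, channel = "R", fov = full_fov(nrow(values), ncol(values))) {
  structure(list(values = values, channel = channel, fov = fov,
                 degenerate = FALSE),
            class = "od_channel")
}

# Noisy bright disc on a darker background, as a channel.
disc_channel <- function(H, W, centre, radius, bg = 0.3, fg = 0.8,
                         noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- bg + (fg - bg) * opticdisc:::disc_coverage(H, W, centre, radius)
  if (noise_sd > 0) v <- v + matrix(rnorm(H * W, 0, noise_sd), H, W)
  as_channel(pmin(pmax(v, 0), 1))
}

# Exhaustive multilevel-Otsu maximiser over all threshold combinations.
# Independent of the package implementation: direct evaluation of the
# between-class variance over every strictly increasing threshold vector.
brute_otsu <- function(histogram, k) {
  L <- length(histogram)
  p <- histogram / sum(histogram)
  lev <- seq_len(L) - 1
  mu_T <- sum(p * lev)
  objective <- function(th) {
    bounds <- c(-1, th, L - 1)
    s <- 0
    for (j in seq_len(k + 1)) {
      sel <- lev > bounds[j] & lev <= bounds[j + 1]
      w <- sum(p[sel])
      if (w > 0) {
        mu <- sum(p[sel] * lev[sel]) / w
        s <- s + w * (mu - mu_T)^2
      }
    }
    s
  }
  combos <- utils::combn(0:(L - 2), k)
  vals <- apply(combos, 2, objective)
  best <- max(vals)
  # lexicographically smallest maximiser (combn enumerates in lex order)
  th <- combos[, which(vals >= best - 1e-12)[1]]
  list(TH = as.integer(th), objective = best)
}

# Random occupied histogram with at least k + 1 nonzero bins.
random_histogram <- function(L, k) {
  repeat {
    h <- rpois(L, lambda = sample(c(0.5, 2, 5), 1))
    if (sum(h > 0) >= k + 1) return(h)
  }
}
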