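# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, explicit loops and
# fine-grid numerics.

# Exhaustive Otsu: try every unique intensity as an inclusive threshold and
# maximize the between-class variance computed from the raw pixel values.
brute_force_otsu <- function(image) {
  v <- as.vector(image)
  cand <- sort(unique(v))[-1]          # threshold = smallest foreground value
  best <- -Inf; best_t <- NA
  n <- length(v)
  for (t in cand) {
    fg <- v >= t
    w1 <- mean(fg); w0 <- 1 - w1
    if (w0 == 0 || w1 == 0) next
    bcv <- w0 * w1 * (mean(v[!fg]) - mean(v[fg]))^2
    if (bcv > best + 1e-12) { best <- bcv; best_t <- t }
  }
  best_t
}

# Explicit all-pairs nearest-neighbour matching (channel 1 -> channel 2).
brute_force_coloc <- function(q, p, threshold) {
  nd <- numeric(nrow(q))
  for (i in seq_len(nrow(q))) {
    best <- Inf
    for (j in seq_len(nrow(p))) {
      d <- sqrt((q$cx[i] - p$cx[j])^2 + (q$cy[i] - p$cy[j])^2)
      if (d < best) best <- d
    }
    nd[i] <- best
  }
  list(nearest = nd, percent = 100 * mean(nd < threshold))
}

# Fine-grid (1 nm) profile of a uniform disk convolved with an isotropic
# Gaussian PSF, and its FWHM by linear interpolation. Exploits circular
# symmetry: I(x) = integral over the disk of the 2-D Gaussian centred at
# (x, 0).
disk_psf_fwhm_oracle <- function(disk_diameter, psf_fwhm) {
  sigma <- psf_fwhm / (2 * sqrt(2 * log(2)))
  r <- disk_diameter / 2
  g <- seq(-r, r, by = 0.5)
  du <- g[2] - g[1]
  prof_at <- function(x) {
    # integrate the separable Gaussian over the disk on a fine grid
    tot <- 0
    for (u in g) {
      half <- sqrt(max(r^2 - u^2, 0))
      # integral over v of dnorm(v, 0, sigma) on [-half, half]
      tot <- tot + stats::dnorm(x - u, 0, sigma) *
        (stats::pnorm(half, 0, sigma) - stats::pnorm(-half, 0, sigma)) * du
    }
    tot
  }
  xs <- seq(0, psf_fwhm * 2 + disk_diameter, by = 1)
  prof <- vapply(xs, prof_at, numeric(1))
  half <- prof[1] / 2
  i <- which(prof < half)[1]
  x_half <- xs[i - 1] + (half - prof[i - 1]) / (prof[i] - prof[i - 1])
  2 * x_half
}

# Closed-form OLS on (x, y) pairs, written out longhand.
ols_by_hand <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  a <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  b <- yb - a * xb
  pred <- a * x + b
  r2 <- 1 - sum((y - pred)^2) / sum((y - yb)^2)
  list(slope = a, intercept = b, r_squared = r2)
}

# A bleed-through-free test sensor: EYFP-like protonation fp over a
# perfectly acid-stable dye.
test_sensor <- function(pKa = 6.9, bleed = 0) {
  sensor(fluorophore("FP", "protonation", pKa = pKa),
         fluorophore("DYE", "constant"), bleed_through = bleed)
}
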