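# shared fixture builders for the test suite

# independently written Gaussian peak sum (oracle for the simulator)
oracle_gaussian_sum <- function(mz, centers, amps, resolving_power = 1000) {
  out <- numeric(length(mz))
  for (k in seq_along(centers)) {
    sigma <- centers[k] / resolving_power / (2 * sqrt(2 * log(2)))
    out <- out + amps[k] * exp(-0.5 * ((mz - centers[k]) / sigma)^2)
  }
  out
}

# a tiny three-peptide panel for fast spectral tests
tiny_panel <- function() {
  build_abeta_panel(c("Abeta1-40", "Abeta1-42", "Abeta11pE-42"))
}

# noise-free single-morphotype ROI spectrum
fixture_roi_spectrum <- function(type = "CP", mz = seq(3000, 5600, 1),
                                 panel = default_abeta_panel(),
                                 baseline_b0 = 2) {
  tpl <- plaque_templates()[[type]]
  simulate_roi_spectrum(tpl$profile, panel, mz, filler = tpl$filler,
                        baseline_b0 = baseline_b0, detector_sd = 0)
}

# textbook SNIP reference: LLS transform, decreasing-window clipping with
# clamped boundaries, inverse transform (independent reimplementation)
oracle_snip <- function(v, iterations) {
  n <- length(v)
  y <- log(log(sqrt(v + 1) + 1) + 1)
  for (w in seq(min(iterations, n - 1), 1)) {
    ylo <- c(rep(y[1], w), y[seq_len(n - w)])
    yhi <- c(y[seq(w + 1, n)], rep(y[n], w))
    y <- pmin(y, (ylo + yhi) / 2)
  }
  (exp(exp(y) - 1) - 1)^2 - 1
}

# Savitzky-Golay central kernel by direct local least squares (oracle)
oracle_sg_kernel <- function(half_window, poly_order) {
  x <- -half_window:half_window
  V <- outer(x, 0:poly_order, `^`)
  H <- V %*% solve(crossprod(V)) %*% t(V)
  H[half_window + 1, ]
}

# small deterministic random matrix
rmat <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}
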