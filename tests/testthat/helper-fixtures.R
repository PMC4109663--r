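# shared fixtures: all synthetic, built in code at test time

white_spec <- function(var = 1) noise_spec(ar_coeffs = numeric(0), innovation_var = var)

ar1_spec <- function(a = 0.8, var = 1) noise_spec(ar_coeffs = a, innovation_var = var)

# independent least-squares route for the smoothing quadratic:
# minimize ||A(y - u)||^2 + gamma ||F u||^2 as a stacked LS problem via QR
qr_smooth_oracle <- function(y, A, F_mat, gamma) {
  n <- length(y)
  qr.solve(rbind(A, sqrt(gamma) * F_mat), c(A %*% y, numeric(n)))
}

# brute-force exact signed-rank p-value: enumerate all 2^n sign assignments
enumeration_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# a stable random AR coefficient vector (possibly empty)
random_stable_ar <- function(p_max = 4) {
  p <- sample(0:p_max, 1)
  if (p == 0) return(numeric(0))
  repeat {
    a <- runif(p, -0.5, 0.5) / seq_len(p)
    if (bayeserp:::ar_is_stable(a)) return(a)
  }
}

# small feature tibble with two well-separated classes in feature space
separable_features <- function(n_per_class = 20, gap = 3, noise_sd = 0.1) {
  nm <- feature_names()
  make_class <- function(center, n) {
    m <- matrix(rnorm(n * 78, mean = center, sd = noise_sd), nrow = n)
    colnames(m) <- nm
    tibble::as_tibble(m)
  }
  feats <- dplyr::bind_rows(make_class(gap, n_per_class), make_class(-gap, n_per_class))
  feats$label <- rep(c("target", "nontarget"), each = n_per_class)
  feats
}
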