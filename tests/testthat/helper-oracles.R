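# Independent oracles and small fixture builders shared across tests.

# Brute-force all-pairs signed distance: for each pixel, the minimum
# centre-to-centre Euclidean distance to any opposite-class pixel.
brute_signed_distance <- function(m, pixel_size = 30) {
  out <- matrix(NA_real_, nrow(m), ncol(m))
  f <- which(m == 1, arr.ind = TRUE)
  nf <- which(m == 0, arr.ind = TRUE)
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (is.na(m[i, j])) next
    opp <- if (m[i, j] == 1) nf else f
    d <- sqrt((opp[, 1] - i)^2 + (opp[, 2] - j)^2) * pixel_size
    out[i, j] <- if (m[i, j] == 1) min(d) else -min(d)
  }
  out
}

# Closed-form OLS via normal equations, independent of lm.
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (length(y) - ncol(X))
  list(beta = as.vector(beta), vcov = sigma2 * solve(XtX))
}

# Closed-form weighted least squares via normal equations.
wls_oracle <- function(y, X, w) {
  A <- crossprod(X, w * X)
  beta <- solve(A, crossprod(X, w * y))
  res <- y - X %*% beta
  sigma2 <- sum(w * res^2) / (length(y) - ncol(X))
  list(beta = as.vector(beta), vcov = sigma2 * solve(A))
}

# Small single-scene point table with a fixed truth, no cloud, no lapse.
make_scene_points <- function(seed, n_scenes = 4, n_points = 400,
                              A = 3, lam = 50, sigma_noise = 1,
                              sigma_scene = 2, T_macro = 20,
                              grid_size = 64, cloud_fraction = 0,
                              n_overpasses = 1) {
  sampler <- function(i, lat) {
    edge_effect_truth(T_macro = T_macro, A = A, lam = lam, lapse = -0.0065,
                      sigma_noise = sigma_noise, sigma_scene = sigma_scene)
  }
  cfg <- study_config(n_scenes = n_scenes, n_overpasses = n_overpasses,
                      grid_size = grid_size, n_points_per_sxo = n_points,
                      cloud_fraction = cloud_fraction, seed = seed)
  generate_study(cfg, sampler)
}

analytic_contrast <- function(A, lam, d_edge = 30, d_interior = 500) {
  A * (edge_sigmoid(d_interior, lam) - edge_sigmoid(d_edge, lam))
}
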