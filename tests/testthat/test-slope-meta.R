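test_that("exact log-linear truths are recovered exactly", {
  d <- c(30, 100, 300, 900)
  pts <- data.frame(dist_m = d, tsurf_c = 25 - 2 * log10(d), elev_m = 100)
  sl <- scene_slope(pts)
  expect_true(sl$kept)
  expect_equal(sl$beta, -2, tolerance = 1e-10)
  expect_lt(sl$var_beta, 1e-12)
  flat <- data.frame(dist_m = d, tsurf_c = 25, elev_m = 100)
  expect_equal(scene_slope(flat)$beta, 0, tolerance = 1e-10)
})

test_that("slope rejections carry reasons instead of raising", {
  few <- data.frame(dist_m = c(30, 60, 90), tsurf_c = 1:3, elev_m = 0)
  expect_false(scene_slope(few)$kept)
  expect_match(scene_slope(few)$reject_reason, "fewer than 4")
  same <- data.frame(dist_m = rep(90, 6), tsurf_c = rnorm(6), elev_m = rnorm(6))
  r <- scene_slope(same)
  expect_false(r$kept)
  expect_match(r$reject_reason, "singular")
  out <- data.frame(dist_m = c(-5, 30), tsurf_c = 1:2, elev_m = 0)
  expect_error(scene_slope(rbind(out, out)), "in-forest")
})

test_that("slope estimates match the closed-form OLS oracle", {
  set.seed(101)
  for (s in 1:25) {
    n <- sample(5:60, 1)
    pts <- data.frame(dist_m = runif(n, 30, 1000),
                      tsurf_c = rnorm(n, 20, 3),
                      elev_m = runif(n, 0, 500))
    sl <- scene_slope(pts)
    X <- cbind(1, log10(pts$dist_m), pts$elev_m)
    o <- ols_oracle(pts$tsurf_c, X)
    expect_equal(sl$beta, o$beta[2], tolerance = 1e-8)
    expect_equal(sl$var_beta, o$vcov[2, 2], tolerance = 1e-8)
  }
})

test_that("scene_slopes aggregates per unit with full-scene mean temperature", {
  st <- make_scene_points(seed = 83, n_scenes = 3, n_points = 300,
                          n_overpasses = 2)
  sl <- scene_slopes(st$points)
  expect_equal(nrow(sl), 6)
  one <- st$points[st$points$scene_id == sl$scene_id[1] &
                     st$points$overpass_id == sl$overpass_id[1], ]
  expect_equal(sl$scene_mean_t[1], mean(one$tsurf_c)) # all points, both classes
  inf <- one[one$dist_m > 0 & one$dist_m <= 1000, ]
  expect_equal(sl$n_obs[1], nrow(inf))
  pooled <- scene_slopes(st$points, pool_overpasses = TRUE)
  expect_equal(nrow(pooled), 3)
})

test_that("Hampel filter follows the median +/- 3 MAD rule", {
  s <- data.frame(beta = c(-1, 0, 1))
  h <- hampel_filter(s)
  expect_equal(h$mad, 1)
  expect_equal(nrow(h$removed), 0)
  # degenerate MAD: everything off the median goes
  s2 <- data.frame(beta = c(0, 0, 0, 0, 7))
  expect_warning(h2 <- hampel_filter(s2), "degenerate")
  expect_equal(h2$removed$beta, 7)
  expect_equal(nrow(h2$kept), 4)
  expect_error(hampel_filter(data.frame(beta = 1:2)), "at least 3")
})

test_that("an injected far outlier is always removed, matching the interval oracle", {
  for (s in 1:40) {
    set.seed(s)
    b <- rnorm(50)
    inj <- median(b) + 10 * median(abs(b - median(b)))
    bb <- c(b, inj)
    h <- hampel_filter(data.frame(beta = bb))
    expect_true(inj %in% h$removed$beta)
    med <- median(bb); mad <- median(abs(bb - med))
    oracle_out <- bb[abs(bb - med) > 3 * mad]
    expect_setequal(h$removed$beta, oracle_out)
  }
})

test_that("mean-absolute-deviation variant widens or narrows the interval", {
  set.seed(7)
  b <- c(rnorm(30), 9)
  h1 <- hampel_filter(data.frame(beta = b), mad_type = "median")
  h2 <- hampel_filter(data.frame(beta = b), mad_type = "mean")
  expect_equal(h2$mad, mean(abs(b - median(b))))
  expect_true(9 %in% h1$removed$beta && 9 %in% h2$removed$beta)
})

test_that("IVW quadratic equals the analytic WLS oracle and reduces to OLS", {
  set.seed(19)
  n <- 40
  s <- data.frame(scene_mean_t = runif(n, 0, 35),
                  beta = rnorm(n), var_beta = runif(n, 0.1, 2))
  fit <- ivw_quadratic(s)
  X <- cbind(1, s$scene_mean_t, s$scene_mean_t^2)
  o <- wls_oracle(s$beta, X, 1 / s$var_beta)
  expect_equal(c(fit$b0, fit$b1, fit$b2), o$beta, tolerance = 1e-10)
  expect_equal(c(fit$se_b0, fit$se_b1, fit$se_b2), sqrt(diag(o$vcov)),
               tolerance = 1e-10)
  # equal variances: identical to unweighted OLS
  s$var_beta <- 0.7
  fit_eq <- ivw_quadratic(s)
  o_eq <- ols_oracle(s$beta, X)
  expect_equal(c(fit_eq$b0, fit_eq$b1, fit_eq$b2), o_eq$beta,
               tolerance = 1e-12)
  # noiseless quadratic truth
  s3 <- data.frame(scene_mean_t = seq(1, 30, length.out = 10))
  s3$beta <- 0.002 * s3$scene_mean_t^2
  s3$var_beta <- 1e-6
  f3 <- ivw_quadratic(s3)
  expect_equal(f3$b2, 0.002, tolerance = 1e-8)
  expect_lt(abs(f3$b0), 1e-8)
  expect_lt(abs(f3$b1), 1e-8)
  expect_equal(f3$weighted_r2, 1, tolerance = 1e-8)
})

test_that("IVW coefficients are invariant to rescaling all variances", {
  set.seed(23)
  s <- data.frame(scene_mean_t = runif(30, 0, 35), beta = rnorm(30),
                  var_beta = runif(30, 0.1, 2))
  f1 <- ivw_quadratic(s)
  s2 <- s; s2$var_beta <- s$var_beta * 37.5
  f2 <- ivw_quadratic(s2)
  expect_equal(c(f1$b0, f1$b1, f1$b2), c(f2$b0, f2$b1, f2$b2),
               tolerance = 1e-12)
  expect_equal(f1$weighted_r2, f2$weighted_r2, tolerance = 1e-12)
  expect_error(ivw_quadratic(s[1:3, ]), "at least 4")
})

test_that("cooling subset keeps exactly the negative slopes", {
  s <- data.frame(beta = c(-0.5, 0.5, -0.1, 0, 0.2),
                  var_beta = rep(0.1, 5), scene_mean_t = 1:5)
  cs <- subset_cooling(s)
  expect_equal(cs$beta, c(-0.5, -0.1))
  all_cool <- s[s$beta < 0, ]
  expect_identical(subset_cooling(all_cool), all_cool)
  # mixed study: retained fraction equals the fraction of negative betas
  set.seed(3)
  big <- data.frame(beta = rnorm(500, -0.1, 0.3), var_beta = 0.1,
                    scene_mean_t = rnorm(500))
  expect_equal(nrow(subset_cooling(big)) / 500, mean(big$beta < 0))
})

test_that("the no-outlier variant matches the filtered fit on clean slopes", {
  set.seed(29)
  s <- data.frame(scene_mean_t = runif(40, 0, 35), var_beta = 0.05)
  s$beta <- -(0.4 - 0.05 * s$scene_mean_t + 0.004 * s$scene_mean_t^2) +
    rnorm(40, 0, 0.1)
  s$kept <- TRUE
  h <- hampel_filter(s)
  if (nrow(h$removed) == 0) {
    f1 <- ivw_quadratic(h$kept)
    f2 <- no_outlier_variant(s)
    expect_equal(f1$b2, f2$b2, tolerance = 1e-12)
  } else {
    f1 <- ivw_quadratic(h$kept)
    f2 <- no_outlier_variant(s)
    expect_lt(abs(f1$b2 - f2$b2), 2 * max(f1$se_b2, f2$se_b2))
  }
})
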