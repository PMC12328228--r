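test_that("T_opt lookup uses half-open cells with the east/south rule", {
  g <- raster_grid(matrix(1:6, 2, 3), origin = c(0, 2000), pixel_size = 1000)
  pts <- data.frame(x = c(500, 1000, 2500, 1), y = c(1500, 1500, 300, 2000),
                    dist_m = 1, tsurf_c = 1, elev_m = 1)
  out <- attach_topt(pts, g)
  expect_equal(out$topt_c[1], 1)  # strictly inside cell (1,1)
  expect_equal(out$topt_c[2], 3)  # vertical boundary -> eastern cell (1,2)
  expect_equal(out$topt_c[3], 6)  # cell (2,3)
  expect_equal(out$topt_c[4], 1)  # horizontal boundary y=2000 -> southern row 1
  # boundary y = 1000 belongs to the southern cell (row 2)
  p2 <- data.frame(x = 500, y = 1000, dist_m = 1, tsurf_c = 1, elev_m = 1)
  expect_equal(attach_topt(p2, g)$topt_c, 2)
})

test_that("points on undefined cells are dropped and counted", {
  v <- matrix(c(10, NA), 1, 2)
  g <- raster_grid(v, origin = c(0, 1000), pixel_size = 1000)
  pts <- data.frame(x = c(500, 1500, 9999), y = c(500, 500, 500),
                    dist_m = 1, tsurf_c = 1, elev_m = 1)
  out <- attach_topt(pts, g)
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "dropped"), 2)
  off <- data.frame(x = -1e6, y = -1e6, dist_m = 1, tsurf_c = 1, elev_m = 1)
  expect_error(attach_topt(off, g), "cover")
})

test_that("scene eligibility applies the 500/2/800 rules inclusively", {
  mk <- function(scene, n, novp, dmax) {
    data.frame(scene_id = scene,
               overpass_id = rep(sprintf("O%02d", seq_len(novp)), length.out = n),
               dist_m = c(rep(100, n - 1), dmax),
               tsurf_c = 20, elev_m = 100)
  }
  pts <- rbind(mk("A", 499, 3, 900),   # too few obs
               mk("B", 600, 1, 900),   # too few overpasses
               mk("C", 600, 2, 799),   # too shallow
               mk("D", 600, 2, 800),   # inclusive boundary: eligible
               mk("E", 500, 2, 1000))  # all at the boundaries: eligible
  el <- filter_eligible_scenes(pts)
  lg <- el$log[order(el$log$scene_id), ]
  expect_equal(lg$eligible, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_match(lg$reason[1], "fewer than 500")
  expect_match(lg$reason[2], "fewer than 2 overpasses")
  expect_match(lg$reason[3], ">= 800")
  expect_setequal(unique(el$points$scene_id), c("D", "E"))
  # non-forest points are excluded before counting
  neg <- mk("F", 600, 2, 900)
  neg$dist_m[1:200] <- -100
  el2 <- filter_eligible_scenes(neg)
  expect_equal(el2$log$n_obs[el2$log$scene_id == "F"], 400)
})

test_that("eligibility is monotone under adding points", {
  set.seed(13)
  base <- data.frame(scene_id = "S", overpass_id = rep(c("O1", "O2"), 300),
                     dist_m = runif(600, 30, 900), tsurf_c = 20, elev_m = 0)
  base$dist_m[1] <- 850
  el1 <- filter_eligible_scenes(base)
  expect_true(el1$log$eligible)
  more <- rbind(base, data.frame(scene_id = "S", overpass_id = "O03",
                                 dist_m = runif(200, 30, 400), tsurf_c = 21,
                                 elev_m = 5))
  expect_true(filter_eligible_scenes(more)$log$eligible)
})

test_that("identical T_surf and T_opt give a zero gap curve and contrast", {
  st <- make_scene_points(seed = 91, n_scenes = 3, n_points = 400)
  pts <- st$points[st$points$dist_m > 0, ]
  pts$topt_c <- pts$tsurf_c
  gc <- fit_gap_curve(pts)
  expect_lt(max(abs(gc$curve$gap)), 1e-8)
  expect_equal(gc$contrast$delta_c, 0, tolerance = 1e-10)
  expect_equal(nrow(gc$curve), 501)
  expect_equal(range(gc$curve$dist_m), c(0, 500))
})

test_that("uniform T_opt shifts the gap curve by exactly the constant", {
  st <- make_scene_points(seed = 97, n_scenes = 4, n_points = 500, A = 2)
  pts <- st$points[st$points$dist_m > 0, ]
  pts$topt_c <- 25
  gc <- fit_gap_curve(pts)
  m_t <- fit_edge_curve(pts, dist_range = c(0, 1000))
  pr_t <- predict_partial(m_t, seq(0, 500))
  expect_equal(gc$curve$gap, pr_t$fit - 25, tolerance = 1e-8)
  ct_t <- edge_interior_contrast(m_t)
  expect_equal(gc$contrast$delta_c, ct_t$delta_c, tolerance = 1e-8)
  expect_equal(gc$contrast$se_quadrature, ct_t$se_quadrature,
               tolerance = 1e-6)
})

test_that("gap curves demand in-forest points with finite T_opt", {
  st <- make_scene_points(seed = 91, n_scenes = 3, n_points = 300)
  pts <- st$points
  pts$topt_c <- 25
  expect_error(fit_gap_curve(pts), "inside the forest")
  inf <- pts[pts$dist_m > 0, ]
  inf$topt_c[1] <- NA
  expect_error(fit_gap_curve(inf), "topt_c")
})

test_that("synthetic T_opt modes realize their documented scenarios", {
  st <- make_scene_points(seed = 103, n_scenes = 3, n_points = 200)
  tg <- synthetic_topt(st, mode = "uniform", value = 25)
  expect_true(all(tg$values == 25))
  tg2 <- synthetic_topt(st, mode = "offset-from-interior", offset = -2)
  tr <- st$truths[!duplicated(st$truths$scene_id), ]
  pts <- attach_topt(st$points, tg2)
  for (s in tr$scene_id) {
    got <- unique(pts$topt_c[pts$scene_id == s])
    expect_equal(got, tr$T_macro[tr$scene_id == s] - tr$A[tr$scene_id == s] - 2)
  }
})
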