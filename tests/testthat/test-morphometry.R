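# Per-astrocyte shape statistics against analytic shapes and brute-force
# geometric oracles.

test_that("the longest branch is the farthest endpoint from the nucleus", {
  # single 20 um horizontal segment starting at the nucleus
  m <- matrix(FALSE, 41, 61); m[21, 11:51] <- TRUE
  sk <- skeletonize_arbor(make_arbor(m, nucleus_yx_um = c(10, 5)))
  expect_equal(as.numeric(longest_branch(sk)), 20, tolerance = 0.03)
  expect_false(attr(longest_branch(sk), "fallback"))

  # star with arms 5, 10 and 15 um: the longest wins
  m2 <- matrix(FALSE, 161, 161)
  m2[81, 81:111] <- TRUE      # 15 um arm (30 px at 0.5 um)
  m2[81:101, 81] <- TRUE      # 10 um arm
  m2[71:81, 81] <- TRUE       # 5 um arm
  sk2 <- skeletonize_arbor(make_arbor(m2, nucleus_yx_um = c(40, 40)))
  expect_equal(as.numeric(longest_branch(sk2)), 15, tolerance = 0.01)
})

test_that("the longest branch equals the exhaustive pixel-distance maximum", {
  set.seed(31)
  for (rep in 1:5) {
    angs <- sort(stats::runif(5, 0, 360))
    if (min(diff(c(angs, angs[1] + 360))) < 25) next  # avoid merged branches
    arb <- make_star_arbor(angs, length_um = stats::runif(1, 20, 35))
    sk <- skeletonize_arbor(arb)
    lb <- as.numeric(longest_branch(sk))
    pts <- (sk$pixels - 1) * rep(sk$pixel_size_um, each = nrow(sk$pixels))
    oracle <- max(sqrt(rowSums(sweep(pts, 2, sk$nucleus_yx_um)^2)))
    expect_equal(lb, oracle, tolerance = 1e-9)
  }
})

test_that("a cyclic skeleton falls back to the pixel maximum with a flag", {
  m <- matrix(FALSE, 61, 61)
  m[21, 21:41] <- TRUE; m[41, 21:41] <- TRUE
  m[21:41, 21] <- TRUE; m[21:41, 41] <- TRUE    # hollow square ring
  sk <- skeletonize_arbor(make_arbor(m, nucleus_yx_um = c(15, 15)))
  lb <- longest_branch(sk)
  expect_true(attr(lb, "fallback"))
  expect_gt(as.numeric(lb), 0)
})

test_that("a disc has unit length-to-width ratio", {
  yy <- seq(0, 40, by = 0.5)
  m <- outer((yy - 20)^2, (yy - 20)^2, `+`) <= 100
  lw <- length_width_ratio(make_arbor(m))
  expect_equal(lw$lw_ratio, 1, tolerance = 2 / 40)   # 2 / diameter-in-px
})

test_that("an ellipse recovers its analytic axis ratio", {
  yy <- seq(0, 50, by = 0.2); xx <- seq(0, 12, by = 0.2)
  m <- outer(((yy - 25) / 20)^2, ((xx - 6) / 5)^2, `+`) <= 1
  lw <- length_width_ratio(make_arbor(m, c(0.2, 0.2)))
  expect_equal(lw$lw_ratio, 4, tolerance = 0.05)
  expect_equal(lw$length_um, 40, tolerance = 0.02)
  expect_equal(lw$width_um, 10, tolerance = 0.05)
  expect_error(length_width_ratio(make_arbor(matrix(FALSE, 5, 5))),
               "degenerate")
})

test_that("calipers match the rotation-search oracle on random polygons", {
  set.seed(32)
  for (i in 1:30) {
    k <- sample(5:12, 1)
    pts <- matrix(stats::runif(2 * k, 0, 30), k, 2)
    f <- max_feret(pts)
    width <- extent_along(convex_hull(pts), c(-f$axis[2], f$axis[1]))
    oracle <- feret_rotation_oracle(pts)
    expect_equal(f$length_um, oracle$length, tolerance = 0.01)
    expect_equal(width, oracle$width, tolerance = 0.01)
  }
})

test_that("orientation reads 0, 45 and 90 degrees off aligned ellipses", {
  atl <- region_atlas(matrix(1L, 64, 64), midline_axis = c(1, 0),
                      pixel_size_um = c(0.2, 0.2))
  cfg <- septastro_config()
  ellipse <- function(angle_deg) {
    th <- angle_deg * pi / 180
    yy <- seq(-30, 30, by = 0.2)
    m <- matrix(FALSE, length(yy), length(yy))
    for (i in seq_along(yy)) {
      u <- yy[i] * cos(th) - yy * sin(th)
      v <- yy[i] * sin(th) + yy * cos(th)
      m[i, ] <- (u / 20)^2 + (v / 5)^2 <= 1
    }
    make_arbor(m, c(0.2, 0.2))
  }
  o0 <- orientation_angle(ellipse(0), atl, cfg)
  o45 <- orientation_angle(ellipse(45), atl, cfg)
  o90 <- orientation_angle(ellipse(90), atl, cfg)
  expect_true(o0$defined)
  expect_lt(o0$orientation_deg, 1)
  expect_equal(o45$orientation_deg, 45, tolerance = 1)
  expect_gt(o90$orientation_deg, 89)
  # the PCA estimator agrees on a strongly elongated shape
  op <- orientation_angle(ellipse(45), atl, cfg, method = "pca")
  expect_equal(op$orientation_deg, 45, tolerance = 1)
})

test_that("near-isotropic cells have undefined orientation", {
  yy <- seq(0, 40, by = 0.5)
  disc <- outer((yy - 20)^2, (yy - 20)^2, `+`) <= 100
  atl <- region_atlas(matrix(1L, 64, 64))
  o <- orientation_angle(make_arbor(disc), atl, septastro_config())
  expect_false(o$defined)
  expect_true(is.na(o$orientation_deg))
})

test_that("angle binning uses half-open bins and sums to one", {
  expect_equal(unname(bin_angles(c(10, 40, 80))), rep(1 / 3, 3))
  expect_equal(unname(bin_angles(c(0, 0, 0))), c(1, 0, 0))
  expect_equal(unname(bin_angles(c(30, 60, 90))), c(0, 1 / 3, 2 / 3))
  expect_equal(sum(bin_angles(stats::runif(50, 0, 90))), 1)
  expect_equal(names(bin_angles(45)), c("[0,30)", "[30,60)", "[60,90]"))
  expect_error(bin_angles(numeric(0)), "no defined")
  expect_error(bin_angles(c(NA, NA)), "no defined")
  expect_error(bin_angles(10, edges_deg = c(0, 50)), "span")
  expect_error(bin_angles(100), "\\[0, 90\\]")
})

test_that("a six-armed star crosses every circle six times", {
  arb <- make_star_arbor(c(5, 65, 125, 185, 245, 305), length_um = 30)
  sk <- skeletonize_arbor(arb)
  sp <- sholl_profile(sk, step_um = 5.1)
  expect_true(all(sp$intersections[sp$radius_um > 5 &
                                     sp$radius_um < 29] == 6))
})

test_that("a single segment crosses only circles shorter than itself", {
  m <- matrix(FALSE, 41, 81); m[21, 11:71] <- TRUE   # 30 um segment
  sk <- skeletonize_arbor(make_arbor(m, nucleus_yx_um = c(10, 5)))
  sp <- sholl_profile(sk, step_um = 7.3)
  expect_true(all(sp$intersections[sp$radius_um < 30] == 1))
  expect_equal(nrow(sp), 4)        # radii 7.3 .. 29.2 only
})

test_that("sholl counts equal the analytic circle-polyline oracle", {
  set.seed(33)
  arb <- make_star_arbor(c(20, 95, 150, 240, 310), length_um = 28)
  sk <- skeletonize_arbor(arb)
  sp <- sholl_profile(sk, step_um = 4.7)
  polylines <- lapply(sk$edges, `[[`, "polyline_um")
  oracle <- vapply(sp$radius_um, function(r)
    circle_polyline_crossings(polylines, sk$nucleus_yx_um, r), integer(1))
  expect_equal(sp$intersections, oracle)
  expect_error(sholl_profile(sk, step_um = 0), "step_um")
})

test_that("measure_astrocyte assembles one coherent record with a region", {
  atl <- make_atlas(c(320, 320))
  cfg <- synth_config(noise_sd = 0, branch_length_sd_um = 0,
                      branch_length_mean_um = 25)
  set.seed(34)
  cell <- sample_arbor(cfg, c(32, 8), 7L)   # inside the MS column (x < 16)
  st <- render_cells(list(cell), cfg, atlas = atl)
  arb <- segment_arbor(st, "tdT", cell$soma_yx_um, septastro_config())
  arb$cell_id <- 7L
  rec <- measure_astrocyte(arb, atl, septastro_config())
  expect_equal(rec$cell_id, 7L)
  expect_equal(rec$region_label, "MS")
  expect_equal(rec$longest_branch_um, 25, tolerance = 1)
  expect_gte(rec$lw_ratio, 1)
  expect_equal(rec$territory_volume_um3, rec$territory_area_um2 * 5)
})
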