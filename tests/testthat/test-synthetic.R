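# Ground-truth simulator: atlas presets, arbor sampling, rendering, puncta
# fields, census mosaics, and reproducibility from (seed, config).

test_that("the default atlas preset labels every pixel with MS medial", {
  atl <- make_atlas(c(256, 256))
  expect_true(all(atl$labels %in% 1:4))
  expect_true(all(atl$labels[, 1] == 1L))          # MS column at the midline
  expect_equal(atl$midline_axis, c(1, 0))
  lat <- atl$labels[, 256]
  expect_equal(unique(lat[1:85]), 2L)              # dorsal -> ventral stacking
  expect_equal(unique(lat[172:256]), 4L)
  expect_error(make_atlas(c(32, 32)), "64")
  expect_error(make_atlas(c(128, 128), layout = "hexagonal"), "preset")
  expect_identical(make_atlas(c(128, 128))$labels,
                   make_atlas(c(128, 128))$labels)
})

test_that("degenerate von Mises arbors collapse onto the midline", {
  cfg <- synth_config(orientation_kappa = 1e6, orientation_mu_deg = 0)
  set.seed(2)
  cell <- sample_arbor(cfg, c(100, 100))
  expect_lt(cell$true_orientation_deg, 1)
})

test_that("isotropic branch angles are uniform after folding to [0, 90)", {
  cfg <- synth_config(orientation_kappa = 0)
  set.seed(3)
  angles <- unlist(lapply(1:1700, function(i)
    sample_arbor(cfg, c(100, 100), i)$branch_angles_deg))
  expect_gte(length(angles), 10000)
  counts <- table(cut(angles, seq(0, 90, by = 10), include.lowest = TRUE))
  chi <- stats::chisq.test(counts)
  expect_gt(chi$p.value, 0.01)
})

test_that("fixed-length arbors record an exact longest branch", {
  cfg <- synth_config(branch_length_sd_um = 0, branch_length_mean_um = 40)
  set.seed(4)
  cell <- sample_arbor(cfg, c(100, 100))
  expect_equal(cell$true_longest_branch_um, 40)
  expect_equal(unname(cell$branch_lengths_um), rep(40, cfg$n_branches))
})

test_that("generated ground truth satisfies its own invariants", {
  cfg <- synth_config()
  set.seed(5)
  for (i in 1:20) {
    cell <- sample_arbor(cfg, c(100, 100), i)
    d <- sqrt(rowSums(sweep(cell$tips_um, 2, cell$soma_yx_um)^2))
    expect_equal(cell$true_longest_branch_um, max(d))
    expect_true(cell$true_orientation_deg >= 0 &&
                  cell$true_orientation_deg <= 90)
    expect_true(all(cell$branch_lengths_um > 1))
  }
  expect_error(sample_arbor(synth_config(branch_length_mean_um = -1),
                            c(0, 0)))
  expect_error(sample_arbor(synth_config(n_branches = 1L), c(0, 0)))
})

test_that("noise-free rendering confines reporter signal to the arbor", {
  cfg <- synth_config(noise_sd = 0, background_level = 0,
                      branch_length_sd_um = 0, psf_sigma_um = 0.5)
  set.seed(6)
  cell <- sample_arbor(cfg, c(60, 60))
  st <- render_cells(list(cell), cfg, shape_yx = c(600, 600))
  proj <- max_project(st, "tdT")
  lit <- which(proj > 0.01 * max(proj), arr.ind = TRUE)
  # every clearly lit pixel lies within a few PSF sigmas of a branch segment
  pts <- (lit - 1) * 0.2
  mind <- vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    min(vapply(seq_len(nrow(cell$tips_um)), function(b) {
      a <- cell$soma_yx_um; bb <- cell$tips_um[b, ]
      t <- max(0, min(1, sum((p - a) * (bb - a)) / sum((bb - a)^2)))
      sqrt(sum((a + t * (bb - a) - p)^2))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(max(mind), cfg$branch_width_um / 2 + 3 * cfg$psf_sigma_um)
})

test_that("rendering is deterministic given the RNG state", {
  cfg <- synth_config()
  set.seed(7); cell <- sample_arbor(cfg, c(60, 60))
  set.seed(8); st1 <- render_cells(list(cell), cfg, shape_yx = c(400, 400))
  set.seed(8); st2 <- render_cells(list(cell), cfg, shape_yx = c(400, 400))
  expect_identical(st1$voxels, st2$voxels)
})

test_that("rendered DAPI has one local maximum per soma", {
  cfg <- synth_config(noise_sd = 0)
  somas <- rbind(c(30, 30), c(30, 90), c(90, 30), c(90, 90), c(60, 60))
  set.seed(9)
  cells <- lapply(1:5, function(i) sample_arbor(cfg, somas[i, ], i))
  st <- render_cells(cells, cfg, shape_yx = c(600, 600))
  proj <- max_project(st, "DAPI")
  # local maxima of the projection above half amplitude
  pk <- which(proj > cfg$amplitude / 2 &
                proj == as.matrix(EBImage::dilate(proj,
                  EBImage::makeBrush(9, "box"))), arr.ind = TRUE)
  expect_equal(nrow(pk), 5)
  pos <- (pk - 1) * 0.2
  d <- sqrt(outer(pos[, 1], somas[, 1], `-`)^2 +
            outer(pos[, 2], somas[, 2], `-`)^2)
  expect_lt(max(apply(d, 2, min)), 0.21)   # within one voxel of truth
})

test_that("overlapping somata abort rendering and name the collision", {
  cfg <- synth_config()
  set.seed(10)
  cells <- list(sample_arbor(cfg, c(50, 50), 1L),
                sample_arbor(cfg, c(50, 53), 2L))
  expect_error(render_cells(cells, cfg, shape_yx = c(400, 400)), "\\(1,2\\)")
})

test_that("fully colocalized puncta all have a partner within the radius", {
  cfg <- synth_config(coloc_fraction = 1, lambda_post_per_um3 = 0,
                      lambda_pre_per_um3 = 0.02, coloc_radius_um = 0.3)
  set.seed(11)
  gp <- sample_puncta(cfg, c(5, 50, 50))
  expect_equal(nrow(gp$coloc_pairs), nrow(gp$pre_um))
  expect_equal(nrow(gp$post_um), nrow(gp$pre_um))
  d <- sqrt(rowSums((gp$pre_um[gp$coloc_pairs[, 1], , drop = FALSE] -
                     gp$post_um[gp$coloc_pairs[, 2], , drop = FALSE])^2))
  expect_true(all(d <= cfg$coloc_radius_um + 1e-12))
  expect_false(anyDuplicated(gp$coloc_pairs[, 1]) > 0)
  expect_false(anyDuplicated(gp$coloc_pairs[, 2]) > 0)
})

test_that("puncta counts follow the Poisson intensity of the field", {
  cfg <- synth_config(lambda_pre_per_um3 = 0.01, coloc_fraction = 0)
  set.seed(12)
  counts <- vapply(1:100, function(i)
    nrow(sample_puncta(cfg, c(5, 100, 100))$pre_um), numeric(1))
  expect_equal(length(sample_puncta(cfg, c(5, 20, 20))$coloc_pairs), 0)
  mu <- 0.01 * 5 * 100 * 100            # lambda * V = 500
  se <- sqrt(mu / 100)
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("puncta sampling rejects impossible configurations", {
  expect_error(sample_puncta(synth_config(), c(0, 10, 10)), "volume")
  cfg <- synth_config()
  cfg$coloc_radius_um <- 0   # bypass constructor check to hit the operator's
  expect_error(sample_puncta(cfg, c(5, 10, 10)), "coloc_radius_um")
})

test_that("census positivity follows each region's probability", {
  atl <- make_atlas(c(128, 128))
  set.seed(13)
  all_pos <- sample_census(synth_config(
    n_cells_per_region = 50L,
    p_double_positive = c(MS = 1, dLS = 1, iLS = 1, vLS = 1)), atl)
  expect_true(all(all_pos$double_positive))
  none <- sample_census(synth_config(
    n_cells_per_region = 50L,
    p_double_positive = c(MS = 0, dLS = 0, iLS = 0, vLS = 0)), atl)
  expect_false(any(none$double_positive))
  big <- sample_census(synth_config(
    n_cells_per_region = 10000L,
    p_double_positive = c(MS = 0.74, dLS = 0.74, iLS = 0.74, vLS = 0.74)),
    atl, regions = "MS")
  frac <- mean(big$double_positive)
  expect_lt(abs(frac - 0.74), 3 * sqrt(0.74 * 0.26 / 10000))
  # placed cells actually lie inside their region
  px <- round(big$y_um / 0.2) + 1
  py <- round(big$x_um / 0.2) + 1
  expect_true(all(atl$labels[cbind(pmax(1, pmin(128, px)),
                                   pmax(1, pmin(128, py)))] == 1L))
})

test_that("a census cannot be drawn from an absent region", {
  lab <- matrix(1L, 64, 64)      # MS only
  atl <- region_atlas(lab)
  set.seed(14)
  expect_error(sample_census(synth_config(), atl, regions = "dLS"),
               "zero area")
})

test_that("the full simulation is reproducible and seed-sensitive", {
  cfg <- synth_config(n_cells_per_region = 20L)
  s1 <- simulate_septum(cfg, seed = 21)
  s2 <- simulate_septum(cfg, seed = 21)
  s3 <- simulate_septum(cfg, seed = 22)
  expect_identical(s1$stack$voxels, s2$stack$voxels)
  expect_identical(s1$census, s2$census)
  expect_identical(s1$puncta$pre_um, s2$puncta$pre_um)
  expect_false(identical(s1$stack$voxels, s3$stack$voxels))
})
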