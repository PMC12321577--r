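# Nucleus detection, arbor segmentation, skeletonization and territories.

test_that("nuclei are detected at their true positions without merging", {
  cfg <- synth_config(noise_sd = 0)
  somas <- rbind(c(30, 30), c(30, 90), c(90, 30), c(90, 90), c(60, 60))
  set.seed(21)
  cells <- lapply(1:5, function(i) sample_arbor(cfg, somas[i, ], i))
  st <- render_cells(cells, cfg, shape_yx = c(600, 600))
  nuc <- detect_nuclei(st, "DAPI", septastro_config())
  expect_equal(nrow(nuc$centroids_um), 5)
  d <- sqrt(outer(nuc$centroids_um[, 1], somas[, 1], `-`)^2 +
            outer(nuc$centroids_um[, 2], somas[, 2], `-`)^2)
  expect_lt(max(apply(d, 2, min)), 0.21)          # within one voxel
  expect_setequal(setdiff(unique(as.vector(nuc$labels)), 0L), 1:5)
})

test_that("a blank channel yields an empty nucleus set", {
  vox <- array(0, dim = c(1, 3, 64, 64))
  st <- image_stack(vox, c(1, 0.2, 0.2), "DAPI")
  nuc <- detect_nuclei(st, "DAPI", septastro_config())
  expect_equal(nrow(nuc$centroids_um), 0)
  expect_error(detect_nuclei(st, "GFP", septastro_config()), "GFP")
})

test_that("two nuclei 20 um apart stay separate detections", {
  cfg <- synth_config(noise_sd = 2)
  set.seed(22)
  cells <- list(sample_arbor(cfg, c(40, 30), 1L),
                sample_arbor(cfg, c(40, 50), 2L))
  st <- render_cells(cells, cfg, shape_yx = c(400, 400))
  nuc <- detect_nuclei(st, "DAPI", septastro_config())
  expect_equal(nrow(nuc$centroids_um), 2)
})

test_that("the segmented mask hugs the rendered arbor support", {
  cfg <- synth_config(noise_sd = 0, background_level = 0,
                      branch_length_sd_um = 0)
  set.seed(23)
  cell <- sample_arbor(cfg, c(60, 60))
  st <- render_cells(list(cell), cfg, shape_yx = c(600, 600))
  # reconstruct the pre-blur support exactly as the renderer does
  support <- matrix(FALSE, 600, 600)
  for (b in seq_len(nrow(cell$tips_um))) {
    px <- septastro:::raster_segment(cell$soma_yx_um, cell$tips_um[b, ],
                                     c(0.2, 0.2), 600, 600)
    support[px] <- TRUE
  }
  support <- as.matrix(EBImage::dilate(support, EBImage::makeBrush(5,
    "disc"))) > 0
  # threshold at 10% of amplitude: the PSF tail (sigma 2.5 px) stays above
  # 1 for ~6 px beyond the support but drops below 10 within ~3 px
  arb <- segment_arbor(st, "tdT", cell$soma_yx_um,
                       septastro_config(arbor_threshold = 10))
  expect_true(arb$mask[301, 301])      # nucleus pixel inside the mask
  # mask within a small dilation of the support and covering most of it
  grown <- as.matrix(EBImage::dilate(support, EBImage::makeBrush(9,
    "disc"))) > 0
  expect_true(all(grown[arb$mask]))
  expect_gt(mean(arb$mask[support]), 0.95)
  # connectedness: exactly one component
  expect_equal(max(EBImage::bwlabel(arb$mask)), 1)
})

test_that("arbors reaching the image edge are flagged border-touching", {
  cfg <- synth_config(noise_sd = 0, branch_length_sd_um = 0)
  set.seed(24)
  # soma 30 um from the bottom edge of a 59.8 um tall field: the 40 um
  # branches (concentrated along +y, the midline direction) cross the edge
  cell <- sample_arbor(cfg, c(30, 60))
  st <- render_cells(list(cell), cfg, shape_yx = c(300, 600))
  arb <- segment_arbor(st, "tdT", cell$soma_yx_um, septastro_config())
  expect_true(arb$border_touching)
})

test_that("an all-background window raises a 'no arbor found' error", {
  vox <- array(10, dim = c(1, 3, 200, 200))
  st <- image_stack(vox, c(1, 0.2, 0.2), "tdT")
  expect_error(segment_arbor(st, "tdT", c(20, 20), septastro_config()),
               "no arbor found")
})

test_that("a straight bar thins to one path of near-full length", {
  m <- matrix(FALSE, 21, 101)
  m[9:13, 11:91] <- TRUE                  # 40 x 2 um bar at 0.5 um pixels
  sk <- skeletonize_arbor(make_arbor(m, nucleus_yx_um = c(5, 25)))
  expect_equal(nrow(sk$endpoints_um), 2)
  expect_equal(length(sk$edges), 1)
  # thinning erodes up to half the bar width at each end
  expect_gt(sk$total_length_um, 40 - 2 * 1 - 2 * 0.5 * sqrt(2))
  expect_lt(sk$total_length_um, 41)
})

test_that("a plus-sign mask keeps four arms around one junction", {
  m <- matrix(FALSE, 81, 81)
  m[41, 11:71] <- TRUE; m[11:71, 41] <- TRUE
  sk <- skeletonize_arbor(make_arbor(m, nucleus_yx_um = c(20, 20)))
  expect_equal(nrow(sk$endpoints_um), 4)
  expect_equal(length(sk$edges), 4)
  # each edge joins one endpoint to the junction (polyline orientation is
  # unspecified): the terminus that is not an endpoint must be shared
  ep_key <- apply(round(sk$endpoints_um, 6), 1, paste, collapse = ",")
  junctions <- unique(unlist(lapply(sk$edges, function(e) {
    term <- e$polyline_um[c(1, nrow(e$polyline_um)), , drop = FALSE]
    keys <- apply(round(term, 6), 1, paste, collapse = ",")
    keys[!(keys %in% ep_key)]
  })))
  expect_equal(length(junctions), 1)      # all arms meet at one node
})

test_that("a star arbor keeps one endpoint per generated branch", {
  arb <- make_star_arbor(c(10, 70, 130, 190, 250, 310))
  sk <- skeletonize_arbor(arb)
  expect_equal(nrow(sk$endpoints_um), 6)
  expect_error(skeletonize_arbor(make_arbor(matrix(FALSE, 10, 10))), "empty")
})

test_that("skeleton length is invariant under translation and rotation", {
  arb <- make_star_arbor(c(15, 80, 160, 230, 300), centre_um = c(35, 35),
                         shape_px = c(401, 401))
  len0 <- skeletonize_arbor(arb)$total_length_um
  # translate the mask by 7 pixels in y and 11 in x
  m <- arb$mask
  mt <- matrix(FALSE, nrow(m), ncol(m))
  mt[8:nrow(m), 12:ncol(m)] <- m[1:(nrow(m) - 7), 1:(ncol(m) - 11)]
  lent <- skeletonize_arbor(make_arbor(mt, arb$pixel_size_um,
                                       arb$nucleus_yx_um + c(1.4, 2.2)))$total_length_um
  expect_equal(lent, len0, tolerance = 1e-8)
  # rotate by 90 degrees
  mr <- t(m)[ncol(m):1, ]
  lenr <- skeletonize_arbor(make_arbor(mr, arb$pixel_size_um))$total_length_um
  expect_equal(lenr, len0, tolerance = 1e-8)
})

test_that("territories are the convex hull with area x depth volume", {
  m <- matrix(FALSE, 120, 70)
  m[10:110, 10:60] <- TRUE                # 20 x 10 um rectangle at 0.2 um
  terr <- compute_territory(make_arbor(m, c(0.2, 0.2)), depth_um = 5)
  expect_equal(terr$area_um2, 200)
  expect_equal(terr$volume_um3, 1000)
  # the hull contains every mask pixel
  pix <- (which(m, arr.ind = TRUE) - 1) * 0.2
  expect_true(all(points_in_polygon(pix, terr$polygon_um)))
  # collinear masks are degenerate
  line <- matrix(FALSE, 20, 20); line[5, 3:17] <- TRUE
  expect_error(compute_territory(make_arbor(line)), "degenerate")
})

test_that("hull area never decreases when pixels are added", {
  set.seed(25)
  m <- matrix(FALSE, 60, 60)
  m[cbind(sample(10:50, 40, TRUE), sample(10:50, 40, TRUE))] <- TRUE
  a0 <- compute_territory(make_arbor(m))$area_um2
  for (i in 1:10) {
    m[sample(60, 1), sample(60, 1)] <- TRUE
    a1 <- compute_territory(make_arbor(m))$area_um2
    expect_gte(a1, a0 - 1e-9)
    a0 <- a1
  }
})
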