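test_that("zero-noise localizations lie on the structure and are conserved", {
  s <- structure_model("sphere", center = c(500, -200, 100), axes = 120,
                       n_emitters = 300)
  acq <- acquisition_params(sigma_xy = 0, sigma_z = 0, blink_mean = 3,
                            n_frames = 1000, seed = 11)
  tab <- simulate_localizations(s, acq)
  truth <- attr(tab, "truth")
  # count conservation: rows = sum of per-structure blink counts
  expect_identical(nrow(tab), sum(truth$n_locs))
  expect_identical(sort(unique(tab$truth_cluster)), 1L)
  # every localization sits inside the (zero-noise) sphere
  d <- sqrt((tab$x_nm - 500)^2 + (tab$y_nm + 200)^2 + (tab$z_nm - 100)^2)
  expect_lte(max(d), 120 + 1e-9)
  # blinking duplicates emitter positions
  expect_gt(nrow(tab), 300)
  expect_lte(length(unique(paste(tab$x_nm, tab$y_nm, tab$z_nm))), 300)
  # frames live in [0, n_frames)
  expect_gte(min(tab$frame), 0L)
  expect_lt(max(tab$frame), 1000L)
})

test_that("uniform-ball sample Rg approaches the closed form sqrt(3/5) R", {
  s <- structure_model("sphere", axes = 100, n_emitters = 20000)
  acq <- acquisition_params(sigma_xy = 0, sigma_z = 0, blink_mean = 1,
                            seed = 2)
  tab <- simulate_localizations(s, acq)
  expect_equal(radius_of_gyration(tab), sqrt(3 / 5) * 100, tolerance = 0.01)
})

test_that("simulators are bit-identical under a fixed seed", {
  s <- structure_model("ellipsoid", axes = c(150, 80, 40), n_emitters = 200)
  acq <- acquisition_params(seed = 99, background_density = 5)
  expect_identical(simulate_localizations(s, acq),
                   simulate_localizations(s, acq))
  d1 <- simulate_rg_sample(50, mean_rg_nm = 84, seed = 7)
  d2 <- simulate_rg_sample(50, mean_rg_nm = 84, seed = 7)
  expect_identical(d1, d2)
  sc <- foci_scene(n_a = 5, n_b = 5, n_overlap = 2, seed = 3)
  expect_identical(simulate_foci_image(sc), simulate_foci_image(sc))
  sp <- dot_blot_spec(rbind(g = c(input = 1, HP1a = 2)), noise_cv = 0.2,
                      seed = 5)
  expect_identical(simulate_dot_blot(sp), simulate_dot_blot(sp))
})

test_that("background localizations are labeled 0 and fill the volume", {
  s <- structure_model("sphere", axes = 80, n_emitters = 100)
  acq <- acquisition_params(background_density = 50, seed = 4,
                            fov = list(xlim = c(-2000, 2000),
                                       ylim = c(-2000, 2000)))
  tab <- simulate_localizations(s, acq)
  expect_gt(sum(tab$truth_cluster == 0L), 0)
  bg <- tab[tab$truth_cluster == 0L, ]
  expect_true(all(abs(bg$z_nm) <= 350))
})

test_that("invalid structures and parameters are rejected", {
  expect_error(structure_model("sphere", axes = -10), "positive")
  expect_error(structure_model("sphere", axes = c(10, 20, 30)), "equal")
  expect_error(acquisition_params(sigma_xy = NaN), "finite")
  expect_error(acquisition_params(n_frames = 0), ">= 1")
  s_out <- structure_model("sphere", center = c(0, 0, 500), axes = 50)
  expect_error(simulate_localizations(s_out, acquisition_params()),
               "z-depth")
})

test_that("ellipsoid anisotropy is recovered in the simulated cloud", {
  s <- structure_model("ellipsoid", axes = c(200, 100, 50),
                       n_emitters = 20000)
  acq <- acquisition_params(sigma_xy = 0, sigma_z = 0, blink_mean = 1,
                            seed = 8)
  tab <- simulate_localizations(s, acq)
  spread <- cluster_anisotropy(tab)
  # uniform ellipsoid: principal spreads are the semi-axes / sqrt(5)
  expect_equal(spread, c(200, 100, 50) / sqrt(5), tolerance = 0.05)
  expect_equal(spread[3] / spread[1], 50 / 200, tolerance = 0.05)
})

test_that("segmented-path structures carry a consistent ground-truth Rg", {
  path <- matrix(c(-300, 0, 0, 0, 200, 0, 300, 200, 100), ncol = 3,
                 byrow = TRUE)
  s <- structure_model("segmented_path", path = path, tube_sigma = 20,
                       n_emitters = 30000)
  acq <- acquisition_params(sigma_xy = 0, sigma_z = 0, blink_mean = 1,
                            seed = 12)
  tab <- simulate_localizations(s, acq)
  expect_equal(radius_of_gyration(tab), s$rg_struct, tolerance = 0.02)
})

test_that("rendered conventional images integrate to the localization count", {
  empty <- loc_table(numeric(0), numeric(0), numeric(0), integer(0))
  img0 <- render_conventional_image(empty, pixel_size = 100)
  expect_true(all(img0 == 0))
  one <- loc_table(0, 0, 0, 0L)
  img1 <- render_conventional_image(one, pixel_size = 100, psf_sigma = 250)
  expect_equal(sum(img1), 1, tolerance = 1e-6)
  # two clusters 2 um apart give two local maxima at their centers
  set.seed(21)
  xy <- rbind(cbind(rnorm(300, 0, 60), rnorm(300, 0, 60)),
              cbind(rnorm(300, 2000, 60), rnorm(300, 0, 60)))
  tab <- loc_table(xy[, 1], xy[, 2], rep(0, 600), rep(0L, 600))
  img <- render_conventional_image(tab, pixel_size = 100, psf_sigma = 150)
  ctr <- which(img == max(img), arr.ind = TRUE)
  origin <- attr(img, "origin")
  px <- attr(img, "pixel_size")
  peak1_x <- origin[1] + (ctr[1, 2] - 1) * px
  expect_lt(min(abs(peak1_x - c(0, 2000))), px)
  # second cluster: maximum over the right half of the field
  right <- img[, (origin[1] + (seq_len(ncol(img)) - 1) * px) > 1000]
  expect_gt(max(right), 0.5 * max(img))
})

test_that("foci scenes record the overlap plan and validate centroids", {
  sc <- foci_scene(n_a = 20, n_b = 10, n_overlap = 8, seed = 6)
  expect_equal(sc$overlap_fraction, 0.4)
  expect_equal(sum(sc$a_overlaps), 8)
  expect_error(foci_scene(n_a = 3, n_b = 2, n_overlap = 3, seed = 1),
               "n_overlap")
  mask <- matrix(FALSE, 64, 64); mask[20:40, 20:40] <- TRUE
  expect_error(
    foci_scene(image_shape = c(64, 64), nucleus_mask = mask,
               foci_a = data.frame(row = 5, col = 5),
               foci_b = data.frame(row = 25, col = 25)),
    "inside the nucleus mask")
})

test_that("gel simulation records the weighted-mean ground truth", {
  lad <- default_ladder()
  one <- simulate_gel_profile(gel_lane_spec(
    data.frame(mw_kb = 5, intensity = 3, sigma = 1e-9), lad))
  expect_equal(one$truth$mean_length_kb, 5)
  two <- simulate_gel_profile(gel_lane_spec(
    data.frame(mw_kb = c(2, 8), intensity = c(4, 4), sigma = c(1e-9, 1e-9)),
    lad))
  expect_equal(two$truth$mean_length_kb, 2 / (1 / 2 + 1 / 8))
  scaled <- simulate_gel_profile(gel_lane_spec(
    data.frame(mw_kb = c(2, 8), intensity = c(40, 40),
               sigma = c(1e-9, 1e-9)), lad))
  expect_equal(scaled$truth$mean_length_kb, two$truth$mean_length_kb)
  expect_error(ladder_calibration(c(10, 10), c(5, 2)), "increasing")
})

test_that("dot-blot simulation is exact at zero noise", {
  tr <- rbind(Vonly = c(input = 1, HP1a = 0.05, IgG = 0.01),
              TRF1HP1a = c(input = 1, HP1a = 1.4, IgG = 0.01))
  grid <- simulate_dot_blot(dot_blot_spec(tr, noise_cv = 0))
  nb <- normalize_dot_blot(grid, control_groups = "Vonly")
  expect_equal(nb$ratios$mean_ratio[nb$ratios$group == "TRF1HP1a" &
                                      nb$ratios$antibody == "HP1a"], 1.4)
  expect_equal(nb$folds$fold_vs_control[nb$folds$group == "TRF1HP1a" &
                                          nb$folds$antibody == "HP1a"], 28)
  # IgG stays at background level relative to input
  expect_equal(unique(nb$ratios$mean_ratio[nb$ratios$antibody == "IgG"]),
               0.01)
})
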