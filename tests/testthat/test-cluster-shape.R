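test_that("radius of gyration matches closed forms and the pairwise identity", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  two <- matrix(c(0, 0, 0, 100, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two), 50)
  expect_error(radius_of_gyration(matrix(numeric(0), 0, 3)), "empty")
  set.seed(41)
  for (i in 1:10) {
    X <- random_cluster(50)
    expect_equal(radius_of_gyration(X), rg_pairwise_oracle(X),
                 tolerance = 1e-9)
  }
})

test_that("Rg is rigid-motion invariant and scale equivariant", {
  set.seed(42)
  for (i in 1:5) {
    X <- random_cluster(80)
    rg <- radius_of_gyration(X)
    R <- random_rotation()
    shifted <- sweep(X %*% R, 2, c(1e5, -2e4, 3e3), `+`)
    expect_equal(radius_of_gyration(shifted), rg, tolerance = 1e-9)
    expect_equal(radius_of_gyration(2.5 * X), 2.5 * rg, tolerance = 1e-9)
  }
})

test_that("adding a point at the center of mass shrinks Rg by sqrt(N/(N+1))", {
  set.seed(43)
  X <- random_cluster(60)
  n <- nrow(X)
  rg <- radius_of_gyration(X)
  X2 <- rbind(X, colMeans(X))
  expect_equal(radius_of_gyration(X2), rg * sqrt(n / (n + 1)),
               tolerance = 1e-9)
  expect_lt(radius_of_gyration(X2), rg)
})

test_that("principal-axis spreads satisfy the trace identity and flag degeneracy", {
  set.seed(44)
  for (i in 1:5) {
    X <- random_cluster(100)
    spread <- cluster_anisotropy(X)
    expect_equal(sum(spread^2), radius_of_gyration(X)^2, tolerance = 1e-9)
    expect_true(all(diff(spread) <= 0))
  }
  planar <- cbind(rnorm(50), rnorm(50), 0)
  expect_equal(cluster_anisotropy(planar)[3], 0, tolerance = 1e-9)
  tiny <- cluster_anisotropy(matrix(rnorm(6), 2, 3))
  expect_true(isTRUE(attr(tiny, "degenerate")))
  line <- cbind(1:50, 2 * (1:50), -(1:50))
  expect_true(isTRUE(attr(cluster_anisotropy(line), "degenerate")))
})

test_that("density clustering recovers well-separated simulated telomeres", {
  empty <- loc_table(numeric(0), numeric(0), numeric(0), integer(0))
  expect_length(cluster_localizations(empty), 0)
  set.seed(45)
  st <- list(structure_model("sphere", center = c(0, 0, 0), axes = 80,
                             n_emitters = 150, structure_id = 1L),
             structure_model("sphere", center = c(900, 0, 0), axes = 80,
                             n_emitters = 150, structure_id = 2L))
  tab <- simulate_localizations(st, acquisition_params(seed = 46))
  cl <- cluster_localizations(tab)
  expect_length(cl, 2)
  assign <- attr(cl, "assignment")
  for (k in 1:2) {
    truth_lab <- tab$truth_cluster[assign == k]
    purity <- max(table(truth_lab)) / length(truth_lab)
    expect_gte(purity, 0.95)
  }
})

test_that("clustering is invariant under a 10 um translation of a copy", {
  set.seed(47)
  s <- structure_model("sphere", axes = 70, n_emitters = 120)
  tab <- simulate_localizations(s, acquisition_params(seed = 48))
  shifted <- loc_table(c(tab$x_nm, tab$x_nm + 1e4),
                       c(tab$y_nm, tab$y_nm + 1e4),
                       c(tab$z_nm, tab$z_nm),
                       c(tab$frame, tab$frame))
  cl <- cluster_localizations(shifted)
  expect_length(cl, 2)
  expect_equal(cl[[1]]$N, cl[[2]]$N)
  expect_equal(cl[[1]]$rg, cl[[2]]$rg, tolerance = 1e-9)
})

test_that("the localization-count filter is strict at the boundary", {
  mk <- function(n, z = 0) {
    set.seed(50 + n)
    X <- random_cluster(n, scale = 40)
    cluster_from_matrix(sweep(X, 2, c(0, 0, z - mean(X[, 3])), `+`))
  }
  policy <- cluster_filter_policy(min_points = 200, focal_window = 250)
  expect_length(filter_clusters(list(mk(200)), policy), 0)
  expect_length(filter_clusters(list(mk(201)), policy), 1)
  # center of mass exactly on the focal plane is retained
  expect_length(filter_clusters(list(mk(300, z = 0)), policy,
                                focal_plane_z = 0), 1)
  # outside the focal window is dropped
  expect_length(filter_clusters(list(mk(300, z = 400)), policy,
                                focal_plane_z = 0), 0)
})

test_that("relaxing min_points never decreases the retained count", {
  set.seed(60)
  clusters <- lapply(sample(50:400, 20), function(n)
    cluster_from_matrix(random_cluster(n, scale = 50)))
  strict <- filter_clusters(clusters,
                            cluster_filter_policy(min_points = 200,
                                                  focal_window = 1e4))
  loose <- filter_clusters(clusters,
                           cluster_filter_policy(min_points = 100,
                                                 focal_window = 1e4))
  expect_gte(length(loose), length(strict))
})

test_that("reference-mask gating keeps only clusters under the mask", {
  mask <- matrix(FALSE, 10, 10)
  mask[1:10, 1:5] <- TRUE   # x in [0, 500) nm at 100 nm pixels
  policy <- cluster_filter_policy(min_points = 10, focal_window = 1e4,
                                  reference_mask = mask,
                                  mask_pixel_size = 100,
                                  mask_origin = c(0, 0))
  mk_at <- function(x) {
    X <- random_cluster(50, scale = 20)
    cluster_from_matrix(sweep(X, 2, c(x - mean(X[, 1]), 450 - mean(X[, 2]),
                                      -mean(X[, 3])), `+`))
  }
  set.seed(61)
  kept <- filter_clusters(list(mk_at(200), mk_at(800)), policy)
  expect_length(kept, 1)
  expect_lt(kept[[1]]$com[1], 500)
})
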