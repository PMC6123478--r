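small_groups <- function() {
  list(list(label = "ref", n_nuclei = 2, telomeres_per_nucleus = 5,
            mean_rg_nm = 84),
       list(label = "big", n_nuclei = 2, telomeres_per_nucleus = 5,
            mean_rg_nm = 95))
}

small_config <- function(seed = 7, ...) {
  experiment_config(groups = small_groups(),
                    acquisition = acquisition_params(n_frames = 2000),
                    filter = cluster_filter_policy(min_points = 200,
                                                   focal_window = 5000),
                    seed = seed, ...)
}

test_that("config validation fills defaults and names violations", {
  cfg <- validate_config(list(groups = list(list(label = "only",
                                                 n_nuclei = 1,
                                                 telomeres_per_nucleus = 3,
                                                 mean_rg_nm = 84))))
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$clustering$linkage_radius, 75)
  expect_equal(cfg$filter$min_points, 200)
  expect_equal(cfg$analysis$reference_group, "only")
  expect_equal(cfg$groups[[1]]$rg_cv, 0.35)
  expect_error(validate_config(list()), "at least one group")
  expect_error(validate_config(list(groups = small_groups(),
                                    acquisition = list(sigma_xy = -3))),
               "sigma_xy")
  dup <- small_groups(); dup[[2]]$label <- "ref"
  expect_error(validate_config(list(groups = dup)), "duplicate")
  expect_error(validate_config(list(groups = small_groups(),
                                    bogus_key = 1)), "bogus_key")
  bad <- small_groups(); bad[[1]]$n_nuclei <- 0
  expect_error(validate_config(list(groups = bad)), "n_nuclei")
})

test_that("configurations round-trip through YAML", {
  raw <- list(groups = list(list(label = "a", n_nuclei = 1,
                                 telomeres_per_nucleus = c(4, 6),
                                 mean_rg_nm = 84)),
              acquisition = list(n_frames = 1500, sigma_xy = 25),
              clustering = list(linkage_radius = 60),
              seed = 11)
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  yaml::write_yaml(raw, path)
  cfg <- read_experiment_config(path)
  expect_equal(cfg$acquisition$sigma_xy, 25)
  expect_equal(cfg$acquisition$n_frames, 1500L)
  expect_equal(cfg$clustering$linkage_radius, 60)
  expect_equal(cfg$clustering$min_cluster_seed, 10)  # default filled
  expect_equal(cfg$seed, 11L)
})

test_that("a run is deterministic and its counts are filter-monotone", {
  cfg <- small_config(seed = 9)
  r1 <- run_shape_experiment(cfg)
  r2 <- run_shape_experiment(cfg)
  expect_identical(as.data.frame(r1$shape_table),
                   as.data.frame(r2$shape_table))
  expect_identical(r1$fractions, r2$fractions)
  expect_true(all(r1$counts$clusters_kept <= r1$counts$clusters_found))
  expect_true(all(r1$counts$localizations >= r1$counts$clusters_found))
  # provenance: the report embeds the resolved config and seed
  expect_identical(r1$seed, 9L)
  expect_s3_class(r1$config, "experiment_config")
  expect_s3_class(r1$comparisons, "comparison_result")
})

test_that("zero-noise single-group runs pass the truth through exactly", {
  cfg <- experiment_config(
    groups = list(list(label = "only", n_nuclei = 2,
                       telomeres_per_nucleus = 4, mean_rg_nm = 84,
                       rg_cv = 0)),
    acquisition = acquisition_params(sigma_xy = 0, sigma_z = 0,
                                     blink_mean = 1, n_frames = 1000),
    filter = cluster_filter_policy(min_points = 50, focal_window = 5000),
    seed = 13)
  rep <- run_shape_experiment(cfg)
  # every planted telomere is found and kept
  expect_true(all(rep$counts$clusters_found == 4))
  expect_true(all(rep$counts$clusters_kept == 4))
  # with zero noise and rg_cv = 0 every cluster is a uniform ball sample
  # of the same structural size (Rg 84 nm): no noise floor is subtracted
  expect_equal(mean(rep$shape_table$rg_nm), 84, tolerance = 0.05)
  # fractions against the group itself: cutoff equals the group mean
  expect_equal(attr(rep$fractions, "cutoff_nm"),
               mean(rep$shape_table$rg_nm))
})

test_that("run artifacts are written to the output directory", {
  dir <- tempfile("runout")
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- small_config(seed = 21, out_dir = dir)
  rep <- run_shape_experiment(cfg)
  expect_true(all(file.exists(file.path(dir, c(
    "shape_table.csv", "summary_group.csv", "summary_nucleus.csv",
    "fractions.csv", "stage_counts.csv", "comparisons.csv",
    "report.yaml")))))
  back <- read_shape_table(file.path(dir, "shape_table.csv"))
  expect_equal(as.data.frame(back), as.data.frame(rep$shape_table),
               tolerance = 1e-6)
  meta <- yaml::read_yaml(file.path(dir, "report.yaml"))
  expect_equal(meta$seed, 21)
})

test_that("simulated group differences propagate through the full pipeline", {
  cfg <- experiment_config(
    groups = list(
      list(label = "ref", n_nuclei = 3, telomeres_per_nucleus = 8,
           mean_rg_nm = 84),
      list(label = "big", n_nuclei = 3, telomeres_per_nucleus = 8,
           mean_rg_nm = 105, shape = "ellipsoid", aspect = c(4, 2, 1))),
    acquisition = acquisition_params(n_frames = 2000),
    filter = cluster_filter_policy(min_points = 200, focal_window = 5000),
    seed = 31)
  rep <- run_shape_experiment(cfg)
  s <- rep$summary$group
  expect_gt(s$mean_rg_nm[s$group == "big"], s$mean_rg_nm[s$group == "ref"])
  fr <- rep$fractions
  expect_gt(fr$fraction[fr$group == "big"], fr$fraction[fr$group == "ref"])
})
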