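#' Build an experiment configuration
#'
#' Describes a complete simulated shape experiment: the groups (each a
#' population of nuclei containing spherical or ellipsoidal telomere
#' structures calibrated to a target observed mean Rg), the acquisition
#' parameters, the clustering and filtering settings, and the analysis
#' options. The resolved configuration is validated against the schema
#' and embedded verbatim in the run report for provenance.
#'
#' Group fields: `label`; `n_nuclei`; `telomeres_per_nucleus` (a count
#' or a `c(min, max)` range sampled per nucleus); `mean_rg_nm` (target
#' observed mean Rg -- the structural size is solved from the
#' noise-additivity law); `rg_cv` (lognormal CV of structural radius
#' across telomeres, default 0.35); `shape` (`"sphere"` or
#' `"ellipsoid"`); `aspect` (relative semi-axes for ellipsoids, default
#' `c(1, 1, 1)`); `n_emitters` (default 100).
#'
#' @param groups list of group definition lists (see Details).
#' @param acquisition an [acquisition_params()] object or a named list
#'   of its arguments.
#' @param clustering list with `linkage_radius`, `min_cluster_seed`.
#' @param filter a [cluster_filter_policy()] or named list of its
#'   arguments.
#' @param analysis list with `dims` (`"3d"`/`"2d"`) and
#'   `reference_group` (defaults to the first group label).
#' @param drift_correction list with `enabled`, `frames_per_bin`,
#'   `pixel_size`.
#' @param nucleus_field_nm XY side length of the telomere placement
#'   region per nucleus, nm.
#' @param min_separation_nm minimum distance between telomere centers.
#' @param seed top-level random seed (expanded into per-nucleus
#'   sub-seeds, so any nucleus re-simulates identically).
#' @param out_dir optional output directory for the run artifacts.
#' @param write_molecules also write each nucleus' molecule list (off by
#'   default; the lists are large).
#' @return validated object of class `"experiment_config"`.
#' @export
experiment_config <- function(groups,
                              acquisition = acquisition_params(),
                              clustering = list(linkage_radius = 75,
                                                min_cluster_seed = 10),
                              filter = cluster_filter_policy(),
                              analysis = list(dims = "3d",
                                              reference_group = NULL),
                              drift_correction = list(enabled = FALSE,
                                                      frames_per_bin = 500,
                                                      pixel_size = 30),
                              nucleus_field_nm = 8000,
                              min_separation_nm = 800,
                              seed = 1L, out_dir = NULL,
                              write_molecules = FALSE) {
  raw <- list(groups = groups, acquisition = acquisition,
              clustering = clustering, filter = filter,
              analysis = analysis, drift_correction = drift_correction,
              nucleus_field_nm = nucleus_field_nm,
              min_separation_nm = min_separation_nm, seed = seed,
              out_dir = out_dir, write_molecules = write_molecules)
  validate_config(raw)
}

#' Validate a raw experiment configuration
#'
#' Schema-checks a raw (possibly file-parsed) configuration: unknown
#' keys, missing or duplicate groups, non-positive sizes and negative
#' noise parameters are all reported together as named violations.
#' Defaults are filled for omitted optional fields.
#'
#' @param raw a named list (e.g. from [yaml::read_yaml()]) or an
#'   `experiment_config`.
#' @return validated `experiment_config`, or an error listing every
#'   violation.
#' @export
validate_config <- function(raw) {
  if (inherits(raw, "experiment_config")) raw <- unclass(raw)
  errs <- character(0)
  note <- function(fmt, ...) errs <<- c(errs, sprintf(fmt, ...))
  known <- c("groups", "acquisition", "clustering", "filter", "analysis",
             "drift_correction", "nucleus_field_nm", "min_separation_nm",
             "seed", "out_dir", "write_molecules")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    note("unknown config key(s): %s", paste(unknown, collapse = ", "))
  groups <- raw$groups
  if (is.null(groups) || length(groups) == 0) {
    note("config must define at least one group")
    groups <- list()
  }
  g_known <- c("label", "n_nuclei", "telomeres_per_nucleus", "mean_rg_nm",
               "rg_cv", "shape", "aspect", "n_emitters")
  groups <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    bad <- setdiff(names(g), g_known)
    if (length(bad))
      note("group %d: unknown key(s) %s", i, paste(bad, collapse = ", "))
    if (is.null(g$label) || !nzchar(g$label)) note("group %d: missing label", i)
    if (is.null(g$n_nuclei) || !is_number(g$n_nuclei) || g$n_nuclei < 1)
      note("group %d: n_nuclei must be a positive count", i)
    tpn <- g$telomeres_per_nucleus
    if (is.null(tpn) || !length(tpn) %in% 1:2 || any(tpn < 1))
      note("group %d: telomeres_per_nucleus must be a count or c(min, max)", i)
    if (is.null(g$mean_rg_nm) || !is_number(g$mean_rg_nm) || g$mean_rg_nm <= 0)
      note("group %d: mean_rg_nm must be > 0", i)
    g$rg_cv <- g$rg_cv %||% 0.35
    if (!is_number(g$rg_cv) || g$rg_cv < 0)
      note("group %d: rg_cv must be >= 0", i)
    g$shape <- g$shape %||% "sphere"
    if (!g$shape %in% c("sphere", "ellipsoid"))
      note("group %d: shape must be 'sphere' or 'ellipsoid'", i)
    g$aspect <- g$aspect %||% c(1, 1, 1)
    if (length(g$aspect) != 3 || any(g$aspect <= 0))
      note("group %d: aspect must be 3 positive values", i)
    g$n_emitters <- g$n_emitters %||% 100
    if (!is_number(g$n_emitters) || g$n_emitters < 2)
      note("group %d: n_emitters must be >= 2", i)
    g
  })
  labels <- vapply(groups, function(g) g$label %||% "", "")
  if (anyDuplicated(labels[nzchar(labels)]))
    note("duplicate group label(s): %s",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  acq <- raw$acquisition
  if (!inherits(acq, "acquisition_params")) {
    acq <- tryCatch(do.call(acquisition_params, as.list(acq %||% list())),
                    error = function(e) {
                      note("acquisition: %s", conditionMessage(e))
                      acquisition_params()
                    })
  }
  cl <- raw$clustering %||% list()
  cl$linkage_radius <- cl$linkage_radius %||% 75
  cl$min_cluster_seed <- cl$min_cluster_seed %||% 10
  if (!is_number(cl$linkage_radius) || cl$linkage_radius <= 0)
    note("clustering: linkage_radius must be > 0")
  if (!is_number(cl$min_cluster_seed) || cl$min_cluster_seed < 1)
    note("clustering: min_cluster_seed must be >= 1")
  flt <- raw$filter
  if (!inherits(flt, "cluster_filter_policy")) {
    flt <- tryCatch(do.call(cluster_filter_policy, as.list(flt %||% list())),
                    error = function(e) {
                      note("filter: %s", conditionMessage(e))
                      cluster_filter_policy()
                    })
  }
  an <- raw$analysis %||% list()
  an$dims <- an$dims %||% "3d"
  if (!an$dims %in% c("3d", "2d")) note("analysis: dims must be '3d' or '2d'")
  an$reference_group <- an$reference_group %||%
    (if (length(labels) && nzchar(labels[1])) labels[1] else NULL)
  if (!is.null(an$reference_group) && length(labels) &&
      !an$reference_group %in% labels)
    note("analysis: reference_group '%s' is not a group label",
         an$reference_group)
  dc <- raw$drift_correction %||% list()
  dc$enabled <- isTRUE(dc$enabled)
  dc$frames_per_bin <- dc$frames_per_bin %||% 500
  dc$pixel_size <- dc$pixel_size %||% 30
  field <- raw$nucleus_field_nm %||% 8000
  minsep <- raw$min_separation_nm %||% 800
  if (!is_number(field) || field <= 0) note("nucleus_field_nm must be > 0")
  if (!is_number(minsep) || minsep < 0) note("min_separation_nm must be >= 0")
  seed <- raw$seed %||% 1L
  if (!is_number(seed)) note("seed must be a number")
  if (length(errs))
    stopf("invalid experiment config:\n  - %s", paste(errs, collapse = "\n  - "))
  structure(list(groups = groups, acquisition = acq, clustering = cl,
                 filter = flt, analysis = an, drift_correction = dc,
                 nucleus_field_nm = field, min_separation_nm = minsep,
                 seed = as.integer(seed), out_dir = raw$out_dir,
                 write_molecules = isTRUE(raw$write_molecules)),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' @param path YAML file with the [experiment_config()] schema.
#' @return validated `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$filter$reference_mask))
    stopf("reference masks cannot be specified in YAML; construct the config in R")
  validate_config(raw)
}

place_structures <- function(group, config) {
  k <- group$telomeres_per_nucleus
  K <- if (length(k) == 2) sample(seq(k[1], k[2]), 1) else as.integer(k)
  field <- config$nucleus_field_nm
  minsep <- config$min_separation_nm
  zhalf <- config$acquisition$z_depth / 2 * 0.9
  pos <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(K)) {
    for (try in 1:5000) {
      cand <- c(stats::runif(2, 0, field), stats::runif(1, -zhalf, zhalf))
      if (nrow(pos) == 0 ||
          min(colSums((t(pos[, 1:2, drop = FALSE]) - cand[1:2])^2)) >=
            minsep^2) {
        pos <- rbind(pos, cand)
        break
      }
      if (try == 5000)
        stopf("could not place %d separated telomeres in a %g nm field",
              K, field)
    }
  }
  acq <- config$acquisition
  noise2 <- 2 * acq$sigma_xy^2 + acq$sigma_z^2
  rg2 <- group$mean_rg_nm^2 - noise2
  if (rg2 <= 0)
    stopf("group '%s': mean_rg_nm is below the noise floor (%.1f nm)",
          group$label, sqrt(noise2))
  aspect <- if (group$shape == "sphere") c(1, 1, 1) else group$aspect
  base_scale <- sqrt(5 * rg2 / sum(aspect^2))
  sdlog <- sqrt(log(1 + group$rg_cv^2))
  size <- base_scale * stats::rlnorm(K, meanlog = -sdlog^2, sdlog = sdlog)
  lapply(seq_len(K), function(i) {
    structure_model(shape = group$shape, center = pos[i, ],
                    axes = size[i] * aspect,
                    n_emitters = group$n_emitters, structure_id = i)
  })
}

#' Run a complete simulated shape experiment
#'
#' Executes the full pipeline for every group and nucleus of the
#' configuration: simulate localizations, optionally drift-correct,
#' cluster, filter, compute per-telomere Rg; then assembles the group
#' shape table, distribution summaries, reference-cutoff irregular
#' fractions and (with two or more groups) the ANOVA + Tukey
#' comparison. The run is deterministic given `config$seed`.
#'
#' @param config a validated [experiment_config()].
#' @return A list of class `"shape_experiment"`: `config`, `seed`,
#'   `counts` (per-nucleus stage record counts), `shape_table`,
#'   `summary`, `fractions` (with the recomputed cutoff as attribute),
#'   `correlation` (Rg vs N per group), `comparisons`
#'   (`comparison_result` or `NULL`), `version`. When `config$out_dir`
#'   is set, the tables, the comparison CSV and a YAML report are also
#'   written there.
#' @export
run_shape_experiment <- function(config) {
  if (!inherits(config, "experiment_config")) config <- validate_config(config)
  counts <- list()
  records <- list()
  for (gi in seq_along(config$groups)) {
    group <- config$groups[[gi]]
    for (nu in seq_len(group$n_nuclei)) {
      res <- with_seed(sub_seed(config$seed, gi * 100003 + nu), {
        structures <- place_structures(group, config)
        tab <- simulate_localizations(structures, config$acquisition)
        if (config$drift_correction$enabled) {
          dc <- correct_drift(tab, config$drift_correction$frames_per_bin,
                              config$drift_correction$pixel_size)
          tab <- dc$table
        }
        clusters <- cluster_localizations(tab,
                                          config$clustering$linkage_radius,
                                          config$clustering$min_cluster_seed)
        kept <- filter_clusters(clusters, config$filter, focal_plane_z = 0)
        list(n_locs = nrow(tab), n_clusters = length(clusters),
             n_kept = length(kept), kept = kept)
      })
      counts[[length(counts) + 1L]] <- data.frame(
        group = group$label, nucleus = nu, localizations = res$n_locs,
        clusters_found = res$n_clusters, clusters_kept = res$n_kept)
      if (res$n_kept > 0) {
        records[[length(records) + 1L]] <- data.frame(
          group = group$label, nucleus = nu,
          telomere = seq_along(res$kept),
          rg_nm = vapply(res$kept, radius_of_gyration, 0,
                         dims = config$analysis$dims),
          n_locs = vapply(res$kept, `[[`, 0L, "N"))
      }
    }
  }
  counts <- do.call(rbind, counts)
  if (length(records) == 0)
    stopf("no telomere clusters survived filtering in any nucleus")
  table <- as_shape_table(do.call(rbind, records))
  summary <- summarize_shape_distribution(table)
  ref <- config$analysis$reference_group
  fractions <- fraction_irregular(table, ref)
  correlation <- rg_count_correlation(table)
  comparisons <- NULL
  grp_sizes <- table(table$group)
  if (length(grp_sizes) >= 2 && all(grp_sizes >= 2)) {
    comparisons <- anova_tukey(group_samples(
      split(table$rg_nm, table$group), unit = "per-telomere Rg (nm)"))
  }
  report <- structure(
    list(config = config, seed = config$seed, counts = counts,
         shape_table = table, summary = summary, fractions = fractions,
         correlation = correlation, comparisons = comparisons,
         version = as.character(utils::packageVersion("telostorm"))),
    class = "shape_experiment")
  if (!is.null(config$out_dir)) write_experiment(report, config$out_dir)
  report
}

write_experiment <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_shape_table(report$shape_table, file.path(dir, "shape_table.csv"))
  utils::write.csv(report$summary$group,
                   file.path(dir, "summary_group.csv"), row.names = FALSE)
  utils::write.csv(report$summary$nucleus,
                   file.path(dir, "summary_nucleus.csv"), row.names = FALSE)
  fr <- report$fractions
  fr$cutoff_nm <- attr(report$fractions, "cutoff_nm")
  utils::write.csv(fr, file.path(dir, "fractions.csv"), row.names = FALSE)
  utils::write.csv(report$counts, file.path(dir, "stage_counts.csv"),
                   row.names = FALSE)
  if (!is.null(report$comparisons))
    write_comparisons(report$comparisons, file.path(dir, "comparisons.csv"))
  cfg <- unclass(report$config)
  cfg$acquisition <- unclass(cfg$acquisition)
  cfg$acquisition$drift <- if (is.null(cfg$acquisition$drift)) NULL else
    "<function>"
  cfg$filter <- unclass(cfg$filter)
  cfg$filter$reference_mask <- if (is.null(cfg$filter$reference_mask)) NULL
    else "<matrix>"
  yaml::write_yaml(list(seed = report$seed, version = report$version,
                        config = cfg),
                   file.path(dir, "report.yaml"))
  invisible(dir)
}

#' @export
print.shape_experiment <- function(x, ...) {
  cat(sprintf("Shape experiment (seed %d, telostorm %s)\n",
              x$seed, x$version))
  cat(sprintf("  %d group(s), %d nuclei, %d telomeres after filtering\n",
              length(unique(x$shape_table$group)),
              nrow(unique(x$shape_table[c("group", "nucleus")])),
              nrow(x$shape_table)))
  cat(sprintf("  localizations simulated: %d; clusters found: %d; kept: %d\n",
              sum(x$counts$localizations), sum(x$counts$clusters_found),
              sum(x$counts$clusters_kept)))
  cat(sprintf("  reference cutoff: %.1f nm\n",
              attr(x$fractions, "cutoff_nm")))
  print(format(merge(x$summary$group[, c("group", "n_telomeres",
                                         "mean_rg_nm", "median_rg_nm")],
                     x$fractions[, c("group", "fraction")], by = "group"),
               digits = 3), row.names = FALSE)
  if (!is.null(x$comparisons)) {
    cat("  Tukey-adjusted pairwise p-values:\n")
    print(format(x$comparisons$comparisons[, c("comparison", "estimate",
                                               "p_adj")],
                 digits = 3), row.names = FALSE)
  }
  invisible(x)
}
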