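#' Specify a synthetic ChIP dot blot
#'
#' Ground truth for a dot-blot grid: per (group, antibody) the true
#' signal level relative to that group's input spot, a multiplicative
#' lognormal noise level, and a replicate structure (triplicates by
#' default, matching standard ChIP practice). The `"input"` antibody is
#' the loading reference (e.g. 10% of total chromatin) and must be
#' present; an IgG row models the immunoprecipitation background.
#'
#' @param true_ratio numeric matrix of ground-truth IP/input signal
#'   ratios (>= 0), rows = groups, columns = antibodies; one column must
#'   be named `"input"` (typically all 1).
#' @param input_level absolute intensity of the input spots.
#' @param input_fraction fraction of chromatin loaded as input (e.g.
#'   0.1 for 10% input); recorded as metadata.
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   spot noise (0 = noise-free).
#' @param n_replicates independent replicates.
#' @param seed random seed.
#' @return object of class `"dot_blot_spec"`.
#' @export
dot_blot_spec <- function(true_ratio, input_level = 1000,
                          input_fraction = 0.1, noise_cv = 0.1,
                          n_replicates = 3, seed = NULL) {
  if (!is.matrix(true_ratio) || is.null(rownames(true_ratio)) ||
      is.null(colnames(true_ratio)))
    stopf("`true_ratio` must be a matrix with group rownames and antibody colnames")
  if (any(true_ratio < 0) || any(!is.finite(true_ratio)))
    stopf("`true_ratio` entries must be finite and >= 0")
  if (!"input" %in% colnames(true_ratio))
    stopf("`true_ratio` must contain an 'input' antibody column")
  check_number(input_level, "input_level", lower = 0, strict_lower = TRUE)
  check_number(input_fraction, "input_fraction", lower = 0,
               strict_lower = TRUE)
  check_number(noise_cv, "noise_cv", lower = 0)
  check_number(n_replicates, "n_replicates", lower = 1)
  structure(list(true_ratio = true_ratio, input_level = input_level,
                 input_fraction = input_fraction, noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "dot_blot_spec")
}

#' Simulate a dot-blot intensity grid
#'
#' Spot intensity = input level x true ratio x multiplicative lognormal
#' noise with the specified CV, independently per replicate.
#'
#' @param spec a [dot_blot_spec()].
#' @return data.frame of class `"dot_blot_grid"` with columns
#'   `group,antibody,replicate,intensity` and attribute
#'   `input_fraction`.
#' @export
simulate_dot_blot <- function(spec) {
  if (!inherits(spec, "dot_blot_spec")) stopf("`spec` must be a dot_blot_spec")
  groups <- rownames(spec$true_ratio)
  abs_ <- colnames(spec$true_ratio)
  grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                      antibody = abs_, group = groups,
                      stringsAsFactors = FALSE)[, 3:1]
  mu <- spec$input_level * spec$true_ratio[cbind(grid$group, grid$antibody)]
  with_seed(spec$seed, {
    if (spec$noise_cv > 0) {
      sdlog <- sqrt(log(1 + spec$noise_cv^2))
      mu <- mu * stats::rlnorm(nrow(grid), meanlog = -sdlog^2 / 2,
                               sdlog = sdlog)
    }
    grid$intensity <- mu
    structure(grid, input_fraction = spec$input_fraction,
              class = c("dot_blot_grid", "data.frame"))
  })
}

#' Normalize a ChIP dot-blot grid
#'
#' Implements the standard ChIP dot-blot arithmetic: per replicate, each
#' IP spot is normalized to its group's input spot
#' (`ratio_to_input = IP / input`); replicate ratios are averaged with
#' an s.e.m. Optionally a mark-per-histone ratio is formed per replicate
#' (e.g. H3K9me3 per H3) before averaging. Fold changes are reported
#' against a designated control -- with several control groups, the
#' pooled control is the mean of the control-group means.
#'
#' @param grid a `dot_blot_grid` (or data.frame with
#'   `group,antibody,replicate,intensity`); every group needs an
#'   `"input"` spot with nonzero intensity in each replicate.
#' @param control_groups character vector of control group labels (or
#'   `NULL` for no fold changes).
#' @param per_ratio optional `c(numerator, denominator)` antibody pair,
#'   e.g. `c("H3K9me3", "H3")`, for the per-histone normalization.
#' @return list of class `"dot_blot_norm"`:
#' \describe{
#'   \item{ratios}{per (group, antibody) mean `ratio_to_input` with
#'     s.e.m. and replicate count.}
#'   \item{folds}{per (group, antibody) fold change vs the pooled
#'     control (`NULL` when `control_groups` is `NULL`).}
#'   \item{per_ratio}{per-group mean of the replicate-wise
#'     numerator/denominator ratio with s.e.m. and fold vs control
#'     (`NULL` unless requested).}
#' }
#' @export
normalize_dot_blot <- function(grid, control_groups = NULL,
                               per_ratio = NULL) {
  need <- c("group", "antibody", "replicate", "intensity")
  if (!all(need %in% names(grid)))
    stopf("grid needs columns %s", paste(need, collapse = ", "))
  inp <- grid[grid$antibody == "input", ]
  if (nrow(inp) == 0) stopf("grid has no 'input' antibody spots")
  if (any(inp$intensity <= 0)) stopf("zero input intensity")
  ikey <- paste(inp$group, inp$replicate)
  ival <- stats::setNames(inp$intensity, ikey)
  ip <- grid[grid$antibody != "input", ]
  key <- paste(ip$group, ip$replicate)
  if (!all(key %in% ikey))
    stopf("every (group, replicate) needs an input spot")
  ip$ratio <- ip$intensity / ival[key]
  agg <- function(df, value) {
    out <- do.call(rbind, lapply(split(df, df[c("group", "antibody")],
                                       drop = TRUE), function(d)
      data.frame(group = d$group[1], antibody = d$antibody[1],
                 n = nrow(d), mean_ratio = mean(d[[value]]),
                 sem = sem(d[[value]]))))
    rownames(out) <- NULL
    out
  }
  ratios <- agg(ip, "ratio")
  folds <- NULL
  if (!is.null(control_groups)) {
    if (!all(control_groups %in% grid$group))
      stopf("unknown control group(s): %s",
            paste(setdiff(control_groups, grid$group), collapse = ", "))
    folds <- do.call(rbind, lapply(split(ratios, ratios$antibody),
                                   function(d) {
      ctrl <- mean(d$mean_ratio[d$group %in% control_groups])
      d$fold_vs_control <- d$mean_ratio / ctrl
      d
    }))
    rownames(folds) <- NULL
  }
  pr <- NULL
  if (!is.null(per_ratio)) {
    if (length(per_ratio) != 2)
      stopf("`per_ratio` must name a numerator and a denominator antibody")
    if (!all(per_ratio %in% ip$antibody))
      stopf("antibody '%s' missing from the grid",
            setdiff(per_ratio, ip$antibody)[1])
    num <- ip[ip$antibody == per_ratio[1], ]
    den <- ip[ip$antibody == per_ratio[2], ]
    dkey <- stats::setNames(den$ratio, paste(den$group, den$replicate))
    num$pr <- num$ratio / dkey[paste(num$group, num$replicate)]
    pr <- do.call(rbind, lapply(split(num, num$group), function(d)
      data.frame(group = d$group[1],
                 antibody = paste(per_ratio, collapse = "/"),
                 n = nrow(d), mean_ratio = mean(d$pr), sem = sem(d$pr))))
    rownames(pr) <- NULL
    if (!is.null(control_groups)) {
      ctrl <- mean(pr$mean_ratio[pr$group %in% control_groups])
      pr$fold_vs_control <- pr$mean_ratio / ctrl
    }
  }
  structure(list(ratios = ratios, folds = folds, per_ratio = pr),
            class = "dot_blot_norm")
}

#' @export
print.dot_blot_norm <- function(x, digits = 3, ...) {
  cat("Dot-blot ratios to input:\n")
  print(format(x$ratios, digits = digits), row.names = FALSE)
  if (!is.null(x$folds)) {
    cat("Fold changes vs pooled control:\n")
    print(format(x$folds, digits = digits), row.names = FALSE)
  }
  if (!is.null(x$per_ratio)) {
    cat("Per-denominator ratios:\n")
    print(format(x$per_ratio, digits = digits), row.names = FALSE)
  }
  invisible(x)
}
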