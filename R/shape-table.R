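#' Group shape table of per-telomere radii of gyration
#'
#' The tidy record feeding all group-level shape statistics: one row per
#' telomere with its group label, nucleus index, telomere index within
#' the nucleus, observed Rg (nm) and localization count.
#'
#' @param group character/factor group labels.
#' @param nucleus nucleus index per record.
#' @param telomere telomere index within its nucleus.
#' @param rg_nm radius of gyration, nm (>= 0).
#' @param n_locs localization count per telomere.
#' @return data.frame of class `"group_shape_table"`.
#' @export
group_shape_table <- function(group, nucleus, telomere, rg_nm, n_locs = NA) {
  n <- length(rg_nm)
  recycle <- function(x) if (length(x) == 1L) rep(x, n) else x
  group <- recycle(group); nucleus <- recycle(nucleus)
  telomere <- recycle(telomere)
  if (!all(lengths(list(group, nucleus, telomere)) == n))
    stopf("all columns must have equal length")
  if (n > 0 && (!all(is.finite(rg_nm)) || any(rg_nm < 0)))
    stopf("`rg_nm` must be finite and >= 0")
  df <- data.frame(group = as.character(group), nucleus = nucleus,
                   telomere = telomere, rg_nm = as.numeric(rg_nm),
                   n_locs = n_locs)
  key <- paste(df$group, df$nucleus, df$telomere)
  if (anyDuplicated(key))
    stopf("(nucleus, telomere) indices must be unique within each group")
  class(df) <- c("group_shape_table", "data.frame")
  df
}

as_shape_table <- function(df) {
  group_shape_table(df$group, df$nucleus, df$telomere, df$rg_nm, df$n_locs)
}

#' Fraction of irregular telomeres above a reference-mean cutoff
#'
#' The cutoff is the arithmetic mean Rg of the reference group,
#' recomputed from the data at hand (the often-quoted 84 nm is one
#' study's realized value, not a constant). For every group, the
#' fraction of telomeres with Rg equal to or greater than the cutoff is
#' reported -- a telomere exactly at the cutoff counts as irregular.
#'
#' @param table a [group_shape_table()].
#' @param reference_group label of the reference group (present and
#'   non-empty).
#' @return data.frame with `group`, `n`, `n_irregular`, `fraction`
#'   (NA for an empty group), plus attribute `cutoff_nm`.
#' @export
fraction_irregular <- function(table, reference_group) {
  if (!reference_group %in% table$group)
    stopf("reference group '%s' has no records", reference_group)
  cutoff <- mean(table$rg_nm[table$group == reference_group])
  groups <- unique(table$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    rg <- table$rg_nm[table$group == g]
    data.frame(group = g, n = length(rg),
               n_irregular = sum(rg >= cutoff),
               fraction = if (length(rg)) sum(rg >= cutoff) / length(rg)
                          else NA_real_)
  }))
  attr(out, "cutoff_nm") <- cutoff
  out
}

#' Per-group and per-nucleus summaries of the Rg distribution
#'
#' Mirrors the usual violin-plot annotation: per group the mean (over
#' telomeres, not a nucleus-mean-of-means), median, interquartile range,
#' s.e.m. and 95% confidence interval of the mean; plus a per-(group,
#' nucleus) breakdown for assessing inter-nucleus heterogeneity.
#'
#' @param table a [group_shape_table()] with every group non-empty.
#' @return list of class `"shape_summary"` with elements `group` and
#'   `nucleus` (data.frames).
#' @export
summarize_shape_distribution <- function(table) {
  per_group <- function(df, label) {
    rg <- df$rg_nm
    n <- length(rg)
    s <- if (n > 1) sem(rg) else NA_real_
    half <- if (n > 1) stats::qt(0.975, n - 1) * s else NA_real_
    data.frame(group = label, n_telomeres = n,
               n_nuclei = length(unique(df$nucleus)),
               mean_rg_nm = mean(rg), median_rg_nm = stats::median(rg),
               q25_nm = unname(stats::quantile(rg, 0.25)),
               q75_nm = unname(stats::quantile(rg, 0.75)),
               sem_nm = s,
               ci95_lo_nm = mean(rg) - half, ci95_hi_nm = mean(rg) + half)
  }
  groups <- unique(table$group)
  g <- do.call(rbind, lapply(groups, function(gl)
    per_group(table[table$group == gl, ], gl)))
  nuc <- do.call(rbind, lapply(groups, function(gl) {
    df <- table[table$group == gl, ]
    do.call(rbind, lapply(unique(df$nucleus), function(nu) {
      rg <- df$rg_nm[df$nucleus == nu]
      data.frame(group = gl, nucleus = nu, n_telomeres = length(rg),
                 mean_rg_nm = mean(rg), median_rg_nm = stats::median(rg))
    }))
  }))
  structure(list(group = g, nucleus = nuc), class = "shape_summary")
}

#' @export
print.shape_summary <- function(x, digits = 3, ...) {
  cat("Per-group Rg summary:\n")
  print(format(x$group, digits = digits), row.names = FALSE)
  cat(sprintf("(%d nuclei in the per-nucleus breakdown)\n",
              nrow(x$nucleus)))
  invisible(x)
}

#' Per-group Pearson correlation of Rg with localization count
#'
#' A quality control: telomere Rg should be a property of the structure,
#' not of how many localizations were collected, so only weak
#' correlations with N are expected.
#'
#' @param table a [group_shape_table()] with an `n_locs` column.
#' @return data.frame with `group`, `n`, `r` (NA when a group has fewer
#'   than 3 records or zero variance in either variable).
#' @export
rg_count_correlation <- function(table) {
  groups <- unique(table$group)
  do.call(rbind, lapply(groups, function(g) {
    df <- table[table$group == g, ]
    r <- if (nrow(df) >= 3 && stats::sd(df$rg_nm) > 0 &&
             stats::sd(df$n_locs) > 0)
      stats::cor(df$rg_nm, df$n_locs) else NA_real_
    data.frame(group = g, n = nrow(df), r = r)
  }))
}

#' Read / write a group shape table as CSV
#'
#' Columns `group,nucleus,telomere,rg_nm,n_locs`.
#' @param table a [group_shape_table()].
#' @param path file path.
#' @return the table (read) or `path` invisibly (write).
#' @export
write_shape_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_shape_table
#' @export
read_shape_table <- function(path) {
  as_shape_table(utils::read.csv(path))
}

#' Plot per-nucleus Rg records
#'
#' One panel per group: each dot is one telomere, grouped by nucleus
#' index on the x axis, with the per-nucleus mean marked -- the display
#' used to check that group differences are not driven by a few outlier
#' nuclei.
#'
#' @param x a [group_shape_table()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.group_shape_table <- function(x, ...) {
  groups <- unique(x$group)
  old <- graphics::par(mfrow = c(1, length(groups)))
  on.exit(graphics::par(old))
  ylim <- range(x$rg_nm)
  for (g in groups) {
    df <- x[x$group == g, ]
    nuc <- as.integer(factor(df$nucleus))
    graphics::plot(jitter(nuc, 0.3), df$rg_nm, pch = 16, cex = 0.5,
                   col = grDevices::hcl.colors(max(nuc), "Dark 3")[nuc],
                   xlab = "nucleus index", ylab = "Rg (nm)", main = g,
                   ylim = ylim, ...)
    mu <- tapply(df$rg_nm, nuc, mean)
    graphics::points(as.integer(names(mu)), mu, pch = 3, cex = 1.2)
  }
  invisible(x)
}
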