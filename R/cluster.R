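#' Identify telomere clusters by density-based clustering
#'
#' Groups localizations into telomere clusters with a 3D DBSCAN: points
#' with at least `min_cluster_seed` neighbours (the point itself
#' included) within `linkage_radius` are core points; clusters are the
#' connected sets of core points plus their border neighbours, and all
#' remaining localizations are labeled background. Telomere foci are
#' well separated relative to their ~80 nm radius of gyration, so the
#' defaults (75 nm linkage radius, 10-point seed) isolate individual
#' telomeres while rejecting sparse background. Neighbour search uses a
#' spatial grid hash, so runtime is linear in the localization count for
#' well-separated clusters.
#'
#' @param table a [loc_table()] (may be empty).
#' @param linkage_radius neighbour radius in nm (> 0).
#' @param min_cluster_seed minimum neighbours (including self) for a
#'   core point.
#' @return A list of class `"telomere_cluster_set"` whose elements are
#'   [telomere_cluster()] objects, with attribute `assignment`: the
#'   integer cluster label per input row (0 = background).
#' @export
cluster_localizations <- function(table, linkage_radius = 75,
                                  min_cluster_seed = 10) {
  check_number(linkage_radius, "linkage_radius", lower = 0,
               strict_lower = TRUE)
  check_number(min_cluster_seed, "min_cluster_seed", lower = 1)
  n <- nrow(table)
  if (n == 0) {
    return(structure(list(), assignment = integer(0),
                     class = "telomere_cluster_set"))
  }
  X <- loc_coords(table)
  nbrs <- grid_neighbours(X, linkage_radius)
  core <- lengths(nbrs) >= min_cluster_seed
  labels <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cid <- cid + 1L
    labels[i] <- cid
    frontier <- i
    while (length(frontier) > 0) {
      reach <- unique(unlist(nbrs[frontier], use.names = FALSE))
      reach <- reach[labels[reach] == 0L]
      labels[reach] <- cid
      frontier <- reach[core[reach]]
    }
  }
  df <- as.data.frame(table)
  clusters <- lapply(seq_len(cid), function(k) {
    telomere_cluster(df[labels == k, , drop = FALSE], telomere_id = k)
  })
  structure(clusters, assignment = labels, class = "telomere_cluster_set")
}

# neighbour lists within radius r via a uniform grid (cell edge = r)
grid_neighbours <- function(X, r) {
  n <- nrow(X)
  cell <- floor(X / r)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  cell_map <- split(seq_len(n), key)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  r2 <- r * r
  nbrs <- vector("list", n)
  for (pts in cell_map) {
    c0 <- cell[pts[1], ]
    keys <- paste(c0[1] + offs[, 1], c0[2] + offs[, 2], c0[3] + offs[, 3],
                  sep = ",")
    cand <- unlist(cell_map[keys], use.names = FALSE)
    A <- X[pts, , drop = FALSE]
    B <- X[cand, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    for (j in seq_along(pts)) nbrs[[pts[j]]] <- cand[d2[j, ] <= r2]
  }
  nbrs
}

#' Construct a telomere cluster
#'
#' One telomere's localization subset together with its point count N,
#' center of mass (arithmetic mean position) and radius of gyration.
#'
#' @param locs data.frame of member localizations with columns
#'   `x_nm,y_nm,z_nm` (at least one row).
#' @param telomere_id,nucleus_id identifiers.
#' @return An object of class `"telomere_cluster"` with fields `locs`,
#'   `N`, `com` (3-vector, nm), `rg` (nm), `nucleus_id`, `telomere_id`.
#' @export
telomere_cluster <- function(locs, telomere_id = 1L, nucleus_id = 1L) {
  if (nrow(locs) < 1) stopf("a telomere cluster needs at least one point")
  X <- as.matrix(locs[, c("x_nm", "y_nm", "z_nm"), drop = FALSE])
  com <- colMeans(X)
  rg <- sqrt(mean(rowSums(sweep(X, 2, com)^2)))
  structure(list(locs = locs, N = nrow(locs), com = com, rg = rg,
                 nucleus_id = nucleus_id, telomere_id = telomere_id),
            class = "telomere_cluster")
}

#' @export
print.telomere_cluster <- function(x, ...) {
  cat(sprintf("Telomere cluster %s: N = %d, Rg = %.1f nm, com = (%.0f, %.0f, %.0f) nm\n",
              format(x$telomere_id), x$N, x$rg,
              x$com[1], x$com[2], x$com[3]))
  invisible(x)
}

#' @export
print.telomere_cluster_set <- function(x, ...) {
  cat(sprintf("%d telomere cluster(s); %d background localization(s)\n",
              length(x), sum(attr(x, "assignment") == 0L)))
  invisible(x)
}
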