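#' Radius of gyration of a localization cluster
#'
#' The root-mean-square distance of a cluster's localization points from
#' their center of mass,
#' \deqn{R_g^2 = \frac{1}{N}\sum_{k=1}^{N} \left| \vec r_k - \vec r_{com} \right|^2,}
#' the scalar measure of telomere spatial extent. Computed in 3D by
#' default; a 2D (XY-projected) mode is available since some SMLM
#' datasets are analyzed on projected coordinates. Rg is invariant under
#' rigid rotation/translation and scales linearly with the coordinates.
#'
#' @param x a [telomere_cluster()], a [loc_table()], or a numeric matrix
#'   of coordinates (columns x, y\[, z\]).
#' @param dims `"3d"` (default) or `"2d"` for the XY projection.
#' @return Rg in the coordinate units (nm); error when the cluster is
#'   empty.
#' @export
radius_of_gyration <- function(x, dims = c("3d", "2d")) {
  dims <- match.arg(dims)
  X <- shape_coords(x, dims)
  if (nrow(X) == 0) stopf("cannot compute Rg of an empty cluster")
  com <- colMeans(X)
  sqrt(mean(rowSums(sweep(X, 2, com)^2)))
}

shape_coords <- function(x, dims = "3d") {
  if (inherits(x, "telomere_cluster")) x <- x$locs
  if (is.data.frame(x)) {
    if (all(c("x_nm", "y_nm") %in% names(x))) {
      cols <- if (dims == "2d") c("x_nm", "y_nm") else c("x_nm", "y_nm", "z_nm")
      return(as.matrix(as.data.frame(x)[, cols, drop = FALSE]))
    }
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x))
    stopf("expected a telomere_cluster, loc_table, or coordinate matrix")
  if (dims == "2d" && ncol(x) >= 2) x <- x[, 1:2, drop = FALSE]
  x
}

#' Principal-axis spreads (anisotropy) of a cluster
#'
#' Quantifies how far a telomere departs from a globular shape: the
#' square roots of the eigenvalues of the localization-position
#' covariance (population normalization), in descending order. Their
#' squares sum to Rg^2 (trace identity), so a uniform ball gives three
#' nearly equal values while an irregular telomere that is spread out in
#' two dimensions but compact (dense) in one gives a small third value.
#'
#' @param x as in [radius_of_gyration()]; needs N >= 3.
#' @return numeric length-3 vector (nm), descending. Clusters with fewer
#'   than 3 points or (near-)collinear geometry carry attribute
#'   `degenerate = TRUE`.
#' @export
cluster_anisotropy <- function(x) {
  X <- shape_coords(x, "3d")
  n <- nrow(X)
  if (n < 3) {
    out <- rep(NA_real_, 3)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  C <- stats::cov(X) * (n - 1) / n
  ev <- sort(pmax(0, eigen(C, symmetric = TRUE, only.values = TRUE)$values),
             decreasing = TRUE)
  out <- sqrt(ev)
  if (out[1] > 0 && out[2] / out[1] < 1e-8)
    attr(out, "degenerate") <- TRUE
  out
}

#' Filtering policy for telomere clusters
#'
#' Encodes the quality-control rules applied before shape analysis:
#' keep clusters consisting of strictly more than `min_points`
#' localizations, with center of mass within `focal_window` of the focal
#' plane, and (optionally) with XY center of mass inside a reference
#' mask derived from the conventional-image overlay, which excludes
#' nontelomeric background.
#'
#' @param min_points count threshold; the retention rule is strict
#'   (`N > min_points`), so the default 200 keeps clusters of 201+.
#' @param focal_window allowed |z_com - focal plane|, nm (> 0).
#' @param reference_mask optional logical/0-1 matrix (rows = y).
#' @param mask_pixel_size pixel size of `reference_mask`, nm.
#' @param mask_origin nm coordinates of the centre of mask pixel \[1,1\].
#' @return An object of class `"cluster_filter_policy"`.
#' @export
cluster_filter_policy <- function(min_points = 200, focal_window = 250,
                                  reference_mask = NULL,
                                  mask_pixel_size = NULL,
                                  mask_origin = c(0, 0)) {
  check_number(min_points, "min_points", lower = 0)
  check_number(focal_window, "focal_window", lower = 0, strict_lower = TRUE)
  if (!is.null(reference_mask)) {
    if (!is.matrix(reference_mask))
      stopf("`reference_mask` must be a matrix")
    if (is.null(mask_pixel_size))
      stopf("`mask_pixel_size` is required with a reference mask")
    check_number(mask_pixel_size, "mask_pixel_size", lower = 0,
                 strict_lower = TRUE)
  }
  structure(list(min_points = min_points, focal_window = focal_window,
                 reference_mask = reference_mask,
                 mask_pixel_size = mask_pixel_size,
                 mask_origin = mask_origin),
            class = "cluster_filter_policy")
}

#' Apply the cluster filtering policy
#'
#' Retains clusters with `N` strictly greater than `policy$min_points`
#' (a cluster of exactly `min_points` localizations is excluded), center
#' of mass within `focal_window` of `focal_plane_z`, and, when a
#' reference mask is supplied, XY center of mass inside the mask. Input
#' order is preserved; an empty result is not an error.
#'
#' @param clusters a list of [telomere_cluster()] objects (or a
#'   `telomere_cluster_set`).
#' @param policy a [cluster_filter_policy()].
#' @param focal_plane_z focal plane position, nm (default 0, the centre
#'   of the z-depth window).
#' @return the retained clusters, as a plain list.
#' @export
filter_clusters <- function(clusters, policy = cluster_filter_policy(),
                            focal_plane_z = 0) {
  if (!inherits(policy, "cluster_filter_policy"))
    stopf("`policy` must be a cluster_filter_policy")
  keep <- vapply(clusters, function(cl) {
    if (cl$N <= policy$min_points) return(FALSE)
    if (abs(cl$com[3] - focal_plane_z) > policy$focal_window) return(FALSE)
    if (!is.null(policy$reference_mask)) {
      px <- policy$mask_pixel_size
      col <- floor((cl$com[1] - policy$mask_origin[1]) / px + 0.5) + 1L
      row <- floor((cl$com[2] - policy$mask_origin[2]) / px + 0.5) + 1L
      m <- policy$reference_mask
      if (row < 1 || row > nrow(m) || col < 1 || col > ncol(m)) return(FALSE)
      if (!(m[row, col] > 0)) return(FALSE)
    }
    TRUE
  }, TRUE)
  unclass(clusters)[keep]
}
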