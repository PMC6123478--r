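#' Construct a localization table (molecule list)
#'
#' The molecule list is the entry point of the STORM pipeline: one row per
#' fitted single-molecule localization, with 3D coordinates in nanometres,
#' the camera frame of appearance, and the fitted photon count.
#'
#' @param x_nm,y_nm,z_nm numeric coordinates in nm (finite).
#' @param frame 0-based integer acquisition frame per localization.
#' @param photons photon count per localization (> 0), or `NULL`.
#' @param truth_cluster optional integer ground-truth cluster label per
#'   localization (0 = background), carried by the simulator.
#' @param n_frames total frames in the acquisition; must be at least
#'   `max(frame) + 1`. Defaults to `max(frame) + 1`.
#' @param z_depth imaged z-depth range in nm (metadata).
#' @return A `data.frame` of class `"loc_table"` with columns
#'   `x_nm,y_nm,z_nm,frame,photons[,truth_cluster]` and attributes
#'   `n_frames` and `z_depth`.
#' @export
loc_table <- function(x_nm, y_nm, z_nm, frame, photons = NULL,
                      truth_cluster = NULL, n_frames = NULL,
                      z_depth = NULL) {
  n <- length(x_nm)
  if (length(y_nm) != n || length(z_nm) != n || length(frame) != n)
    stopf("coordinate and frame vectors must have equal length")
  if (n > 0 && !all(is.finite(x_nm) & is.finite(y_nm) & is.finite(z_nm)))
    stopf("localization coordinates must be finite")
  frame <- as.integer(frame)
  if (n > 0 && (anyNA(frame) || any(frame < 0L)))
    stopf("frame indices must be non-negative integers")
  if (is.null(photons)) photons <- rep(NA_real_, n)
  if (n > 0 && any(!is.na(photons) & photons <= 0))
    stopf("photon counts must be > 0 when provided")
  df <- data.frame(x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm),
                   z_nm = as.numeric(z_nm), frame = frame,
                   photons = as.numeric(photons))
  if (!is.null(truth_cluster)) {
    if (length(truth_cluster) != n)
      stopf("`truth_cluster` must match the number of localizations")
    df$truth_cluster <- as.integer(truth_cluster)
  }
  max_frame <- if (n > 0) max(frame) else -1L
  n_frames <- n_frames %||% (max_frame + 1L)
  if (n_frames < max_frame + 1L)
    stopf("`n_frames` (%d) must be >= max(frame) + 1 (%d)",
          n_frames, max_frame + 1L)
  structure(df, n_frames = as.integer(n_frames), z_depth = z_depth,
            class = c("loc_table", "data.frame"))
}

loc_coords <- function(table, dims = c("3d", "2d")) {
  dims <- match.arg(dims)
  cols <- if (dims == "2d") c("x_nm", "y_nm") else c("x_nm", "y_nm", "z_nm")
  as.matrix(as.data.frame(table)[, cols, drop = FALSE])
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("Localization table: %d localizations over %d frames\n",
              nrow(x), attr(x, "n_frames")))
  if (nrow(x) > 0) {
    cat(sprintf("  x: [%.0f, %.0f] nm  y: [%.0f, %.0f] nm  z: [%.0f, %.0f] nm\n",
                min(x$x_nm), max(x$x_nm), min(x$y_nm), max(x$y_nm),
                min(x$z_nm), max(x$z_nm)))
  }
  if (!is.null(attr(x, "z_depth")))
    cat(sprintf("  z-depth window: %.0f nm\n", attr(x, "z_depth")))
  if (!is.null(x$truth_cluster))
    cat(sprintf("  ground-truth clusters: %d (+%d background)\n",
                length(setdiff(unique(x$truth_cluster), 0L)),
                sum(x$truth_cluster == 0L)))
  invisible(x)
}

#' Read / write a molecule list
#'
#' The on-disk dialect is a delimited text file with header columns
#' `x_nm,y_nm,z_nm,frame,photons[,truth_cluster]`; coordinates in nm and
#' 0-based integer frames. Files ending in `.csv` are comma separated,
#' anything else is tab separated.
#'
#' @param path file path.
#' @param n_frames,z_depth optional acquisition metadata for
#'   [loc_table()]; `n_frames` defaults to `max(frame) + 1`.
#' @return `read_molecule_list()` returns a [loc_table()];
#'   `write_molecule_list()` returns `path` invisibly.
#' @export
read_molecule_list <- function(path, n_frames = NULL, z_depth = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("x_nm", "y_nm", "z_nm", "frame")
  if (!all(need %in% names(df)))
    stopf("molecule list must have columns %s", paste(need, collapse = ", "))
  loc_table(df$x_nm, df$y_nm, df$z_nm, df$frame,
            photons = df$photons, truth_cluster = df$truth_cluster,
            n_frames = n_frames, z_depth = z_depth)
}

#' @param table a [loc_table()].
#' @rdname read_molecule_list
#' @export
write_molecule_list <- function(table, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
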