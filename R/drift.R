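#' Drift correction by image correlation analysis
#'
#' Estimates stage drift over the acquisition by binning localizations
#' into consecutive frame intervals, rendering each bin as a 2D (XY)
#' histogram image on a common grid, and locating the cross-correlation
#' peak of each bin against the reference (first non-empty) bin with
#' parabolic sub-pixel interpolation. The per-bin displacement is
#' interpolated linearly across frames and subtracted from every
#' localization. Lateral drift dominates in practice, so only XY is
#' corrected; the Z coordinate is passed through unchanged.
#'
#' @param table a [loc_table()] spanning at least two frame bins.
#' @param frames_per_bin frames per correlation bin (>= 1).
#' @param pixel_size rendering pixel size for the correlation images, nm.
#' @param smooth_px Gaussian smoothing (s.d., pixels) applied to the
#'   binned images before correlation; widens the correlation peak so
#'   the parabolic sub-pixel fit is stable under counting noise.
#' @return A list of class `"drift_corrected"`:
#' \describe{
#'   \item{table}{the drift-corrected [loc_table()].}
#'   \item{trace}{class `"drift_trace"` data.frame with
#'     `frame_bin_start`, `dx_nm`, `dy_nm`: the estimated displacement of
#'     each bin relative to the reference bin (zero for the reference).}
#' }
#' A bin containing no localizations gets its displacement interpolated
#' from its neighbours, with a warning; fewer than two usable bins is an
#' error.
#' @export
correct_drift <- function(table, frames_per_bin, pixel_size = 30,
                          smooth_px = 1) {
  if (!inherits(table, "loc_table")) stopf("`table` must be a loc_table")
  check_number(frames_per_bin, "frames_per_bin", lower = 1)
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  n_frames <- attr(table, "n_frames")
  n_bins <- ceiling(n_frames / frames_per_bin)
  if (n_bins < 2)
    stopf("acquisition spans fewer than 2 bins at %d frames per bin",
          as.integer(frames_per_bin))
  bin <- pmin(n_bins - 1L, table$frame %/% as.integer(frames_per_bin))
  counts <- tabulate(bin + 1L, nbins = n_bins)
  usable <- which(counts > 0L)
  if (length(usable) < 2)
    stopf("fewer than 2 bins contain localizations")
  if (any(counts == 0L))
    warnf("%d empty frame bin(s); displacement interpolated from neighbours",
          sum(counts == 0L))
  pad <- 4 * pixel_size
  xlim <- range(table$x_nm) + c(-pad, pad)
  ylim <- range(table$y_nm) + c(-pad, pad)
  ref_bin <- usable[1]
  idx_ref <- bin == ref_bin - 1L
  render_bin <- function(idx) {
    H <- bin_image(table$x_nm[idx], table$y_nm[idx], xlim, ylim, pixel_size)
    if (smooth_px > 0) H <- gauss_blur(H, smooth_px)
    H
  }
  H_ref <- render_bin(idx_ref)
  F_ref <- stats::fft(H_ref)
  dx <- dy <- rep(NA_real_, n_bins)
  dx[ref_bin] <- dy[ref_bin] <- 0
  for (b in setdiff(usable, ref_bin)) {
    H_b <- render_bin(bin == b - 1L)
    sh <- xcorr_shift(F_ref, stats::fft(H_b), dim(H_ref))
    dx[b] <- sh[2] * pixel_size   # columns index x
    dy[b] <- sh[1] * pixel_size
  }
  centers <- ((seq_len(n_bins) - 1) * frames_per_bin +
                pmin(seq_len(n_bins) * frames_per_bin, n_frames) - 1) / 2
  ok <- !is.na(dx)
  dx_fun <- stats::approxfun(centers[ok], dx[ok], rule = 2)
  dy_fun <- stats::approxfun(centers[ok], dy[ok], rule = 2)
  dx <- ifelse(ok, dx, dx_fun(centers))
  dy <- ifelse(ok, dy, dy_fun(centers))
  corrected <- as.data.frame(table)
  corrected$x_nm <- corrected$x_nm - dx_fun(corrected$frame)
  corrected$y_nm <- corrected$y_nm - dy_fun(corrected$frame)
  out <- loc_table(corrected$x_nm, corrected$y_nm, corrected$z_nm,
                   corrected$frame, photons = corrected$photons,
                   truth_cluster = corrected$truth_cluster,
                   n_frames = n_frames, z_depth = attr(table, "z_depth"))
  trace <- data.frame(
    frame_bin_start = as.integer((seq_len(n_bins) - 1) * frames_per_bin),
    dx_nm = dx, dy_nm = dy)
  class(trace) <- c("drift_trace", "data.frame")
  structure(list(table = out, trace = trace), class = "drift_corrected")
}

# displacement (rows, cols) of image B relative to reference A from their
# FFTs, with parabolic sub-pixel refinement and circular unwrapping
xcorr_shift <- function(F_a, F_b, dims) {
  C <- Re(stats::fft(Conj(F_a) * F_b, inverse = TRUE))
  peak <- which(C == max(C))[1]
  py <- (peak - 1) %% dims[1] + 1
  px <- (peak - 1) %/% dims[1] + 1
  sub <- function(vals, i, n) {
    cm1 <- vals[(i - 2) %% n + 1]; c0 <- vals[i]; cp1 <- vals[i %% n + 1]
    den <- cm1 - 2 * c0 + cp1
    if (den == 0) 0 else 0.5 * (cm1 - cp1) / den
  }
  oy <- sub(C[, px], py, dims[1])
  ox <- sub(C[py, ], px, dims[2])
  wrap <- function(v, n) ifelse(v > n / 2, v - n, v)
  c(wrap(py - 1 + oy, dims[1]), wrap(px - 1 + ox, dims[2]))
}

#' @export
print.drift_corrected <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("Drift-corrected molecule list: %d localizations, %d bins\n",
              nrow(x$table), nrow(tr)))
  cat(sprintf("  max |drift|: %.1f nm (x), %.1f nm (y)\n",
              max(abs(tr$dx_nm)), max(abs(tr$dy_nm))))
  invisible(x)
}

#' Write a drift trace as CSV
#'
#' Columns `frame_bin_start,dx_nm,dy_nm`.
#' @param trace a drift trace from [correct_drift()].
#' @param path output file.
#' @export
write_drift_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
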