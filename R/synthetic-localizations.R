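#' Ground-truth telomere structure model
#'
#' Parametric description of one underlying telomere structure from which
#' emitter (fluorophore) positions are drawn. Spheres and triaxial
#' ellipsoids are sampled uniformly over their volume; the ellipsoid
#' family with one short axis models the irregular, "compact in one
#' dimension" class seen for enlarged telomeres. A segmented-path shape
#' (piecewise-linear backbone with a Gaussian tube) is provided as an
#' alternative irregular generator.
#'
#' The analytic radius of gyration of the emitter distribution is stored
#' as `rg_struct`: for a uniform solid ellipsoid with semi-axes
#' \eqn{a,b,c}, \eqn{R_g^2 = (a^2+b^2+c^2)/5} (a ball of radius R gives
#' \eqn{\sqrt{3/5}\,R}); for a segmented path it is the backbone Rg plus
#' the 3D tube variance \eqn{3\sigma_t^2}.
#'
#' @param shape `"sphere"`, `"ellipsoid"` or `"segmented_path"`.
#' @param center 3-vector, nm.
#' @param axes semi-axis lengths in nm; a scalar radius for spheres.
#' @param n_emitters number of underlying fluorophore positions (>= 1).
#' @param orientation optional 3x3 rotation matrix applied to the shape.
#' @param path for `"segmented_path"`: a k x 3 matrix of backbone
#'   vertices (nm, relative to `center`).
#' @param tube_sigma Gaussian tube s.d. around the backbone, nm.
#' @param structure_id identifier.
#' @return An object of class `"structure_model"`.
#' @export
structure_model <- function(shape = c("sphere", "ellipsoid", "segmented_path"),
                            center = c(0, 0, 0), axes = 100,
                            n_emitters = 100, orientation = NULL,
                            path = NULL, tube_sigma = 0,
                            structure_id = 1L) {
  shape <- match.arg(shape)
  if (length(center) != 3 || !all(is.finite(center)))
    stopf("`center` must be a finite 3-vector")
  check_number(n_emitters, "n_emitters", lower = 1)
  if (!is.null(orientation)) {
    if (!is.matrix(orientation) || !all(dim(orientation) == c(3, 3)) ||
        !all(is.finite(orientation)))
      stopf("`orientation` must be a finite 3x3 rotation matrix")
  }
  if (shape == "segmented_path") {
    if (is.null(path) || !is.matrix(path) || ncol(path) != 3 ||
        nrow(path) < 2 || !all(is.finite(path)))
      stopf("segmented_path shapes need a k x 3 `path` matrix (k >= 2)")
    check_number(tube_sigma, "tube_sigma", lower = 0)
    dense <- densify_path(path, n = 2000L)
    dense <- sweep(dense, 2, colMeans(dense))
    rg_struct <- sqrt(mean(rowSums(dense^2)) + 3 * tube_sigma^2)
    axes <- c(NA_real_, NA_real_, NA_real_)
  } else {
    if (length(axes) == 1) axes <- rep(axes, 3)
    if (length(axes) != 3 || !all(is.finite(axes)) || any(axes <= 0))
      stopf("`axes` must be three positive semi-axis lengths")
    if (shape == "sphere" && length(unique(axes)) > 1)
      stopf("sphere requires equal semi-axes")
    rg_struct <- sqrt(sum(axes^2) / 5)
  }
  structure(list(structure_id = structure_id, shape = shape,
                 center = as.numeric(center), axes = as.numeric(axes),
                 orientation = orientation, n_emitters = as.integer(n_emitters),
                 path = path, tube_sigma = tube_sigma,
                 rg_struct = rg_struct),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure %s: %s, %d emitters, ground-truth Rg %.1f nm\n",
              format(x$structure_id), x$shape, x$n_emitters, x$rg_struct))
  invisible(x)
}

# resample a polyline to n points uniformly spaced in arc length
densify_path <- function(path, n = 2000L) {
  seg <- diff(path)
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0)) stopf("path has zero-length segments")
  cum <- c(0, cumsum(len))
  s <- seq(0, cum[length(cum)], length.out = n)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx >= nrow(path)] <- nrow(path) - 1L
  t <- (s - cum[idx]) / len[idx]
  path[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * t
}

sample_emitters <- function(model) {
  m <- model$n_emitters
  if (model$shape %in% c("sphere", "ellipsoid")) {
    # uniform over the unit ball, then scaled by the semi-axes
    dir <- matrix(stats::rnorm(3 * m), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    r <- stats::runif(m)^(1 / 3)
    pts <- dir * r
    pts <- sweep(pts, 2, model$axes, `*`)
  } else {
    dense <- densify_path(model$path, n = max(2000L, m))
    pts <- dense[sample.int(nrow(dense), m, replace = TRUE), , drop = FALSE]
    if (model$tube_sigma > 0)
      pts <- pts + matrix(stats::rnorm(3 * m, sd = model$tube_sigma), ncol = 3)
  }
  if (!is.null(model$orientation)) pts <- pts %*% t(model$orientation)
  sweep(pts, 2, model$center, `+`)
}

#' Acquisition parameters for the STORM simulator
#'
#' Defaults reflect typical 3D STORM acquisitions of telomeric FISH
#' probes: lateral localization error s.d. of 30 nm, axial resolution of
#' 70 nm FWHM (s.d. 70/2.355 = 29.7 nm), 35,000 frames and a 700 nm
#' z-depth window centred on the focal plane (z = 0). Whether the quoted
#' precision/resolution figures are s.d. or FWHM differs between
#' instruments, so both are plain parameters.
#'
#' @param sigma_xy lateral localization error s.d., nm.
#' @param sigma_z axial localization error s.d., nm.
#' @param n_frames number of camera frames.
#' @param z_depth imaged z range, nm (window `[-z_depth/2, z_depth/2]`).
#' @param blink_mean mean localizations per emitter; blink counts are
#'   drawn as 1 + Geometric so every emitter appears at least once.
#' @param background_density spurious localizations per cubic micron.
#' @param photon_mean mean fitted photon count per localization.
#' @param fov optional list with `xlim`, `ylim` (nm) bounding the field;
#'   derived from the structures when `NULL`.
#' @param drift optional vectorized function `f(frame)` returning an
#'   n x 3 matrix of per-frame drift displacements in nm, added to every
#'   localization (used to emulate stage drift).
#' @param seed random seed for the simulation.
#' @return An object of class `"acquisition_params"`.
#' @export
acquisition_params <- function(sigma_xy = 30, sigma_z = 70 / 2.355,
                               n_frames = 35000, z_depth = 700,
                               blink_mean = 5, background_density = 0,
                               photon_mean = 3000, fov = NULL,
                               drift = NULL, seed = NULL) {
  check_number(sigma_xy, "sigma_xy", lower = 0)
  check_number(sigma_z, "sigma_z", lower = 0)
  check_number(n_frames, "n_frames", lower = 1)
  check_number(z_depth, "z_depth", lower = 0, strict_lower = TRUE)
  check_number(blink_mean, "blink_mean", lower = 1)
  check_number(background_density, "background_density", lower = 0)
  check_number(photon_mean, "photon_mean", lower = 1)
  if (!is.null(drift) && !is.function(drift))
    stopf("`drift` must be NULL or a function of the frame index")
  structure(list(sigma_xy = sigma_xy, sigma_z = sigma_z,
                 n_frames = as.integer(n_frames), z_depth = z_depth,
                 blink_mean = blink_mean,
                 background_density = background_density,
                 photon_mean = photon_mean, fov = fov, drift = drift,
                 seed = seed),
            class = "acquisition_params")
}

rblink <- function(n, blink_mean) {
  if (blink_mean <= 1) return(rep(1L, n))
  1L + stats::rgeom(n, prob = 1 / blink_mean)
}

rphotons <- function(n, photon_mean) {
  pmax(1, round(stats::rexp(n, rate = 1 / photon_mean)))
}

#' Simulate a STORM molecule list from ground-truth structures
#'
#' Each structure's emitters are placed within/along the structure; each
#' emitter yields `1 + Geometric` blink events with mean
#' `acq$blink_mean`; every localization is the emitter position plus
#' independent Gaussian error `(sigma_xy, sigma_xy, sigma_z)`. Frames are
#' assigned uniformly over the acquisition, optional drift is added as a
#' function of frame, and background localizations are added as a
#' homogeneous Poisson process over the imaged volume. Ground-truth
#' cluster membership is recorded in the `truth_cluster` column and a
#' per-structure truth table is attached as attribute `"truth"`.
#'
#' @param structures a `structure_model` or list of them; all centers
#'   must lie inside the z-depth window.
#' @param acq an [acquisition_params()] object.
#' @return A [loc_table()] with `truth_cluster` labels (0 = background)
#'   and attribute `truth`: a data.frame with per-structure
#'   `structure_id`, `n_emitters`, `n_locs`, `rg_emitters` (realized
#'   emitter-position Rg) and `rg_struct` (analytic).
#' @export
simulate_localizations <- function(structures, acq = acquisition_params()) {
  if (inherits(structures, "structure_model")) structures <- list(structures)
  if (length(structures) == 0) stopf("`structures` must be non-empty")
  if (!all(vapply(structures, inherits, TRUE, "structure_model")))
    stopf("`structures` must be structure_model objects")
  if (!inherits(acq, "acquisition_params"))
    stopf("`acq` must be an acquisition_params object")
  zhalf <- acq$z_depth / 2
  cz <- vapply(structures, function(s) s$center[3], 0)
  if (any(abs(cz) > zhalf))
    stopf("structure centers must lie within the z-depth window [%g, %g] nm",
          -zhalf, zhalf)
  with_seed(acq$seed, {
    per <- lapply(structures, function(s) {
      em <- sample_emitters(s)
      k <- rblink(nrow(em), acq$blink_mean)
      locs <- em[rep.int(seq_len(nrow(em)), k), , drop = FALSE]
      centered <- sweep(em, 2, colMeans(em))
      list(locs = locs, n_emitters = nrow(em),
           rg_emitters = sqrt(mean(rowSums(centered^2))))
    })
    pts <- do.call(rbind, lapply(per, `[[`, "locs"))
    labels <- rep.int(seq_along(structures),
                      vapply(per, function(p) nrow(p$locs), 0L))
    fov <- acq$fov %||% {
      ext <- vapply(structures, function(s) {
        r <- if (all(is.finite(s$axes))) max(s$axes) else
          max(sqrt(rowSums(sweep(s$path, 2, 0)^2))) + 3 * s$tube_sigma
        c(s$center[1] - r, s$center[1] + r, s$center[2] - r, s$center[2] + r)
      }, numeric(4))
      list(xlim = c(min(ext[1, ]) - 500, max(ext[2, ]) + 500),
           ylim = c(min(ext[3, ]) - 500, max(ext[4, ]) + 500))
    }
    # localization error applies to emitter-derived points; background
    # points are already uniform over the imaged volume
    if (acq$sigma_xy > 0 || acq$sigma_z > 0) {
      n0 <- nrow(pts)
      pts <- pts + cbind(stats::rnorm(n0, sd = acq$sigma_xy),
                         stats::rnorm(n0, sd = acq$sigma_xy),
                         stats::rnorm(n0, sd = acq$sigma_z))
    }
    n_bg <- 0L
    if (acq$background_density > 0) {
      vol_um3 <- diff(fov$xlim) * diff(fov$ylim) * acq$z_depth / 1e9
      n_bg <- stats::rpois(1, acq$background_density * vol_um3)
      if (n_bg > 0) {
        bg <- cbind(stats::runif(n_bg, fov$xlim[1], fov$xlim[2]),
                    stats::runif(n_bg, fov$ylim[1], fov$ylim[2]),
                    stats::runif(n_bg, -zhalf, zhalf))
        pts <- rbind(pts, bg)
        labels <- c(labels, rep.int(0L, n_bg))
      }
    }
    n <- nrow(pts)
    frame <- sample.int(acq$n_frames, n, replace = TRUE) - 1L
    if (!is.null(acq$drift)) {
      d <- acq$drift(frame)
      if (!is.matrix(d) || nrow(d) != n || ncol(d) != 3)
        stopf("`drift` must return an n x 3 matrix of displacements")
      pts <- pts + d
    }
    tab <- loc_table(pts[, 1], pts[, 2], pts[, 3], frame,
                     photons = rphotons(n, acq$photon_mean),
                     truth_cluster = labels,
                     n_frames = acq$n_frames, z_depth = acq$z_depth)
    truth <- data.frame(
      structure_id = vapply(structures, function(s) as.integer(s$structure_id), 0L),
      n_emitters = vapply(per, `[[`, 0L, "n_emitters"),
      n_locs = as.integer(tabulate(labels, nbins = length(structures))),
      rg_emitters = vapply(per, `[[`, 0, "rg_emitters"),
      rg_struct = vapply(structures, `[[`, 0, "rg_struct"))
    attr(tab, "truth") <- truth
    tab
  })
}

#' Simulate per-telomere radius-of-gyration samples at group scale
#'
#' Vectorized generator for group-level shape analyses: draws a
#' population of spherical telomere structures whose radii vary
#' lognormally across telomeres, simulates their localization clouds
#' under the acquisition noise model, and returns the observed Rg per
#' telomere. The group is calibrated on the observed scale: the
#' structural radius distribution is solved from the noise-additivity
#' law \eqn{E[R_{g,obs}^2] = R_{g,struct}^2 + 2\sigma_{xy}^2 + \sigma_z^2}
#' so that the mean squared observed Rg matches `mean_rg_nm^2`.
#'
#' @param n_telomeres number of telomeres to simulate.
#' @param mean_rg_nm target observed mean Rg, nm (calibrated through the
#'   noise-additivity law). Exactly one of `mean_rg_nm`, `rg_struct_nm`.
#' @param rg_struct_nm alternatively, a fixed structural Rg for every
#'   telomere (no radius heterogeneity unless `rg_cv > 0`).
#' @param rg_cv lognormal coefficient of variation of the structural
#'   radius across telomeres (default 0.35, reproducing the broad
#'   per-telomere Rg spread seen in telomere STORM data).
#' @param n_emitters emitters per telomere.
#' @param acq an [acquisition_params()] object (its `seed` is ignored).
#' @param seed random seed.
#' @return data.frame with `telomere`, `rg_nm` (observed), `n_locs`,
#'   `rg_struct_nm` (per-telomere ground truth).
#' @export
simulate_rg_sample <- function(n_telomeres, mean_rg_nm = NULL,
                               rg_struct_nm = NULL, rg_cv = 0.35,
                               n_emitters = 100,
                               acq = acquisition_params(), seed = NULL) {
  check_number(n_telomeres, "n_telomeres", lower = 1)
  check_number(rg_cv, "rg_cv", lower = 0)
  check_number(n_emitters, "n_emitters", lower = 2)
  if (is.null(mean_rg_nm) == is.null(rg_struct_nm))
    stopf("supply exactly one of `mean_rg_nm`, `rg_struct_nm`")
  noise2 <- 2 * acq$sigma_xy^2 + acq$sigma_z^2
  if (!is.null(mean_rg_nm)) {
    check_number(mean_rg_nm, "mean_rg_nm", lower = 0, strict_lower = TRUE)
    rg2_struct <- mean_rg_nm^2 - noise2
    if (rg2_struct <= 0)
      stopf("`mean_rg_nm` is below the localization-noise floor (%.1f nm)",
            sqrt(noise2))
    r_target2 <- rg2_struct * 5 / 3   # E[R^2] for a uniform ball
  } else {
    check_number(rg_struct_nm, "rg_struct_nm", lower = 0, strict_lower = TRUE)
    r_target2 <- rg_struct_nm^2 * 5 / 3
  }
  with_seed(seed, {
    m <- as.integer(n_telomeres)
    sdlog <- sqrt(log(1 + rg_cv^2))
    # calibrate E[R^2] = r_target2 under the lognormal radius law
    meanlog <- (log(r_target2) - 2 * sdlog^2) / 2
    radius <- stats::rlnorm(m, meanlog = meanlog, sdlog = sdlog)
    k <- rblink(m * n_emitters, acq$blink_mean)
    emitter_tel <- rep.int(seq_len(m), rep.int(n_emitters, m))
    dir <- matrix(stats::rnorm(3 * m * n_emitters), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    em <- dir * stats::runif(m * n_emitters)^(1 / 3) * radius[emitter_tel]
    loc_tel <- emitter_tel[rep.int(seq_along(k), k)]
    pts <- em[rep.int(seq_along(k), k), , drop = FALSE]
    n <- nrow(pts)
    pts <- pts + cbind(stats::rnorm(n, sd = acq$sigma_xy),
                       stats::rnorm(n, sd = acq$sigma_xy),
                       stats::rnorm(n, sd = acq$sigma_z))
    n_locs <- tabulate(loc_tel, nbins = m)
    mu <- rowsum(pts, loc_tel) / n_locs
    sq <- rowsum(pts^2, loc_tel) / n_locs
    rg <- sqrt(pmax(0, rowSums(sq - mu^2)))
    data.frame(telomere = seq_len(m), rg_nm = rg, n_locs = n_locs,
               rg_struct_nm = radius * sqrt(3 / 5))
  })
}

#' Render a conventional (diffraction-limited) image of a molecule list
#'
#' Emulates the widefield overlay used to confirm that localization
#' clusters are telomeric: each localization contributes a unit-integral
#' 2D Gaussian of width `psf_sigma`, so total image intensity equals the
#' localization count (up to truncation at the field edge).
#'
#' @param locs a [loc_table()] (may be empty).
#' @param pixel_size pixel size in nm (> 0).
#' @param psf_sigma PSF Gaussian s.d. in nm.
#' @param xlim,ylim field extent in nm; derived from the data (plus a
#'   3*`psf_sigma` margin) when `NULL`.
#' @return numeric intensity matrix (rows = y, columns = x) with
#'   attributes `pixel_size` and `origin` (nm coordinates of the centre
#'   of pixel \[1,1\]).
#' @export
render_conventional_image <- function(locs, pixel_size, psf_sigma = 250,
                                      xlim = NULL, ylim = NULL) {
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_number(psf_sigma, "psf_sigma", lower = 0)
  if (nrow(locs) == 0) {
    img <- matrix(0, nrow = 8, ncol = 8)
    attr(img, "pixel_size") <- pixel_size
    attr(img, "origin") <- c(0, 0)
    return(img)
  }
  pad <- 3 * max(psf_sigma, pixel_size)
  xlim <- xlim %||% (range(locs$x_nm) + c(-pad, pad))
  ylim <- ylim %||% (range(locs$y_nm) + c(-pad, pad))
  H <- bin_image(locs$x_nm, locs$y_nm, xlim, ylim, pixel_size)
  if (psf_sigma > 0)
    H <- gauss_blur(H, sigma_px = psf_sigma / pixel_size)
  attr(H, "pixel_size") <- pixel_size
  attr(H, "origin") <- c(xlim[1] + pixel_size / 2, ylim[1] + pixel_size / 2)
  H
}

# 2D histogram: rows index y, columns index x
bin_image <- function(x, y, xlim, ylim, pixel_size) {
  nx <- max(1L, ceiling(diff(xlim) / pixel_size))
  ny <- max(1L, ceiling(diff(ylim) / pixel_size))
  ix <- pmin(nx, pmax(1L, floor((x - xlim[1]) / pixel_size) + 1L))
  iy <- pmin(ny, pmax(1L, floor((y - ylim[1]) / pixel_size) + 1L))
  keep <- x >= xlim[1] & x <= xlim[2] & y >= ylim[1] & y <= ylim[2]
  H <- matrix(0, nrow = ny, ncol = nx)
  if (any(keep)) {
    tab <- table(factor(iy[keep], levels = seq_len(ny)),
                 factor(ix[keep], levels = seq_len(nx)))
    H <- H + unclass(tab)
  }
  dimnames(H) <- NULL
  H
}

# circular FFT convolution with a unit-integral Gaussian kernel
gauss_blur <- function(H, sigma_px) {
  ny <- nrow(H); nx <- ncol(H)
  ky <- gauss_kernel_1d(ny, sigma_px)
  kx <- gauss_kernel_1d(nx, sigma_px)
  K <- outer(ky, kx)
  Re(stats::fft(stats::fft(H) * stats::fft(K), inverse = TRUE)) / (nx * ny)
}

gauss_kernel_1d <- function(n, sigma_px) {
  # kernel centred at index 1 with circular wrap
  d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  k <- exp(-d^2 / (2 * sigma_px^2))
  k / sum(k)
}
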