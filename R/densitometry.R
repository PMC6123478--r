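#' Lane densitometry profile
#'
#' A background-subtracted intensity trace along the migration axis of
#' one gel lane. Positions must be strictly increasing; negative
#' intensities (possible after background subtraction) are clipped to
#' zero with a warning.
#'
#' @param position migration coordinate samples (strictly increasing).
#' @param intensity signal intensity at each position.
#' @param lane lane label.
#' @return data.frame of class `"lane_profile"`.
#' @export
lane_profile <- function(position, intensity, lane = "lane1") {
  if (length(position) != length(intensity))
    stopf("`position` and `intensity` must have equal length")
  if (any(diff(position) <= 0))
    stopf("`position` must be strictly increasing")
  if (any(intensity < 0)) {
    warnf("%d negative intensities clipped to zero", sum(intensity < 0))
    intensity <- pmax(0, intensity)
  }
  structure(data.frame(position = position, intensity = intensity,
                       lane = lane),
            class = c("lane_profile", "data.frame"))
}

#' Rolling-minimum background subtraction for a lane profile
#'
#' Subtracts, at every position, the minimum intensity within a window
#' of `width` samples -- a simple local-baseline estimate for lanes with
#' a slowly varying background under discrete bands.
#'
#' @param profile a [lane_profile()].
#' @param width window width in samples (odd recommended).
#' @return the background-subtracted [lane_profile()].
#' @export
subtract_background <- function(profile, width = 51) {
  check_number(width, "width", lower = 1)
  n <- nrow(profile)
  h <- floor(width / 2)
  base <- vapply(seq_len(n), function(i)
    min(profile$intensity[max(1, i - h):min(n, i + h)]), 0)
  lane_profile(profile$position, profile$intensity - base,
               lane = profile$lane[1])
}

#' Ladder calibration of migration position to molecular weight
#'
#' @param position anchor migration positions (strictly increasing).
#' @param mw_kb molecular weights at the anchors, kb (strictly
#'   decreasing with migration; >= 2 anchors).
#' @return data.frame of class `"ladder_calibration"`.
#' @export
ladder_calibration <- function(position, mw_kb) {
  if (length(position) < 2) stopf("a ladder needs at least 2 anchors")
  if (length(position) != length(mw_kb)) stopf("anchor vectors differ in length")
  if (any(diff(position) <= 0))
    stopf("ladder migration positions must be strictly increasing")
  if (any(diff(mw_kb) >= 0) || any(mw_kb <= 0))
    stopf("ladder molecular weights must be positive and strictly decreasing")
  structure(data.frame(position = position, mw_kb = mw_kb),
            class = c("ladder_calibration", "data.frame"))
}

#' Build the position-to-molecular-weight function from a ladder
#'
#' Gel migration is close to linear in log molecular weight, so the map
#' is a piecewise-linear interpolation of log10(MW) against migration
#' position; the anchors are reproduced exactly. Queries beyond the
#' anchors are extrapolated from the terminal segment with a warning.
#'
#' @param ladder a [ladder_calibration()].
#' @return function `f(position) -> MW (kb)` with attribute `domain`.
#' @export
calibrate_migration <- function(ladder) {
  if (!inherits(ladder, "ladder_calibration"))
    ladder <- ladder_calibration(ladder$position, ladder$mw_kb)
  pos <- ladder$position
  lmw <- log10(ladder$mw_kb)
  domain <- range(pos)
  f <- function(position) {
    if (any(position < domain[1] | position > domain[2]))
      warnf("query outside the ladder calibration domain [%g, %g]; extrapolating",
            domain[1], domain[2])
    lw <- stats::approx(pos, lmw, xout = position, rule = 1)$y
    out <- position < domain[1]
    if (any(out)) {
      sl <- (lmw[2] - lmw[1]) / (pos[2] - pos[1])
      lw[out] <- lmw[1] + sl * (position[out] - pos[1])
    }
    out <- position > domain[2]
    if (any(out)) {
      k <- length(pos)
      sl <- (lmw[k] - lmw[k - 1]) / (pos[k] - pos[k - 1])
      lw[out] <- lmw[k] + sl * (position[out] - pos[k])
    }
    10^lw
  }
  attr(f, "domain") <- domain
  f
}

#' Intensity-weighted mean telomere restriction fragment length
#'
#' The mean length of the telomere smear from Southern blot
#' densitometry,
#' \deqn{\bar L = \frac{\sum_i Int_i}{\sum_i Int_i / MW_i},}
#' the intensity-weighted harmonic mean of molecular weight along the
#' lane. Invariant under uniform intensity scaling and bounded by the
#' molecular weights spanned by the profile.
#'
#' @param profile a [lane_profile()] with positive total intensity.
#' @param cal a position-to-MW function from [calibrate_migration()]
#'   (or a [ladder_calibration()], calibrated on the fly).
#' @return mean fragment length in kb.
#' @export
mean_telomere_length <- function(profile, cal) {
  if (inherits(cal, "ladder_calibration") || is.data.frame(cal))
    cal <- calibrate_migration(cal)
  if (!is.function(cal)) stopf("`cal` must be a calibration function or ladder")
  total <- sum(profile$intensity)
  if (total <= 0) stopf("profile has zero total intensity")
  mw <- cal(profile$position)
  total / sum(profile$intensity / mw)
}

#' Specify a synthetic gel lane
#'
#' @param bands data.frame with `mw_kb` (> 0), `intensity` (>= 0) and
#'   `sigma` (band s.d. in migration units).
#' @param ladder a [ladder_calibration()] giving the migration map used
#'   both to place bands and as the returned calibration.
#' @param profile_length number of samples along the lane.
#' @param smear optional broad component: list with `mw_kb` (centre),
#'   `sigma` (in migration units) and `intensity`.
#' @return object of class `"gel_lane_spec"`.
#' @export
gel_lane_spec <- function(bands, ladder, profile_length = 500,
                          smear = NULL) {
  if (!all(c("mw_kb", "intensity", "sigma") %in% names(bands)))
    stopf("`bands` needs columns mw_kb, intensity, sigma")
  if (any(bands$mw_kb <= 0)) stopf("band molecular weights must be > 0")
  if (any(bands$intensity < 0)) stopf("band intensities must be >= 0")
  if (!inherits(ladder, "ladder_calibration"))
    ladder <- ladder_calibration(ladder$position, ladder$mw_kb)
  check_number(profile_length, "profile_length", lower = 10)
  structure(list(bands = bands, ladder = ladder,
                 profile_length = as.integer(profile_length),
                 smear = smear),
            class = "gel_lane_spec")
}

#' Simulate a gel lane profile with ladder calibration
#'
#' Places each band at the migration position implied by the ladder's
#' log-linear map, sums Gaussian band profiles (plus an optional smear),
#' and records the ground-truth weighted mean length computed from the
#' band masses, `sum(Int) / sum(Int / MW)`.
#'
#' @param spec a [gel_lane_spec()].
#' @param lane lane label.
#' @return list with `profile` ([lane_profile()]), `ladder`
#'   ([ladder_calibration()]) and `truth` (list with `mean_length_kb`
#'   from band bookkeeping).
#' @export
simulate_gel_profile <- function(spec, lane = "lane1") {
  if (!inherits(spec, "gel_lane_spec")) stopf("`spec` must be a gel_lane_spec")
  lad <- spec$ladder
  # inverse map: migration position as a function of log10(MW)
  pos_of_mw <- function(mw) stats::approx(log10(lad$mw_kb), lad$position,
                                          xout = log10(mw), rule = 2)$y
  position <- seq(min(lad$position), max(lad$position),
                  length.out = spec$profile_length)
  dx <- position[2] - position[1]
  centers <- pos_of_mw(spec$bands$mw_kb)
  # keep delta-like band centres as exact grid samples
  narrow <- spec$bands$sigma < dx / 2
  position <- sort(unique(c(position, centers[narrow])))
  intensity <- rep(0, length(position))
  for (i in seq_len(nrow(spec$bands))) {
    ctr <- centers[i]
    if (narrow[i]) {
      j <- which.min(abs(position - ctr))
      intensity[j] <- intensity[j] + spec$bands$intensity[i]
    } else {
      g <- stats::dnorm(position, ctr, spec$bands$sigma[i])
      intensity <- intensity + spec$bands$intensity[i] * g / sum(g)
    }
  }
  if (!is.null(spec$smear)) {
    g <- stats::dnorm(position, pos_of_mw(spec$smear$mw_kb), spec$smear$sigma)
    intensity <- intensity + spec$smear$intensity * g / sum(g)
  }
  truth_mean <- sum(spec$bands$intensity) /
    sum(spec$bands$intensity / spec$bands$mw_kb)
  list(profile = lane_profile(position, intensity, lane = lane),
       ladder = lad,
       truth = list(mean_length_kb = truth_mean))
}
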