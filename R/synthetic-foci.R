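#' Plan a synthetic two-channel foci scene
#'
#' Describes a nucleus with planted Gaussian spots in two channels and a
#' controlled overlap plan: `n_overlap` of the channel-a foci coincide
#' with channel-b foci, the rest are kept well separated. The planned
#' overlap fraction `n_overlap / n_a` is recorded as ground truth so
#' that downstream colocalization scoring can be validated exactly at
#' zero noise.
#'
#' Explicit focus tables can be supplied instead of random placement;
#' every planted centroid must lie inside the nucleus mask.
#'
#' @param image_shape image size in pixels, `c(rows, cols)`.
#' @param pixel_size pixel size, nm.
#' @param nucleus_mask logical matrix; defaults to a centred disc
#'   covering most of the field.
#' @param n_a,n_b number of channel-a / channel-b foci.
#' @param n_overlap number of a-foci planted to coincide with b-foci
#'   (`0 <= n_overlap <= min(n_a, n_b)`).
#' @param spot_sigma Gaussian spot s.d. in pixels.
#' @param amplitude peak amplitude of planted spots (camera counts).
#' @param noise_sd Gaussian camera noise s.d.
#' @param min_separation minimum distance (px) between non-coinciding
#'   foci, keeping planted spots resolvable.
#' @param foci_a,foci_b optional explicit data.frames with columns
#'   `row,col` (and optionally `amplitude`, `sigma`) overriding random
#'   placement; the overlap plan is then inferred from coincident
#'   centroids.
#' @param seed random seed.
#' @return An object of class `"foci_scene"`.
#' @export
foci_scene <- function(image_shape = c(128, 128), pixel_size = 80,
                       nucleus_mask = NULL, n_a = 20, n_b = 10,
                       n_overlap = 8, spot_sigma = 1.5, amplitude = 3000,
                       noise_sd = 50, min_separation = 12,
                       foci_a = NULL, foci_b = NULL, seed = NULL) {
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(spot_sigma, "spot_sigma", lower = 0, strict_lower = TRUE)
  nr <- image_shape[1]; nc <- image_shape[2]
  if (is.null(nucleus_mask)) {
    rc <- expand.grid(row = seq_len(nr), col = seq_len(nc))
    nucleus_mask <- matrix((rc$row - (nr + 1) / 2)^2 +
                             (rc$col - (nc + 1) / 2)^2 <=
                             (0.45 * min(nr, nc))^2, nr, nc)
  }
  if (!all(dim(nucleus_mask) == c(nr, nc)))
    stopf("`nucleus_mask` shape must match `image_shape`")
  placed <- with_seed(seed, place_scene_foci(
    nucleus_mask, n_a, n_b, n_overlap, min_separation, foci_a, foci_b))
  check_inside <- function(df, what) {
    idx <- cbind(round(df$row), round(df$col))
    bad <- idx[, 1] < 1 | idx[, 1] > nr | idx[, 2] < 1 | idx[, 2] > nc
    if (any(bad) || !all(nucleus_mask[idx[!bad, , drop = FALSE]]))
      stopf("all %s centroids must lie inside the nucleus mask", what)
  }
  check_inside(placed$a, "channel-a")
  check_inside(placed$b, "channel-b")
  fill <- function(df, col, val) {
    if (is.null(df[[col]])) df[[col]] <- rep(val, nrow(df))
    df
  }
  placed$a <- fill(fill(placed$a, "amplitude", amplitude), "sigma", spot_sigma)
  placed$b <- fill(fill(placed$b, "amplitude", amplitude), "sigma", spot_sigma)
  structure(list(image_shape = c(nr, nc), pixel_size = pixel_size,
                 nucleus_mask = nucleus_mask, foci_a = placed$a,
                 foci_b = placed$b, a_overlaps = placed$a_overlaps,
                 overlap_fraction = mean(placed$a_overlaps),
                 noise_sd = noise_sd, seed = seed),
            class = "foci_scene")
}

place_scene_foci <- function(mask, n_a, n_b, n_overlap, min_sep,
                             foci_a, foci_b) {
  if (!is.null(foci_a) && !is.null(foci_b)) {
    key_b <- paste(round(foci_b$row), round(foci_b$col))
    a_ov <- paste(round(foci_a$row), round(foci_a$col)) %in% key_b
    return(list(a = foci_a, b = foci_b, a_overlaps = a_ov))
  }
  if (n_overlap < 0 || n_overlap > min(n_a, n_b))
    stopf("`n_overlap` must be between 0 and min(n_a, n_b)")
  cells <- which(mask, arr.ind = TRUE)
  pick <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n_a + n_b - n_overlap)) {
    for (try in 1:5000) {
      cand <- cells[sample.int(nrow(cells), 1), ]
      if (nrow(pick) == 0 ||
          min((pick[, 1] - cand[1])^2 + (pick[, 2] - cand[2])^2) >=
            min_sep^2) {
        pick <- rbind(pick, cand)
        break
      }
      if (try == 5000)
        stopf("could not place %d separated foci; enlarge the mask",
              n_a + n_b - n_overlap)
    }
  }
  a <- data.frame(row = pick[seq_len(n_a), 1], col = pick[seq_len(n_a), 2])
  b_own <- n_b - n_overlap
  b_rows <- c(pick[seq_len(n_overlap), 1],
              if (b_own > 0) pick[n_a + seq_len(b_own), 1])
  b_cols <- c(pick[seq_len(n_overlap), 2],
              if (b_own > 0) pick[n_a + seq_len(b_own), 2])
  b <- data.frame(row = b_rows, col = b_cols)
  list(a = a, b = b,
       a_overlaps = seq_len(n_a) <= n_overlap)
}

#' Simulate a two-channel foci image pair
#'
#' Renders the scene's planted Gaussian spots into two intensity images,
#' adds Gaussian camera noise, and returns the pair together with the
#' nucleus mask and the ground-truth overlap labels.
#'
#' @param scene a [foci_scene()].
#' @return list with `channel_a`, `channel_b` (numeric matrices),
#'   `mask`, and `truth` (`foci_a`, `foci_b`, `a_overlaps`,
#'   `overlap_fraction`).
#' @export
simulate_foci_image <- function(scene) {
  if (!inherits(scene, "foci_scene")) stopf("`scene` must be a foci_scene")
  nr <- scene$image_shape[1]; nc <- scene$image_shape[2]
  render <- function(foci) {
    img <- matrix(0, nr, nc)
    for (i in seq_len(nrow(foci))) {
      s <- foci$sigma[i]
      ext <- ceiling(4 * s)
      rows <- max(1, round(foci$row[i]) - ext):min(nr, round(foci$row[i]) + ext)
      cols <- max(1, round(foci$col[i]) - ext):min(nc, round(foci$col[i]) + ext)
      g <- outer(exp(-(rows - foci$row[i])^2 / (2 * s^2)),
                 exp(-(cols - foci$col[i])^2 / (2 * s^2)))
      img[rows, cols] <- img[rows, cols] + foci$amplitude[i] * g
    }
    img
  }
  with_seed(if (is.null(scene$seed)) NULL else sub_seed(scene$seed, 1L), {
    a <- render(scene$foci_a)
    b <- render(scene$foci_b)
    if (scene$noise_sd > 0) {
      a <- pmax(a + matrix(stats::rnorm(nr * nc, sd = scene$noise_sd), nr, nc), 0)
      b <- pmax(b + matrix(stats::rnorm(nr * nc, sd = scene$noise_sd), nr, nc), 0)
    }
    list(channel_a = a, channel_b = b, mask = scene$nucleus_mask,
         truth = list(foci_a = scene$foci_a, foci_b = scene$foci_b,
                      a_overlaps = scene$a_overlaps,
                      overlap_fraction = scene$overlap_fraction))
  })
}
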