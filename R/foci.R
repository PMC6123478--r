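#' Detect nuclear foci by global thresholding
#'
#' Connected components of supra-threshold pixels (`intensity >
#' threshold`) inside the nucleus mask, discarding components smaller
#' than `min_area`. The threshold is meant to be chosen once per channel
#' per experiment and reused across all control and experimental groups
#' (identical-threshold policy); [score_nuclei()] enforces this by
#' construction since a single configuration scores every nucleus.
#'
#' @param img numeric intensity matrix (non-negative; rows = y).
#' @param mask logical/0-1 nucleus mask of the same shape (non-empty).
#' @param threshold global intensity threshold; a threshold at or above
#'   the image maximum yields an empty focus set (not an error).
#' @param min_area minimum component area in pixels.
#' @param connectivity 8 (default) or 4.
#' @param channel optional channel label.
#' @return An object of class `"foci_set"`: `labels` (integer matrix,
#'   0 = background), `n`, `areas`, `centroids` (row/col), `threshold`,
#'   `min_area`, `channel`, `mask`.
#' @export
detect_foci <- function(img, mask, threshold, min_area = 4,
                        connectivity = 8, channel = NULL) {
  if (!is.matrix(img)) stopf("`img` must be a matrix")
  mask <- mask > 0
  if (!identical(dim(img), dim(mask)))
    stopf("`img` and `mask` must have the same shape")
  if (!any(mask)) stopf("nucleus mask is empty")
  check_number(threshold, "threshold")
  check_number(min_area, "min_area", lower = 1)
  bw <- img > threshold & mask
  labels <- label_components(bw, connectivity = connectivity)
  if (max(labels) > 0) {
    areas <- tabulate(labels[labels > 0])
    keep <- which(areas >= min_area)
    relab <- integer(max(labels))
    relab[keep] <- seq_along(keep)
    labels[labels > 0] <- relab[labels[labels > 0]]
  }
  n <- max(labels)
  areas <- if (n > 0) tabulate(labels[labels > 0], nbins = n) else integer(0)
  centroids <- if (n > 0) {
    idx <- which(labels > 0, arr.ind = TRUE)
    lab <- labels[labels > 0]
    cbind(row = as.numeric(tapply(idx[, 1], lab, mean)),
          col = as.numeric(tapply(idx[, 2], lab, mean)))
  } else matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("row", "col")))
  structure(list(labels = labels, n = n, areas = areas,
                 centroids = centroids, threshold = threshold,
                 min_area = min_area, channel = channel, mask = mask),
            class = "foci_set")
}

#' @export
print.foci_set <- function(x, ...) {
  cat(sprintf("Foci set%s: %d foci above threshold %g (min area %d px)\n",
              if (is.null(x$channel)) "" else paste0(" [", x$channel, "]"),
              x$n, x$threshold, as.integer(x$min_area)))
  invisible(x)
}

# connected-component labeling by iterative label propagation;
# components are small (foci), so few sweeps are needed
label_components <- function(bw, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stopf("`connectivity` must be 4 or 8")
  nr <- nrow(bw); nc <- ncol(bw)
  labels <- matrix(0L, nr, nc)
  labels[bw] <- seq_len(sum(bw))
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  repeat {
    new <- labels
    for (s in shifts) {
      sh <- shift_matrix(labels, s[1], s[2])
      new <- pmax(new, sh)
    }
    new[!bw] <- 0L
    if (identical(new, labels)) break
    labels <- new
  }
  # relabel consecutively
  u <- sort(unique(labels[labels > 0]))
  if (length(u)) {
    relab <- integer(max(u)); relab[u] <- seq_along(u)
    labels[labels > 0] <- relab[labels[labels > 0]]
  }
  labels
}

shift_matrix <- function(M, dr, dc) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(0L, nr, nc)
  rsrc <- max(1, 1 - dr):min(nr, nr - dr)
  csrc <- max(1, 1 - dc):min(nc, nc - dc)
  out[rsrc + dr, csrc + dc] <- M[rsrc, csrc]
  out
}

#' Percent of the nucleus area covered by foci
#'
#' `100 * (focus pixels) / (mask pixels)` -- the "% area per nucleus"
#' readout used to quantify how widely a tagged protein spreads over
#' the nucleus.
#'
#' @param foci a [detect_foci()] result.
#' @param mask nucleus mask; defaults to the mask stored in `foci`.
#' @return percentage in \[0, 100\].
#' @export
percent_area <- function(foci, mask = foci$mask) {
  mask <- mask > 0
  if (!any(mask)) stopf("nucleus mask is empty")
  100 * sum(foci$labels > 0 & mask) / sum(mask)
}

#' Percent of reference foci colocalized with a partner channel
#'
#' A reference focus is colocalized when its pixel set shares at least
#' `overlap_min` pixels with some single partner focus. The measure is
#' asymmetric by design: the denominator is the reference channel (the
#' telomere channel in TIF scoring).
#'
#' @param reference,partner [detect_foci()] results on the same grid.
#' @param overlap_min minimum shared pixels with any one partner focus.
#' @return percentage in \[0, 100\]; `NA` when the reference has zero
#'   foci (undefined).
#' @export
percent_colocalized <- function(reference, partner, overlap_min = 1) {
  check_number(overlap_min, "overlap_min", lower = 1)
  if (reference$n == 0) return(NA_real_)
  if (!identical(dim(reference$labels), dim(partner$labels)))
    stopf("reference and partner foci are on different grids")
  hits <- coloc_hits(reference$labels, partner$labels, reference$n,
                     overlap_min)
  100 * sum(hits) / reference$n
}

coloc_hits <- function(ref_labels, partner_labels, n_ref, overlap_min) {
  vapply(seq_len(n_ref), function(k) {
    p <- partner_labels[ref_labels == k]
    p <- p[p > 0]
    length(p) > 0 && max(tabulate(p)) >= overlap_min
  }, TRUE)
}

#' Percent TIF (telomere dysfunction-induced foci) per nucleus
#'
#' The fraction of telomere foci overlapping a DNA-damage (53BP1) focus:
#' identical contract to [percent_colocalized()] with the telomere
#' channel as reference and the damage channel as partner.
#'
#' @param telomeres telomere-channel [detect_foci()] result.
#' @param damage damage-channel (53BP1) [detect_foci()] result.
#' @inheritParams percent_colocalized
#' @return percentage in \[0, 100\], `NA` with zero telomere foci.
#' @export
percent_tif <- function(telomeres, damage, overlap_min = 1) {
  percent_colocalized(telomeres, damage, overlap_min = overlap_min)
}

#' Number of foci in a focus set
#'
#' @param foci a [detect_foci()] result.
#' @return integer count of labeled regions.
#' @export
count_foci <- function(foci) as.integer(foci$n)

#' Random-placement permutation null for TIF scoring
#'
#' Apparent colocalization can arise from coincidental overlap alone.
#' This null shuffles each damage focus (its exact pixel footprint) to a
#' uniformly random position with its centroid inside the nucleus mask,
#' rescores %TIF, and repeats. Under independence the expected %TIF is
#' approximately 100 x the damage-covered area fraction of the nucleus.
#'
#' @param telomeres,damage [detect_foci()] results on the same grid.
#' @param n_shuffles number of random placements.
#' @param overlap_min as in [percent_colocalized()].
#' @param seed random seed.
#' @return list with `observed` (%TIF of the real configuration),
#'   `null_mean`, `null_sd`, `null` (per-shuffle %TIF vector) and
#'   `coverage_pct` (damage-covered percent of the mask, the analytic
#'   expectation under independence).
#' @export
tif_permutation_null <- function(telomeres, damage, n_shuffles = 200,
                                 overlap_min = 1, seed = NULL) {
  check_number(n_shuffles, "n_shuffles", lower = 1)
  if (telomeres$n == 0) stopf("no telomere foci to score")
  mask <- telomeres$mask
  nr <- nrow(mask); nc <- ncol(mask)
  foci_px <- lapply(seq_len(damage$n), function(k)
    which(damage$labels == k, arr.ind = TRUE))
  mask_cells <- which(mask, arr.ind = TRUE)
  observed <- percent_tif(telomeres, damage, overlap_min)
  with_seed(seed, {
    null <- vapply(seq_len(n_shuffles), function(s) {
      lab <- matrix(0L, nr, nc)
      for (k in seq_along(foci_px)) {
        px <- foci_px[[k]]
        ctr <- round(colMeans(px))
        repeat {
          tgt <- mask_cells[sample.int(nrow(mask_cells), 1), ]
          rows <- px[, 1] - ctr[1] + tgt[1]
          cols <- px[, 2] - ctr[2] + tgt[2]
          if (all(rows >= 1 & rows <= nr & cols >= 1 & cols <= nc)) break
        }
        lab[cbind(rows, cols)] <- k
      }
      hits <- coloc_hits(telomeres$labels, lab, telomeres$n, overlap_min)
      100 * sum(hits) / telomeres$n
    }, 0)
    list(observed = observed, null_mean = mean(null),
         null_sd = stats::sd(null), null = null,
         coverage_pct = 100 * sum(damage$labels > 0 & mask) / sum(mask))
  })
}

#' Score a nucleus pair of channels into a per-nucleus record
#'
#' Applies one shared configuration (thresholds, minimum area, overlap
#' rule) to a two-channel nucleus and returns the tidy per-nucleus row
#' written to the colocalization CSV:
#' `nucleus,channel_a_foci,channel_b_foci,pct_area_a,pct_coloc,pct_tif`.
#' `pct_coloc` and `pct_tif` are both channel-a-referenced overlap
#' percentages (they coincide when channel a is the telomere probe and
#' channel b the damage marker).
#'
#' @param channel_a,channel_b intensity matrices.
#' @param mask nucleus mask.
#' @param threshold_a,threshold_b per-channel global thresholds.
#' @param min_area,overlap_min,connectivity shared detection settings.
#' @param nucleus nucleus identifier.
#' @return one-row data.frame.
#' @export
score_nuclei <- function(channel_a, channel_b, mask, threshold_a,
                         threshold_b, min_area = 4, overlap_min = 1,
                         connectivity = 8, nucleus = 1L) {
  fa <- detect_foci(channel_a, mask, threshold_a, min_area, connectivity,
                    channel = "a")
  fb <- detect_foci(channel_b, mask, threshold_b, min_area, connectivity,
                    channel = "b")
  pc <- percent_colocalized(fa, fb, overlap_min)
  data.frame(nucleus = nucleus, channel_a_foci = count_foci(fa),
             channel_b_foci = count_foci(fb),
             pct_area_a = percent_area(fa, mask),
             pct_coloc = pc, pct_tif = pc)
}

#' Read / write channel images and masks as TIFF
#'
#' Channel images are stored as 16-bit grayscale TIFF, nucleus masks as
#' 8-bit binary TIFF.
#'
#' @param img numeric matrix of intensities in \[0, 65535\].
#' @param mask logical/0-1 matrix.
#' @param path file path.
#' @return matrices on read; `path` invisibly on write.
#' @export
write_channel_image <- function(img, path) {
  img <- pmax(pmin(img, 65535), 0)
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_channel_image
#' @export
read_channel_image <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  storage.mode(img) <- "double"
  img
}

#' @rdname write_channel_image
#' @export
write_nucleus_mask <- function(mask, path) {
  tiff::writeTIFF((mask > 0) * 1, path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_channel_image
#' @export
read_nucleus_mask <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0
}
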