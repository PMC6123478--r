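# independent oracles and small fixture builders used across tests

# Rg via the pairwise-distance identity sqrt( (1/(2N^2)) sum_ij |ri-rj|^2 ),
# accumulated row by row -- independent of the center-of-mass code path
rg_pairwise_oracle <- function(X) {
  n <- nrow(X)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + sum(rowSums((X - matrix(X[i, ], n, ncol(X),
                                         byrow = TRUE))^2))
  }
  sqrt(acc / (2 * n^2))
}

# two-sided permutation p-value for the difference in means
perm_ttest_p <- function(a, b, n_resamples = 1e4) {
  pool <- c(a, b)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  hits <- 0L
  for (i in seq_len(n_resamples)) {
    idx <- sample.int(length(pool), na)
    d <- abs(mean(pool[idx]) - mean(pool[-idx]))
    if (d >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_resamples
}

# random localization cloud as a coordinate matrix
random_cluster <- function(n, scale = 100) {
  matrix(stats::rnorm(3 * n, sd = scale), ncol = 3,
         dimnames = list(NULL, c("x_nm", "y_nm", "z_nm")))
}

cluster_from_matrix <- function(X, id = 1L) {
  telomere_cluster(data.frame(x_nm = X[, 1], y_nm = X[, 2], z_nm = X[, 3]),
                   telomere_id = id)
}

# rotation matrix about a random axis
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# well-separated sphere structures scattered over an XY field
scatter_spheres <- function(n, radius = 80, n_emitters = 150,
                            field = 6000, z = 0) {
  centers <- field * cbind(stats::runif(n), stats::runif(n))
  lapply(seq_len(n), function(i)
    structure_model("sphere", center = c(centers[i, ], z), axes = radius,
                    n_emitters = n_emitters, structure_id = i))
}

# ladder spanning 0.1 - 20 kb, log-linear in migration position
default_ladder <- function() {
  mw <- c(20, 10, 5, 2.5, 1.2, 0.6, 0.3, 0.1)
  ladder_calibration(position = 10 + 80 * (log10(20) - log10(mw)) /
                       (log10(20) - log10(0.1)),
                     mw_kb = mw)
}
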