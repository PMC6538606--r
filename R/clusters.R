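#' Paired t-map between two conditions
#'
#' At every time-frequency point, computes the paired t-statistic of the
#' per-subject condition differences `d_s = c1_s - c2_s`:
#' `t = mean(d) / (sd(d) / sqrt(S))` with the `S - 1` denominator in `sd`,
#' `df = S - 1`.  Points where `sd(d) = 0` (identical values across
#' subjects) are degenerate and set to `t = 0`; their count is returned in
#' the `n_degenerate` attribute.
#'
#' @param c1,c2 Arrays `[subject x frequency x time]` of per-subject maps
#'   for the two conditions (matching shapes, >= 2 subjects).
#' @param freqs,times Optional grid annotations carried into the result.
#' @return A `tf_tmap`: list with `t` (matrix `[frequency x time]`), `df`,
#'   `freqs`, `times`.
#' @export
paired_tmap <- function(c1, c2, freqs = NULL, times = NULL) {
  if (!identical(dim(c1), dim(c2)))
    stop_config("c1 and c2 must have identical [subject x freq x time] shapes")
  S <- dim(c1)[1]
  if (S < 2) stop_config("paired t-statistics need at least 2 subjects")
  d <- c1 - c2
  dm <- matrix(d, S)
  m <- .colMeans(dm, S, ncol(dm))
  v <- (.colSums(dm^2, S, ncol(dm)) - S * m^2) / (S - 1)
  tol <- 1e-12 * (.colSums(dm^2, S, ncol(dm)) / (S - 1) + 1e-300)
  bad <- v <= tol
  tv <- numeric(length(m))
  tv[!bad] <- m[!bad] / sqrt(v[!bad] / S)
  out <- structure(list(t = matrix(tv, dim(c1)[2], dim(c1)[3]),
                        df = S - 1L, freqs = freqs, times = times),
                   class = "tf_tmap")
  attr(out, "n_degenerate") <- sum(bad)
  out
}

#' Cluster-forming t-threshold
#'
#' The `quantile` point of the central t-distribution with `df` degrees of
#' freedom; the default 0.975 is the critical value of a two-sided
#' parametric t-test at level 0.05.
#'
#' @param df Degrees of freedom (>= 1).
#' @param quantile Quantile in (0.5, 1); default 0.975.
#' @return The forming threshold (positive scalar).
#' @export
#' @examples
#' cluster_threshold(7)
cluster_threshold <- function(df, quantile = 0.975) {
  if (df < 1) stop_config("df must be >= 1")
  qt(quantile, df)
}

#' Extract suprathreshold clusters from a t-map
#'
#' Positive clusters are the 4-connected components (edge-adjacent in time
#' or frequency; no diagonals) of `{t > threshold}`, negative clusters the
#' components of `{t < -threshold}`.  The mass of a cluster is the sum of
#' the t-values inside it; positive and negative masses indicate C1 > C2
#' and C2 > C1 respectively.
#'
#' @param tmap A `tf_tmap` (see [paired_tmap()]) or a numeric matrix
#'   `[frequency x time]`.
#' @param threshold Positive cluster-forming threshold.
#' @return A tibble with one row per cluster: `cluster`, `sign` (+1/-1),
#'   `mass`, `n_cells`, and a `mask` list-column of logical matrices.  The
#'   integer label matrix is attached as attribute `labels`.
#' @export
extract_clusters <- function(tmap, threshold) {
  tm <- if (inherits(tmap, "tf_tmap")) tmap$t else tmap
  if (!is.matrix(tm)) stop_config("tmap must be a matrix or tf_tmap")
  if (!is_scalar_num(threshold) || threshold <= 0)
    stop_config("threshold must be a positive scalar")
  lab <- cpp_cluster_label(tm, threshold)
  k <- length(lab$mass)
  out <- tibble::tibble(
    cluster = seq_len(k),
    sign = as.integer(lab$sign),
    mass = as.numeric(lab$mass),
    n_cells = as.integer(lab$n_cells),
    mask = lapply(seq_len(k), function(i) lab$labels == i)
  )
  attr(out, "labels") <- lab$labels
  out
}

#' Permutation p-values for clusters
#'
#' Ranks each cluster's absolute mass against the null distribution of the
#' maximum absolute cluster mass over sign-flip relabelings:
#' `p = (#(null >= |mass|) + 1) / (n_p + 1)`.  The null is shared between
#' positive and negative clusters (two-sided family-wise control within the
#' pair).
#'
#' @param clusters A tibble from [extract_clusters()].
#' @param null_max Numeric vector of `n_p` null maximum |mass| values.
#' @return The tibble with a `p_cluster` column added.
#' @export
cluster_pvalues <- function(clusters, null_max) {
  if (length(null_max) < 1) stop_config("null distribution must be non-empty")
  np <- length(null_max)
  clusters$p_cluster <- vapply(clusters$mass, function(m)
    (sum(null_max >= abs(m)) + 1) / (np + 1), 0)
  clusters
}
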