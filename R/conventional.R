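#' Conventional within-ROI-averaging connectivity test
#'
#' The classical comparator: the sub-ROI series are averaged within each
#' ROI, the time-frequency coherence between the two mean series is
#' estimated per subject and condition, and a single cluster-statistics
#' contrast is run between conditions using exactly the same machinery as
#' the PeSCAR inner loop (paired t-map, 4-connected clusters, sign-flip
#' max-|mass| null, add-one p-values).  The null hypothesis is rejected
#' when any cluster's p-value falls below `alpha` (family-wise control is
#' already provided by the max-statistic null).
#'
#' @inheritParams pescar
#' @param dataset A `pescar_dataset` (see [sim_dataset()]).
#' @return A `conventional_fit`: cluster table with p-values, the t-map,
#'   the max-|mass| null, `min_p` and the rejection `reject`.  Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @seealso [pescar()] for the sub-ROI test this baselines against.
#' @export
conventional_test <- function(dataset, config = pescar_config(), seed = 1L,
                              labelings = NULL) {
  coh <- roi_average_coherence(dataset, config)
  dm <- dim(coh$coh)
  nf <- dm[2]; ntv <- dm[3]; S <- dm[4]
  cohv <- coh$coh
  if (isTRUE(config$fisher_z)) cohv <- atanh(pmin(cohv, 1 - 1e-12))
  dif <- cohv[, , , , 1, drop = FALSE] - cohv[, , , , 2, drop = FALSE]
  dim(dif) <- c(1L, nf, ntv, S)
  d_array <- aperm(dif, c(4, 2, 3, 1))
  dim(d_array) <- c(S, nf * ntv, 1L)

  if (is.null(labelings))
    labelings <- sign_flip_labelings(S, config$n_perm, seed)
  thr <- cluster_threshold(S - 1L, config$forming_quantile)
  eng <- perm_engine(d_array, nf, labelings, thr, config$alpha,
                     config$pair_agg)
  tm <- matrix(eng$tmap_obs[, 1], nf, ntv)
  clusters <- extract_clusters(tm, thr)
  if (nrow(clusters))
    clusters <- cluster_pvalues(clusters, eng$null_max[-1, 1])
  else
    clusters$p_cluster <- numeric(0)
  min_p <- if (nrow(clusters)) min(clusters$p_cluster) else 1

  structure(list(
    clusters = clusters,
    tmap = tm,
    null_max = eng$null_max[-1, 1],
    min_p = min_p,
    reject = min_p < config$alpha,
    t_threshold = thr,
    df = eng$df,
    n_perm = eng$n_perm,
    exhaustive = isTRUE(attr(labelings, "exhaustive")),
    alpha = config$alpha,
    freqs = coh$freqs,
    times = coh$times,
    config = config
  ), class = "conventional_fit")
}

#' @export
print.conventional_fit <- function(x, ...) {
  cat("<conventional_fit>  whole-ROI averaged cluster permutation test\n")
  cat(sprintf("  n_perm: %d (%s) | t threshold: %.3f (df = %d)\n",
              x$n_perm, if (x$exhaustive) "exhaustive" else "sampled",
              x$t_threshold, x$df))
  cat(sprintf("  clusters: %d | min cluster p: %.4g | reject at %g: %s\n",
              nrow(x$clusters), x$min_p, x$alpha,
              if (x$reject) "yes" else "no"))
  invisible(x)
}
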