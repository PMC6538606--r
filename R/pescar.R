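#' Original connectivity matrix from per-pair cluster results
#'
#' Builds the `N x M` directional matrix whose entry for sub-ROI pair
#' `(i, j)` is the mass of that pair's most massive significant cluster of
#' the matching sign (cluster p-value below `alpha`), and 0 otherwise.  The
#' total connectivity `A` (sum of absolute entries) is attached as
#' attribute `"A"`.
#'
#' @param clusters Tibble of clusters for all pairs (columns `pair`,
#'   `sign`, `mass`, `p_cluster`), e.g. from a [pescar()] fit.  Pairs with
#'   no clusters may simply be absent.
#' @param pair_index Tibble with one row per evaluated pair (columns
#'   `pair`, `roi1_subroi`, `roi2_subroi`) defining the full `N x M` grid;
#'   clusters referencing pairs outside it are an error.
#' @param direction `"C1>C2"` (positive masses) or `"C2>C1"` (negative).
#' @param alpha Element-selection threshold on the cluster p-value.
#' @param agg `"largest"` (default) or `"sum"` of the significant masses.
#' @return Matrix `[N x M]` with attributes `A` (total connectivity) and
#'   `direction`.
#' @export
original_matrix <- function(clusters, pair_index,
                            direction = c("C1>C2", "C2>C1"), alpha = 0.05,
                            agg = c("largest", "sum")) {
  direction <- match.arg(direction)
  agg <- match.arg(agg)
  want_sign <- if (direction == "C1>C2") 1L else -1L
  if (nrow(clusters) && !all(clusters$pair %in% pair_index$pair))
    stop_config("clusters reference pairs missing from pair_index")
  n1 <- max(pair_index$roi1_subroi)
  n2 <- max(pair_index$roi2_subroi)
  a <- matrix(0, n1, n2)
  sel <- clusters[clusters$sign == want_sign & clusters$p_cluster < alpha, ,
                  drop = FALSE]
  if (nrow(sel)) {
    for (p in unique(sel$pair)) {
      m <- sel$mass[sel$pair == p]
      val <- if (agg == "largest") m[which.max(abs(m))] else sum(m)
      i <- pair_index$roi1_subroi[pair_index$pair == p]
      j <- pair_index$roi2_subroi[pair_index$pair == p]
      a[i, j] <- val
    }
  }
  attr(a, "A") <- sum(abs(a))
  attr(a, "direction") <- direction
  a
}

#' Directional permutation p-values for total connectivity
#'
#' Compares the observed total connectivity of each direction with its
#' permutation null: `p = (k + 1) / (n_p + 1)` where `k` counts null values
#' at least as large as the observed total, and Bonferroni-adjusts over the
#' two directions (`p_adj = min(1, 2 p)`).
#'
#' @param A12,A21 Observed total connectivity values.
#' @param null12,null21 Numeric null vectors (length `n_p` each).
#' @return A tibble with one row per direction: `direction`, `A`, `k`,
#'   `p`, `p_adj`.
#' @export
#' @examples
#' pescar_pvalues(5, 0, runif(999), runif(999))
pescar_pvalues <- function(A12, A21, null12, null21) {
  r12 <- perm_pvalue(A12, null12)
  r21 <- perm_pvalue(A21, null21)
  tibble::tibble(
    direction = c("C1>C2", "C2>C1"),
    A = c(A12, A21),
    k = c(r12$k, r21$k),
    p = c(r12$p, r21$p),
    p_adj = pmin(1, 2 * c(r12$p, r21$p))
  )
}

#' Time-frequency summary map of significant connections
#'
#' Sums the binary cluster masks of all significant clusters of one
#' direction over pairs.  Unweighted, the map counts how many significant
#' connections cover each time-frequency point; weighted, each mask is
#' multiplied by its pair's t-map before summation, so the map integrates
#' to the summed significant cluster masses.
#'
#' @param clusters Cluster tibble (columns `pair`, `sign`, `mass`,
#'   `p_cluster`, `mask`).
#' @param dims Grid dimensions `c(n_freq, n_time)`.
#' @param direction `"C1>C2"` or `"C2>C1"`.
#' @param alpha Significance threshold on `p_cluster`.
#' @param weighted Weight masks by t-values (requires `tmaps`).
#' @param tmaps List of t-map matrices indexed by pair (required when
#'   `weighted = TRUE`).
#' @return Matrix `[n_freq x n_time]`.
#' @export
tf_summary_map <- function(clusters, dims, direction = c("C1>C2", "C2>C1"),
                           alpha = 0.05, weighted = FALSE, tmaps = NULL) {
  direction <- match.arg(direction)
  want_sign <- if (direction == "C1>C2") 1L else -1L
  out <- matrix(0, dims[1], dims[2])
  sel <- clusters[clusters$sign == want_sign & clusters$p_cluster < alpha, ,
                  drop = FALSE]
  if (weighted && is.null(tmaps) && nrow(sel))
    stop_config("tmaps must be supplied for the weighted map")
  for (r in seq_len(nrow(sel))) {
    msk <- sel$mask[[r]]
    out <- out + if (weighted) msk * tmaps[[sel$pair[r]]] else msk
  }
  out
}

#' Fit the PeSCAR test
#'
#' Runs the full pipeline on a two-condition multi-subject study: for every
#' cross-ROI sub-ROI pair, a paired t-map over the time-frequency plane is
#' computed between the per-subject condition coherence maps, suprathreshold
#' clusters are extracted and assigned permutation p-values from the
#' pair's sign-flip max-|mass| null, significant cluster masses are
#' assembled into directional original connectivity matrices, and the total
#' connectivity `A = sum |a_ij|` of each direction is tested against the
#' null of the same statistic over condition relabelings.  Directional
#' p-values `p = (k + 1)/(n_p + 1)` are Bonferroni-corrected over the two
#' directions.  The inner and outer nulls share one labeling set, so the
#' whole nested test costs `O(n_p * N * M)` t-maps.
#'
#' @param x A `pescar_dataset` (epoched series; coherence is computed
#'   first) or a `pescar_coherence` object.
#' @param config A [pescar_config()].
#' @param seed Seed for the sampled-labeling case (ignored when the
#'   relabelings are enumerated exhaustively).
#' @param labelings Optional pre-built labeling matrix from
#'   [sign_flip_labelings()]; supply the same matrix to
#'   [conventional_test()] to share the permutation scheme across methods.
#' @param ... Unused.
#' @return A `pescar_fit` with observed totals `A12`/`A21`, exceedance
#'   counts `k12`/`k21`, raw and Bonferroni-adjusted p-values, the
#'   directional original connectivity matrices, null distributions,
#'   per-pair cluster table, and weighted/unweighted time-frequency summary
#'   maps.  Supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' sc <- pescar_scenario("continuous", n_subjects = 3, n_subrois = 2,
#'                       n_epochs = 8, seed = 7)
#' cfg <- sim_profile("reduced", freqs = seq(14, 21, 1), n_perm = 7)
#' fit <- pescar(sim_dataset(sc), cfg)
#' tidy(fit)
pescar <- function(x, ...) UseMethod("pescar")

#' @rdname pescar
#' @export
pescar.pescar_dataset <- function(x, config = pescar_config(), seed = 1L,
                                  labelings = NULL, ...) {
  fit <- pescar(coherence_maps(x, config), config = config, seed = seed,
                labelings = labelings)
  fit$realized_snr_db <- attr(x, "realized_snr_db")
  fit
}

#' @rdname pescar
#' @export
pescar.pescar_coherence <- function(x, config = pescar_config(), seed = 1L,
                                    labelings = NULL, ...) {
  t0 <- proc.time()[[3]]
  dm <- dim(x$coh)
  npair <- dm[1]; nf <- dm[2]; ntv <- dm[3]; S <- dm[4]
  cohv <- x$coh
  if (isTRUE(config$fisher_z)) cohv <- atanh(pmin(cohv, 1 - 1e-12))
  dif <- cohv[, , , , 1, drop = FALSE] - cohv[, , , , 2, drop = FALSE]
  dim(dif) <- c(npair, nf, ntv, S)
  d_array <- aperm(dif, c(4, 2, 3, 1))
  dim(d_array) <- c(S, nf * ntv, npair)

  if (is.null(labelings))
    labelings <- sign_flip_labelings(S, config$n_perm, seed)
  thr <- cluster_threshold(S - 1L, config$forming_quantile)
  eng <- perm_engine(d_array, nf, labelings, thr, config$alpha,
                     config$pair_agg)
  np <- eng$n_perm
  pv <- pescar_pvalues(eng$A12[1], eng$A21[1], eng$A12[-1], eng$A21[-1])

  cl_list <- vector("list", npair)
  tmaps <- vector("list", npair)
  for (p in seq_len(npair)) {
    tm <- matrix(eng$tmap_obs[, p], nf, ntv)
    tmaps[[p]] <- tm
    cl <- extract_clusters(tm, thr)
    if (nrow(cl)) {
      cl <- cluster_pvalues(cl, eng$null_max[-1, p])
      cl$pair <- p
      cl$significant <- abs(cl$mass) > eng$crit[p]
      cl_list[[p]] <- cl
    }
  }
  clusters <- dplyr::bind_rows(cl_list)
  if (nrow(clusters) == 0) {
    clusters <- tibble::tibble(pair = integer(), cluster = integer(),
                               sign = integer(), mass = numeric(),
                               n_cells = integer(), p_cluster = numeric(),
                               significant = logical(), mask = list())
  } else {
    clusters <- clusters[, c("pair", "cluster", "sign", "mass", "n_cells",
                             "p_cluster", "significant", "mask")]
  }

  n1 <- max(x$pair_index$roi1_subroi)
  n2 <- max(x$pair_index$roi2_subroi)
  orig <- list(
    "C1>C2" = structure(matrix(eng$a12_obs, n1, n2), A = eng$A12[1],
                        direction = "C1>C2"),
    "C2>C1" = structure(matrix(eng$a21_obs, n1, n2), A = eng$A21[1],
                        direction = "C2>C1")
  )
  sig <- clusters[clusters$significant, , drop = FALSE]
  dims <- c(nf, ntv)
  tf_unweighted <- list(
    "C1>C2" = tf_summary_map(sig, dims, "C1>C2", alpha = 1),
    "C2>C1" = tf_summary_map(sig, dims, "C2>C1", alpha = 1)
  )
  tf_weighted <- list(
    "C1>C2" = tf_summary_map(sig, dims, "C1>C2", alpha = 1, weighted = TRUE,
                             tmaps = tmaps),
    "C2>C1" = tf_summary_map(sig, dims, "C2>C1", alpha = 1, weighted = TRUE,
                             tmaps = tmaps)
  )

  structure(list(
    A12 = eng$A12[1], A21 = eng$A21[1],
    k12 = pv$k[1], k21 = pv$k[2],
    p12 = pv$p[1], p21 = pv$p[2],
    p12_adj = pv$p_adj[1], p21_adj = pv$p_adj[2],
    original = orig,
    null = list("C1>C2" = eng$A12[-1], "C2>C1" = eng$A21[-1]),
    clusters = clusters,
    tmaps = tmaps,
    crit = eng$crit,
    tf_unweighted = tf_unweighted,
    tf_weighted = tf_weighted,
    t_threshold = thr,
    df = eng$df,
    n_perm = np,
    exhaustive = isTRUE(attr(labelings, "exhaustive")),
    alpha = config$alpha,
    pair_index = x$pair_index,
    freqs = x$freqs,
    times = x$times,
    config = config,
    seed = seed,
    elapsed_s = proc.time()[[3]] - t0
  ), class = "pescar_fit")
}

#' @export
print.pescar_fit <- function(x, ...) {
  cat("<pescar_fit>  nested sign-flip permutation test of ROI-ROI connectivity\n")
  cat(sprintf("  n_perm: %d (%s) | t threshold: %.3f (df = %d) | alpha: %g\n",
              x$n_perm, if (x$exhaustive) "exhaustive" else "sampled",
              x$t_threshold, x$df, x$alpha))
  cat(sprintf("  C1>C2: A = %.3f, k = %d, p = %.4g, p_adj = %.4g\n",
              x$A12, x$k12, x$p12, x$p12_adj))
  cat(sprintf("  C2>C1: A = %.3f, k = %d, p = %.4g, p_adj = %.4g\n",
              x$A21, x$k21, x$p21, x$p21_adj))
  nsig <- sum(x$clusters$significant)
  cat(sprintf("  significant clusters: %d across %d pairs\n", nsig,
              length(unique(x$clusters$pair[x$clusters$significant]))))
  invisible(x)
}
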