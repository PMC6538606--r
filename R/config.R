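#' Analysis configuration
#'
#' Bundles the tunable parameters of the whole pipeline: the Morlet
#' time-frequency decomposition, the cluster statistics and the permutation
#' scheme.  The configuration is echoed into every fit and serialized
#' result so that outputs are reproducible.
#'
#' @param freqs Frequency grid in Hz for the wavelet decomposition
#'   (default 8-45 Hz in 1-Hz steps).
#' @param n_cycles Number of Morlet cycles (default 7; must be >= 3).
#' @param decim Integer decimation factor applied to the wavelet time axis
#'   (default 6: 600 Hz epochs give a ~100 Hz effective rate).
#' @param edge_sd Width of the epoch-edge exclusion zone in units of the
#'   wavelet's Gaussian time SD at the lowest analysis frequency (default
#'   2): time points closer than `edge_sd * sigma_t` to an epoch edge are
#'   excluded from the statistical time range.
#' @param n_perm Requested number of permutations `n_p` (default 1000).
#'   With `S` subjects there are `2^S` distinct per-subject condition swaps;
#'   when `2^S <= n_perm` all of them are enumerated (realized
#'   `n_p = 2^S - 1`), otherwise `n_perm` sign patterns are sampled
#'   uniformly with replacement.
#' @param alpha Element-selection threshold: a sub-ROI pair enters the
#'   original connectivity matrix only if its cluster p-value is below
#'   `alpha` (default 0.05).
#' @param forming_quantile Quantile of the central t-distribution used as
#'   the two-sided cluster-forming threshold (default 0.975).
#' @param pair_agg How a pair's matrix entry is formed when several
#'   same-direction clusters are significant: `"largest"` (the
#'   largest-|mass| cluster, default) or `"sum"` (sum of all significant
#'   masses).
#' @param fisher_z Apply the Fisher/arctanh variance-stabilizing transform
#'   to coherence before the paired t-statistics (default `FALSE`:
#'   t-tests operate on raw coherence).
#' @return An object of class `pescar_config`.
#' @seealso [sim_profile()] for configurations matched to the synthetic
#'   simulation studies.
#' @export
pescar_config <- function(freqs = seq(8, 45, by = 1),
                          n_cycles = 7,
                          decim = 6L,
                          edge_sd = 2,
                          n_perm = 1000L,
                          alpha = 0.05,
                          forming_quantile = 0.975,
                          pair_agg = c("largest", "sum"),
                          fisher_z = FALSE) {
  pair_agg <- match.arg(pair_agg)
  if (length(freqs) < 1 || any(freqs <= 0))
    stop_config("freqs must be positive frequencies in Hz")
  if (!is_scalar_num(n_cycles) || n_cycles < 3)
    stop_config("n_cycles must be >= 3")
  if (!is_scalar_num(decim) || decim < 1)
    stop_config("decim must be a positive integer")
  if (!is_scalar_num(n_perm) || n_perm < 1)
    stop_config("n_perm must be >= 1")
  if (!is_scalar_num(alpha) || alpha <= 0 || alpha >= 1)
    stop_config("alpha must lie in (0, 1)")
  if (!is_scalar_num(forming_quantile) || forming_quantile <= 0.5 ||
      forming_quantile >= 1)
    stop_config("forming_quantile must lie in (0.5, 1)")
  structure(list(freqs = as.numeric(freqs), n_cycles = n_cycles,
                 decim = as.integer(decim), edge_sd = edge_sd,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 forming_quantile = forming_quantile, pair_agg = pair_agg,
                 fisher_z = fisher_z),
            class = "pescar_config")
}

#' @export
print.pescar_config <- function(x, ...) {
  cat("<pescar_config>\n")
  cat(sprintf("  freqs: %g-%g Hz (%d) | n_cycles: %g | decim: %d | edge_sd: %g\n",
              min(x$freqs), max(x$freqs), length(x$freqs), x$n_cycles,
              x$decim, x$edge_sd))
  cat(sprintf("  n_perm: %d | alpha: %g | forming quantile: %g | pair_agg: %s\n",
              x$n_perm, x$alpha, x$forming_quantile, x$pair_agg))
  invisible(x)
}

#' Analysis profiles for the synthetic simulation studies
#'
#' Two ready-made configurations matched to the burst simulations (15-20 Hz
#' bursts in 1-s epochs at 600 Hz): `"full"` analyses 8-30 Hz at a 100 Hz
#' effective time resolution with `n_perm = 1000`; `"reduced"` is the
#' desk/CI-scale profile (12-23 Hz, 50 Hz effective rate,
#' `n_perm = 500`) used for Monte-Carlo power runs.
#'
#' @param profile `"full"` or `"reduced"`.
#' @param ... Overrides passed on to [pescar_config()].
#' @return A [pescar_config()].
#' @export
sim_profile <- function(profile = c("reduced", "full"), ...) {
  profile <- match.arg(profile)
  defaults <- if (profile == "full") {
    list(freqs = seq(8, 30, by = 1), decim = 6L, n_perm = 1000L)
  } else {
    list(freqs = seq(12, 23, by = 1), decim = 12L, n_perm = 500L)
  }
  args <- utils::modifyList(defaults, list(...))
  do.call(pescar_config, args)
}
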