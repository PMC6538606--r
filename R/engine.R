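# Shared nested-permutation engine.
#
# The inner (per-pair, cluster-level) null and the outer (total
# connectivity) null reuse ONE set of sign-flip relabelings: for each pair
# the t-maps of all labelings are computed in a single BLAS product, their
# extreme cluster masses are extracted in C, the per-pair max-|mass| null is
# built from the non-identity labelings, and every labeling's clusters are
# ranked against that same null.  Cost is O(n_labelings * n_pairs) t-maps
# instead of O(n_labelings^2).

#' Sign-flip relabeling set
#'
#' Per-subject condition swaps for the paired design, encoded as rows of
#' +1/-1 (a -1 swaps that subject's conditions, i.e. flips the sign of its
#' difference map).  Row 1 is always the identity labeling.  When
#' `2^n_subjects <= n_perm` all distinct relabelings are enumerated
#' (realized `n_p = 2^S - 1`); otherwise `n_perm` patterns are sampled
#' uniformly with replacement.
#'
#' @param n_subjects Number of subjects `S`.
#' @param n_perm Requested permutation count.
#' @param seed Seed for the sampled case.
#' @return Integer matrix `[n_p + 1 x S]` with attribute `exhaustive`.
#' @export
sign_flip_labelings <- function(n_subjects, n_perm, seed = 1) {
  S <- as.integer(n_subjects)
  if (2^S <= n_perm) {
    g <- as.matrix(expand.grid(rep(list(c(1L, -1L)), S), KEEP.OUT.ATTRS = FALSE))
    dimnames(g) <- NULL
    attr(g, "exhaustive") <- TRUE
    return(g)
  }
  M <- withr::with_seed(seed,
    matrix(sample(c(1L, -1L), S * n_perm, replace = TRUE), n_perm, S))
  out <- rbind(rep(1L, S), M)
  attr(out, "exhaustive") <- FALSE
  out
}

# Smallest mass value achieving cluster significance at level alpha.
# The reference set contains the max-|mass| values of ALL labelings,
# identity included, so that every labeling (the observed one and each
# permuted one) is ranked by the same symmetric rule: a cluster is
# significant iff #(all values >= |mass|) / n_lab < alpha, equivalent to
# |mass| > crit.  For the identity labeling this reduces exactly to the
# add-one convention (#(null >= |mass|) + 1)/(n_p + 1) < alpha, because
# the identity's own maximum always counts itself; treating permuted
# labelings by the same rule is what keeps the outer test exact.
crit_value <- function(all_vals, alpha) {
  n <- length(all_vals)
  m_max <- ceiling(alpha * n) - 1
  if (m_max < 1) return(Inf)
  if (m_max >= n) return(0)
  sort(all_vals, decreasing = TRUE)[m_max + 1]
}

# Core engine.  d_array: [subject x cell x pair] per-subject difference
# maps on an nf x nt grid (cells column-major, frequency fastest).
# labelings: [n_lab x S] sign matrix, identity first.  Returns per-labeling
# total connectivity for both directions plus per-pair observables.
perm_engine <- function(d_array, nf, labelings, thr, alpha,
                        pair_agg = "largest") {
  dm <- dim(d_array)
  S <- dm[1]; ncell <- dm[2]; npair <- dm[3]
  stopifnot(ncol(labelings) == S, ncell %% nf == 0)
  n_lab <- nrow(labelings)
  np <- n_lab - 1L
  Lt <- t(labelings * 1.0)

  A12 <- numeric(n_lab)
  A21 <- numeric(n_lab)
  tmap_obs <- matrix(0, ncell, npair)
  null_max <- matrix(0, n_lab, npair)
  crit <- numeric(npair)
  a12_obs <- numeric(npair)
  a21_obs <- numeric(npair)

  for (p in seq_len(npair)) {
    D <- matrix(d_array[, , p], S, ncell)
    Mt <- crossprod(D, Lt) / S                       # cell x labeling means
    m2 <- .colSums(D^2, S, ncell)
    V <- (m2 - S * Mt^2) / (S - 1)
    tol <- 1e-12 * (m2 / (S - 1) + 1e-300)
    bad <- V <= tol                                  # sd ~ 0: degenerate
    V[bad] <- Inf
    Tm <- Mt / sqrt(V / S)
    Tm[bad] <- 0
    ex <- cpp_mass_extremes(Tm, nf, thr)
    mp <- ex[, 1]
    mn <- ex[, 2]
    nm <- pmax(mp, -mn)
    cr <- crit_value(nm, alpha)
    if (pair_agg == "sum") {
      sums <- cpp_mass_sums(Tm, nf, thr, cr)
      a12p <- sums[, 1]
      a21p <- sums[, 2]
    } else {
      a12p <- ifelse(mp > cr, mp, 0)
      a21p <- ifelse(-mn > cr, -mn, 0)
    }
    A12 <- A12 + a12p
    A21 <- A21 + a21p
    tmap_obs[, p] <- Tm[, 1]
    null_max[, p] <- nm
    crit[p] <- cr
    a12_obs[p] <- a12p[1]
    a21_obs[p] <- a21p[1]
  }
  list(A12 = A12, A21 = A21, tmap_obs = tmap_obs, null_max = null_max,
       crit = crit, a12_obs = a12_obs, a21_obs = a21_obs,
       n_perm = np, nf = nf, nt = ncell %/% nf, df = S - 1L)
}

# Permutation p-value with the add-one convention; exceedances include ties
# (null >= observed), which keeps the test exact under exchangeability.
perm_pvalue <- function(observed, null_vals) {
  k <- sum(null_vals >= observed)
  list(k = k, p = (k + 1) / (length(null_vals) + 1))
}
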