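# Independent brute-force implementations used as oracles.  These share no
# code with the package internals: t-statistics come from t.test(), cluster
# search is a plain queue-based flood fill, and every permutation is an
# explicit loop over sign assignments.

# 4-connected components of a logical matrix -> list of cell-index lists.
oracle_flood <- function(mask) {
  comps <- list()
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (!mask[i, j] || seen[i, j]) next
      queue <- list(c(i, j))
      seen[i, j] <- TRUE
      cells <- list()
      while (length(queue)) {
        c0 <- queue[[1]]
        queue <- queue[-1]
        cells[[length(cells) + 1]] <- c0
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          a <- c0[1] + d[1]
          b <- c0[2] + d[2]
          if (a >= 1 && a <= nrow(mask) && b >= 1 && b <= ncol(mask) &&
              mask[a, b] && !seen[a, b]) {
            seen[a, b] <- TRUE
            queue[[length(queue) + 1]] <- c(a, b)
          }
        }
      }
      comps[[length(comps) + 1]] <- cells
    }
  }
  comps
}

# Signed cluster masses of a t-map at a threshold.
oracle_cluster_masses <- function(tm, thr) {
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) tm > thr else tm < -thr
    for (cells in oracle_flood(mask)) {
      mass <- sum(vapply(cells, function(c0) tm[c0[1], c0[2]], 0))
      out[[length(out) + 1]] <- list(sign = sgn, mass = mass)
    }
  }
  out
}

# Full naive nested-permutation pipeline on a coherence array
# [pair x freq x time x subject x condition], enumerating all 2^S sign
# assignments.  Returns observed totals, directional p-values, per-cluster
# p-values of the identity labeling, and the null vectors.
oracle_pescar <- function(coh, alpha = 0.05, forming_q = 0.975) {
  dm <- dim(coh)
  npair <- dm[1]; nf <- dm[2]; nt <- dm[3]; S <- dm[4]
  thr <- qt(forming_q, S - 1)
  signs_all <- as.matrix(expand.grid(rep(list(c(1, -1)), S)))
  id <- which(apply(signs_all, 1, function(r) all(r == 1)))
  ord <- c(id, setdiff(seq_len(nrow(signs_all)), id))
  n_lab <- nrow(signs_all)
  np <- n_lab - 1

  tmap_for <- function(p, sgns) {
    tm <- matrix(0, nf, nt)
    for (fi in seq_len(nf)) {
      for (ti in seq_len(nt)) {
        d <- vapply(seq_len(S), function(s)
          sgns[s] * (coh[p, fi, ti, s, 1] - coh[p, fi, ti, s, 2]), 0)
        if (stats::sd(d) > 1e-12)
          tm[fi, ti] <- unname(stats::t.test(d)$statistic)
      }
    }
    tm
  }

  masses <- lapply(ord, function(l) lapply(seq_len(npair), function(p)
    oracle_cluster_masses(tmap_for(p, signs_all[l, ]), thr)))

  A12 <- numeric(n_lab)
  A21 <- numeric(n_lab)
  obs_clusters <- list()
  for (p in seq_len(npair)) {
    nm <- vapply(seq_len(n_lab), function(li) {
      ms <- vapply(masses[[li]][[p]], function(cl) abs(cl$mass), 0)
      if (length(ms)) max(ms) else 0
    }, 0)
    null <- nm[-1]
    for (li in seq_len(n_lab)) {
      best12 <- 0
      best21 <- 0
      for (cl in masses[[li]][[p]]) {
        pv <- (sum(null >= abs(cl$mass)) + 1) / (np + 1)
        if (li == 1)
          obs_clusters[[length(obs_clusters) + 1]] <-
            list(pair = p, sign = cl$sign, mass = cl$mass, p = pv)
        # selection by the symmetric rule: rank against ALL labelings'
        # maxima (for the identity this equals the add-one p above)
        pv_sel <- sum(nm >= abs(cl$mass)) / n_lab
        if (pv_sel < alpha) {
          if (cl$sign > 0 && cl$mass > best12) best12 <- cl$mass
          if (cl$sign < 0 && -cl$mass > best21) best21 <- -cl$mass
        }
      }
      A12[li] <- A12[li] + best12
      A21[li] <- A21[li] + best21
    }
  }
  p12 <- (sum(A12[-1] >= A12[1]) + 1) / (np + 1)
  p21 <- (sum(A21[-1] >= A21[1]) + 1) / (np + 1)
  list(A12 = A12[1], A21 = A21[1], p12 = p12, p21 = p21,
       p12_adj = min(1, 2 * p12), p21_adj = min(1, 2 * p21),
       clusters = obs_clusters, null12 = A12[-1], null21 = A21[-1])
}

# Naive across-epoch coherence, explicit accumulation loops.
oracle_coherence <- function(x, y) {
  d <- dim(x)
  out <- matrix(0, d[2], d[3])
  for (fi in seq_len(d[2])) {
    for (ti in seq_len(d[3])) {
      cross <- 0i
      ax <- 0
      ay <- 0
      for (e in seq_len(d[1])) {
        cross <- cross + x[e, fi, ti] * Conj(y[e, fi, ti])
        ax <- ax + Mod(x[e, fi, ti])^2
        ay <- ay + Mod(y[e, fi, ti])^2
      }
      den <- sqrt(ax * ay)
      out[fi, ti] <- if (den > 0) Mod(cross) / den else 0
    }
  }
  out
}
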