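test_that("original connectivity matrices aggregate significant masses", {
  pair_index <- tibble::tibble(pair = 1:6,
                               roi1_subroi = rep(1:2, 3),
                               roi2_subroi = rep(1:3, each = 2))
  cl <- tibble::tibble(
    pair = c(1L, 3L, 5L, 5L, 6L),
    sign = c(1L, 1L, -1L, 1L, 1L),
    mass = c(5, 3, -4, 2, 1),
    p_cluster = c(0.01, 0.02, 0.001, 0.004, 0.5)
  )
  m12 <- original_matrix(cl, pair_index, "C1>C2", alpha = 0.05)
  m21 <- original_matrix(cl, pair_index, "C2>C1", alpha = 0.05)
  # three significant C1>C2 masses {+5, +3, +2} and one C2>C1 mass {-4}
  expect_equal(attr(m12, "A"), 10)
  expect_equal(attr(m21, "A"), 4)
  expect_equal(m12[1, 1], 5)
  expect_equal(m12[1, 2], 3)
  expect_equal(m12[1, 3], 2)
  expect_equal(m12[2, 3], 0) # non-significant
  expect_equal(m21[1, 3], -4)

  # the stated toy: significant masses {+5, +3, -4} -> A12 = 8, A21 = 4
  cl2 <- tibble::tibble(pair = 1:3, sign = c(1L, 1L, -1L),
                        mass = c(5, 3, -4), p_cluster = c(0.01, 0.01, 0.01))
  expect_equal(attr(original_matrix(cl2, pair_index, "C1>C2"), "A"), 8)
  expect_equal(attr(original_matrix(cl2, pair_index, "C2>C1"), "A"), 4)

  # nothing significant -> zero matrix, A = 0
  m0 <- original_matrix(cl2, pair_index, "C1>C2", alpha = 0.001)
  expect_true(all(m0 == 0))
  expect_equal(attr(m0, "A"), 0)

  # per-pair aggregation: largest vs sum
  cl3 <- tibble::tibble(pair = c(1L, 1L), sign = c(1L, 1L), mass = c(5, 2),
                        p_cluster = c(0.01, 0.01))
  expect_equal(attr(original_matrix(cl3, pair_index, "C1>C2"), "A"), 5)
  expect_equal(attr(original_matrix(cl3, pair_index, "C1>C2", agg = "sum"),
                    "A"), 7)

  # clusters referencing unknown pairs are an invalid input
  clbad <- tibble::tibble(pair = 99L, sign = 1L, mass = 1,
                          p_cluster = 0.01)
  expect_error(original_matrix(clbad, pair_index, "C1>C2"), "missing")
})

test_that("directional permutation p-values follow (k+1)/(np+1) with Bonferroni", {
  # A larger than all 1000 null values
  null <- runif(1000)
  out <- pescar_pvalues(2, 0, null, null)
  expect_equal(out$p[1], 1 / 1001)
  expect_equal(out$p_adj[1], 2 / 1001)
  # k = 39 exceedances with np = 999 -> p = 0.04
  null2 <- c(rep(5, 39), rep(0.1, 960))
  out2 <- pescar_pvalues(1, 1, null2, null2)
  expect_equal(out2$k[1], 39)
  expect_equal(out2$p[1], 0.04)
  expect_equal(out2$p_adj[1], 0.08)
  # A = 0 with any positive null values -> p = 1 (ties count)
  out3 <- pescar_pvalues(0, 0, c(0, 0, runif(8)), rep(0, 10))
  expect_equal(out3$p, c(1, 1))
  expect_equal(out3$p_adj, c(1, 1))
  # Bonferroni is capped at 1
  out4 <- pescar_pvalues(0.5, 0.5, runif(9), runif(9))
  expect_true(all(out4$p_adj <= 1))
})

test_that("time-frequency summary maps count and weight cluster masks", {
  m1 <- matrix(FALSE, 3, 4); m1[1, 1:2] <- TRUE
  m2 <- matrix(FALSE, 3, 4); m2[1, 1:2] <- TRUE # identical mask
  m3 <- matrix(FALSE, 3, 4); m3[3, 4] <- TRUE
  cl <- tibble::tibble(
    pair = c(1L, 2L, 3L), sign = c(1L, 1L, -1L),
    mass = c(4, 6, -2), p_cluster = c(0.01, 0.01, 0.01),
    mask = list(m1, m2, m3)
  )
  un12 <- tf_summary_map(cl, c(3, 4), "C1>C2")
  expect_equal(un12[1, 1], 2) # two significant pairs share the mask
  expect_equal(sum(un12), 4)
  expect_true(all(un12 == round(un12) & un12 >= 0))
  un21 <- tf_summary_map(cl, c(3, 4), "C2>C1")
  expect_equal(sum(un21), 1)
  # no significant clusters -> zero map
  expect_equal(sum(tf_summary_map(cl, c(3, 4), "C1>C2", alpha = 0.001)), 0)
  # weighted map integrates to the summed masses of the direction
  tmaps <- list(matrix(2, 3, 4), matrix(3, 3, 4), matrix(-1, 3, 4))
  w12 <- tf_summary_map(cl, c(3, 4), "C1>C2", weighted = TRUE,
                        tmaps = tmaps)
  expect_equal(sum(w12), 2 * 2 + 3 * 2) # mask sums times t-values
})

test_that("the nested pipeline matches the exhaustive brute-force oracle", {
  # 3 subjects, 2x2 pairs, 6x8 grid, all 2^3 relabelings; checked at a
  # permissive alpha (clusters can reach significance: min p = 1/8) and at
  # the default alpha (degenerate: nothing can pass, A must be 0)
  coh <- make_coherence(n1 = 2, n2 = 2, nf = 6, nt = 8, n_subjects = 3,
                        seed = 14)
  for (al in c(0.3, 0.05)) {
    cfg <- pescar_config(freqs = 1:6, n_perm = 8, alpha = al)
    fit <- pescar(coh, cfg)
    orc <- oracle_pescar(coh$coh, alpha = al)
    expect_identical(fit$n_perm, 7L)
    expect_true(fit$exhaustive)
    expect_equal(fit$A12, orc$A12, tolerance = 1e-12)
    expect_equal(fit$A21, orc$A21, tolerance = 1e-12)
    expect_equal(fit$p12, orc$p12, tolerance = 1e-12)
    expect_equal(fit$p21, orc$p21, tolerance = 1e-12)
    expect_equal(sort(fit$null[["C1>C2"]]), sort(orc$null12),
                 tolerance = 1e-12)
    expect_equal(sort(fit$null[["C2>C1"]]), sort(orc$null21),
                 tolerance = 1e-12)
    # every observed cluster p matches
    okey <- function(p, s, m) sprintf("%d|%d|%.9f", p, s, m)
    om <- vapply(orc$clusters, function(cl)
      okey(cl$pair, cl$sign, cl$mass), "")
    op <- vapply(orc$clusters, function(cl) cl$p, 0)
    for (i in seq_len(nrow(fit$clusters))) {
      key <- okey(fit$clusters$pair[i], fit$clusters$sign[i],
                  fit$clusters$mass[i])
      expect_equal(fit$clusters$p_cluster[i], op[match(key, om)],
                   tolerance = 1e-12)
    }
    if (al == 0.05) expect_equal(fit$A12, 0)
  }
})

test_that("identical conditions give adjusted p-values of 1", {
  coh <- make_coherence(seed = 5)
  coh$coh[, , , , 2] <- coh$coh[, , , , 1]
  fit <- pescar(coh, pescar_config(freqs = 1:6, n_perm = 8))
  expect_equal(fit$A12, 0)
  expect_equal(fit$A21, 0)
  expect_equal(fit$p12_adj, 1)
  expect_equal(fit$p21_adj, 1)
})

test_that("fits are deterministic and invariant to subject order", {
  coh <- make_coherence(n_subjects = 4, seed = 21)
  cfg <- pescar_config(freqs = 1:6, n_perm = 16, alpha = 0.3)
  f1 <- pescar(coh, cfg)
  f2 <- pescar(coh, cfg)
  expect_identical(f1$A12, f2$A12)
  expect_identical(f1$null, f2$null)
  expect_identical(tidy(f1), tidy(f2))
  # permute subjects (exhaustive labelings -> same multiset of relabelings)
  cohp <- coh
  cohp$coh <- coh$coh[, , , c(3, 1, 4, 2), ]
  f3 <- pescar(cohp, cfg)
  expect_equal(f3$A12, f1$A12, tolerance = 1e-12)
  expect_equal(f3$p12, f1$p12, tolerance = 1e-12)
  expect_equal(f3$p21, f1$p21, tolerance = 1e-12)
  expect_equal(sort(f3$null[["C1>C2"]]), sort(f1$null[["C1>C2"]]),
               tolerance = 1e-12)
})

test_that("A = 0 forces a raw p of 1 and the engine result is coherent", {
  coh <- make_coherence(n_subjects = 5, seed = 33)
  cfg <- pescar_config(freqs = 1:6, n_perm = 32, alpha = 0.2)
  fit <- pescar(coh, cfg)
  expect_gte(fit$A12, 0)
  expect_gte(fit$A21, 0)
  if (fit$A12 == 0) expect_equal(fit$p12, 1)
  # A equals the sum over the original matrix, and matches the cluster
  # table reconstruction through original_matrix()
  expect_equal(fit$A12, sum(abs(fit$original[["C1>C2"]])), tolerance = 1e-12)
  expect_equal(fit$A21, sum(abs(fit$original[["C2>C1"]])), tolerance = 1e-12)
  sig <- fit$clusters
  sig$p_cluster <- ifelse(sig$significant, 0, 1) # significance as computed
  m12 <- original_matrix(sig, fit$pair_index, "C1>C2", alpha = 0.5)
  expect_equal(attr(m12, "A"), fit$A12, tolerance = 1e-12)
  # tf summary maps: unweighted integer counts, weighted sums to masses
  un <- fit$tf_unweighted[["C1>C2"]]
  expect_true(all(un == round(un) & un >= 0))
  w_total <- sum(fit$tf_weighted[["C1>C2"]])
  mass_total <- sum(sig$mass[sig$significant & sig$sign > 0])
  expect_equal(w_total, mass_total, tolerance = 1e-10)
})

test_that("sampled labelings are reproducible and exclude-identity by construction", {
  lab <- sign_flip_labelings(12, 50, seed = 7)
  expect_equal(dim(lab), c(51L, 12L))
  expect_false(attr(lab, "exhaustive"))
  expect_true(all(lab[1, ] == 1))
  expect_identical(lab, sign_flip_labelings(12, 50, seed = 7))
  lab2 <- sign_flip_labelings(3, 1000)
  expect_true(attr(lab2, "exhaustive"))
  expect_equal(nrow(lab2), 8L)
  expect_equal(nrow(unique(as.data.frame(lab2))), 8L)
})
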