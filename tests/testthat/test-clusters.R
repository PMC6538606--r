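test_that("paired t-maps match a textbook paired t-test and its degeneracies", {
  # identical conditions -> all zero
  S <- 4
  c1 <- array(runif(S * 3 * 5), c(S, 3, 5))
  tm0 <- paired_tmap(c1, c1)
  expect_true(all(tm0$t == 0))
  expect_equal(tm0$df, 3L)

  # constant nonzero difference -> sd = 0 -> t = 0 by the degeneracy rule
  c2 <- c1 - 1
  tmc <- paired_tmap(c1, c2)
  expect_true(all(tmc$t == 0))
  expect_gt(attr(tmc, "n_degenerate"), 0)

  # alternating differences across 8 subjects: compare against t.test()
  d <- c(2, 0, 2, 0, 2, 0, 2, 0)
  a1 <- array(0, c(8, 1, 1))
  a2 <- array(-d, c(8, 1, 1))
  tm <- paired_tmap(a1, a2)
  expect_equal(tm$t[1, 1], unname(stats::t.test(d)$statistic),
               tolerance = 1e-12)

  # random maps: every cell agrees with t.test
  set.seed(8)
  x1 <- array(rnorm(6 * 2 * 3), c(6, 2, 3))
  x2 <- array(rnorm(6 * 2 * 3), c(6, 2, 3))
  tmr <- paired_tmap(x1, x2)
  for (fi in 1:2) {
    for (ti in 1:3) {
      expect_equal(tmr$t[fi, ti],
                   unname(stats::t.test(x1[, fi, ti] - x2[, fi, ti])$statistic),
                   tolerance = 1e-10)
    }
  }
  expect_error(paired_tmap(x1[1, , , drop = FALSE], x2[1, , , drop = FALSE]),
               "2 subjects")
})

test_that("the cluster-forming threshold is the t quantile with known anchors", {
  # standard t-table value at df = 1 and the normal limit
  expect_equal(cluster_threshold(1), 12.706, tolerance = 1e-3)
  expect_equal(cluster_threshold(1e7), 1.960, tolerance = 1e-2)
  # monotone decreasing in df
  v <- vapply(c(1, 2, 5, 10, 50), cluster_threshold, 0)
  expect_true(all(diff(v) < 0))
  expect_error(cluster_threshold(0), "df")
})

test_that("cluster extraction obeys 4-connectivity and mass accounting", {
  # the 3x3 toy map: two clusters of mass +6 and -6 at threshold 2
  toy <- rbind(c(3, 3, 0), c(0, 0, 0), c(0, -3, -3))
  cl <- extract_clusters(toy, 2)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$mass, c(6, -6))
  expect_equal(cl$sign[cl$mass > 0], 1L)
  expect_equal(cl$sign[cl$mass < 0], -1L)

  # no suprathreshold points -> empty
  expect_equal(nrow(extract_clusters(matrix(0, 4, 4), 2)), 0)

  # diagonal-only adjacency separates clusters under 4-connectivity
  diagm <- rbind(c(5, 0, 0), c(0, 5, 0), c(0, 0, 5))
  cld <- extract_clusters(diagm, 2)
  expect_equal(nrow(cld), 3)
  expect_true(all(cld$mass == 5))

  # masks partition the suprathreshold set; masses equal sums over masks
  set.seed(12)
  tm <- matrix(rnorm(20 * 30, sd = 2), 20, 30)
  thr <- 1.5
  clr <- extract_clusters(tm, thr)
  supra <- sum(abs(tm) > thr)
  expect_equal(sum(clr$n_cells), supra)
  total_mask <- Reduce(`+`, clr$mask, matrix(0, 20, 30))
  expect_true(all(total_mask <= 1)) # disjoint
  expect_equal(sum(total_mask), supra)
  for (i in seq_len(nrow(clr))) {
    expect_equal(clr$mass[i], sum(tm[clr$mask[[i]]]), tolerance = 1e-12)
    expect_equal(unique(sign(tm[clr$mask[[i]]])), clr$sign[i])
  }
  # against the naive flood-fill oracle: same multiset of masses
  om <- sort(vapply(oracle_cluster_masses(tm, thr), function(x) x$mass, 0))
  expect_equal(sort(clr$mass), om, tolerance = 1e-10)
})

test_that("cluster p-values follow the add-one rank formula", {
  cl <- tibble::tibble(cluster = 1:3, sign = c(1L, -1L, 1L),
                       mass = c(10, -2.5, 0.5), n_cells = c(4L, 2L, 1L),
                       mask = list(NULL, NULL, NULL))
  null <- c(1, 2, 3, 4)
  out <- cluster_pvalues(cl, null)
  expect_equal(out$p_cluster, c((0 + 1) / 5, (2 + 1) / 5, (4 + 1) / 5))
  # mass above every null value with n_p = 1000 -> 1/1001
  out2 <- cluster_pvalues(cl[1, ], runif(1000) * 5)
  expect_equal(out2$p_cluster, 1 / 1001)
})

test_that("swapping all condition labels negates the t-map and cluster roles", {
  set.seed(3)
  c1 <- array(runif(5 * 4 * 6), c(5, 4, 6))
  c2 <- array(runif(5 * 4 * 6), c(5, 4, 6))
  tm <- paired_tmap(c1, c2)
  tm_sw <- paired_tmap(c2, c1)
  expect_equal(tm_sw$t, -tm$t, tolerance = 1e-12)
  a <- extract_clusters(tm$t, 1)
  b <- extract_clusters(-tm$t, 1)
  expect_equal(sort(a$mass), sort(-b$mass), tolerance = 1e-12)
})

test_that("cluster p-values are super-uniform under exchangeability", {
  # engine-level simulation: pure-noise difference maps, exhaustive
  # sign-flip null; empirical P(p <= q) must not exceed q materially
  set.seed(99)
  S <- 6
  nf <- 4
  ntm <- 5
  thr <- cluster_threshold(S - 1)
  lab <- sign_flip_labelings(S, 2^S)
  reps <- 400
  pmin_obs <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    d <- array(rnorm(S * nf * ntm), c(S, nf * ntm, 1))
    eng <- pescar:::perm_engine(d, nf, lab, thr, 0.05)
    nm_obs <- eng$null_max[1, 1]
    if (nm_obs > 0)
      pmin_obs[r] <- (sum(eng$null_max[-1, 1] >= nm_obs) + 1) /
        (eng$n_perm + 1)
    else pmin_obs[r] <- 1
  }
  for (q in c(0.05, 0.1, 0.25)) {
    emp <- mean(pmin_obs <= q)
    # binomial 3-sigma margin
    expect_lte(emp, q + 3 * sqrt(q * (1 - q) / reps))
  }
})
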