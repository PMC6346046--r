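test_that("2x2 construction matches the printed syndromic layout", {
  u <- gene_set(paste0("g", 1:100))
  id_yes <- gene_set(paste0("g", 1:30))   # 30 ID-associated genes
  cluster <- gene_set(paste0("g", c(1:8, 40:70)))  # 8 of them in cluster
  t <- build_two_by_two(id_yes, cluster, u)
  expect_equal(unname(t[1, ]), c(8, 22))
  expect_equal(unname(rowSums(t)), c(30, 70))
  expect_equal(sum(t), 100)

  # degenerate: set = cluster = universe
  t2 <- build_two_by_two(u, u, u)
  expect_equal(unname(as.vector(unclass(t2))), c(100, 0, 0, 0))
  expect_error(build_two_by_two(u, u, character(0)), "universe")
})

test_that("Haldane correction adds 0.5 everywhere, only when needed, once", {
  t <- contingency_table(matrix(c(8, 22, 0, 11), 2, 2, byrow = TRUE))
  tc <- haldane_correct(t)
  expect_equal(unname(unclass(tc)), matrix(c(8.5, 22.5, 0.5, 11.5), 2, 2,
                                           byrow = TRUE), ignore_attr = TRUE)
  expect_true(attr(tc, "corrected"))
  expect_equal(as.vector(haldane_correct(tc)), as.vector(tc))  # no double

  t2 <- contingency_table(matrix(c(1, 29, 3, 8), 2, 2, byrow = TRUE))
  expect_equal(as.vector(haldane_correct(t2)), as.vector(t2))
})

test_that("odds ratios and the Delta statistic match arithmetic oracles", {
  # printed PC syndromic counts: [[1,29],[3,8]] -> 8/87
  t_pc <- haldane_correct(contingency_table(
    matrix(c(1, 29, 3, 8), 2, 2, byrow = TRUE)))
  expect_equal(odds_ratio(t_pc), 8 / 87, tolerance = 1e-14)
  # Haldane-corrected neocortex: [[8.5,22.5],[0.5,11.5]] -> 97.75/11.25
  t_neo <- haldane_correct(contingency_table(
    matrix(c(8, 22, 0, 11), 2, 2, byrow = TRUE)))
  expect_equal(odds_ratio(t_neo), 97.75 / 11.25, tolerance = 1e-14)

  # symmetric table -> OR 1; uncorrected zero in an off-diagonal -> error
  expect_equal(odds_ratio(contingency_table(matrix(3, 2, 2))), 1)
  expect_error(odds_ratio(contingency_table(
    matrix(c(1, 0, 3, 8), 2, 2, byrow = TRUE))), "haldane")

  d <- ror_statistic(odds_ratio(t_neo), 1, odds_ratio(t_pc), 1)
  expect_equal(d, abs(log10((97.75 / 11.25) / (8 / 87))), tolerance = 1e-12)
  expect_equal(d, 1.975394, tolerance = 1e-6)
  expect_equal(ror_statistic(2, 3, 2, 3), 0)
  # tissue swap leaves Delta unchanged
  expect_equal(ror_statistic(5, 2, 1, 7), ror_statistic(1, 7, 5, 2))
  expect_error(ror_statistic(-1, 1, 1, 1), "positive")
})

test_that("the Patefield sampler reproduces margins and the exact law", {
  # margins always reproduced
  x <- patefield_sample(c(7, 5), c(4, 4, 4), 200, seed = 31)
  expect_true(all(apply(x, 3, rowSums) == c(7, 5)))
  expect_true(all(apply(x, 3, colSums) == c(4, 4, 4)))

  # 2x2 (2,2)/(2,2): P(a11 = 0,1,2) = 1/6, 4/6, 1/6
  x2 <- patefield_sample(c(2, 2), c(2, 2), 2e4, seed = 32)
  f <- tabulate(x2[1, 1, ] + 1, 3) / 2e4
  expect_gt(chisq.test(f * 2e4, p = c(1, 4, 1) / 6)$p.value, 0.01)

  # determinism and error paths
  expect_identical(patefield_sample(c(3, 2), c(2, 2, 1), 50, seed = 5),
                   patefield_sample(c(3, 2), c(2, 2, 1), 50, seed = 5))
  expect_error(patefield_sample(c(2, 2), c(3, 2), 10, seed = 1), "equal sums")
  expect_error(patefield_sample(c(-1, 2), c(1, 0), 10, seed = 1),
               "non-negative")

  # agreement with the independent base-R implementation of the same law
  set.seed(99)
  ref <- r2dtable(2e4, c(3, 2), c(2, 2, 1))
  ref_key <- vapply(ref, table_key, character(1))
  ours <- patefield_sample(c(3, 2), c(2, 2, 1), 2e4, seed = 33)
  our_key <- apply(ours, 3, table_key)
  enum <- enumerate_tables(c(3, 2), c(2, 2, 1))
  for (k in names(enum)) {
    se <- sqrt(enum[[k]] * (1 - enum[[k]]) / 2e4)
    expect_lt(abs(mean(our_key == k) - enum[[k]]), 4 * se)
    expect_lt(abs(mean(our_key == k) - mean(ref_key == k)), 0.02)
  }

  # cell means match independence expectations r_i c_j / N
  exp_mean <- outer(c(3, 2), c(2, 2, 1)) / 5
  obs_mean <- apply(ours, c(1, 2), mean)
  expect_equal(obs_mean, exp_mean, tolerance = 0.05)
})

test_that("the permutation test is deterministic with honest add-one p", {
  tabs <- list(
    A_id = contingency_table(matrix(c(8, 22, 40, 330), 2, 2, byrow = TRUE)),
    A_idfree = contingency_table(matrix(c(3, 27, 45, 325), 2, 2, byrow = TRUE)),
    B_id = contingency_table(matrix(c(2, 28, 50, 320), 2, 2, byrow = TRUE)),
    B_idfree = contingency_table(matrix(c(9, 21, 41, 329), 2, 2, byrow = TRUE)))
  r1 <- ror_permutation_test(tabs, B = 5000, seed = 42)
  r2 <- ror_permutation_test(tabs, B = 5000, seed = 42)
  expect_identical(r1$exceedances, r2$exceedances)
  expect_equal(r1$pvalue, (r1$exceedances + 1) / 5001)
  expect_gt(r1$pvalue, 0)

  # Delta at its minimum (identical tissues) -> p near 1
  same <- list(A_id = tabs$A_id, A_idfree = tabs$A_idfree,
               B_id = tabs$A_id, B_idfree = tabs$A_idfree)
  expect_gte(ror_permutation_test(same, B = 2000, seed = 7)$pvalue, 0.5)

  # degenerate margins are refused with the table named
  bad <- tabs
  bad$B_id <- contingency_table(matrix(c(0, 0, 5, 10), 2, 2, byrow = TRUE))
  expect_error(ror_permutation_test(bad, B = 10, seed = 1), "B_id")
})

test_that("exceedances are non-increasing in the observed Delta", {
  tabs <- list(
    A_id = contingency_table(matrix(c(6, 24, 44, 326), 2, 2, byrow = TRUE)),
    A_idfree = contingency_table(matrix(c(5, 25, 45, 325), 2, 2, byrow = TRUE)),
    B_id = contingency_table(matrix(c(5, 25, 45, 325), 2, 2, byrow = TRUE)),
    B_idfree = contingency_table(matrix(c(5, 25, 45, 325), 2, 2, byrow = TRUE)))
  base <- ror_permutation_test(tabs, B = 4000, seed = 11)
  # recompute exceedance counts for a grid of hypothetical Delta values
  # using the same permuted draws (same seed/margins)
  exceed_at <- vapply(c(0, 0.2, 0.5, 1, 2), function(dd) {
    set.seed(11)
    or_star <- lapply(tabs, function(t)
      pcdevnet:::.or_vec(pcdevnet:::.redraw_2x2(t, 4000)))
    sum(abs(log10(or_star$A_id / or_star$A_idfree) -
              log10(or_star$B_id / or_star$B_idfree)) >= dd)
  }, numeric(1))
  expect_true(all(diff(exceed_at) <= 0))
})

test_that("empirical p approaches the enumeration p on tiny margins", {
  # tiny case: every table has margins (2,2)/(2,2); Delta distribution is
  # fully enumerable through the 3^4 combinations of the four a11 values
  t22 <- contingency_table(matrix(c(2, 0, 0, 2), 2, 2, byrow = TRUE))
  tabs <- list(A_id = t22, A_idfree = t22, B_id = t22, B_idfree = t22)
  obs <- ror_permutation_test(tabs, B = 1e5, seed = 13)
  # enumeration oracle
  pa <- c(1, 4, 1) / 6
  or_of <- function(a) {
    cells <- c(a, 2 - a, 2 - a, a)
    if (any(cells == 0)) cells <- cells + 0.5
    (cells[1] * cells[4]) / (cells[2] * cells[3])
  }
  ors <- vapply(0:2, or_of, numeric(1))
  grid <- expand.grid(i = 1:3, j = 1:3, k = 1:3, l = 1:3)
  dstar <- abs(log10(ors[grid$i] / ors[grid$j]) -
                 log10(ors[grid$k] / ors[grid$l]))
  pr <- pa[grid$i] * pa[grid$j] * pa[grid$k] * pa[grid$l]
  p_exact <- sum(pr[dstar >= obs$delta_obs - 1e-12])
  se <- sqrt(p_exact * (1 - p_exact) / 1e5)
  expect_lt(abs(obs$pvalue - p_exact), 2 * se + 2 / 1e5)
})

test_that("four-table and within-list formulations agree with a shared complement", {
  set.seed(51)
  u <- gene_set(paste0("g", 1:2000))
  id_yes <- gene_set(paste0("g", 1:60))
  id_no <- gene_set(paste0("g", 61:120))
  clA <- gene_set(paste0("g", c(1:25, 70:80, 500:800)))
  clB <- gene_set(paste0("g", c(30:40, 90:115, 1000:1300)))
  tabs <- build_ror_tables(id_yes, id_no, clA, clB, u)
  orA_id <- odds_ratio(haldane_correct(tabs$A_id))
  orA_no <- odds_ratio(haldane_correct(tabs$A_idfree))
  # within-list table for tissue A
  wA <- contingency_table(rbind(
    c(25, 35),   # id_yes: 25 in clA
    c(11, 49)))  # id_no: 11 in clA
  # reduction holds when no Haldane kicks in (no zero cells here)
  expect_equal(orA_id / orA_no, odds_ratio(wA), tolerance = 1e-12)
})

test_that("stratified FDR follows BH across strata", {
  mk <- function(p) structure(list(pvalue = p), class = "RORTestResult")
  expect_equal(stratified_fdr(list(mk(0.001), mk(0.04))), c(0.002, 0.04))
  expect_equal(stratified_fdr(list(mk(0.3))), 0.3)
  q <- stratified_fdr(list(mk(0.9), mk(0.01), mk(0.5)))
  expect_true(all(order(q) == order(c(0.9, 0.01, 0.5))))
})

test_that("overlap depletion test matches the exact hypergeometric tail", {
  # printed counts: universe 182, |A| = 59, |B| = 39, overlap 1
  u <- gene_set(paste0("g", 1:182))
  A <- gene_set(paste0("g", 1:59))
  B <- gene_set(paste0("g", c(1, 60:97)))  # overlap exactly 1
  r <- overlap_depletion_test(A, B, u, tail = "less")
  oracle <- sum(vapply(0:1, function(k)
    choose(59, k) * choose(123, 39 - k), numeric(1))) / choose(182, 39)
  expect_equal(r$pvalue, oracle, tolerance = 1e-12)
  expect_equal(r$overlap, "g1")
  # agreement with the independent fisher.test route
  ft <- fisher.test(matrix(c(1, 58, 38, 85), 2, 2), alternative = "less")
  expect_equal(r$pvalue, ft$p.value, tolerance = 1e-9)

  # boundary: disjoint halves
  A2 <- gene_set(paste0("g", 1:91)); B2 <- gene_set(paste0("g", 92:182))
  r2 <- overlap_depletion_test(A2, B2, u, tail = "less")
  expect_equal(r2$pvalue, dhyper(0, 91, 91, 91), tolerance = 1e-12)
  # extreme: A = B, greater tail is the single most extreme table
  r3 <- overlap_depletion_test(A2, A2, u, tail = "greater")
  expect_equal(r3$pvalue, dhyper(91, 91, 91, 91), tolerance = 1e-12)
})
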