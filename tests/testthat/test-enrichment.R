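test_that("background construction applies the expression and biotype rules", {
  cm <- tiny_counts(c(0, 0,    # all zero -> out
                      5, 5,    # constant -> out (zero variance)
                      3, 9),   # in
                    genes = c("gz", "gc", "gv"))
  ann <- data.frame(gene_id = c("gz", "gc", "gv"),
                    length_bp = 1000, biotype = "protein_coding",
                    ortholog_id = c("a", "b", "c"),
                    ortholog_multiplicity = 1)
  bg <- build_background(cm, ann)
  expect_equal(as.character(bg), "gv")

  ann$biotype[3] <- "lincRNA"
  expect_error(build_background(cm, ann), "empty")

  # one-to-one mode additionally requires the ortholog
  ann2 <- data.frame(gene_id = c("gz", "gc", "gv"),
                     length_bp = 1000, biotype = "protein_coding",
                     ortholog_id = c("a", "b", "c"),
                     ortholog_multiplicity = c(1, 1, 2))
  expect_error(build_background(cm, ann2, "expressed_one_to_one"), "empty")
})

test_that("PWF fit is monotone and recovers two-point membership rates", {
  # two-point design: 1 kb genes 10% members, 10 kb genes 50% members
  set.seed(21)
  n <- 4000
  len <- rep(c(1000, 10000), each = n / 2)
  memb <- c(runif(n / 2) < 0.1, runif(n / 2) < 0.5)
  names(memb) <- names(len) <- paste0("g", 1:n)
  pwf <- fit_pwf(memb, len)
  expect_true(all(diff(unclass(pwf)[order(len)]) >= -1e-12))
  expect_lt(abs(mean(unclass(pwf)[len == 1000]) - 0.1), 0.03)
  expect_lt(abs(mean(unclass(pwf)[len == 10000]) - 0.5), 0.03)

  # membership independent of length -> near-flat weights away from the
  # boundary blocks (isotonic fits are degenerate at the extremes)
  set.seed(22)
  len2 <- exp(rnorm(5000, log(2000), 0.6))
  memb2 <- runif(5000) < 0.3
  names(memb2) <- names(len2) <- paste0("h", 1:5000)
  pwf2 <- fit_pwf(memb2, len2)
  central <- quantile(unclass(pwf2), c(0.05, 0.95))
  expect_lt(max(abs(central - 0.3)), 0.05)
  expect_lt(abs(mean(unclass(pwf2)) - 0.3), 0.02)

  expect_warning(flat <- fit_pwf(setNames(rep(TRUE, 60), paste0("x", 1:60)),
                                 rep(1000, 60)), "constant")
  expect_true(all(unclass(flat) == 1 - 1e-6))
  expect_error(fit_pwf(memb[1:10], len[1:10]), "50")
})

test_that("equal-weight Wallenius reduces exactly to Fisher", {
  set.seed(23)
  for (i in 1:50) {
    N <- sample(12:50, 1)
    bg <- gene_set(paste0("g", 1:N))
    st <- gene_set(sample(as.character(bg), sample(2:(N - 2), 1)))
    cl <- gene_set(sample(as.character(bg), sample(2:(N - 2), 1)))
    pw <- wallenius_test(cl, st, bg)$pvalue
    pf <- fisher_test(cl, st, bg)$pvalue
    expect_lt(abs(pw - pf), 1e-9)
  }
})

test_that("the exact hypergeometric worked example is reproduced", {
  bg <- gene_set(paste0("g", 1:20))
  st <- gene_set(paste0("g", 1:5))
  cl <- gene_set(paste0("g", 1:4))
  r <- fisher_test(cl, st, bg)
  expect_equal(r$pvalue, 5 / 4845, tolerance = 1e-12)
  expect_equal(r$overlap, 4)
  expect_equal(wallenius_test(cl, st, bg)$pvalue, 5 / 4845,
               tolerance = 1e-9)
  # extreme tables
  cl0 <- gene_set(paste0("g", 10:18))
  expect_gt(fisher_test(cl0, st, bg)$pvalue, 0.8)
  expect_equal(fisher_test(cl0, st, bg)$fold, 0)
})

test_that("Wallenius at odds 2 matches the biased-urn sampling oracle", {
  # oracle: sequential weighted sampling without replacement
  set.seed(24)
  m1 <- 8; m2 <- 22; n <- 10; omega <- 2
  draws <- vapply(1:50000, function(i)
    sum(sample.int(m1 + m2, n, prob = c(rep(omega, m1), rep(1, m2))) <= m1),
    numeric(1))
  supp <- max(0, n - m2):min(n, m1)
  pmf <- dwallenius(supp, m1, m2, n, omega)
  for (x in c(3, 5, 6)) {
    pmc <- mean(draws >= x)
    se <- sqrt(pmc * (1 - pmc) / length(draws))
    expect_lt(abs(sum(pmf[supp >= x]) - pmc), 3 * se)
  }
  # the law's mean matches the sampling mean
  expect_equal(sum(supp * pmf), mean(draws), tolerance = 0.02)
})

test_that("length-confounded clusters are de-significed by the correction", {
  # membership and set both length-biased the same way: wallenius p > fisher p
  set.seed(25)
  n <- 2000
  len <- exp(rnorm(n, log(2000), 0.8))
  names(len) <- paste0("g", 1:n)
  p_in <- plogis(scale(log(len)) * 1.5 - 1.2)
  cl_genes <- names(len)[runif(n) < p_in]
  st_genes <- names(len)[runif(n) < p_in]
  bg <- gene_set(names(len))
  cl <- gene_set(cl_genes); st <- gene_set(st_genes)
  memb <- setNames(names(len) %in% cl_genes, names(len))
  pwf <- fit_pwf(memb, len)
  pw <- wallenius_test(cl, st, bg, pwf)$pvalue
  pf <- fisher_test(cl, st, bg)$pvalue
  expect_gt(pw, pf)
})

test_that("null sets are calibrated and planted enrichment is detected", {
  set.seed(26)
  N <- 500
  bg <- gene_set(paste0("g", 1:N))
  cl <- gene_set(paste0("g", 1:100))
  ps <- replicate(2000, {
    st <- gene_set(sample(as.character(bg), 25))
    fisher_test(cl, st, bg)$pvalue
  })
  # discrete test: P(p <= 0.05) cannot exceed 0.05; allow band below
  expect_lte(mean(ps <= 0.05), 0.07)
  expect_gte(mean(ps <= 0.05), 0.03 - 0.02)

  # planted 5x enrichment in a synthetic module is detected at q < 0.05
  hits <- vapply(1:20, function(i) {
    s <- study_sim(seed = 600 + i, n_genes = 2000,
                   modules = data.frame(name = c("M1", "M2"),
                                        size = c(400, 400),
                                        direction = c("up", "down"),
                                        span_log2 = 2))
    ann <- generate_annotation(s$truth)
    lists <- generate_disease_lists(s$truth, seed = 700 + i)
    bg2 <- build_background(s$counts, ann)
    cl2 <- gene_set(intersect(s$truth$gene_ids[s$truth$module == "M1"],
                              as.character(bg2)), name = "M1")
    sets <- list(
      ataxia = gene_set(lists$ataxia$gene_id, name = "ataxia"),
      scz = gene_set(lists$scz$gene_id, name = "scz"))
    lens <- setNames(s$truth$length_bp[match(as.character(bg2),
                                             s$truth$gene_ids)],
                     as.character(bg2))
    pwf <- fit_pwf(setNames(as.character(bg2) %in% as.character(cl2),
                            as.character(bg2)), lens)
    res <- test_enrichment(cl2, sets, bg2, pwf)
    res$qvalue[res$set == "ataxia"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123)
  p <- runif(20)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p))
})
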