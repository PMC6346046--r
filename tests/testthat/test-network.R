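test_that("prefilter removes missing-heavy and constant genes", {
  m <- matrix(rnorm(45), 3, 15,
              dimnames = list(c("gA", "gB", "gC"), sprintf("s%02d", 1:15)))
  m["gA", 1:8] <- NA          # 8/15 > 50% missing
  m["gB", ] <- 2              # zero variance
  out <- prefilter_genes(m)
  expect_equal(rownames(out), "gC")
  expect_setequal(attr(out, "removed"), c("gA", "gB"))
})

test_that("signed adjacency maps correlation to [0,1] as specified", {
  set.seed(1)
  x <- rnorm(10)
  em <- rbind(a = x, b = x, c = -x, d = rnorm(10))
  colnames(em) <- sprintf("s%02d", 1:10)
  A <- signed_adjacency(em, beta = 3)
  expect_equal(A["a", "b"], 1)            # cor 1 -> 1
  expect_equal(A["a", "c"], 0)            # cor -1 -> 0
  expect_true(all(A >= 0 & A <= 1))
  expect_equal(diag(A), setNames(rep(0, 4), rownames(em)))
})

test_that("mean connectivity strictly decreases with the power", {
  s <- study_sim(seed = 501, n_genes = 200)
  std <- standardize_rows(variance_stabilize(s$counts))
  scan <- scan_soft_threshold(std, candidates = 1:6)
  expect_true(all(diff(scan$table$mean_connectivity) < 0))
  # pinning wins regardless of the scan
  expect_equal(scan_soft_threshold(std, candidates = 1:6, power = 3)$chosen, 3)
})

test_that("an exact power-law degree sequence fits scale-free topology", {
  # construct a connectivity vector following p(k) ~ k^-2 and check the
  # regression-based fit index directly
  set.seed(2)
  k <- round(10 * (1 - runif(3000))^(-1 / 1.5))  # heavy-tailed degrees
  r2 <- pcdevnet:::.scale_free_rsq(k, n_bins = 10)
  expect_gte(r2, 0.95)
})

test_that("TOM has its closed-form values and is a valid similarity", {
  # complete graph: all a_ij = 1 -> TOM = 1 everywhere
  n <- 6
  A <- matrix(1, n, n); diag(A) <- 0
  rownames(A) <- colnames(A) <- paste0("g", 1:n)
  tom <- compute_tom(NULL, adjacency = A)
  expect_true(all(abs(tom - 1) < 1e-12))

  # two genes with a_ij = 0 and no shared neighbours -> TOM = 0
  A2 <- matrix(0, 4, 4)
  A2[1, 2] <- A2[2, 1] <- 1   # 1-2 connected
  A2[3, 4] <- A2[4, 3] <- 1   # 3-4 connected, disjoint
  rownames(A2) <- colnames(A2) <- paste0("g", 1:4)
  tom2 <- compute_tom(NULL, adjacency = A2)
  expect_equal(tom2[1, 3], 0)

  s <- study_sim(seed = 502, n_genes = 200)
  std <- standardize_rows(variance_stabilize(s$counts))
  tom3 <- compute_tom(std, beta = 3)
  expect_true(isSymmetric(tom3))
  expect_true(all(tom3 >= -1e-12 & tom3 <= 1 + 1e-12))
  expect_true(all(abs(diag(tom3) - 1) < 1e-12))
})

test_that("planted modules are recovered and labelling ignores gene order", {
  s <- study_sim(seed = 503)
  std <- standardize_rows(prefilter_genes(variance_stabilize(s$counts)))
  tom <- compute_tom(std, beta = 3)
  asg <- detect_modules(1 - tom, min_size = 30)
  truth_lab <- s$truth$module[match(asg$gene_id, s$truth$gene_ids)]
  expect_gte(ari(truth_lab, asg$module), 0.8)

  # small blocks (< min size) go unassigned
  asg_strict <- detect_modules(1 - tom, min_size = 60)
  szs <- table(asg_strict$module)
  expect_true(all(szs[names(szs) != "unassigned"] >= 60))

  # permuting gene order leaves module composition unchanged
  perm <- sample(nrow(std))
  asg_p <- detect_modules(1 - tom[perm, perm], min_size = 30)
  merged <- merge(asg, asg_p, by = "gene_id")
  expect_gte(ari(merged$module.x, merged$module.y), 0.999)
})

test_that("module recovery degrades monotonically with added noise", {
  aris <- vapply(c(0.05, 0.3, 0.8), function(a) {
    s <- study_sim(seed = 504, alpha = a)
    std <- standardize_rows(prefilter_genes(variance_stabilize(s$counts)))
    asg <- suppressWarnings(
      detect_modules(1 - compute_tom(std, beta = 3), min_size = 30))
    ari(s$truth$module[match(asg$gene_id, s$truth$gene_ids)], asg$module)
  }, numeric(1))
  expect_true(all(diff(aris) <= 0.05))  # non-increasing up to jitter
  expect_gt(aris[1], aris[3])
})

test_that("eigengenes are unit-norm, oriented, and explain coherent variance", {
  # identical standardized profiles -> eigengene is that profile, ve = 1
  x <- rnorm(10)
  xs <- (x - mean(x)) / sd(x)
  em <- rbind(g1 = xs, g2 = xs, g3 = xs)
  colnames(em) <- sprintf("s%02d", 1:10)
  asg <- data.frame(gene_id = rownames(em), module = "M1")
  eg <- compute_eigengenes(em, asg)
  expect_equal(eg$var_explained[["M1"]], 1)
  expect_equal(abs(cor(eg$profiles["M1", ], xs)), 1)
  expect_equal(sum(eg$profiles["M1", ]^2), 1)
  # orientation: positive correlation with the module mean profile
  expect_gt(sum(eg$profiles["M1", ] * colMeans(em)), 0)

  # coherent module explains more variance than random sets of equal size
  s <- study_sim(seed = 505)
  std <- standardize_rows(prefilter_genes(variance_stabilize(s$counts)))
  mod_genes <- intersect(s$truth$gene_ids[s$truth$module == "M1"],
                         rownames(std))
  asg2 <- data.frame(gene_id = mod_genes, module = "M1")
  ve_mod <- compute_eigengenes(std, asg2)$var_explained[["M1"]]
  set.seed(6)
  ve_rand <- replicate(100, {
    g <- sample(rownames(std), length(mod_genes))
    compute_eigengenes(std, data.frame(gene_id = g, module = "R"))$
      var_explained[["R"]]
  })
  expect_true(all(ve_mod >= ve_rand))
})

test_that("module merging respects the height threshold and is idempotent", {
  set.seed(7)
  base <- rnorm(15)
  mk <- function(n, profile, noise) {
    t(vapply(seq_len(n), function(i) profile + rnorm(15, sd = noise),
             numeric(15)))
  }
  em <- rbind(mk(40, base, 0.1), mk(40, base + rnorm(15, sd = 0.12), 0.1),
              mk(40, rnorm(15), 0.1))
  rownames(em) <- sprintf("g%03d", 1:120)
  colnames(em) <- sprintf("s%02d", 1:15)
  em <- standardize_rows(em)
  asg <- data.frame(gene_id = rownames(em),
                    module = rep(c("M1", "M2", "M3"), each = 40))
  eg <- compute_eigengenes(em, asg)
  cors <- cor(t(eg$profiles))
  expect_gt(cors["M1", "M2"], 0.5)   # near-duplicate modules
  expect_lt(cors["M1", "M3"], 0.5)
  merged <- merge_modules(em, asg, height = 0.5)
  mods <- setdiff(unique(merged$module), "unassigned")
  expect_length(mods, 2)             # M1+M2 merged, M3 kept
  again <- merge_modules(em, merged, height = 0.5)
  expect_identical(merged$module, again$module)
})

test_that("kME behaves like a correlation and core shrinks with threshold", {
  s <- study_sim(seed = 506)
  std <- standardize_rows(prefilter_genes(variance_stabilize(s$counts)))
  asg <- detect_modules(1 - compute_tom(std, beta = 3), min_size = 30)
  eg <- compute_eigengenes(std, asg)
  mm <- module_membership(std, eg)
  expect_true(all(mm >= -1 - 1e-12 & mm <= 1 + 1e-12, na.rm = TRUE))
  mod <- rownames(eg$profiles)[1]

  # a gene equal to the eigengene has kME 1; its negation -1
  std2 <- rbind(std, clone = eg$profiles[mod, ], anti = -eg$profiles[mod, ])
  mm2 <- module_membership(std2, eg)
  expect_equal(unname(mm2["clone", mod]), 1, tolerance = 1e-12)
  expect_equal(unname(mm2["anti", mod]), -1, tolerance = 1e-12)

  sizes <- vapply(c(0.5, 0.8, 0.95), function(th)
    length(core_members(mm, asg, mod, th)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_false("anti" %in% as.character(core_members(mm2, asg, mod, 0.8)))
})

test_that("module-time correlation classifies planted directions", {
  s <- study_sim(seed = 507)
  std <- standardize_rows(prefilter_genes(variance_stabilize(s$counts)))
  asg <- detect_modules(1 - compute_tom(std, beta = 3), min_size = 30)
  eg <- compute_eigengenes(std, asg)
  mtc <- module_time_correlation(eg, s$design)
  # identify each found module with its dominant truth label
  for (i in seq_len(nrow(mtc))) {
    genes <- asg$gene_id[asg$module == mtc$module[i]]
    dom <- names(which.max(table(s$truth$module[match(genes,
                                                      s$truth$gene_ids)])))
    if (dom == "M2") expect_equal(mtc$class[i], "neg")
    if (dom %in% c("M1", "M3")) expect_equal(mtc$class[i], "pos")
  }
  # sign flip of the eigengene flips r
  eg2 <- eg; eg2$profiles[1, ] <- -eg2$profiles[1, ]
  mtc2 <- module_time_correlation(eg2, s$design)
  expect_equal(mtc2$r[1], -mtc$r[1], tolerance = 1e-12)
})

test_that("flat eigengenes are rarely classified as temporal", {
  set.seed(8)
  design <- data.frame(sample_id = sprintf("s%02d", 1:15),
                       time_point = rep(c("P0", "P4", "P8", "P14", "P21"),
                                        each = 3),
                       time_rank = rep(1:5, each = 3), replicate = rep(1:3, 5))
  miscls <- replicate(100, {
    prof <- rnorm(15); prof <- prof / sqrt(sum(prof^2))
    eg <- structure(list(profiles = matrix(prof, 1, 15,
                           dimnames = list("M1", design$sample_id)),
                         var_explained = c(M1 = 0.5)),
                    class = "EigengeneSet")
    module_time_correlation(eg, design)$class != "none"
  })
  expect_lte(mean(miscls), 0.10)
})

test_that("cross-tissue coherence separates coherent from incoherent modules", {
  s <- study_sim(seed = 508)
  std <- standardize_rows(prefilter_genes(variance_stabilize(s$counts)))
  mod_genes <- intersect(s$truth$gene_ids[s$truth$module == "M1"],
                         rownames(std))
  own <- cross_tissue_coherence(mod_genes, std)
  expect_gte(own, 0.5)

  # the same module evaluated in an unrelated "tissue": independent noise
  set.seed(9)
  other <- matrix(rnorm(length(mod_genes) * 15), length(mod_genes), 15,
                  dimnames = list(mod_genes, sprintf("o%02d", 1:15)))
  away <- cross_tissue_coherence(mod_genes, other)
  expect_lt(away, own)
  expect_lt(away, 0.3)

  expect_warning(single <- cross_tissue_coherence(mod_genes[1], std))
  expect_true(is.na(single))
})
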