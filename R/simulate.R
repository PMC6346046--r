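# Synthetic developmental time-course generator.
#
# Emulates the study design this pipeline targets: a purified neuronal
# population profiled at 5 postnatal time points (P0, P4, P8, P14, P21) in
# triplicate, with planted monotone temporal co-expression modules, NB
# counts, log-normal gene lengths and sample depths, and disease gene lists
# with planted module enrichment and planted cross-tissue ID-composition
# bias. Everything is deterministic given the config seed.

#' Simulation configuration
#'
#' Negative-binomial counts are parameterized by (mean mu, dispersion alpha)
#' with variance `mu + alpha * mu^2`. Module trajectories are linear in
#' log2-mean across time ranks with total span `span_log2`; on top of the
#' trend each module carries a per-sample latent factor (log2 sd
#' `latent_sd`) so that modules are identifiable co-expression units and not
#' just shared trends. Gene lengths are log-normal with median 2 kb; sample
#' depth factors log-normal with `sdlog = 0.2` (rescaled to geometric mean
#' 1) to force non-trivial size-factor estimation.
#'
#' @param n_genes Total number of genes.
#' @param time_points Ordered time-point labels.
#' @param n_replicates Replicates per time point.
#' @param modules Data frame with columns `name`, `size`, `direction`
#'   (`"up"`, `"down"` or `"flat"`), `span_log2`.
#' @param alpha NB dispersion; either a single value used for all genes or
#'   a function `function(n)` returning per-gene values.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline mean
#'   parameters (natural-log scale).
#' @param length_meanlog,length_sdlog Log-normal gene-length parameters;
#'   defaults give median 2 kb.
#' @param length_bias_factor Multiplier applied to module genes' lengths
#'   (1 = no length/DE confounding; >1 exercises the length-bias
#'   correction).
#' @param depth_sdlog Log-normal sd of sample depth factors.
#' @param latent_sd Per-module, per-sample latent log2 sd.
#' @param background_span_sd Sd (log2 units across the full time range) of
#'   the small independent temporal slopes given to background genes; real
#'   transcriptomes are not exactly flat outside co-expression modules.
#'   Set to 0 for an exactly-flat background (null simulations).
#' @param frac_noncoding Fraction of background genes annotated non-coding.
#' @param frac_multi_ortholog Fraction of background genes with a
#'   non-one-to-one ortholog mapping.
#' @param seed Mandatory RNG seed.
#' @return A list of class `"SimConfig"`.
#' @export
sim_config <- function(n_genes = 2000,
                       time_points = c("P0", "P4", "P8", "P14", "P21"),
                       n_replicates = 3,
                       modules = data.frame(
                         name = c("M1", "M2", "M3"),
                         size = c(400, 400, 100),
                         direction = c("up", "down", "up"),
                         span_log2 = c(2, 2, 2),
                         stringsAsFactors = FALSE),
                       alpha = 0.05,
                       baseline_meanlog = log(100), baseline_sdlog = 1,
                       length_meanlog = log(2000), length_sdlog = 0.6,
                       length_bias_factor = 1,
                       depth_sdlog = 0.2,
                       latent_sd = 0.25,
                       background_span_sd = 0.15,
                       frac_noncoding = 0.1,
                       frac_multi_ortholog = 0.05,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory for every stochastic call")
  stopifnot(n_genes >= 1, n_replicates >= 1, length(time_points) >= 2)
  if (sum(modules$size) > n_genes)
    stop("module sizes exceed n_genes")
  if (!all(modules$direction %in% c("up", "down", "flat")))
    stop("module direction must be up, down or flat")
  structure(list(
    n_genes = n_genes, time_points = time_points,
    n_replicates = n_replicates, modules = modules, alpha = alpha,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    length_bias_factor = length_bias_factor,
    depth_sdlog = depth_sdlog, latent_sd = latent_sd,
    background_span_sd = background_span_sd,
    frac_noncoding = frac_noncoding,
    frac_multi_ortholog = frac_multi_ortholog,
    seed = as.integer(seed)), class = "SimConfig")
}

#' Generate the simulation ground truth
#'
#' Draws per-gene module labels (non-module genes are `"background"`),
#' baseline means, dispersions, lengths, depth factors and per-module
#' latent sample factors. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `"SyntheticTruth"`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$n_genes
  gene_ids <- sprintf("g%04d", seq_len(n))
  module <- rep("background", n)
  pool <- sample.int(n)  # random placement of module genes
  at <- 1L
  for (k in seq_len(nrow(config$modules))) {
    sz <- config$modules$size[k]
    module[pool[at:(at + sz - 1L)]] <- config$modules$name[k]
    at <- at + sz
  }
  nt_ <- length(config$time_points)
  slope <- rep(0, n)
  for (k in seq_len(nrow(config$modules))) {
    dir <- switch(config$modules$direction[k], up = 1, down = -1, flat = 0)
    slope[module == config$modules$name[k]] <-
      dir * config$modules$span_log2[k] / (nt_ - 1)
  }
  bg <- module == "background"
  if (config$background_span_sd > 0)
    slope[bg] <- stats::rnorm(sum(bg), 0,
                              config$background_span_sd / (nt_ - 1))
  baseline <- rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  alpha <- if (is.function(config$alpha)) config$alpha(n) else
    rep(config$alpha, n)
  length_bp <- pmax(200L, as.integer(round(
    rlnorm(n, config$length_meanlog, config$length_sdlog))))
  if (config$length_bias_factor != 1) {
    in_mod <- module != "background"
    length_bp[in_mod] <- as.integer(round(
      length_bp[in_mod] * config$length_bias_factor))
  }
  tp <- config$time_points
  nt <- length(tp)
  ns <- nt * config$n_replicates
  depth <- rlnorm(ns, 0, config$depth_sdlog)
  depth <- depth / exp(mean(log(depth)))  # geometric mean 1
  latent <- matrix(0, nrow(config$modules), ns,
                   dimnames = list(config$modules$name, NULL))
  if (config$latent_sd > 0 && nrow(config$modules))
    latent[] <- stats::rnorm(length(latent), 0, config$latent_sd)
  # marker panel: 2 target markers from the first "up" module (high
  # baseline, increasing), 4 off-target markers among background genes with
  # baseline forced near zero (flat-low / absent)
  up_mods <- config$modules$name[config$modules$direction == "up"]
  markers <- NULL
  bg_idx <- which(module == "background")
  if (length(up_mods) && length(bg_idx) >= 4) {
    tgt <- sample(which(module == up_mods[1L]), 2L)
    baseline[tgt] <- pmax(baseline[tgt], 100)
    off <- sample(bg_idx, 4L)
    baseline[off] <- 0.5
    markers <- data.frame(
      gene_id = gene_ids[c(tgt, off)],
      cell_type = c("target", "target", "offtype1", "offtype1",
                    "offtype2", "offtype2"),
      expected_profile = c("increasing", "increasing", rep("absent", 4L)),
      stringsAsFactors = FALSE)
  }
  structure(list(
    config = config, gene_ids = gene_ids, module = module, slope = slope,
    baseline = baseline, alpha = alpha, length_bp = length_bp,
    depth_factors = depth, latent = latent, markers = markers,
    count_seed = (config$seed + 1L) %% .Machine$integer.max),
    class = "SyntheticTruth")
}

#' Expected (noise-free) per-time means
#'
#' The trajectory model: `mu_gt = baseline_g * 2^(slope_g * (t - t_mid))`
#' with `slope = dir * span_log2 / (T - 1)` over time ranks `1..T`, so an
#' "up" module gene's expected mean is strictly increasing in time rank and
#' spans `span_log2` log2 units from first to last time point.
#'
#' @param truth A `SyntheticTruth`.
#' @return Gene-by-time matrix of expected means (no depth, no latent).
#' @export
expected_means <- function(truth) {
  cfg <- truth$config
  nt <- length(cfg$time_points)
  slope <- truth$slope
  tmid <- (nt + 1) / 2
  out <- outer(seq_len(cfg$n_genes), seq_len(nt), function(g, t)
    truth$baseline[g] * 2^(slope[g] * (t - tmid)))
  dimnames(out) <- list(truth$gene_ids, cfg$time_points)
  out
}

#' Simulate the count matrix and sample design
#'
#' Counts are NB with mean `expected_mean * depth_factor * 2^latent` and
#' the truth's per-gene dispersion. Deterministic given the truth.
#'
#' @param truth A `SyntheticTruth`.
#' @return List with `counts` (a validated count matrix) and `design`.
#' @export
generate_counts <- function(truth) {
  cfg <- truth$config
  set.seed(truth$count_seed)
  nt <- length(cfg$time_points)
  nr <- cfg$n_replicates
  ns <- nt * nr
  design <- data.frame(
    sample_id = paste0(rep(cfg$time_points, each = nr), "_r",
                       rep(seq_len(nr), nt)),
    time_point = rep(cfg$time_points, each = nr),
    time_rank = rep(seq_len(nt), each = nr),
    replicate = rep(seq_len(nr), nt),
    stringsAsFactors = FALSE)
  em <- expected_means(truth)
  mu <- em[, design$time_rank, drop = FALSE]
  mu <- sweep(mu, 2, truth$depth_factors, `*`)
  mod_idx <- match(truth$module, rownames(truth$latent))
  lat <- matrix(1, cfg$n_genes, ns)
  has <- !is.na(mod_idx)
  if (any(has)) lat[has, ] <- 2^truth$latent[mod_idx[has], , drop = FALSE]
  mu <- mu * lat
  counts <- matrix(rnbinom(length(mu), mu = mu,
                           size = 1 / pmax(truth$alpha, 1e-12)),
                   cfg$n_genes, ns,
                   dimnames = list(truth$gene_ids, design$sample_id))
  storage.mode(counts) <- "double"
  list(counts = validate_count_matrix(counts), design = design)
}

#' Simulate disease gene lists with planted structure
#'
#' Builds (i) an ASD-like list in which ID-comorbid ("yes") genes fall
#' preferentially into tissue cluster A and ID-free ("no") genes into
#' cluster B (or vice versa) at the configured per-tissue composition odds;
#' (ii) a neutral schizophrenia-like list sampled independently of modules;
#' (iii) a generic enriched list (ataxia-like) whose members land in the
#' target module at `enrich_factor` times the background rate.
#'
#' A gene's cluster-A membership probability for the ID-"yes" arm is
#' `base_A * sqrt(odds["A"])` and for the ID-"no" arm
#' `base_A / sqrt(odds["A"])` (similarly for B), so the expected within-list
#' odds ratio in tissue A is approximately `odds["A"]`.
#'
#' @param truth A `SyntheticTruth`.
#' @param tissue_modules Length-2 character vector naming the modules that
#'   play the role of the two tissue clusters (default: first two).
#' @param n_id_yes,n_id_no ASD-list arm sizes.
#' @param composition_odds Named numeric `c(A = , B = )` per-tissue
#'   ID-composition odds; `c(1, 1)` plants no bias.
#' @param n_neutral Neutral-list size.
#' @param n_enriched Enriched-list size.
#' @param enrich_factor Fold enrichment of the enriched list in the target
#'   module (1 = none).
#' @param enrich_module Module targeted by the enriched list.
#' @param seed RNG seed.
#' @return Named list of `DiseaseGeneList` objects (`asd`, `scz`, `ataxia`).
#' @export
generate_disease_lists <- function(truth,
                                   tissue_modules = head(truth$config$modules$name, 2L),
                                   n_id_yes = 60, n_id_no = 60,
                                   composition_odds = c(A = 8, B = 0.1),
                                   n_neutral = 60,
                                   n_enriched = 60, enrich_factor = 5,
                                   enrich_module = tissue_modules[1L],
                                   seed) {
  if (missing(seed)) stop("a seed is mandatory for every stochastic call")
  stopifnot(length(tissue_modules) == 2L)
  set.seed(as.integer(seed))
  n <- truth$config$n_genes
  if (n_id_yes + n_id_no + n_neutral + n_enriched > n)
    stop("requested list sizes exceed the gene pool")
  inA <- truth$module == tissue_modules[1L]
  inB <- truth$module == tissue_modules[2L]
  baseA <- mean(inA); baseB <- mean(inB)
  pick <- function(x, k) x[sample.int(length(x), k)]
  draw_arm <- function(n_arm, pA, pB, exclude) {
    avail_A <- setdiff(truth$gene_ids[inA], exclude)
    avail_B <- setdiff(truth$gene_ids[inB], exclude)
    avail_O <- setdiff(truth$gene_ids[!inA & !inB], exclude)
    grp <- sample(c("A", "B", "O"), n_arm, replace = TRUE,
                  prob = c(pA, pB, max(1 - pA - pB, 0.01)))
    nA <- min(sum(grp == "A"), length(avail_A))
    nB <- min(sum(grp == "B"), length(avail_B))
    nO <- n_arm - nA - nB
    c(pick(avail_A, nA), pick(avail_B, nB), pick(avail_O, nO))
  }
  clamp <- function(p) pmin(pmax(p, 1e-6), 0.9)
  pA_yes <- clamp(baseA * sqrt(composition_odds[[1L]]))
  pB_yes <- clamp(baseB * sqrt(composition_odds[[2L]]))
  pA_no  <- clamp(baseA / sqrt(composition_odds[[1L]]))
  pB_no  <- clamp(baseB / sqrt(composition_odds[[2L]]))
  yes_ids <- draw_arm(n_id_yes, pA_yes, pB_yes, character())
  no_ids <- draw_arm(n_id_no, pA_no, pB_no, yes_ids)
  cats <- c("S", "1", "2", "3", "4")
  asd <- data.frame(
    gene_id = c(yes_ids, no_ids),
    category = sample(cats, n_id_yes + n_id_no, replace = TRUE),
    syndromic = FALSE,
    id_comorbid = rep(c("yes", "no"), c(n_id_yes, n_id_no)),
    stringsAsFactors = FALSE)
  taken <- asd$gene_id
  scz_ids <- sample(setdiff(truth$gene_ids, taken), n_neutral)
  scz <- data.frame(gene_id = scz_ids,
                    category = sample(as.character(1:6), n_neutral,
                                      replace = TRUE),
                    syndromic = FALSE, id_comorbid = "unknown",
                    stringsAsFactors = FALSE)
  taken <- c(taken, scz_ids)
  # enriched list: expected in-module fraction = enrich_factor * base rate
  in_tgt <- truth$module == enrich_module
  p_in <- min(enrich_factor * mean(in_tgt), 0.95)
  n_in <- stats::rbinom(1L, n_enriched, p_in)
  avail_in <- setdiff(truth$gene_ids[in_tgt], taken)
  avail_out <- setdiff(truth$gene_ids[!in_tgt], taken)
  n_in <- min(n_in, length(avail_in))
  atx_ids <- c(sample(avail_in, n_in),
               sample(avail_out, n_enriched - n_in))
  atx <- data.frame(gene_id = atx_ids,
                    category = sample(as.character(1:6), n_enriched,
                                      replace = TRUE),
                    syndromic = FALSE, id_comorbid = "unknown",
                    stringsAsFactors = FALSE)
  list(asd = validate_disease_gene_list(asd, "asd_synthetic"),
       scz = validate_disease_gene_list(scz, "scz_synthetic"),
       ataxia = validate_disease_gene_list(atx, "ataxia_synthetic"))
}

#' Marker panel for the synthetic target population
#'
#' @param truth A `SyntheticTruth`.
#' @return Data frame (gene_id, cell_type, expected_profile).
#' @export
generate_marker_panel <- function(truth) {
  if (is.null(truth$markers))
    stop("truth carries no marker panel (too few background genes)")
  truth$markers
}

#' Build the gene annotation table for a synthetic truth
#'
#' All module genes are protein-coding with one-to-one orthologs; a
#' configured fraction of background genes is annotated non-coding, and a
#' further fraction carries a many-to-one ortholog mapping, exercising the
#' biotype and ortholog filters downstream.
#'
#' @param truth A `SyntheticTruth`.
#' @return Annotation data frame (gene_id, length_bp, biotype, ortholog_id,
#'   ortholog_multiplicity).
#' @export
generate_annotation <- function(truth) {
  cfg <- truth$config
  set.seed((cfg$seed + 2L) %% .Machine$integer.max)
  n <- cfg$n_genes
  biotype <- rep("protein_coding", n)
  mult <- rep(1L, n)
  bg <- which(truth$module == "background")
  n_nc <- round(cfg$frac_noncoding * length(bg))
  if (n_nc > 0) biotype[sample(bg, n_nc)] <- "lincRNA"
  bg_pc <- setdiff(bg, which(biotype != "protein_coding"))
  n_multi <- round(cfg$frac_multi_ortholog * length(bg_pc))
  if (n_multi > 0) mult[sample(bg_pc, n_multi)] <- 2L
  data.frame(gene_id = truth$gene_ids,
             length_bp = truth$length_bp,
             biotype = biotype,
             ortholog_id = paste0("H_", truth$gene_ids),
             ortholog_multiplicity = mult,
             stringsAsFactors = FALSE)
}
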