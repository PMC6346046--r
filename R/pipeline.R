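# Config-driven orchestration: simulate -> qc -> de -> network -> enrich ->
# ror, with a machine-readable run report. Analysis drivers and tests call
# the stage functions directly; run_pipeline() wires them together.

.default_config <- function() list(
  out_dir = "results/pipeline",
  stages = list(simulate = TRUE, qc = TRUE, de = TRUE, network = TRUE,
                enrich = TRUE, ror = TRUE),
  sim = list(),
  paths = list(counts = NULL, design = NULL, annotation = NULL),
  power = 3,
  min_module_size = 30,
  merge_height = 0.5,
  kme_threshold = 0.8,
  q_threshold = 0.05,
  permutations = 1e5,
  background_mode = "expressed_nonzero_variance",
  seed = NULL)

#' Validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a list. Unknown keys are errors
#' (strict mode); defaults are filled in and echoed in the run report.
#' Numeric knobs are range-checked; a seed is required whenever a
#' stochastic stage (simulate or ror) is enabled.
#'
#' @param config Path to a YAML or JSON file, or a named list.
#' @return A validated config list of class `"RunConfig"`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  def <- .default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  if (!is.null(cfg$merge_height) &&
      (cfg$merge_height < 0 || cfg$merge_height > 1))
    stop("merge_height must lie in [0, 1]")
  if (cfg$kme_threshold < 0 || cfg$kme_threshold > 1)
    stop("kme_threshold must lie in [0, 1]")
  if (cfg$q_threshold <= 0 || cfg$q_threshold >= 1)
    stop("q_threshold must lie in (0, 1)")
  if (cfg$min_module_size < 1) stop("min_module_size must be >= 1")
  if (cfg$power <= 0) stop("power must be positive")
  if (cfg$permutations < 1) stop("permutations must be >= 1")
  if ((isTRUE(cfg$stages$simulate) || isTRUE(cfg$stages$ror)) &&
      is.null(cfg$seed))
    stop("a seed is required when a stochastic stage is enabled")
  class(cfg) <- c("RunConfig", class(cfg))
  cfg
}

.log <- function(...) message("[pipeline] ", ...)

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing stage outputs
#' under `config$out_dir` and a JSON run report last. A disabled upstream
#' stage causes dependents to be skipped with a recorded reason rather
#' than an error.
#'
#' @param config A `RunConfig` (or something [validate_config()] accepts).
#' @return The run report (list), invisibly also written to
#'   `run_report.json`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "RunConfig")) config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = config[setdiff(names(config), "stages")],
                 stages = list())
  t0 <- Sys.time()
  env <- new.env()
  mark <- function(stage, status, extra = list()) {
    report$stages[[stage]] <<- c(list(status = status), extra)
    .log(stage, ": ", status)
  }

  # --- simulate / load -------------------------------------------------
  if (isTRUE(config$stages$simulate)) {
    sim_args <- config$sim
    sim_args$seed <- sim_args$seed %||% config$seed
    cfg <- do.call(sim_config, sim_args)
    env$truth <- generate_truth(cfg)
    gc <- generate_counts(env$truth)
    env$counts <- gc$counts; env$design <- gc$design
    env$ann <- generate_annotation(env$truth)
    env$lists <- generate_disease_lists(env$truth,
                                        seed = (config$seed + 3) %% .Machine$integer.max)
    write_count_matrix(env$counts, file.path(config$out_dir, "counts.tsv"))
    write_tsv(env$design, file.path(config$out_dir, "design.tsv"))
    write_tsv(env$ann, file.path(config$out_dir, "annotation.tsv"))
    for (nm in names(env$lists))
      write_tsv(env$lists[[nm]],
                file.path(config$out_dir, paste0("genelist_", nm, ".tsv")))
    mark("simulate", "ok", list(n_genes = nrow(env$counts),
                                n_samples = ncol(env$counts)))
  } else if (!is.null(config$paths$counts)) {
    env$counts <- read_count_matrix(config$paths$counts)
    env$design <- read_sample_design(config$paths$design)
    env$ann <- read_gene_annotation(config$paths$annotation)
    mark("simulate", "skipped (inputs loaded from files)")
  } else {
    mark("simulate", "skipped")
  }

  has_data <- !is.null(env$counts)

  # --- qc ---------------------------------------------------------------
  if (isTRUE(config$stages$qc) && has_data) {
    env$sf <- estimate_size_factors(env$counts)
    env$vsd <- variance_stabilize(env$counts, env$sf)
    pca <- pca_qc(env$vsd, env$design)
    write_tsv(data.frame(sample_id = rownames(pca$scores), pca$scores),
              file.path(config$out_dir, "pca_scores.tsv"))
    extra <- list(silhouette = pca$silhouette, verdict = pca$verdict)
    if (!is.null(env$truth)) {
      rpkm <- compute_rpkm(env$counts, env$ann)
      mr <- marker_report(rpkm, generate_marker_panel(env$truth), env$design)
      write_tsv(mr$report, file.path(config$out_dir, "marker_report.tsv"))
      extra$marker_verdict <- mr$verdict
    }
    mark("qc", "ok", extra)
  } else mark("qc", if (has_data) "skipped" else "skipped (no data)")

  # --- de ---------------------------------------------------------------
  if (isTRUE(config$stages$de) && has_data) {
    if (is.null(env$sf)) env$sf <- estimate_size_factors(env$counts)
    de <- lrt_time_course(env$counts, env$design, size_factors = env$sf)
    sp <- split_by_trend(de, env$design, config$q_threshold)
    env$de <- sp$de; env$de_pos <- sp$pos; env$de_neg <- sp$neg
    write_tsv(sp$de, file.path(config$out_dir, "de_results.tsv"))
    mark("de", "ok", list(n_pos = length(sp$pos), n_neg = length(sp$neg)))
  } else mark("de", if (has_data) "skipped" else "skipped (no data)")

  # --- network ----------------------------------------------------------
  if (isTRUE(config$stages$network) && has_data) {
    if (is.null(env$vsd)) {
      if (is.null(env$sf)) env$sf <- estimate_size_factors(env$counts)
      env$vsd <- variance_stabilize(env$counts, env$sf)
    }
    expr <- prefilter_genes(env$vsd)
    env$std <- standardize_rows(expr)
    tom <- compute_tom(env$std, beta = config$power)
    assignment <- detect_modules(1 - tom, min_size = config$min_module_size)
    assignment <- merge_modules(env$std, assignment,
                                height = config$merge_height)
    env$modules <- assignment
    env$eigengenes <- compute_eigengenes(env$std, assignment)
    env$kme <- module_membership(env$std, env$eigengenes)
    mtc <- module_time_correlation(env$eigengenes, env$design)
    kme_own <- rep(NA_real_, nrow(assignment))
    has_mod <- assignment$module != "unassigned"
    kme_own[has_mod] <- env$kme[cbind(assignment$gene_id[has_mod],
                                      assignment$module[has_mod])]
    write_tsv(data.frame(assignment, kME = kme_own),
              file.path(config$out_dir, "modules.tsv"))
    write_tsv(data.frame(module = rownames(env$eigengenes$profiles),
                         env$eigengenes$profiles, check.names = FALSE),
              file.path(config$out_dir, "eigengenes.tsv"))
    write_tsv(mtc, file.path(config$out_dir, "module_time_correlation.tsv"))
    env$mtc <- mtc
    mark("network", "ok",
         list(n_modules = nrow(env$eigengenes$profiles),
              sizes = as.list(table(assignment$module))))
  } else mark("network", if (has_data) "skipped" else "skipped (no data)")

  # --- enrich -----------------------------------------------------------
  if (isTRUE(config$stages$enrich) && has_data) {
    if (is.null(env$modules)) {
      mark("enrich", "skipped (network stage did not run)")
    } else if (is.null(env$lists)) {
      mark("enrich", "skipped (no gene lists)")
    } else {
      bg <- build_background(env$counts, env$ann, config$background_mode)
      lens <- env$ann$length_bp[match(as.character(bg), env$ann$gene_id)]
      names(lens) <- as.character(bg)
      rows <- list()
      sets <- lapply(env$lists, function(l)
        filter_sfari_categories(l, c(1:4), include_syndromic = TRUE))
      for (mod in setdiff(unique(env$modules$module), "unassigned")) {
        cl <- gene_set(env$modules$gene_id[env$modules$module == mod],
                       name = mod)
        membership <- setNames(names(lens) %in% as.character(cl),
                               names(lens))
        pwf <- fit_pwf(membership, lens)
        rows[[mod]] <- test_enrichment(cl, sets, bg, pwf)
      }
      enr <- do.call(rbind, rows)
      write_tsv(enr, file.path(config$out_dir, "enrichment.tsv"))
      env$background <- bg
      mark("enrich", "ok", list(n_tests = nrow(enr)))
    }
  } else mark("enrich", if (has_data) "skipped" else "skipped (no data)")

  # --- ror --------------------------------------------------------------
  if (isTRUE(config$stages$ror) && has_data) {
    if (is.null(env$modules) || is.null(env$lists)) {
      mark("ror", "skipped (needs network modules and gene lists)")
    } else {
      mtc <- env$mtc
      tissue_mods <- head(mtc$module[order(mtc$pvalue)], 2)
      clA <- gene_set(env$modules$gene_id[env$modules$module == tissue_mods[1]],
                      name = tissue_mods[1])
      clB <- gene_set(env$modules$gene_id[env$modules$module == tissue_mods[2]],
                      name = tissue_mods[2])
      universe <- gene_set(rownames(env$counts), name = "all_genes")
      strata <- c("syndromic_only", "categories_1_4", "all")
      res <- list()
      for (i in seq_along(strata)) {
        parts <- partition_by_id_status(env$lists$asd, strata[i])
        if (!length(parts$id_yes) || !length(parts$id_no)) next
        tabs <- build_ror_tables(parts$id_yes, parts$id_no, clA, clB,
                                 universe)
        res[[strata[i]]] <- tryCatch(
          ror_permutation_test(tabs, B = config$permutations,
                               seed = (config$seed + 7 + i) %%
                                 .Machine$integer.max),
          error = function(e) NULL)
      }
      res <- Filter(Negate(is.null), res)
      if (length(res)) {
        q <- stratified_fdr(res)
        out <- data.frame(stratum = names(res),
                          delta = vapply(res, `[[`, numeric(1), "delta_obs"),
                          pvalue = vapply(res, `[[`, numeric(1), "pvalue"),
                          qvalue = q)
        write_tsv(out, file.path(config$out_dir, "ror_results.tsv"))
        mark("ror", "ok", list(strata = names(res)))
      } else mark("ror", "skipped (no usable strata)")
    }
  } else mark("ror", if (has_data) "skipped" else "skipped (no data)")

  report$wall_time_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(report)
}
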