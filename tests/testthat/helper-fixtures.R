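# Shared fixtures, built in code.

tiny_counts <- function(values = 0:5, genes = c("g1", "g2", "g3"),
                        samples = c("s1", "s2")) {
  m <- matrix(values, length(genes), length(samples), byrow = TRUE,
              dimnames = list(genes, samples))
  storage.mode(m) <- "double"
  validate_count_matrix(m)
}

tiny_design <- function(samples = c("s1", "s2"),
                        time_points = c("P0", "P4")) {
  data.frame(sample_id = samples, time_point = time_points,
             time_rank = seq_along(time_points), replicate = 1L,
             stringsAsFactors = FALSE)
}

# Study-shaped simulation: 5 time points x 3 replicates.
study_sim <- function(seed, n_genes = 1000,
                      modules = data.frame(
                        name = c("M1", "M2", "M3"),
                        size = c(50, 50, 50),
                        direction = c("up", "down", "up"),
                        span_log2 = c(2, 2, 2),
                        stringsAsFactors = FALSE), ...) {
  cfg <- sim_config(n_genes = n_genes, modules = modules, seed = seed, ...)
  truth <- generate_truth(cfg)
  c(list(truth = truth), generate_counts(truth))
}

# Flat-null simulation used for calibration checks.
null_sim <- function(seed, n_genes = 500, alpha = 0.1) {
  study_sim(seed, n_genes = n_genes,
            modules = data.frame(name = character(0), size = integer(0),
                                 direction = character(0),
                                 span_log2 = numeric(0)),
            alpha = alpha, latent_sd = 0, background_span_sd = 0)
}

# Adjusted Rand index between two label vectors (independent of the
# clustering route under test).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Exhaustive enumeration of 2xC tables with fixed margins and their
# central (Fisher) probabilities; oracle for the Patefield sampler.
enumerate_tables <- function(row_margins, col_margins) {
  stopifnot(length(row_margins) == 2)
  cc <- length(col_margins)
  grid <- expand.grid(lapply(col_margins, function(m) 0:m))
  keep <- rowSums(grid) == row_margins[1]
  grid <- grid[keep, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(grid))) {
    top <- as.numeric(grid[i, ])
    bot <- col_margins - top
    if (any(bot < 0)) next
    t <- rbind(top, bot)
    lp <- sum(lfactorial(row_margins)) + sum(lfactorial(col_margins)) -
      lfactorial(sum(row_margins)) - sum(lfactorial(t))
    out[[paste(t, collapse = ",")]] <- exp(lp)
  }
  out
}

table_key <- function(t) paste(t, collapse = ",")
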