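# Normalization, RPKM, variance stabilization and sample-level QC.

#' Median-of-ratios size factors
#'
#' For each sample j, the factor is the median over reference genes (genes
#' with positive counts in every sample) of `count_gj / geomean_g`, where
#' `geomean_g` is the gene's geometric mean across samples. Factors are
#' rescaled to geometric mean 1 so they are comparable across runs.
#'
#' @param counts Count matrix (genes x samples); `NA` cells are excluded
#'   from the reference set.
#' @return Named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  cm <- unclass(counts)
  ref <- rowSums(is.na(cm)) == 0 & apply(cm, 1, function(x) all(x > 0))
  if (!any(ref))
    stop("no gene has positive counts in all samples; ",
         "supply a pseudo-reference or filter samples")
  lg <- log(cm[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(sweep(lg, 1, geo)), 2, median)
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(cm)
  sf
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm_gj = count_gj / ((length_g / 1e3) * (mapped_total_j / 1e6))`.
#' Mapped totals default to column sums of the count matrix, the only
#' estimate available from a count table alone.
#'
#' @param counts Count matrix.
#' @param ann Gene annotation (provides `length_bp`).
#' @param mapped_totals Optional per-sample mapped-read totals.
#' @return Matrix of RPKM values with attribute `scale = "rpkm"`; genes
#'   without a length are dropped with a warning.
#' @export
compute_rpkm <- function(counts, ann, mapped_totals = NULL) {
  cm <- unclass(counts)
  if (is.null(mapped_totals)) mapped_totals <- colSums(cm, na.rm = TRUE)
  stopifnot(all(mapped_totals > 0), length(mapped_totals) == ncol(cm))
  len <- ann$length_bp[match(rownames(cm), ann$gene_id)]
  drop <- is.na(len)
  if (any(drop)) {
    warning(sum(drop), " gene(s) without length dropped from RPKM")
    cm <- cm[!drop, , drop = FALSE]
    len <- len[!drop]
  }
  out <- sweep(cm / (len / 1e3), 2, mapped_totals / 1e6, `/`)
  attr(out, "scale") <- "rpkm"
  out
}

#' Variance-stabilizing transform
#'
#' `log2(count / size_factor + pseudocount)`. This is a deliberately simple
#' monotone stabilizer of normalized counts (see the methods vignette);
#' downstream steps consume only the stabilized values.
#'
#' @param counts Count matrix.
#' @param size_factors Per-sample positive factors.
#' @param pseudocount Added before the log (default 1).
#' @return Matrix with attribute `scale = "log_stabilized"`.
#' @export
variance_stabilize <- function(counts, size_factors = estimate_size_factors(counts),
                               pseudocount = 1) {
  stopifnot(all(size_factors > 0))
  out <- log2(sweep(unclass(counts), 2, size_factors, `/`) + pseudocount)
  attr(out, "scale") <- "log_stabilized"
  out
}

#' Standardize each gene to mean 0, sd 1
#'
#' The sample standard deviation uses denominator `n - 1` — material at
#' triplicate scale. Zero-variance and all-missing rows are dropped with a
#' warning. Idempotent.
#'
#' @param em Expression matrix (genes x samples).
#' @return Standardized matrix with attribute `scale = "standardized"`.
#' @export
standardize_rows <- function(em) {
  m <- unclass(em)
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1, sd, na.rm = TRUE)
  bad <- is.na(s) | s == 0
  if (any(bad)) {
    warning(sum(bad), " zero-variance or all-missing gene(s) dropped")
    m <- m[!bad, , drop = FALSE]
    mu <- mu[!bad]; s <- s[!bad]
  }
  out <- (m - mu) / s
  attr(out, "scale") <- "standardized"
  out
}

#' PCA on samples with a time-point separation verdict
#'
#' PCA of the centered sample-by-gene matrix (all non-zero-variance genes
#' by default). The separation verdict is the mean silhouette width of the
#' time-point labels in PC1-PC2 score space: `"separated"` iff it exceeds
#' `threshold`.
#'
#' @param em Expression matrix (genes x samples).
#' @param design Sample design (provides `time_point`).
#' @param n_components Number of components (reduced if samples are few).
#' @param threshold Silhouette threshold for the verdict (default 0.25).
#' @return List of class `"PCAResult"`: `scores` (samples x PCs),
#'   `loadings`, `var_explained`, `silhouette`, `verdict`.
#' @export
pca_qc <- function(em, design, n_components = 5, threshold = 0.25) {
  m <- unclass(em)
  m <- m[apply(m, 1, function(x) sd(x, na.rm = TRUE) > 0), , drop = FALSE]
  x <- t(m)  # samples x genes
  n_components <- min(n_components, nrow(x) - 1L, ncol(x))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  labs <- design$time_point[match(rownames(x), design$sample_id)]
  sil <- NA_real_
  if (length(unique(labs)) >= 2L) {
    d <- dist(scores[, 1:2, drop = FALSE])
    sil <- mean(cluster::silhouette(as.integer(factor(labs)), d)[, "sil_width"])
  }
  structure(list(scores = scores, loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
                 var_explained = ve[seq_len(n_components)],
                 silhouette = sil,
                 verdict = if (!is.na(sil) && sil > threshold) "separated"
                           else "not_separated"),
            class = "PCAResult")
}

#' Covariate association with principal components
#'
#' Pearson correlation test of a per-sample covariate (e.g. an RNA-quality
#' score) against each component's scores, BH-adjusted across components.
#' A constant covariate yields p = 1 everywhere with a warning.
#'
#' @param pca A `PCAResult`.
#' @param covariate Numeric vector, one value per sample.
#' @return Data frame (component, r, pvalue, qvalue).
#' @export
covariate_pc_association <- function(pca, covariate) {
  stopifnot(length(covariate) == nrow(pca$scores))
  k <- ncol(pca$scores)
  if (sd(covariate) == 0) {
    warning("constant covariate; all p-values set to 1")
    return(data.frame(component = colnames(pca$scores),
                      r = 0, pvalue = 1, qvalue = 1))
  }
  r <- p <- numeric(k)
  for (i in seq_len(k)) {
    ct <- cor.test(pca$scores[, i], covariate)
    r[i] <- unname(ct$estimate); p[i] <- ct$p.value
  }
  data.frame(component = colnames(pca$scores), r = r, pvalue = p,
             qvalue = p.adjust(p, "BH"))
}

#' Marker-panel report and capture-purity verdict
#'
#' Per-marker mean RPKM per time point, plus a purity verdict: `"enriched"`
#' iff the target markers' overall mean RPKM exceeds the off-target
#' markers' by at least `ratio`; `"indeterminate"` when either side of the
#' comparison is absent from the matrix.
#'
#' @param rpkm RPKM matrix.
#' @param panel Marker table (gene_id, cell_type, expected_profile).
#' @param design Sample design.
#' @param ratio Required target/off-target mean-RPKM ratio (default 10).
#' @return List: `report` (one row per panel row, mean RPKM per time
#'   point, `present` flag) and `verdict`.
#' @export
marker_report <- function(rpkm, panel, design, ratio = 10) {
  m <- unclass(rpkm)
  tps <- unique(design$time_point[order(design$time_rank)])
  prof <- matrix(NA_real_, nrow(panel), length(tps),
                 dimnames = list(panel$gene_id, tps))
  present <- panel$gene_id %in% rownames(m)
  for (i in which(present)) {
    for (tp in tps) {
      sj <- design$sample_id[design$time_point == tp]
      sj <- intersect(sj, colnames(m))
      prof[i, tp] <- mean(m[panel$gene_id[i], sj], na.rm = TRUE)
    }
  }
  report <- data.frame(panel, present = present, prof,
                       check.names = FALSE, stringsAsFactors = FALSE)
  is_tgt <- panel$cell_type == "target" & present
  is_off <- panel$cell_type != "target" & present
  verdict <- if (!any(is_tgt) || !any(is_off)) "indeterminate"
  else if (mean(prof[is_tgt, ], na.rm = TRUE) >=
           ratio * mean(prof[is_off, ], na.rm = TRUE)) "enriched"
  else "not_enriched"
  list(report = report, verdict = verdict)
}
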