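# Negative-binomial time-course differential expression.
#
# The model: counts y_gj ~ NB(mu_gj, alpha_g) with log link and per-sample
# offsets log(size factor). The full model has one mean per time point
# (time as an unordered factor), the reduced model a common mean; the test
# is the likelihood-ratio statistic against chi-square with T-1 df, BH
# adjusted across tested genes. Significant genes are split into positively
# and negatively time-correlated clusters by the sign of the Spearman
# correlation between fitted per-time means and time ranks.

#' Estimate per-gene NB dispersions
#'
#' Method-of-moments within time points, shrunk toward a mean-dispersion
#' trend. For normalized counts `z = y/s`, within a time point
#' `Var(z) ~ mu * mean(1/s) + alpha * mu^2`; the per-gene estimate pools the
#' per-time-point moment estimates weighted by their degrees of freedom,
#' truncated at 0. The trend is a regression of these raw estimates on
#' `1/mean` across genes; the returned value is the weighted average
#' of raw and trend estimates (weight `shrink_weight` on the trend),
#' floored at 1e-8. Genes with all-zero counts
#' get `NA` (excluded from testing).
#'
#' @param counts Count matrix.
#' @param design Sample design (provides `time_point`).
#' @param size_factors Per-sample size factors.
#' @param shrink_weight Weight on the trend (default 0.9; at triplicate scale the per-gene moment estimate carries only ~10 df, so the cross-gene trend dominates).
#' @return Named numeric vector of dispersions (`NA` for all-zero genes).
#' @export
estimate_dispersions <- function(counts, design,
                                 size_factors = estimate_size_factors(counts),
                                 shrink_weight = 0.9) {
  cm <- unclass(counts)
  sf <- size_factors[colnames(cm)]
  tp <- design$time_point[match(colnames(cm), design$sample_id)]
  reps <- table(tp)
  if (max(reps) < 2) stop("need >= 2 replicates in at least one time point")
  z <- sweep(cm, 2, sf, `/`)
  cinv <- mean(1 / sf)
  raw <- rep(NA_real_, nrow(cm))
  gmean <- rowMeans(z, na.rm = TRUE)
  groups <- split(seq_len(ncol(cm)), tp)
  num <- den <- rep(0, nrow(cm))
  for (idx in groups) {
    if (length(idx) < 2) next
    m <- rowMeans(z[, idx, drop = FALSE], na.rm = TRUE)
    v <- apply(z[, idx, drop = FALSE], 1, var, na.rm = TRUE)
    w <- length(idx) - 1
    ok <- !is.na(m) & m > 0 & !is.na(v)
    num[ok] <- num[ok] + w * (v[ok] - m[ok] * cinv) / m[ok]^2
    den[ok] <- den[ok] + w
  }
  has <- den > 0 & gmean > 0
  raw[has] <- pmax(num[has] / den[has], 0)
  # trend: alpha as a smooth function of 1/mean across genes
  fit_ok <- has & is.finite(raw)
  trend <- rep(NA_real_, nrow(cm))
  if (sum(fit_ok) >= 10) {
    tf <- lm(raw[fit_ok] ~ I(1 / gmean[fit_ok]))
    trend[fit_ok] <- pmax(coef(tf)[1] + coef(tf)[2] / gmean[fit_ok], 0)
  } else trend[fit_ok] <- mean(raw[fit_ok])
  alpha <- rep(NA_real_, nrow(cm))
  alpha[fit_ok] <- pmax((1 - shrink_weight) * raw[fit_ok] +
                          shrink_weight * trend[fit_ok], 1e-8)
  names(alpha) <- rownames(cm)
  alpha
}

#' NB GLM likelihood-ratio test for a time effect
#'
#' Per gene, fits the NB GLM (log link, fixed dispersion, offsets = log
#' size factors) with time as an unordered factor and with an intercept
#' only; the LRT statistic is the deviance difference, referred to
#' chi-square with T-1 df. Fitting is iteratively reweighted least squares
#' (deviance tolerance 1e-8, max 100 iterations). Genes whose fit fails to
#' converge are flagged with missing p.
#'
#' @param counts Count matrix.
#' @param design Sample design.
#' @param dispersions Per-gene dispersions from [estimate_dispersions()].
#' @param size_factors Per-sample size factors.
#' @return Data frame of class `"DEResult"`: gene_id, stat, df, pvalue,
#'   qvalue (BH across tested genes), dispersion, converged; attribute
#'   `fitted_means` holds the gene-by-time fitted (normalized) means.
#' @export
lrt_time_course <- function(counts, design,
                            dispersions = NULL,
                            size_factors = estimate_size_factors(counts)) {
  cm <- unclass(counts)
  sf <- size_factors[colnames(cm)]
  ord <- match(colnames(cm), design$sample_id)
  tp <- factor(design$time_point[ord],
               levels = unique(design$time_point[order(design$time_rank)]))
  if (nlevels(tp) < 2) stop("time factor needs >= 2 levels")
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, design, size_factors)
  ng <- nrow(cm)
  stat <- p <- rep(NA_real_, ng)
  conv <- rep(FALSE, ng)
  fitted_means <- matrix(NA_real_, ng, nlevels(tp),
                         dimnames = list(rownames(cm), levels(tp)))
  off <- log(sf)
  df <- nlevels(tp) - 1L
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  for (g in seq_len(ng)) {
    a <- dispersions[g]
    if (is.na(a)) next
    y <- cm[g, ]
    ok <- !is.na(y)
    if (sum(ok) < nlevels(tp) + 1) next
    fam <- MASS::negative.binomial(theta = 1 / a)
    res <- tryCatch({
      full <- glm(y[ok] ~ tp[ok] + offset(off[ok]), family = fam,
                  control = ctrl)
      red <- glm(y[ok] ~ 1 + offset(off[ok]), family = fam, control = ctrl)
      list(stat = max(red$deviance - full$deviance, 0),
           mu = tapply(fitted(full) / sf[ok], tp[ok], mean),
           conv = full$converged && red$converged)
    }, error = function(e) NULL)
    if (is.null(res) || !res$conv) next
    stat[g] <- res$stat
    p[g] <- stats::pchisq(res$stat, df, lower.tail = FALSE)
    fitted_means[g, names(res$mu)] <- res$mu
    conv[g] <- TRUE
  }
  q <- rep(NA_real_, ng)
  q[!is.na(p)] <- p.adjust(p[!is.na(p)], "BH")
  out <- data.frame(gene_id = rownames(cm), stat = stat, df = df,
                    pvalue = p, qvalue = q,
                    dispersion = unname(dispersions), converged = conv,
                    stringsAsFactors = FALSE)
  attr(out, "fitted_means") <- fitted_means
  class(out) <- c("DEResult", class(out))
  out
}

#' Split significant genes by temporal trend
#'
#' Among genes with `q < q_threshold`, the trend sign is the sign of the
#' Spearman correlation between the fitted per-time means and the time
#' ranks; genes with zero correlation are excluded with a warning. Adds a
#' `trend` column (`"pos"`, `"neg"`, `"none"`) to the result.
#'
#' @param de A `DEResult` from [lrt_time_course()].
#' @param design Sample design (provides the time ranks).
#' @param q_threshold Significance threshold (default 0.05).
#' @return List: `pos` and `neg` `GeneSet`s, and `de` with the trend
#'   column filled in.
#' @export
split_by_trend <- function(de, design, q_threshold = 0.05) {
  fm <- attr(de, "fitted_means")
  ranks <- vapply(colnames(fm), function(tp)
    design$time_rank[match(tp, design$time_point)], numeric(1))
  trend <- rep("none", nrow(de))
  sig <- which(!is.na(de$qvalue) & de$qvalue < q_threshold)
  n_zero <- 0L
  for (g in sig) {
    r <- suppressWarnings(cor(fm[g, ], ranks, method = "spearman"))
    if (is.na(r) || r == 0) { n_zero <- n_zero + 1L; next }
    trend[g] <- if (r > 0) "pos" else "neg"
  }
  if (n_zero) warning(n_zero, " significant gene(s) with zero trend excluded")
  de$trend <- trend
  list(pos = gene_set(de$gene_id[trend == "pos"], name = "DE_pos"),
       neg = gene_set(de$gene_id[trend == "neg"], name = "DE_neg"),
       de = de)
}
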