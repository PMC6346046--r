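# Over-representation testing with gene-length bias correction.
#
# The length bias in category enrichment of RNA-seq-derived clusters is
# handled the standard way: fit a monotone probability weighting function
# (PWF) of cluster membership on gene length over the background, reduce it
# to a two-group odds parameter (mean weight inside vs outside the tested
# set), and evaluate the overlap count under the Wallenius noncentral
# hypergeometric distribution. With equal weights the test reduces exactly
# to the central hypergeometric (Fisher) upper tail.

#' Build an enrichment background
#'
#' Background = protein-coding genes with non-zero total read count and
#' non-zero variance across samples; mode `"expressed_one_to_one"`
#' additionally requires a one-to-one ortholog.
#'
#' @param counts Count matrix.
#' @param ann Gene annotation.
#' @param mode `"expressed_nonzero_variance"` or `"expressed_one_to_one"`.
#' @return A `GeneSet`.
#' @export
build_background <- function(counts, ann,
                             mode = c("expressed_nonzero_variance",
                                      "expressed_one_to_one")) {
  mode <- match.arg(mode)
  cm <- unclass(counts)
  tot <- rowSums(cm, na.rm = TRUE)
  v <- apply(cm, 1, function(x) var(x, na.rm = TRUE))
  keep <- tot > 0 & !is.na(v) & v > 0
  idx <- match(rownames(cm), ann$gene_id)
  keep <- keep & !is.na(idx) & ann$biotype[idx] == "protein_coding"
  if (mode == "expressed_one_to_one")
    keep <- keep & !is.na(ann$ortholog_id[idx]) &
      ann$ortholog_multiplicity[idx] == 1
  if (!any(keep)) stop("empty background")
  gene_set(rownames(cm)[keep], name = mode)
}

#' Fit the probability weighting function (PWF)
#'
#' Isotonic (monotone non-decreasing) regression of the cluster-membership
#' indicator on gene length over the background; fitted values are clipped
#' to `[1e-6, 1 - 1e-6]`.
#'
#' @param membership Named logical vector over the background.
#' @param lengths Gene lengths (bp), same order/names as `membership`.
#' @return Named numeric vector of class `"PWF"` (per-gene weights).
#' @export
fit_pwf <- function(membership, lengths) {
  stopifnot(length(membership) == length(lengths))
  if (length(membership) < 50)
    stop("background too small to fit a PWF (need >= 50 genes)")
  if (all(membership) || !any(membership)) {
    warning("membership is constant; PWF is flat at the clipped bound")
    w <- rep(if (all(membership)) 1 - 1e-6 else 1e-6, length(membership))
    names(w) <- names(membership)
    return(structure(w, class = "PWF"))
  }
  ir <- isoreg(lengths, as.numeric(membership))
  w <- numeric(length(lengths))
  w[ir$ord] <- ir$yf
  w <- pmin(pmax(w, 1e-6), 1 - 1e-6)
  names(w) <- names(membership)
  structure(w, class = "PWF")
}

# Log of the Wallenius noncentral hypergeometric pmf by numerical
# integration of the representation
#   P(x) = C(m1,x) C(m2,n-x) * Integral_0^1 d z^(d-1) (1-z^w)^x (1-z)^(n-x) dz
# with d = w*(m1-x) + (m2-(n-x)), computed on the log scale for stability.
.dwall_log <- function(x, m1, m2, n, omega, rel.tol = 1e-10) {
  if (x < max(0, n - m2) || x > min(n, m1)) return(-Inf)
  d <- omega * (m1 - x) + (m2 - (n - x))
  if (d <= 0) return(0)  # urn exhausted: the single attainable outcome
  logf <- function(z) {
    out <- log(d) + (d - 1) * log(z)
    if (x > 0) out <- out + x * log1p(-z^omega)
    if (n - x > 0) out <- out + (n - x) * log1p(-z)
    out
  }
  opt <- optimize(logf, c(1e-12, 1 - 1e-12), maximum = TRUE)
  M <- opt$objective
  I <- integrate(function(z) exp(logf(z) - M), 0, 1,
                 rel.tol = rel.tol, subdivisions = 400L)$value
  lchoose(m1, x) + lchoose(m2, n - x) + M + log(I)
}

#' Wallenius noncentral hypergeometric pmf
#'
#' Probability of drawing `x` of the `m1` weighted ("white") items in `n`
#' draws without replacement from `m1 + m2` items, white items having odds
#' `omega`. Computed by adaptive quadrature of the standard integral
#' representation; the full pmf is renormalized to sum to one.
#'
#' @param x Overlap count(s).
#' @param m1 Number of white items.
#' @param m2 Number of black items.
#' @param n Number of draws.
#' @param omega Odds of a white item being drawn.
#' @return Probabilities.
#' @export
dwallenius <- function(x, m1, m2, n, omega) {
  support <- max(0, n - m2):min(n, m1)
  lp <- vapply(support, .dwall_log, numeric(1), m1 = m1, m2 = m2, n = n,
               omega = omega)
  M <- max(lp)
  pr <- exp(lp - M)
  pr <- pr / sum(pr)
  out <- rep(0, length(x))
  hit <- match(x, support)
  out[!is.na(hit)] <- pr[hit[!is.na(hit)]]
  out
}

# Mean of the Wallenius law: solve (1-mu/m1)^(1/w) = 1 - (n-mu)/m2.
.wallenius_mean <- function(m1, m2, n, omega) {
  lo <- max(0, n - m2); hi <- min(n, m1)
  f <- function(mu) (1 - mu / m1)^(1 / omega) - (1 - (n - mu) / m2)
  if (lo >= hi) return(lo)
  uniroot(f, c(lo + 1e-9, hi - 1e-9), tol = 1e-10)$root
}

# Monte-Carlo upper tail for extreme odds, via the exact biased-urn
# process (sequential weighted sampling without replacement).
.wallenius_tail_mc <- function(x, m1, m2, n, omega, draws = 1e5, seed = 1L) {
  set.seed(seed)
  w <- c(rep(omega, m1), rep(1, m2))
  hits <- vapply(seq_len(draws), function(i)
    sum(sample.int(m1 + m2, n, prob = w) <= m1), numeric(1))
  (sum(hits >= x) + 1) / (draws + 1)
}

#' Length-corrected over-representation test (Wallenius)
#'
#' Over-representation of `set` in `cluster` against `background`, with the
#' PWF reduced to a two-group odds parameter: the odds of a set gene being
#' drawn is `(w_in/(1-w_in)) / (w_out/(1-w_out))`, where `w_in`/`w_out` are
#' the mean PWF weights inside/outside the set. p is the upper-tail
#' probability of the observed overlap under the Wallenius law; `expected`
#' is the law's mean. With a `NULL` PWF all weights are equal and the test
#' is exactly Fisher's upper tail. Odds beyond 1e3 fall back to a
#' Monte-Carlo tail.
#'
#' @param cluster A `GeneSet` (tested cluster).
#' @param set A `GeneSet` (annotation/disease set).
#' @param background A `GeneSet` (universe).
#' @param pwf Optional `PWF` named over the background.
#' @return One-row data frame: set, cluster, overlap, expected, fold,
#'   odds, pvalue, method.
#' @export
wallenius_test <- function(cluster, set, background, pwf = NULL) {
  bg <- as.character(background)
  set_g <- intersect(as.character(set), bg)
  cl_g <- intersect(as.character(cluster), bg)
  if (!length(set_g)) {
    warning("empty set after background intersection")
    return(data.frame(set = attr(set, "name"), cluster = attr(cluster, "name"),
                      overlap = 0L, expected = 0, fold = NA_real_,
                      odds = NA_real_, pvalue = 1, method = "wallenius",
                      stringsAsFactors = FALSE))
  }
  K <- length(set_g); n <- length(cl_g); N <- length(bg)
  x <- length(intersect(set_g, cl_g))
  omega <- 1
  if (!is.null(pwf)) {
    w <- unclass(pwf)[bg]
    in_set <- bg %in% set_g
    w_in <- mean(w[in_set]); w_out <- mean(w[!in_set])
    omega <- (w_in / (1 - w_in)) / (w_out / (1 - w_out))
  }
  if (omega > 1e3 || omega < 1e-3) {
    p <- .wallenius_tail_mc(x, K, N - K, n, omega)
  } else {
    pmf <- dwallenius(max(0, n - (N - K)):min(n, K), K, N - K, n, omega)
    support <- max(0, n - (N - K)):min(n, K)
    p <- sum(pmf[support >= x])
  }
  expected <- .wallenius_mean(K, N - K, n, omega)
  data.frame(set = attr(set, "name") %||% "set",
             cluster = attr(cluster, "name") %||% "cluster",
             overlap = x, expected = expected, fold = x / expected,
             odds = omega, pvalue = p, method = "wallenius",
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fisher (central hypergeometric) over-representation test
#'
#' Upper-tail hypergeometric probability of the observed overlap;
#' `expected` is `n * K / N`.
#'
#' @inheritParams wallenius_test
#' @return One-row data frame in the same shape as [wallenius_test()].
#' @export
fisher_test <- function(cluster, set, background) {
  bg <- as.character(background)
  set_g <- intersect(as.character(set), bg)
  cl_g <- intersect(as.character(cluster), bg)
  if (!length(set_g)) {
    warning("empty set after background intersection")
    return(data.frame(set = attr(set, "name"), cluster = attr(cluster, "name"),
                      overlap = 0L, expected = 0, fold = NA_real_,
                      odds = 1, pvalue = 1, method = "fisher",
                      stringsAsFactors = FALSE))
  }
  K <- length(set_g); n <- length(cl_g); N <- length(bg)
  x <- length(intersect(set_g, cl_g))
  p <- phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  expected <- n * K / N
  data.frame(set = attr(set, "name") %||% "set",
             cluster = attr(cluster, "name") %||% "cluster",
             overlap = x, expected = expected, fold = x / expected,
             odds = 1, pvalue = p, method = "fisher",
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (delegates to [stats::p.adjust()]).
#'
#' @param pvalues Numeric vector of p-values.
#' @return q-values.
#' @export
bh_adjust <- function(pvalues) p.adjust(pvalues, method = "BH")

#' Test a family of gene sets against one cluster
#'
#' Runs [wallenius_test()] (or [fisher_test()]) for each set and BH-adjusts
#' across the family — one family per annotation source per cluster.
#'
#' @param cluster A `GeneSet`.
#' @param sets Named list of `GeneSet`s.
#' @param background A `GeneSet`.
#' @param pwf Optional `PWF` (forces the Wallenius route).
#' @param method `"wallenius"` or `"fisher"`.
#' @return Data frame with one row per set, including `qvalue`.
#' @export
test_enrichment <- function(cluster, sets, background, pwf = NULL,
                            method = c("wallenius", "fisher")) {
  method <- match.arg(method)
  rows <- lapply(sets, function(s)
    if (method == "wallenius") wallenius_test(cluster, s, background, pwf)
    else fisher_test(cluster, s, background))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$qvalue <- bh_adjust(out$pvalue)
  out
}
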