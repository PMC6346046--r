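# Cross-tissue ratio-of-odds-ratios permutation test.
#
# For each tissue, two 2x2 tables (ID-comorbid and ID-free gene lists vs
# cluster membership) give odds ratios OR_ID and OR_IDfree; the per-tissue
# ratio of odds ratios is ROR = OR_ID / OR_IDfree and the test statistic is
# Delta = |log10 ROR_A - log10 ROR_B|. The null distribution is obtained by
# redrawing each table conditional on its own margins (Patefield sampling;
# a single hypergeometric draw in the 2x2 case), applying Haldane's
# correction to any zero-containing draw, and recomputing Delta; the
# empirical p uses the add-one convention (#exceedances + 1) / (B + 1).

#' Build a 2x2 membership table
#'
#' Rows: in `set` / not in `set`; columns: in `cluster` / not in `cluster`,
#' within `universe`.
#'
#' @param set,cluster,universe `GeneSet`s (or character vectors);
#'   `set` and `cluster` must lie within `universe`.
#' @return 2x2 integer matrix of class `"ContingencyTable"` with attribute
#'   `corrected = FALSE`.
#' @export
build_two_by_two <- function(set, cluster, universe) {
  u <- unique(as.character(universe))
  if (!length(u)) stop("empty universe")
  s <- intersect(as.character(set), u)
  cl <- intersect(as.character(cluster), u)
  a <- length(intersect(s, cl))
  t <- matrix(c(a, length(s) - a,
                length(cl) - a, length(u) - length(s) - length(cl) + a),
              2, 2, byrow = TRUE,
              dimnames = list(c("in_set", "not_set"),
                              c("in_cluster", "not_cluster")))
  contingency_table(t)
}

#' Construct a contingency table object
#' @param cells Non-negative matrix of cell counts.
#' @param corrected Has Haldane's correction been applied?
#' @return Matrix of class `"ContingencyTable"`.
#' @export
contingency_table <- function(cells, corrected = FALSE) {
  cells <- as.matrix(cells)
  stopifnot(all(cells >= 0))
  structure(cells, corrected = corrected,
            class = c("ContingencyTable", class(cells)))
}

#' Haldane's correction
#'
#' Adds 0.5 to every cell iff the table contains a zero; already-corrected
#' tables pass through unchanged (no double correction).
#'
#' @param t A `ContingencyTable`.
#' @return The (possibly corrected) table, `corrected` flag set.
#' @export
haldane_correct <- function(t) {
  if (isTRUE(attr(t, "corrected"))) return(t)
  if (any(t == 0)) {
    out <- contingency_table(unclass(t) + 0.5, corrected = TRUE)
    dimnames(out) <- dimnames(t)
    out
  } else {
    attr(t, "corrected") <- TRUE
    t
  }
}

#' Odds ratio of a 2x2 table
#'
#' `(a * d) / (b * c)`. A zero in the off-diagonal cells of an uncorrected
#' table is an error instructing Haldane correction first.
#'
#' @param t A 2x2 `ContingencyTable`.
#' @return Positive odds ratio.
#' @export
odds_ratio <- function(t) {
  stopifnot(all(dim(t) == c(2, 2)))
  if (!isTRUE(attr(t, "corrected")) && (t[1, 2] == 0 || t[2, 1] == 0))
    stop("zero cell in an uncorrected table; apply haldane_correct() first")
  (t[1, 1] * t[2, 2]) / (t[1, 2] * t[2, 1])
}

#' The cross-tissue ROR statistic
#'
#' `Delta = |log10(or_id_A / or_idfree_A) - log10(or_id_B / or_idfree_B)|`.
#'
#' @param or_id_A,or_idfree_A,or_id_B,or_idfree_B Positive odds ratios.
#' @return Non-negative Delta.
#' @export
ror_statistic <- function(or_id_A, or_idfree_A, or_id_B, or_idfree_B) {
  ors <- c(or_id_A, or_idfree_A, or_id_B, or_idfree_B)
  if (any(!is.finite(ors)) || any(ors <= 0))
    stop("odds ratios must be positive and finite")
  abs(log10(or_id_A / or_idfree_A) - log10(or_id_B / or_idfree_B))
}

#' Sample r x c tables with fixed margins (Patefield)
#'
#' Exact i.i.d. draws from the distribution of tables conditional on both
#' margin vectors (the central multivariate hypergeometric), by sequential
#' conditional hypergeometric filling: scanning cells row-wise, each cell
#' is a hypergeometric draw of the row's remaining total against the
#' remaining column masses. Deterministic given the seed.
#'
#' @param row_margins,col_margins Non-negative integer margin vectors with
#'   equal sums.
#' @param n_tables Number of tables to draw.
#' @param seed RNG seed.
#' @return Array of dimension `c(r, c, n_tables)`.
#' @export
patefield_sample <- function(row_margins, col_margins, n_tables, seed) {
  if (missing(seed)) stop("a seed is mandatory for every stochastic call")
  r <- length(row_margins); cc <- length(col_margins)
  if (any(row_margins < 0) || any(col_margins < 0) ||
      any(row_margins != round(row_margins)) ||
      any(col_margins != round(col_margins)))
    stop("margins must be non-negative integers")
  if (sum(row_margins) != sum(col_margins))
    stop("row and column margins must have equal sums")
  set.seed(as.integer(seed))
  out <- array(0, dim = c(r, cc, n_tables))
  if (r == 2 && cc == 2) {
    a <- rhyper(n_tables, col_margins[1], col_margins[2], row_margins[1])
    out[1, 1, ] <- a
    out[1, 2, ] <- row_margins[1] - a
    out[2, 1, ] <- col_margins[1] - a
    out[2, 2, ] <- col_margins[2] - row_margins[1] + a
    return(out)
  }
  for (b in seq_len(n_tables)) {
    colrem <- col_margins
    for (i in seq_len(r)) {
      rowrem <- row_margins[i]
      for (j in seq_len(cc - 1L)) {
        rest <- sum(colrem[(j + 1L):cc])
        aij <- rhyper(1L, colrem[j], rest, rowrem)
        out[i, j, b] <- aij
        rowrem <- rowrem - aij
        colrem[j] <- colrem[j] - aij
      }
      out[i, cc, b] <- rowrem
      colrem[cc] <- colrem[cc] - rowrem
    }
  }
  out
}

# Vectorized 2x2 margin-conditional redraw -> B x 4 matrix (a, b, c, d),
# Haldane-corrected per draw where a zero occurs.
.redraw_2x2 <- function(t, B) {
  rm <- rowSums(t); cm <- colSums(t)
  a <- rhyper(B, cm[1], cm[2], rm[1])
  cells <- cbind(a, rm[1] - a, cm[1] - a, cm[2] - rm[1] + a)
  zero <- rowSums(cells == 0) > 0
  cells[zero, ] <- cells[zero, , drop = FALSE] + 0.5
  cells
}

.or_vec <- function(cells) (cells[, 1] * cells[, 4]) / (cells[, 2] * cells[, 3])

#' ROR permutation test
#'
#' Takes the four observed (uncorrected, integer) tables labelled
#' tissue x list, computes the observed Delta from their Haldane-corrected
#' versions, then redraws each table independently conditional on its own
#' margins `B` times, Haldane-correcting any zero-containing draw, and
#' reports the add-one empirical p of the observed Delta.
#'
#' @param tables Named list of four 2x2 `ContingencyTable`s:
#'   `A_id`, `A_idfree`, `B_id`, `B_idfree`.
#' @param B Number of permutations.
#' @param seed RNG seed.
#' @return List of class `"RORTestResult"`: per-tissue ORs and RORs,
#'   `delta_obs`, `B`, `exceedances`, `pvalue`, `seed`.
#' @export
ror_permutation_test <- function(tables, B = 1e5, seed) {
  if (missing(seed)) stop("a seed is mandatory for every stochastic call")
  stopifnot(B >= 1)
  need <- c("A_id", "A_idfree", "B_id", "B_idfree")
  if (!all(need %in% names(tables)))
    stop("tables must be named ", paste(need, collapse = ", "))
  tables <- tables[need]
  for (nm in need) {
    t <- tables[[nm]]
    if (any(rowSums(t) == 0) || any(colSums(t) == 0))
      stop("degenerate margins (zero row/column) in table ", nm)
    if (any(t != round(t)) || isTRUE(attr(t, "corrected")))
      stop("observed tables must be uncorrected integer counts (", nm, ")")
  }
  ors <- vapply(tables, function(t) odds_ratio(haldane_correct(t)),
                numeric(1))
  ror_A <- ors[["A_id"]] / ors[["A_idfree"]]
  ror_B <- ors[["B_id"]] / ors[["B_idfree"]]
  delta_obs <- ror_statistic(ors[["A_id"]], ors[["A_idfree"]],
                             ors[["B_id"]], ors[["B_idfree"]])
  set.seed(as.integer(seed))
  or_star <- lapply(tables, function(t) .or_vec(.redraw_2x2(t, B)))
  delta_star <- abs(log10(or_star$A_id / or_star$A_idfree) -
                    log10(or_star$B_id / or_star$B_idfree))
  exceed <- sum(delta_star >= delta_obs)
  structure(list(odds_ratios = ors, ror_A = unname(ror_A),
                 ror_B = unname(ror_B), delta_obs = delta_obs,
                 B = B, exceedances = exceed,
                 pvalue = (exceed + 1) / (B + 1),
                 seed = as.integer(seed)),
            class = "RORTestResult")
}

#' Within-list formulation of the ROR test
#'
#' When the two lists share the same complement within the universe, the
#' per-tissue ROR reduces algebraically to the odds ratio of the combined
#' within-list table (rows ID / ID-free, columns in / out of the tissue's
#' cluster). This variant permutes one such table per tissue on its own
#' margins — usable when only the within-list counts are known.
#'
#' @param table_A,table_B 2x2 within-list tables (rows ID / ID-free,
#'   columns in / out of cluster), uncorrected integer counts.
#' @param B Number of permutations.
#' @param seed RNG seed.
#' @return An `"RORTestResult"` (the `odds_ratios` slot holds the two
#'   within-list ORs).
#' @export
ror_permutation_test_within <- function(table_A, table_B, B = 1e5, seed) {
  if (missing(seed)) stop("a seed is mandatory for every stochastic call")
  for (t in list(table_A, table_B)) {
    if (any(rowSums(t) == 0) || any(colSums(t) == 0))
      stop("degenerate margins (zero row/column)")
    if (any(t != round(t)) || isTRUE(attr(t, "corrected")))
      stop("observed tables must be uncorrected integer counts")
  }
  ror_A <- odds_ratio(haldane_correct(table_A))
  ror_B <- odds_ratio(haldane_correct(table_B))
  delta_obs <- abs(log10(ror_A) - log10(ror_B))
  set.seed(as.integer(seed))
  orA <- .or_vec(.redraw_2x2(table_A, B))
  orB <- .or_vec(.redraw_2x2(table_B, B))
  delta_star <- abs(log10(orA) - log10(orB))
  exceed <- sum(delta_star >= delta_obs)
  structure(list(odds_ratios = c(A = ror_A, B = ror_B),
                 ror_A = ror_A, ror_B = ror_B, delta_obs = delta_obs,
                 B = B, exceedances = exceed,
                 pvalue = (exceed + 1) / (B + 1), seed = as.integer(seed)),
            class = "RORTestResult")
}

#' Build the four ROR tables from gene sets
#'
#' The complement row of every table is the universe minus both lists
#' (shared complement), which makes the four-table ROR reduce exactly to
#' the within-list formulation — the two routes cross-check each other.
#'
#' @param id_yes,id_no `GeneSet`s (ID-comorbid / ID-free arms).
#' @param cluster_A,cluster_B Tissue cluster `GeneSet`s.
#' @param universe Universe `GeneSet`.
#' @return Named list of four `ContingencyTable`s (`A_id`, `A_idfree`,
#'   `B_id`, `B_idfree`).
#' @export
build_ror_tables <- function(id_yes, id_no, cluster_A, cluster_B, universe) {
  u <- unique(as.character(universe))
  rest <- setdiff(u, union(as.character(id_yes), as.character(id_no)))
  one <- function(set, cluster) {
    s <- intersect(as.character(set), u)
    cl <- intersect(as.character(cluster), u)
    a <- length(intersect(s, cl))
    c3 <- length(intersect(rest, cl))
    contingency_table(matrix(
      c(a, length(s) - a, c3, length(rest) - c3), 2, 2, byrow = TRUE,
      dimnames = list(c("in_set", "complement"),
                      c("in_cluster", "not_cluster"))))
  }
  list(A_id = one(id_yes, cluster_A), A_idfree = one(id_no, cluster_A),
       B_id = one(id_yes, cluster_B), B_idfree = one(id_no, cluster_B))
}

#' BH adjustment across permutation strata
#'
#' @param results List of `RORTestResult`s (e.g. the syndromic-only and
#'   categories-1-4 runs).
#' @return Numeric vector of q-values, one per stratum.
#' @export
stratified_fdr <- function(results) {
  p <- vapply(results, function(r) r$pvalue, numeric(1))
  bh_adjust(p)
}

#' Overlap depletion/enrichment test between two gene sets
#'
#' Exact hypergeometric tail probability of the observed overlap between
#' `setA` and `setB` within `universe`. `tail = "less"` tests depletion
#' (P(X <= overlap)), `"greater"` enrichment, `"two_sided"` sums all
#' tables at most as probable as the observed one.
#'
#' @param setA,setB,universe `GeneSet`s.
#' @param tail `"less"`, `"greater"` or `"two_sided"`.
#' @return List: `overlap` (gene IDs), `pvalue`, `table`.
#' @export
overlap_depletion_test <- function(setA, setB, universe,
                                   tail = c("less", "greater", "two_sided")) {
  tail <- match.arg(tail)
  u <- unique(as.character(universe))
  if (!length(u)) stop("empty universe")
  A <- intersect(as.character(setA), u)
  B <- intersect(as.character(setB), u)
  ov <- intersect(A, B)
  k <- length(ov); K <- length(A); n <- length(B); N <- length(u)
  p <- switch(tail,
    less = phyper(k, K, N - K, n),
    greater = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    two_sided = {
      dk <- dhyper(k, K, N - K, n)
      supp <- max(0, n - (N - K)):min(n, K)
      sum(dhyper(supp, K, N - K, n)[dhyper(supp, K, N - K, n) <=
                                      dk * (1 + 1e-7)])
    })
  list(overlap = ov, pvalue = p,
       table = build_two_by_two(A, B, u))
}
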