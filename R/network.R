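# Signed weighted co-expression network: soft threshold scan, topological
# overlap, module detection, eigengenes, merging, module membership.

#' Prefilter genes for network analysis
#'
#' Removes genes with more than 50% missing values and/or zero variance.
#'
#' @param em Expression matrix (genes x samples).
#' @return Filtered matrix with attribute `removed` (gene IDs).
#' @export
prefilter_genes <- function(em) {
  m <- unclass(em)
  frac_na <- rowMeans(is.na(m))
  v <- apply(m, 1, function(x) var(x, na.rm = TRUE))
  keep <- frac_na <= 0.5 & !is.na(v) & v > 0
  if (!any(keep)) stop("no genes survive the missingness/variance filter")
  out <- m[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(m)[!keep]
  attr(out, "scale") <- attr(em, "scale")
  out
}

#' Signed adjacency from gene-gene correlation
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta` with Pearson correlation on
#' pairwise-complete observations; the signed map sends cor = -1 to 0 and
#' cor = 1 to 1. Diagonal is set to 0.
#'
#' @param em Expression matrix (genes x samples).
#' @param beta Soft-threshold power.
#' @return Gene-by-gene adjacency matrix.
#' @export
signed_adjacency <- function(em, beta) {
  stopifnot(beta > 0)
  C <- cor(t(unclass(em)), use = "pairwise.complete.obs")
  A <- ((1 + C) / 2)^beta
  diag(A) <- 0
  A
}

#' Scan soft-threshold powers for scale-free fit
#'
#' For each candidate power, builds the signed adjacency, computes the
#' connectivity `k_i = sum_j a_ij`, and fits `log10 p(k) ~ log10 k` over 10
#' equal-occupancy connectivity bins. The signed fit index is
#' `-sign(slope) * R^2` (positive when the degree distribution decreases).
#' The chosen power is the smallest candidate reaching `rsq_target`, else
#' the argmax; a pinned `power` overrides the scan.
#'
#' @param em Expression matrix.
#' @param candidates Candidate powers.
#' @param rsq_target Fit threshold for choosing the power (default 0.8).
#' @param power Optional pinned power (returned as chosen regardless).
#' @param n_bins Number of equal-occupancy bins (default 10).
#' @return List of class `"SoftThresholdScan"`: `table` (power, rsq,
#'   mean_connectivity), `chosen`.
#' @export
scan_soft_threshold <- function(em, candidates = 1:10, rsq_target = 0.8,
                                power = NULL, n_bins = 10) {
  stopifnot(all(candidates > 0))
  C <- cor(t(unclass(em)), use = "pairwise.complete.obs")
  S <- (1 + C) / 2
  diag(S) <- 0
  rsq <- meank <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    A <- S^candidates[i]
    diag(A) <- 0
    k <- rowSums(A)
    meank[i] <- mean(k)
    rsq[i] <- .scale_free_rsq(k, n_bins)
  }
  tab <- data.frame(power = candidates, rsq = rsq,
                    mean_connectivity = meank)
  chosen <- if (!is.null(power)) power
  else if (any(!is.na(rsq) & rsq >= rsq_target))
    min(candidates[!is.na(rsq) & rsq >= rsq_target])
  else candidates[which.max(rsq)]
  structure(list(table = tab, chosen = chosen),
            class = "SoftThresholdScan")
}

# Signed scale-free topology fit index on a connectivity vector.
# Equal-occupancy bins; p(k) is the width-normalized density per bin (raw
# per-bin frequency is constant by construction under occupancy binning).
.scale_free_rsq <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  br <- unique(quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 4) return(NA_real_)
  bin <- cut(k, br, include.lowest = TRUE)
  width <- diff(br)
  pk <- as.numeric(tapply(k, bin, length)) / (length(k) * width)
  km <- tapply(k, bin, mean)
  ok <- !is.na(pk) & pk > 0 & !is.na(km) & km > 0
  if (sum(ok) < 3) return(NA_real_)
  fit <- lm(log10(pk[ok]) ~ log10(km[ok]))
  r2 <- summary(fit)$r.squared
  -sign(coef(fit)[2]) * r2
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal. The corresponding dissimilarity is `1 - TOM`.
#'
#' @param em Expression matrix, or a precomputed adjacency via
#'   `adjacency =`.
#' @param beta Soft-threshold power (ignored when `adjacency` given).
#' @param adjacency Optional adjacency matrix.
#' @return Gene-by-gene TOM similarity matrix.
#' @export
compute_tom <- function(em, beta = 3, adjacency = NULL) {
  A <- if (is.null(adjacency)) signed_adjacency(em, beta) else adjacency
  k <- rowSums(A)
  L <- A %*% A            # diag(A) = 0, so this is sum over u != i,j
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  tom
}

#' Detect modules by hierarchical clustering of TOM dissimilarity
#'
#' Average-linkage clustering of `1 - TOM` with a static largest-gap cut:
#' the tree is cut at the midpoint of the largest gap in the sorted merge
#' heights, searched between the 2% quantile and `cut_quantile`. Dense
#' modules complete their subtrees at low heights while background genes
#' attach at high heights, so the widest gap separates the two regimes
#' regardless of what fraction of genes is in modules. Clusters smaller
#' than `min_size` become `"unassigned"`. Modules are labelled
#' `M1, M2, ...` in decreasing size (ties broken by the alphabetically
#' first member), which makes the labelling invariant to gene order.
#'
#' @param dissim Symmetric dissimilarity matrix (e.g. `1 - TOM`).
#' @param min_size Minimum module size (default 30).
#' @param cut_quantile Upper quantile of merge heights bounding the gap
#'   search (default 0.99).
#' @return Data frame of class `"ModuleAssignment"` (gene_id, module) with
#'   attributes `sizes` and `cut_height`.
#' @export
detect_modules <- function(dissim, min_size = 30, cut_quantile = 0.99) {
  stopifnot(isSymmetric(unname(dissim)))
  tree <- hclust(as.dist(dissim), method = "average")
  hs <- sort(tree$height)
  n <- length(hs)
  i0 <- max(1L, floor(0.02 * n))
  i1 <- min(n - 1L, ceiling(cut_quantile * n))
  gaps <- diff(hs)[i0:i1]
  k <- which.max(gaps) + i0 - 1L
  h <- (hs[k] + hs[k + 1L]) / 2
  cl <- cutree(tree, h = h)
  assignment <- .finalize_assignment(names(cl), cl, min_size)
  if (all(assignment$module == "unassigned"))
    warning("all genes unassigned at this cut")
  attr(assignment, "cut_height") <- unname(h)
  assignment
}

# Relabel integer clusters as M1.. by decreasing size (alphabetical
# tie-break), pushing small clusters to "unassigned".
.finalize_assignment <- function(gene_ids, cl, min_size) {
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_size]
  module <- rep("unassigned", length(cl))
  if (length(keep)) {
    first_gene <- vapply(keep, function(k) min(gene_ids[cl == k]), character(1))
    ord <- order(-as.integer(sizes[keep]), first_gene)
    for (i in seq_along(ord))
      module[cl == keep[ord[i]]] <- paste0("M", i)
  }
  out <- data.frame(gene_id = gene_ids, module = module,
                    stringsAsFactors = FALSE)
  attr(out, "sizes") <- table(out$module)
  class(out) <- c("ModuleAssignment", class(out))
  out
}

#' Module eigengenes
#'
#' First right singular vector of each module's standardized gene-by-sample
#' matrix, sign-oriented to correlate positively with the module's mean
#' profile; rows are unit-norm. A single-gene module's eigengene is that
#' gene's standardized profile (unit-normalized).
#'
#' @param em_std Standardized expression matrix.
#' @param assignment A `ModuleAssignment`.
#' @return List of class `"EigengeneSet"`: `profiles` (module x sample,
#'   unit norm) and `var_explained`.
#' @export
compute_eigengenes <- function(em_std, assignment) {
  mods <- setdiff(unique(assignment$module), "unassigned")
  if (!length(mods)) stop("no assigned modules")
  m <- unclass(em_std)
  profiles <- matrix(NA_real_, length(mods), ncol(m),
                     dimnames = list(mods, colnames(m)))
  ve <- setNames(rep(NA_real_, length(mods)), mods)
  for (mod in mods) {
    genes <- assignment$gene_id[assignment$module == mod]
    X <- m[genes, , drop = FALSE]
    if (nrow(X) == 1L) {
      v <- X[1, ] / sqrt(sum(X[1, ]^2))
      ve[mod] <- 1
    } else {
      sv <- svd(X, nu = 0, nv = 1)
      v <- sv$v[, 1]
      ve[mod] <- sv$d[1]^2 / sum(sv$d^2)
    }
    if (sum(v * colMeans(X)) < 0) v <- -v
    profiles[mod, ] <- v
  }
  structure(list(profiles = profiles, var_explained = ve),
            class = "EigengeneSet")
}

#' Merge modules with similar eigengenes
#'
#' Average-linkage clustering of eigengene dissimilarity (1 - correlation);
#' modules linking below `height` are merged (keeping the larger module's
#' label), eigengenes are recomputed, and the procedure repeats until no
#' further merge occurs — so a second call changes nothing.
#'
#' @param em_std Standardized expression matrix.
#' @param assignment A `ModuleAssignment`.
#' @param height Merge height on 1 - correlation (default 0.5).
#' @return A merged `ModuleAssignment`.
#' @export
merge_modules <- function(em_std, assignment, height = 0.5) {
  repeat {
    mods <- setdiff(unique(assignment$module), "unassigned")
    if (length(mods) < 2L) break
    eg <- compute_eigengenes(em_std, assignment)
    d <- 1 - cor(t(eg$profiles))
    grp <- cutree(hclust(as.dist(d), method = "average"), h = height)
    if (max(table(grp)) == 1L) break
    module <- assignment$module
    for (g in unique(grp)) {
      members <- names(grp)[grp == g]
      if (length(members) < 2L) next
      sizes <- vapply(members, function(mm) sum(module == mm), integer(1))
      target <- members[which.max(sizes)]
      module[module %in% members] <- target
    }
    cl <- match(module, unique(module))
    names(cl) <- assignment$gene_id
    unas <- module == "unassigned"
    assignment2 <- .finalize_assignment(assignment$gene_id, cl, min_size = 1)
    assignment2$module[unas] <- "unassigned"
    attr(assignment2, "sizes") <- table(assignment2$module)
    assignment <- assignment2
  }
  attr(assignment, "provenance") <- "post_merge"
  assignment
}

#' Module membership (kME) and core members
#'
#' kME is the Pearson correlation of each gene's profile with each module
#' eigengene. `core_members()` returns the genes assigned to a module
#' whose own-module kME exceeds the threshold.
#'
#' @param em_std Standardized expression matrix.
#' @param eigengenes An `EigengeneSet`.
#' @return Gene-by-module matrix of kME values in `[-1, 1]`.
#' @export
module_membership <- function(em_std, eigengenes) {
  m <- unclass(em_std)
  suppressWarnings(cor(t(m), t(eigengenes$profiles)))
}

#' @rdname module_membership
#' @param mm kME matrix from [module_membership()].
#' @param assignment A `ModuleAssignment`.
#' @param module Module label.
#' @param threshold kME cutoff (default 0.8).
#' @export
core_members <- function(mm, assignment, module, threshold = 0.8) {
  genes <- assignment$gene_id[assignment$module == module]
  kme <- mm[genes, module]
  gene_set(genes[!is.na(kme) & kme > threshold],
           name = paste0(module, "_core"))
}

#' Correlate module eigengenes with developmental time
#'
#' Pearson correlation of each eigengene profile against per-sample time
#' ranks; modules are classified `"pos"`/`"neg"` when `|r|` exceeds
#' `r_threshold` and p < 0.05, else `"none"`.
#'
#' @param eigengenes An `EigengeneSet`.
#' @param design Sample design.
#' @param r_threshold Correlation magnitude threshold (default 0.5).
#' @return Data frame (module, r, pvalue, class).
#' @export
module_time_correlation <- function(eigengenes, design, r_threshold = 0.5) {
  ranks <- design$time_rank[match(colnames(eigengenes$profiles),
                                  design$sample_id)]
  mods <- rownames(eigengenes$profiles)
  r <- p <- numeric(length(mods))
  for (i in seq_along(mods)) {
    ct <- cor.test(eigengenes$profiles[i, ], ranks)
    r[i] <- unname(ct$estimate); p[i] <- ct$p.value
  }
  cls <- ifelse(abs(r) > r_threshold & p < 0.05,
                ifelse(r > 0, "pos", "neg"), "none")
  data.frame(module = mods, r = r, pvalue = p, class = cls,
             stringsAsFactors = FALSE)
}

#' Cross-tissue coherence of a module
#'
#' Variance-explained fraction of the first principal component of the
#' module genes' standardized profiles in another tissue's expression
#' matrix. A coherent module retains a dominant first component; a module
#' that is incoherent in the other tissue does not.
#'
#' @param module_genes A `GeneSet` (or character vector).
#' @param em_other Expression matrix of the other tissue.
#' @return Coherence fraction in (0, 1], or `NA` (with a warning) when
#'   fewer than 2 module genes are present.
#' @export
cross_tissue_coherence <- function(module_genes, em_other) {
  m <- unclass(em_other)
  genes <- intersect(as.character(module_genes), rownames(m))
  if (length(genes) < 2L) {
    warning("fewer than 2 module genes present in the other tissue")
    return(NA_real_)
  }
  X <- suppressWarnings(standardize_rows(m[genes, , drop = FALSE]))
  if (nrow(X) < 2L) {
    warning("fewer than 2 variable module genes in the other tissue")
    return(NA_real_)
  }
  d <- svd(X, nu = 0, nv = 0)$d
  d[1]^2 / sum(d^2)
}
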