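# Tabular conventions used throughout: tab-separated, UTF-8, mandatory header
# row, missing token "NA". Gene matching is exact string match after
# whitespace trimming; no case folding (cross-species translation must go
# through the ortholog mapping table).

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    na.strings = "NA", check.names = FALSE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

.trim <- function(x) trimws(as.character(x))

#' Read a gene-by-sample count matrix
#'
#' Reads a tab-separated table whose first column holds gene identifiers and
#' whose header row holds sample identifiers. Cells must be non-negative
#' integers or the missing token `"NA"`; missing cells are kept as `NA` (they
#' are flagged, never silently zeroed).
#'
#' @param path Path to a TSV file.
#' @return An integer matrix with gene IDs as row names and sample IDs as
#'   column names; class `"CountMatrix"` is prepended for printing.
#' @export
read_count_matrix <- function(path) {
  tab <- .read_tsv(path)
  if (ncol(tab) < 2L) stop("count matrix needs a gene column plus >= 1 sample")
  gene_ids <- .trim(tab[[1L]])
  sample_ids <- .trim(colnames(tab)[-1L])
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(gene_ids, sample_ids)
  validate_count_matrix(counts)
}

#' Validate a count matrix
#'
#' Enforces the count-matrix invariants: unique gene and sample IDs,
#' non-negative integer counts where present. Non-integer or negative cells
#' are hard errors naming the offending row and column.
#'
#' @param counts Numeric matrix with gene row names and sample column names;
#'   `NA` marks missing cells.
#' @return The validated matrix with class `"CountMatrix"`.
#' @export
validate_count_matrix <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must carry gene row names and sample column names")
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g))
    stop("duplicated gene IDs: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s))
    stop("duplicated sample IDs: ", paste(dup_s, collapse = ", "))
  bad <- which(!is.na(counts) & (counts < 0 | counts != round(counts)),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("negative or non-integer count at gene '",
         rownames(counts)[bad[1L, 1L]], "', sample '",
         colnames(counts)[bad[1L, 2L]], "'")
  class(counts) <- c("CountMatrix", class(counts))
  counts
}

#' Write a count matrix to TSV
#' @param counts A count matrix.
#' @param path Output path.
#' @export
write_count_matrix <- function(counts, path) {
  tab <- data.frame(gene_id = rownames(counts), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample design table
#'
#' Columns: `sample_id`, `time_point` (ordinal label), `time_rank` (numeric
#' rank of the time point), `replicate`; further columns are kept as
#' covariates. The design must describe at least two time points.
#'
#' @param path Path to a TSV file.
#' @return A data frame with one row per sample.
#' @export
read_sample_design <- function(path) {
  tab <- .read_tsv(path)
  validate_sample_design(tab)
}

#' Validate a sample design table
#' @param design Data frame with columns `sample_id`, `time_point`,
#'   `time_rank`, `replicate`.
#' @param counts Optional count matrix to check sample coverage against.
#' @return The validated design.
#' @export
validate_sample_design <- function(design, counts = NULL) {
  need <- c("sample_id", "time_point", "time_rank", "replicate")
  miss <- setdiff(need, colnames(design))
  if (length(miss)) stop("design lacks columns: ", paste(miss, collapse = ", "))
  design$sample_id <- .trim(design$sample_id)
  if (anyDuplicated(design$sample_id)) stop("duplicated sample_id in design")
  if (length(unique(design$time_point)) < 2L)
    stop("design must contain >= 2 time points")
  if (!is.null(counts)) {
    missing_s <- setdiff(colnames(counts), design$sample_id)
    if (length(missing_s))
      stop("samples without a design row: ", paste(missing_s, collapse = ", "))
  }
  design
}

#' Read a gene annotation table
#'
#' Columns: `gene_id`, `length_bp`, `biotype`, `ortholog_id`,
#' `ortholog_multiplicity`. Unknown biotypes are preserved verbatim; a
#' missing `ortholog_id` means the gene has no ortholog.
#'
#' @param path Path to a TSV file.
#' @return A data frame with one row per gene.
#' @export
read_gene_annotation <- function(path) {
  tab <- .read_tsv(path)
  need <- c("gene_id", "length_bp", "biotype", "ortholog_id",
            "ortholog_multiplicity")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("annotation lacks columns: ", paste(miss, collapse = ", "))
  tab$gene_id <- .trim(tab$gene_id)
  if (anyDuplicated(tab$gene_id)) stop("duplicated gene_id in annotation")
  if (any(!is.na(tab$length_bp) & tab$length_bp <= 0))
    stop("length_bp must be >= 1")
  has_orth <- !is.na(tab$ortholog_id) & nzchar(.trim(tab$ortholog_id))
  tab$ortholog_id[!has_orth] <- NA_character_
  if (any(has_orth & (is.na(tab$ortholog_multiplicity) |
                      tab$ortholog_multiplicity < 1)))
    stop("ortholog_multiplicity must be >= 1 when ortholog_id present")
  tab
}

#' Read a disease gene list
#'
#' Columns: `gene_id`, `category` (one of 1..6 or `"S"`), `syndromic`
#' (logical), `id_comorbid` (`"yes"`, `"no"` or `"unknown"`; blank defaults
#' to `"unknown"`). Category `"S"` implies `syndromic = TRUE`.
#'
#' @param path Path to a TSV file.
#' @param list_name Name recorded on the list; defaults to the file stem.
#' @return A data frame of class `"DiseaseGeneList"` with attribute
#'   `list_name`.
#' @export
read_disease_gene_list <- function(path,
                                   list_name = sub("\\.[^.]*$", "", basename(path))) {
  tab <- .read_tsv(path)
  need <- c("gene_id", "category", "syndromic", "id_comorbid")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("gene list lacks columns: ", paste(miss, collapse = ", "))
  tab$gene_id <- .trim(tab$gene_id)
  tab$category <- .trim(tab$category)
  validate_disease_gene_list(tab, list_name)
}

#' Validate a disease gene list
#' @param tab Data frame with the disease-list columns.
#' @param list_name Name to record on the list.
#' @return The validated list, class `"DiseaseGeneList"`.
#' @export
validate_disease_gene_list <- function(tab, list_name = "genelist") {
  if (anyDuplicated(tab$gene_id)) stop("duplicated gene_id in disease list")
  ok_cat <- c(as.character(1:6), "S")
  bad <- setdiff(unique(tab$category), ok_cat)
  if (length(bad))
    stop("invalid category value(s): ", paste(bad, collapse = ", "))
  tab$syndromic <- as.logical(tab$syndromic)
  tab$syndromic[tab$category == "S"] <- TRUE
  idc <- .trim(tab$id_comorbid)
  idc[is.na(idc) | !nzchar(idc)] <- "unknown"
  bad_id <- setdiff(unique(idc), c("yes", "no", "unknown"))
  if (length(bad_id))
    stop("invalid id_comorbid value(s): ", paste(bad_id, collapse = ", "))
  tab$id_comorbid <- idc
  attr(tab, "list_name") <- list_name
  class(tab) <- c("DiseaseGeneList", class(tab))
  tab
}

#' Construct a gene set
#'
#' A gene set is a named character vector of unique gene IDs with an
#' optional background ("universe") hint.
#'
#' @param members Character vector of gene IDs.
#' @param name Set name.
#' @param universe_hint Optional name of the intended background.
#' @return Character vector of class `"GeneSet"`.
#' @export
gene_set <- function(members, name = "set", universe_hint = NULL) {
  members <- unique(.trim(members))
  members <- members[!is.na(members) & nzchar(members)]
  structure(members, name = name, universe_hint = universe_hint,
            class = "GeneSet")
}

#' Filter a disease gene list by SFARI-style category
#'
#' Keeps genes whose confidence category is in `categories`; syndromic genes
#' are added iff `include_syndromic`. The returned set's name records the
#' filter applied. An empty result is a warning, not an error.
#'
#' @param list A `DiseaseGeneList`.
#' @param categories Character or integer vector of categories (subset of
#'   1..6 and `"S"`).
#' @param include_syndromic Keep syndromic genes regardless of category?
#' @return A `GeneSet`.
#' @export
filter_sfari_categories <- function(list, categories, include_syndromic = TRUE) {
  categories <- as.character(categories)
  bad <- setdiff(categories, c(as.character(1:6), "S"))
  if (length(bad)) stop("invalid categories: ", paste(bad, collapse = ", "))
  keep <- list$category %in% categories
  if (include_syndromic) keep <- keep | list$syndromic
  if (!any(keep)) warning("category filter produced an empty gene set")
  nm <- paste0(attr(list, "list_name"), "_cat", paste(categories, collapse = ""),
               if (include_syndromic) "+S" else "")
  gene_set(list$gene_id[keep], name = nm)
}

#' Map a gene set to one-to-one orthologs
#'
#' Translates members through the annotation's ortholog mapping, keeping
#' only genes with `ortholog_multiplicity == 1`. The mapping is forced to be
#' injective: if two retained genes map to the same ortholog, both are
#' dropped with a warning. Genes absent from the annotation are dropped and
#' counted in the attached report.
#'
#' @param set A `GeneSet` (IDs on the source-species side).
#' @param ann Gene annotation table.
#' @return A `GeneSet` of ortholog IDs with attribute `ortholog_report`
#'   (dropped-gene counts by reason).
#' @export
restrict_to_one_to_one_orthologs <- function(set, ann) {
  idx <- match(as.character(set), ann$gene_id)
  absent <- is.na(idx)
  orth <- ann$ortholog_id[idx]
  mult <- ann$ortholog_multiplicity[idx]
  one2one <- !absent & !is.na(orth) & !is.na(mult) & mult == 1
  mapped <- orth[one2one]
  coll <- mapped[duplicated(mapped)]
  if (length(coll)) {
    warning("ortholog collisions dropped: ", paste(unique(coll), collapse = ", "))
    keep <- !(mapped %in% coll)
  } else keep <- rep(TRUE, length(mapped))
  report <- c(absent = sum(absent),
              not_one_to_one = sum(!absent & !one2one),
              collisions = length(mapped) - sum(keep))
  out <- gene_set(mapped[keep], name = paste0(attr(set, "name"), "_1to1"),
                  universe_hint = attr(set, "universe_hint"))
  attr(out, "ortholog_report") <- report
  out
}

#' Partition a disease gene list by intellectual-disability status
#'
#' First applies the stratum filter (`"syndromic_only"` keeps syndromic
#' genes; `"categories_1_4"` keeps non-syndromic genes in categories 1-4;
#' `"all"` keeps both), then splits by the `id_comorbid` flag. Genes whose
#' ID status is `"unknown"` belong to neither partition — absence of
#' evidence is kept distinct from evidence of absence.
#'
#' @param list A `DiseaseGeneList`.
#' @param stratum One of `"syndromic_only"`, `"categories_1_4"`, `"all"`.
#' @return List with `GeneSet`s `id_yes` and `id_no`.
#' @export
partition_by_id_status <- function(list,
                                   stratum = c("all", "syndromic_only",
                                               "categories_1_4")) {
  stratum <- match.arg(stratum)
  in_14 <- list$category %in% as.character(1:4)
  keep <- switch(stratum,
    syndromic_only = list$syndromic,
    categories_1_4 = in_14 & !list$syndromic,
    all = in_14 | list$syndromic)
  sub <- list[keep, , drop = FALSE]
  nm <- attr(list, "list_name")
  list(id_yes = gene_set(sub$gene_id[sub$id_comorbid == "yes"],
                         name = paste0(nm, "_", stratum, "_ID")),
       id_no = gene_set(sub$gene_id[sub$id_comorbid == "no"],
                        name = paste0(nm, "_", stratum, "_IDfree")))
}

#' Write a generic data frame as TSV
#' @param tab Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
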