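#!/usr/bin/env Rscript
# Disease-list over-representation in the detected modules, with
# gene-length bias correction: protein-coding expressed background, SFARI
# category filter (1-4 plus syndromic), one-to-one ortholog restriction,
# isotonic PWF of module membership on gene length, and the Wallenius
# noncentral hypergeometric test with BH q-values per module family.

library(pcdevnet)

dat <- "results/data"; out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_count_matrix(file.path(dat, "counts.tsv"))
ann <- read_gene_annotation(file.path(dat, "annotation.tsv"))
mods <- read.delim("results/network/modules.tsv")

bg <- build_background(counts, ann, "expressed_nonzero_variance")
message("Background: ", length(bg),
        " expressed, variable, protein-coding genes")

lists <- list(
  asd = read_disease_gene_list(file.path(dat, "genelist_asd.tsv")),
  scz = read_disease_gene_list(file.path(dat, "genelist_scz.tsv")),
  ataxia = read_disease_gene_list(file.path(dat, "genelist_ataxia.tsv")))
sets <- lapply(lists, function(l)
  filter_sfari_categories(l, 1:4, include_syndromic = TRUE))

lens <- setNames(ann$length_bp[match(as.character(bg), ann$gene_id)],
                 as.character(bg))
rows <- list()
for (m in setdiff(unique(mods$module), "unassigned")) {
  cl <- gene_set(mods$gene_id[mods$module == m], name = m)
  pwf <- fit_pwf(setNames(names(lens) %in% as.character(cl), names(lens)),
                 lens)
  fam <- test_enrichment(cl, sets, bg, pwf, method = "wallenius")
  fam$cluster <- m
  rows[[m]] <- fam
  for (i in seq_len(nrow(fam)))
    message(sprintf("%s ~ %s: overlap %d (expected %.1f, fold %.2f), q = %.2g",
                    m, fam$set[i], fam$overlap[i], fam$expected[i],
                    fam$fold[i], fam$qvalue[i]))
}
write_tsv(do.call(rbind, rows), file.path(out, "enrichment.tsv"))
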