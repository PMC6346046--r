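#!/usr/bin/env Rscript
# Generate the synthetic study dataset: 5 postnatal time points (P0-P21) x 3
# replicates of NB counts over 2000 genes, with two large monotone temporal
# modules (400 up, 400 down), one smaller up module (100), log-normal gene
# lengths and sample depths, and disease gene lists with a planted
# cross-tissue ID-composition bias (odds 8 vs 0.1) plus a module-enriched
# ataxia-like list (5x) and a neutral schizophrenia-like list.

library(pcdevnet)

seed <- 42
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
truth <- generate_truth(cfg)
sim <- generate_counts(truth)
ann <- generate_annotation(truth)
lists <- generate_disease_lists(truth, seed = seed + 1)

write_count_matrix(sim$counts, file.path(out, "counts.tsv"))
write_tsv(sim$design, file.path(out, "design.tsv"))
write_tsv(ann, file.path(out, "annotation.tsv"))
write_tsv(generate_marker_panel(truth), file.path(out, "markers.tsv"))
for (nm in names(lists))
  write_tsv(lists[[nm]], file.path(out, paste0("genelist_", nm, ".tsv")))
write_tsv(data.frame(gene_id = truth$gene_ids, module = truth$module,
                     slope_log2 = truth$slope, baseline = truth$baseline,
                     length_bp = truth$length_bp),
          file.path(out, "truth.tsv"))

message("Simulated ", nrow(sim$counts), " genes x ", ncol(sim$counts),
        " samples; module sizes: ",
        paste(names(table(truth$module)), table(truth$module),
              sep = "=", collapse = ", "))
message("Wrote counts, design, annotation, markers, gene lists and the ",
        "ground truth to ", out)
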