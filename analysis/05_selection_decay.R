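#!/usr/bin/env Rscript
# Selection and gene decay: per-branch counting dN/dS on the in-frame core
# codon alignment, pseudogene detection against the ancestral reference,
# group contrasts (Welch t tests), pseudogene-composition ANOSIM, and the
# omega-vs-pseudogene-load regression.

source("analysis/00_config.R")

outdir <- file.path(RESULTS_DIR, "selection_decay")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

omega_all <- c(); counts_all <- c(); grp_all <- c()
calls_all <- list()

for (group in names(study_configs())) {
  genomes <- load_group(group)
  leaves <- genomes[names(genomes) != "ancestor"]
  ort <- identify_orthologs(genomes, reference = "ancestor")
  aln <- core_alignment(genomes, ort)
  tree <- nj_tree(core_distances(aln[setdiff(rownames(aln), "ancestor"), ]))
  anc <- reconstruct_ancestors(tree, aln)
  bo <- per_branch_omega(tree, aln, ancestors = anc, reference = "ancestor")
  write.table(bo, file.path(outdir, paste0("branch_omega_", group, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  calls <- do.call(rbind, lapply(leaves, detect_pseudogenes,
                                 reference_genome = genomes$ancestor))
  rownames(calls) <- NULL
  calls_all[[group]] <- calls
  write.table(calls, file.path(outdir, paste0("pseudogenes_", group, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ids <- names(leaves)
  cnt <- setNames(as.integer(table(factor(calls$genome_id, levels = ids))), ids)
  tips <- bo[bo$is_tip, ]
  om <- setNames(tips$omega, tips$branch)[ids]
  message(sprintf("[%s] mean omega %.3f (sd %.3f); pseudogenes/genome %.1f (sd %.1f)",
                  group, mean(om, na.rm = TRUE), sd(om, na.rm = TRUE),
                  mean(cnt), sd(cnt)))
  omega_all <- c(omega_all, om)
  counts_all <- c(counts_all, cnt)
  grp_all <- c(grp_all, setNames(rep(group, length(ids)), ids))
}

ps_t <- welch_t_test(counts_all[grp_all == "subseafloor"],
                     counts_all[grp_all == "type"],
                     labels = c("subseafloor", "type"))
print(ps_t)
om_t <- welch_t_test(omega_all[grp_all == "subseafloor"],
                     omega_all[grp_all == "type"],
                     labels = c("subseafloor", "type"))
print(om_t)

reg <- omega_vs_pseudogenes(omega_all, counts_all, grp_all)
write.table(reg, file.path(outdir, "omega_vs_pseudogenes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(reg)

pg <- do.call(rbind, calls_all)
if (length(unique(pg$gene_id)) > 1) {
  pa <- table(pg$genome_id, pg$gene_id) > 0
  grp2 <- grp_all[rownames(pa)]
  if (length(unique(grp2)) >= 2 && all(table(grp2) >= 2)) {
    an <- anosim_test(presence_distance(pa), grp2, n_permutations = 999, seed = 1)
    message(sprintf("pseudogene composition ANOSIM: R = %.3f, p = %.3g",
                    an$statistic, an$p_value))
  }
}

summ <- data.frame(
  genome_id = names(counts_all), group = unname(grp_all),
  pseudogenes = unname(counts_all), omega = unname(omega_all[names(counts_all)]))
write.table(summ, file.path(outdir, "per_genome_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
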