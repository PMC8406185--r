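#!/usr/bin/env Rscript
# Clonal genealogies: JC distances, neighbor-joining with midpoint rooting,
# bootstrap support, and a check of the recovered topology against the true
# simulated genealogy.

source("analysis/00_config.R")

outdir <- file.path(RESULTS_DIR, "phylogeny")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

for (group in names(study_configs())) {
  aln_file <- file.path(RESULTS_DIR, "core", paste0("core_", group, ".fasta"))
  if (!file.exists(aln_file)) stop("run analysis/02_core_genome.R first")
  fa <- Biostrings::readDNAStringSet(aln_file)
  aln <- t(vapply(as.character(fa), function(s) strsplit(s, "")[[1]],
                  character(Biostrings::width(fa)[1])))
  rownames(aln) <- names(fa)

  d <- core_distances(aln)
  write.table(round(d, 6), file.path(outdir, paste0("distances_", group, ".tsv")),
              sep = "\t", quote = FALSE, col.names = NA)
  tree <- bootstrap_support(aln, n_replicates = 100, seed = 1)
  ape::write.tree(tree, file.path(outdir, paste0("tree_", group, ".nwk")))
  supp <- attr(tree, "support")
  message(sprintf("[%s] NJ tree: %d tips; bootstrap support median %.2f (min %.2f)",
                  group, length(tree$tip.label), median(supp), min(supp)))

  true_tree <- ape::read.tree(file.path(DATA_DIR, group, "genealogy.nwk"))
  rf <- phangorn::RF.dist(ape::unroot(tree), ape::unroot(true_tree))
  message(sprintf("[%s] Robinson-Foulds distance to the true genealogy: %d", group, rf))
}
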