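#!/usr/bin/env Rscript
# Core-genome construction for each group: single-copy ortholog families
# against the ancestor reference, per-gene alignments concatenated into the
# core alignment, pangenome singleton statistics, and the ANI matrix.

source("analysis/00_config.R")

outdir <- file.path(RESULTS_DIR, "core")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

for (group in names(study_configs())) {
  genomes <- load_group(group)
  leaves <- genomes[names(genomes) != "ancestor"]
  ort <- identify_orthologs(genomes, reference = "ancestor")
  aln <- core_alignment(genomes, ort)
  aln <- aln[setdiff(rownames(aln), "ancestor"), , drop = FALSE]
  message(sprintf("[%s] %d single-copy families; core alignment %d taxa x %d columns",
                  group, length(unique(ort$family_id)), nrow(aln), ncol(aln)))
  write.table(ort, file.path(outdir, paste0("families_", group, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  fa <- Biostrings::DNAStringSet(apply(aln, 1, paste, collapse = ""))
  Biostrings::writeXStringSet(fa, file.path(outdir, paste0("core_", group, ".fasta")),
                              width = 80)
  bd <- attr(aln, "boundaries")
  write.table(data.frame(family_id = bd$family_id, start = bd$start - 1L,
                         end = bd$end),
              file.path(outdir, paste0("boundaries_", group, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  pg <- cluster_pangenome(leaves)
  message(sprintf("[%s] pangenome: %d clusters, %d core, %d flexible, %d singletons (%.1f%% of flexible)",
                  group, pg$n_clusters, pg$n_core, pg$n_flexible,
                  pg$singleton_count, 100 * pg$singleton_fraction_of_flexible))

  ids <- names(leaves)
  ani <- matrix(100, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) for (j in seq_along(ids)) if (i != j)
    ani[i, j] <- average_nucleotide_identity(leaves[[i]], leaves[[j]])
  write.table(round(ani, 3), file.path(outdir, paste0("ani_", group, ".tsv")),
              sep = "\t", quote = FALSE, col.names = NA)
  message(sprintf("[%s] ANI range off-diagonal: %.2f-%.2f%%",
                  group, min(ani[upper.tri(ani)]), max(ani[upper.tri(ani)])))
}
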