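# Shared configuration for the analysis scripts.
#
# Two simulated strain groups emulate the study contrast: a "subseafloor"
# group evolving nearly clonally (low R/theta, long rare imports of low
# divergence, elevated pseudogenization) and a "type" group with roughly
# 10-fold more recombination per mutation and fewer gene-decay events.
# Recombination parameters are the published group presets
# (clonalkit::recomb_presets()); the remaining knobs are chosen to keep the
# demonstration dataset small enough to re-run in minutes while preserving
# the qualitative structure: ~100 kb of genome carrying 40 genes, 8 + 8
# taxa, root-to-leaf depth 0.01 substitutions/site.

library(clonalkit)

RESULTS_DIR <- "results"
DATA_DIR <- file.path(RESULTS_DIR, "data")

study_configs <- function(seed = 20240901) {
  pre <- recomb_presets()
  sub <- pre[pre$group == "subseafloor", ]
  typ <- pre[pre$group == "type", ]
  list(
    subseafloor = sim_config(
      n_taxa = 8, genome_length = 100000, n_genes = 40,
      mean_gene_length = 900, gc_content = 0.55,
      theta_site = 1, total_depth = 0.01,
      r_over_theta = sub$r_over_theta, delta = sub$delta, nu = sub$nu,
      indel_rate = 2e-4, indel_length_mean = 5,
      pseudogenization_rate = 80, seed = seed),
    type = sim_config(
      n_taxa = 8, genome_length = 100000, n_genes = 40,
      mean_gene_length = 900, gc_content = 0.55,
      theta_site = 1, total_depth = 0.01,
      r_over_theta = typ$r_over_theta, delta = typ$delta, nu = typ$nu,
      indel_rate = 2e-4, indel_length_mean = 5,
      pseudogenization_rate = 8, seed = seed + 1))
}

load_group <- function(group) {
  dir <- file.path(DATA_DIR, group)
  if (!dir.exists(dir))
    stop("dataset for group '", group,
         "' not found; run analysis/01_simulate.R first")
  read_dataset(dir)
}
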