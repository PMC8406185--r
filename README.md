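# clonalkit

Tools for quantifying clonal, recombination-poor genome evolution in sets of
closely related bacterial isolates — the situation of populations physically
isolated from each other and from outside sources of DNA (energy-limited
subseafloor sediments being the motivating case), where diversification
proceeds by point mutation and genetic drift rather than by homologous
recombination, and nonfunctional gene copies accumulate.

The package covers the full comparative-genomics chain for this question,
driven by a forward simulator so that every stage can be exercised and scored
against ground truth without downloading genomes:

- **Synthetic data** — `simulate_dataset()` evolves annotated ~Mbp-scale
  chromosomes down a clonal genealogy with point substitutions,
  homologous-recombination imports (geometric tract lengths, diverged donor),
  indels, and gene-disrupting pseudogenization events, recording every event
  in an `evolution_truth` object.
- **Core genome** — single-copy ortholog families against a reference genome
  (`identify_orthologs()`, >30% amino-acid similarity, paralog exclusion),
  per-gene center-star alignment and concatenation (`core_alignment()`),
  pangenome single-linkage clustering with singleton statistics
  (`cluster_pangenome()`), and fragment-based average nucleotide identity
  (`average_nucleotide_identity()`, ANIb convention via blastn).
- **Phylogeny** — Jukes–Cantor distances, neighbor joining with midpoint
  rooting (`nj_tree()`), column-bootstrap support, and Fitch-parsimony
  ancestral reconstruction (`reconstruct_ancestors()`).
- **Recombination** — a per-branch two-state hidden Markov model over
  core-alignment sites (`fit_recombination_hmm()`), estimating by EM the
  shared parameters R/θ (import initiations per mutation), δ (mean import
  length) and ν (mean divergence of imported DNA), plus a free clonal branch
  length b per branch. The headline statistic is

      r/m = (R/θ) × δ × ν

  the ratio of substitutions introduced by recombination to those introduced
  by mutation. `decode_imports()` lists the posterior import segments.
- **Selection and decay** — Nei–Gojobori counting dN/dS per branch on the
  in-frame codon alignment (`per_branch_omega()`), pseudogene detection by
  the >20% length-loss rule (`detect_pseudogenes()`), group summaries and
  the ω-versus-pseudogene-load regression.
- **Population dynamics** — pairwise SNP/indel diversity and the
  mutation-accumulation null model (`expected_diversity()`,
  `generations_required()`, Drake's-rule rate preset) that asks whether
  observed diversity could have arisen during laboratory culture.
- **Statistics** — Welch t tests, permutation ANOSIM, OLS.

## Worked example

```r
library(clonalkit)

cfg <- sim_config(n_taxa = 12, genome_length = 200000, n_genes = 0,
                  r_over_theta = 0.04, delta = 333, nu = 0.053,
                  total_depth = 0.01, seed = 7)
out <- simulate_dataset(cfg)
fit <- estimate_recombination(leaf_alignment(out$genomes),
                              tol = 1e-3, max_iter = 300)
fit
#> <recomb_fit> R/theta = 0.04231, delta = 334.7, nu = 0.05321, r/m = 0.7536
#>   22 branches, loglik -121141.28, converged after 9 EM iterations
truth_r_over_m(out$truth)
#> [1] 0.6885
```

The fit recovers the generating parameters (R/θ = 0.04, δ = 333, ν = 0.053)
within a few percent at this alignment size, and the estimated r/m agrees
with the realized truth ratio (imported substitutions ÷ clonal
substitutions). The same machinery applied to a low-recombination
configuration (R/θ = 0.006, δ = 500, ν = 0.026 → r/m = 0.078) estimates an
r/m roughly ten-fold lower, the contrast that distinguishes a clonal
population from a freely recombining one.

The generation arithmetic of the culture protocol:

```r
doublings_from_abundance(1, 3.3e9)                       # 31.62 per colony
cumulative_generations(list(list("fixed", 15.67),
                            list("colony", 3.3e9)))      # 47.29
generations_required(drift_model(1e-9, 4.7e6, 1), 20)    # ~4255
```

At common bacterial mutation rates, thousands of generations would be needed
to produce tens of pairwise differences — far more than the ~79 generations
attainable during enrichment and isolation, so observed inter-isolate
diversity must predate the laboratory.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
package's study-style analysis on simulated data, writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R          # two strain groups + ground truth
Rscript analysis/02_core_genome.R       # orthologs, core alignment, pangenome, ANI
Rscript analysis/03_phylogeny.R         # NJ genealogy + bootstrap
Rscript analysis/04_recombination.R     # HMM fits, import segments, r/m table
Rscript analysis/05_selection_decay.R   # dN/dS, pseudogenes, regressions
Rscript analysis/06_population_dynamics.R
Rscript analysis/07_report.R            # headline summary table + figures
```

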