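#' Simulation configuration for clonal genome evolution
#'
#' Collects every knob of the forward simulator into one validated object.
#' Rates are expressed per site (or per gene) per unit of branch length, so a
#' branch of length `b` accumulates point substitutions at density
#' `theta_site * b`, recombination-import initiations at
#' `r_over_theta * theta_site * b`, indel events at `indel_rate * b` and
#' pseudogenization events at `pseudogenization_rate * b` per gene.
#'
#' @param n_taxa number of extant genomes (tree leaves), >= 2.
#' @param genome_length ancestral chromosome length in bp (one circular
#'   chromosome represented as a single linear contig).
#' @param n_genes number of single-copy protein-coding genes packed into the
#'   ancestor; may be 0 for a purely intergenic genome.
#' @param mean_gene_length mean CDS length in bp (drawn per gene, rounded to a
#'   codon multiple, minimum 90 bp).
#' @param gc_content ancestral GC fraction, strictly between 0 and 1.
#' @param theta_site expected substitutions per site per unit branch length.
#' @param r_over_theta recombination-import initiations per point mutation
#'   (the R/theta of the recombination model).
#' @param delta mean length of an imported tract in bp (geometric, >= 1).
#' @param nu per-site divergence of imported DNA, between 0 and 0.75.
#' @param indel_rate indel events per site per unit branch length.
#' @param indel_length_mean mean indel length in bp (geometric).
#' @param indel_gene_bias probability that an indel lands inside a gene
#'   (emulates the observed concentration of indels in coding regions);
#'   remaining mass is uniform over the genome.
#' @param pseudogenization_rate gene-disrupting events per gene per unit
#'   branch length.
#' @param tree_shape `"balanced"` (recursive bisection, all root-to-leaf path
#'   lengths equal to `total_depth`) or `"random-coalescent"` (standard
#'   coalescent topology rescaled to depth `total_depth`).
#' @param total_depth root-to-leaf branch-length units.
#' @param seed integer seed driving the one global RNG of the simulator.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 12,
                       genome_length = 100000,
                       n_genes = 40,
                       mean_gene_length = 900,
                       gc_content = 0.55,
                       theta_site = 1,
                       r_over_theta = 0.01,
                       delta = 300,
                       nu = 0.04,
                       indel_rate = 0,
                       indel_length_mean = 5,
                       indel_gene_bias = 0.8,
                       pseudogenization_rate = 0,
                       tree_shape = c("balanced", "random-coalescent"),
                       total_depth = 0.01,
                       seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  cfg <- list(
    n_taxa = as.integer(n_taxa), genome_length = as.integer(genome_length),
    n_genes = as.integer(n_genes), mean_gene_length = as.integer(mean_gene_length),
    gc_content = gc_content, theta_site = theta_site,
    r_over_theta = r_over_theta, delta = delta, nu = nu,
    indel_rate = indel_rate, indel_length_mean = indel_length_mean,
    indel_gene_bias = indel_gene_bias,
    pseudogenization_rate = pseudogenization_rate,
    tree_shape = tree_shape, total_depth = total_depth, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  rates <- c("theta_site", "r_over_theta", "indel_rate",
             "pseudogenization_rate", "total_depth")
  for (r in rates) {
    if (!is.numeric(cfg[[r]]) || length(cfg[[r]]) != 1 || cfg[[r]] < 0)
      stop(sprintf("'%s' must be a single non-negative number", r))
  }
  if (cfg$n_taxa < 2) stop("'n_taxa' must be >= 2")
  if (cfg$genome_length < 1) stop("'genome_length' must be positive")
  if (cfg$n_genes < 0) stop("'n_genes' must be >= 0")
  if (cfg$gc_content <= 0 || cfg$gc_content >= 1)
    stop("'gc_content' must lie strictly between 0 and 1")
  if (cfg$delta < 1) stop("'delta' (mean import length) must be >= 1")
  if (cfg$nu < 0 || cfg$nu > 0.75) stop("'nu' must lie in [0, 0.75]")
  if (cfg$indel_length_mean < 1) stop("'indel_length_mean' must be >= 1")
  if (cfg$indel_gene_bias < 0 || cfg$indel_gene_bias > 1)
    stop("'indel_gene_bias' must lie in [0, 1]")
  if (cfg$n_genes * cfg$mean_gene_length > cfg$genome_length)
    stop("gene complement does not fit: n_genes * mean_gene_length exceeds genome_length")
  invisible(cfg)
}

#' Recombination-parameter presets for the two strain groups
#'
#' Published point estimates of the recombination parameters for subseafloor
#' *Thalassospira* isolates, surface-world type strains, and the combined set
#' (with group sizes). These serve both as simulator presets (e.g. to emulate
#' the relative recombination regimes of the two habitats) and as worked
#' inputs to [compute_r_over_m()]. They are point estimates of the study
#' system, not ground truth of nature.
#'
#' @return A data.frame with columns `group`, `n_strains`, `r_over_theta`,
#'   `delta`, `nu`.
#' @export
recomb_presets <- function() {
  data.frame(
    group = c("subseafloor", "type", "all"),
    n_strains = c(21L, 13L, 34L),
    r_over_theta = c(0.006, 0.04, 0.053),
    delta = c(500, 333, 244),
    nu = c(0.026, 0.053, 0.055),
    stringsAsFactors = FALSE
  )
}
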