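# Pairwise nucleotide diversity and the laboratory-generation null model:
# could the diversity observed among isolates have arisen during enrichment
# and cultivation rather than in situ?

#' Pairwise SNP and indel-event diversity
#'
#' For each pair of rows: SNPs are columns where both taxa are non-gap and
#' differ; indel events are maximal runs of columns gapped in exactly one of
#' the two (each maximal run = one event; runs separated by a single
#' non-gap column are distinct events).
#'
#' @param alignment character matrix, rows = taxa.
#' @return list of class `diversity_matrix`: `snp` and `indel_events`,
#'   both symmetric matrices with zero diagonals.
#' @export
pairwise_diversity <- function(alignment) {
  n <- nrow(alignment)
  taxa <- rownames(alignment)
  A <- toupper(alignment)
  gap <- A == "-"
  snp <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  ind <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- !gap[i, ] & !gap[j, ]
    snp[i, j] <- snp[j, i] <- sum(both & A[i, ] != A[j, ])
    one <- xor(gap[i, ], gap[j, ])
    r <- rle(one)
    ind[i, j] <- ind[j, i] <- sum(r$values)
    }
  structure(list(snp = snp, indel_events = ind), class = "diversity_matrix")
}

#' Drift model of expected diversity accumulated in culture
#'
#' @param mu_bp mutations per bp per generation.
#' @param L genome length in bp.
#' @param pairwise_factor 2 when both lineages of a compared pair accumulate
#'   mutations since their common ancestor (the default), 1 for divergence
#'   from a fixed reference.
#' @return list of class `drift_model`.
#' @export
drift_model <- function(mu_bp = 1e-9, L = 4.7e6, pairwise_factor = 2) {
  stopifnot(mu_bp > 0, L > 0, pairwise_factor %in% c(1, 2))
  structure(list(mu_bp = mu_bp, L = L, pairwise_factor = pairwise_factor),
            class = "drift_model")
}

#' Drake's-rule mutation rate
#'
#' Roughly one mutation per 300 bacterial genome replications, expressed per
#' bp per generation for a genome of length `L`.
#'
#' @param L genome length (bp).
#' @return mutations per bp per generation.
#' @export
drake_rate <- function(L = 4.7e6) (1 / 300) / L

#' Expected pairwise differences after G generations
#'
#' D = pairwise_factor x mu_bp x L x G, linear in G.
#'
#' @param model a [drift_model()].
#' @param G generations (>= 0).
#' @return expected number of nucleotide differences per genome pair.
#' @export
expected_diversity <- function(model, G) {
  stopifnot(all(G >= 0))
  model$pairwise_factor * model$mu_bp * model$L * G
}

#' Generations required to reach an observed diversity
#'
#' Exact inverse of [expected_diversity()].
#'
#' @param model a [drift_model()].
#' @param D_obs observed number of differences (> 0).
#' @return generations.
#' @export
generations_required <- function(model, D_obs) {
  if (any(D_obs <= 0)) stop("'D_obs' must be positive")
  D_obs / (model$pairwise_factor * model$mu_bp * model$L)
}

#' Doublings between two abundances
#'
#' From X = 2^n X0: n = log2(X / X0).
#'
#' @param X0,X initial and final abundance (cells, gene copies, or OD).
#' @return number of doublings.
#' @export
doublings_from_abundance <- function(X0, X) {
  if (any(c(X0, X) <= 0)) stop("abundances must be positive")
  log2(X / X0)
}

#' Total generations across culture stages
#'
#' Each stage is either a fixed doubling count (`list("fixed", n)`) or a
#' colony grown from a single cell (`list("colony", cells)`, contributing
#' log2(cells) doublings).
#'
#' @param stages list of stages; empty list gives 0.
#' @return total number of generations.
#' @export
cumulative_generations <- function(stages) {
  if (length(stages) == 0) return(0)
  sum(vapply(stages, function(s) {
    kind <- s[[1]]
    if (kind == "fixed") as.numeric(s[[2]])
    else if (kind == "colony") doublings_from_abundance(1, as.numeric(s[[2]]))
    else stop("unknown stage kind: ", kind)
  }, 0))
}

#' Exponential growth rate
#'
#' mu = (ln X - ln X0) / (t - t0), per unit of t.
#'
#' @param X0,X initial and final density (> 0).
#' @param t0,t corresponding times (t > t0).
#' @return growth rate.
#' @export
growth_rate <- function(X0, X, t0, t) {
  if (any(c(X0, X) <= 0)) stop("densities must be positive")
  if (t <= t0) stop("'t' must exceed 't0'")
  (log(X) - log(X0)) / (t - t0)
}

#' Doubling time from a growth rate
#' @param mu growth rate (per unit time).
#' @return ln(2)/mu in the same time unit.
#' @export
doubling_time <- function(mu) log(2) / mu

#' Oxygen consumption rate
#'
#' (starting concentration - final concentration) / days, e.g. in
#' micromoles O2 per liter per day.
#'
#' @param c_start,c_final O2 concentrations.
#' @param days elapsed days (> 0).
#' @return consumption rate.
#' @export
o2_consumption_rate <- function(c_start, c_final, days) {
  if (days <= 0) stop("'days' must be positive")
  (c_start - c_final) / days
}
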