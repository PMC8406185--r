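# Shared fixtures: small simulated datasets, built once per test run and
# cached, so individual tests stay fast and deterministic.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# a small clonal dataset: substitutions only, no imports/indels/decay
clonal_dataset <- function() {
  fixture("clonal", function() {
    simulate_dataset(sim_config(
      n_taxa = 6, genome_length = 30000, n_genes = 15,
      r_over_theta = 0, indel_rate = 0, pseudogenization_rate = 0,
      total_depth = 0.01, seed = 101))
  })
}

# recombination present at the high-recombination group preset
recomb_dataset <- function() {
  fixture("recomb", function() {
    simulate_dataset(sim_config(
      n_taxa = 8, genome_length = 150000, n_genes = 0,
      r_over_theta = 0.04, delta = 333, nu = 0.053,
      total_depth = 0.01, seed = 202))
  })
}

# random codon sequences and a neutral mutation process restricted to the
# sense-codon chain (mutations that would create a stop are redrawn)
random_sense_codons <- function(n) {
  sense <- names(ng86_site_table())
  sample(sense, n, replace = TRUE)
}

mutate_codons_neutral <- function(codons, p) {
  m <- do.call(rbind, strsplit(codons, ""))
  hit <- which(matrix(runif(length(m)) < p, nrow = nrow(m)), arr.ind = TRUE)
  for (r in seq_len(nrow(hit))) {
    i <- hit[r, 1]; j <- hit[r, 2]
    repeat {
      cand <- m[i, ]
      cand[j] <- sample(setdiff(c("A", "C", "G", "T"), m[i, j]), 1)
      if (!paste(cand, collapse = "") %in% c("TAA", "TAG", "TGA")) {
        m[i, ] <- cand
        break
      }
    }
  }
  paste0(m[, 1], m[, 2], m[, 3])
}

# neutral process with nonsynonymous changes accepted at probability `w`
# (purifying selection when w < 1); stops never accepted
mutate_codons_selected <- function(codons, p, w) {
  gc <- Biostrings::GENETIC_CODE
  m <- do.call(rbind, strsplit(codons, ""))
  hit <- which(matrix(runif(length(m)) < p, nrow = nrow(m)), arr.ind = TRUE)
  for (r in seq_len(nrow(hit))) {
    i <- hit[r, 1]; j <- hit[r, 2]
    cand <- m[i, ]
    cand[j] <- sample(setdiff(c("A", "C", "G", "T"), m[i, j]), 1)
    new <- paste(cand, collapse = "")
    if (new %in% c("TAA", "TAG", "TGA")) next
    syn <- gc[[new]] == gc[[paste(m[i, ], collapse = "")]]
    if (syn || runif(1) < w) m[i, ] <- cand
  }
  paste0(m[, 1], m[, 2], m[, 3])
}
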