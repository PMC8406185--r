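# Forward simulator of clonal bacterial genome evolution.
#
# The generative model mirrors the recombination-detection HMM fitted
# downstream: along a branch of length b, point substitutions arrive at
# density theta_site*b per site; recombination imports initiate at
# r_over_theta*theta_site*b per site with geometric tract lengths (mean
# delta) and per-site donor divergence nu; indels arrive at indel_rate*b per
# site with geometric lengths; and genes are disrupted (premature stop or
# terminal truncation) at pseudogenization_rate*b per gene. Event order along
# a branch is fixed: imports, substitutions, pseudogenization, indels.
# Every event is recorded in an EvolutionTruth object so detector accuracy
# can be scored against ground truth.

base_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

# stop codons in integer coding (coding strand)
.STOP_INT <- list(c(4L, 1L, 1L), c(4L, 1L, 3L), c(4L, 3L, 1L))

is_stop_cols <- function(m) {
  # m: 3 x k integer matrix of codons
  (m[1, ] == 4L & m[2, ] == 1L & (m[3, ] == 1L | m[3, ] == 3L)) |
    (m[1, ] == 4L & m[2, ] == 3L & m[3, ] == 1L)
}

sample_sense_codons <- function(k, p) {
  if (k == 0) return(matrix(integer(), 3, 0))
  m <- matrix(sample.int(4L, 3 * k, replace = TRUE, prob = p), nrow = 3)
  bad <- which(is_stop_cols(m))
  while (length(bad) > 0) {
    m[, bad] <- sample.int(4L, 3 * length(bad), replace = TRUE, prob = p)
    bad <- bad[is_stop_cols(m[, bad, drop = FALSE])]
  }
  m
}

#' Simulate the ancestral genome
#'
#' Draws a random chromosome at the requested length and GC content and packs
#' `n_genes` non-overlapping intact ORFs into it (ATG start, sense codons, a
#' stop codon, random strand). Gene lengths are normal around
#' `mean_gene_length` (sd 15%), rounded to codon multiples, minimum 90 bp.
#'
#' @param config a [sim_config()].
#' @return an [annotated_genome()] with id `"ancestor"`.
#' @export
simulate_ancestor <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  L <- config$genome_length
  p <- base_probs(config$gc_content)
  seq <- sample.int(4L, L, replace = TRUE, prob = p)
  genes <- NULL
  n <- config$n_genes
  if (n > 0) {
    lens <- 3L * pmax(30L, round(rnorm(n, config$mean_gene_length / 3,
                                       config$mean_gene_length * 0.15 / 3)))
    if (sum(lens) > L)
      stop("infeasible gene packing: drawn gene lengths exceed genome length")
    slack <- L - sum(lens)
    gaps <- as.vector(rmultinom(1, slack, rep(1, n + 1)))
    starts <- cumsum(gaps[seq_len(n)] + c(0L, lens[-n])) + 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    for (i in seq_len(n)) {
      ncod <- lens[i] %/% 3L
      orf <- c(c(1L, 4L, 3L),                      # ATG
               as.vector(sample_sense_codons(ncod - 2L, p)),
               .STOP_INT[[sample.int(3L, 1)]])
      if (strand[i] == "-") orf <- revcomp_int(orf)
      seq[starts[i]:(starts[i] + lens[i] - 1L)] <- orf
    }
    genes <- data.frame(
      gene_id = sprintf("g%04d", seq_len(n)),
      start = starts, end = starts + lens - 1L,
      strand = strand, frame = 0L, pseudo = FALSE,
      stringsAsFactors = FALSE
    )
  }
  annotated_genome("ancestor", seq, genes)
}

#' Simulate the clonal genealogy
#'
#' Builds the rooted binary tree the genomes evolve along. `"balanced"`
#' recursively bisects the taxon set and allocates branch lengths so every
#' root-to-leaf path sums exactly to `total_depth`; `"random-coalescent"`
#' draws a standard coalescent topology and rescales it to that depth.
#'
#' @param config a [sim_config()].
#' @return a rooted `phylo` with `n_taxa` leaves labelled `t01`, `t02`, ...
#' @export
simulate_genealogy <- function(config) {
  validate_sim_config(config)
  n <- config$n_taxa
  if (n < 2) stop("need at least two taxa")
  tips <- sprintf("t%02d", seq_len(n))
  set.seed(config$seed + 1L)
  if (config$tree_shape == "balanced") {
    rec <- function(idx, budget) {
      # returns "(...)" for the set; the caller attaches the edge length
      k <- length(idx)
      lev <- ceiling(log2(k))
      halves <- split(idx, rep(1:2, c(ceiling(k / 2), floor(k / 2))))
      part <- vapply(halves, function(h) {
        if (length(h) == 1) return(sprintf("%s:%.15g", tips[h], budget))
        sub_lev <- ceiling(log2(length(h)))
        el <- budget * (1 - sub_lev / lev)
        sprintf("%s:%.15g", rec(h, budget - el), el)
      }, character(1))
      sprintf("(%s,%s)", part[1], part[2])
    }
    tr <- ape::read.tree(text = paste0(rec(seq_len(n), config$total_depth), ";"))
  } else {
    tr <- ape::rcoal(n, tip.label = tips)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * config$total_depth / depth
  }
  tr
}

node_labels <- function(tree) {
  c(tree$tip.label, sprintf("n%02d", (length(tree$tip.label) + 1):
                              (length(tree$tip.label) + tree$Nnode)))
}

# ---- per-branch event machinery --------------------------------------------

mutate_sites <- function(seq, sites) {
  # substitute each site to a uniformly chosen different base; sequential so
  # repeat hits at one site see the current state
  from <- integer(length(sites)); to <- integer(length(sites))
  for (i in seq_along(sites)) {
    s <- sites[i]
    from[i] <- seq[s]
    to[i] <- sample((1:4)[-seq[s]], 1)
    seq[s] <- to[i]
  }
  list(seq = seq, from = from, to = to)
}

apply_imports <- function(state, b, cfg) {
  L <- length(state$seq)
  lam <- cfg$r_over_theta * cfg$theta_site * b * L
  n0 <- rpois(1, lam)
  rec <- data.frame(start = integer(), end = integer(), length = integer(),
                    n_changed = integer(), divergence = numeric())
  if (n0 == 0) return(list(state = state, rec = rec))
  starts <- sample.int(L, n0, replace = TRUE)
  lens <- rgeom(n0, 1 / cfg$delta) + 1L
  tr <- IRanges::reduce(IRanges::IRanges(starts, pmin(L, starts + lens - 1L)))
  st <- IRanges::start(tr); en <- IRanges::end(tr)
  nch <- integer(length(st))
  for (i in seq_along(st)) {
    idx <- st[i]:en[i]
    hit <- which(runif(length(idx)) < cfg$nu)
    if (length(hit) > 0) {
      pos <- idx[hit]
      state$seq[pos] <- (state$seq[pos] - 1L +
                           sample.int(3L, length(pos), replace = TRUE)) %% 4L + 1L
    }
    nch[i] <- length(hit)
  }
  rec <- data.frame(start = st, end = en, length = en - st + 1L,
                    n_changed = nch, divergence = nch / (en - st + 1))
  list(state = state, rec = rec)
}

apply_substitutions <- function(state, b, cfg) {
  L <- length(state$seq)
  nmut <- rpois(1, cfg$theta_site * b * L)
  if (nmut == 0)
    return(list(state = state,
                rec = data.frame(site = integer(), from = character(),
                                 to = character())))
  sites <- sample.int(L, nmut, replace = TRUE)
  m <- mutate_sites(state$seq, sites)
  state$seq <- m$seq
  list(state = state,
       rec = data.frame(site = sites, from = BASES[m$from], to = BASES[m$to]))
}

# scan the realized intact ORF: from the gene start, in the coding frame,
# up to cap_len bp along the genome; intact length ends at (and includes)
# the first stop codon
orf_intact_length <- function(seq, start, end, strand, cap_len) {
  L <- length(seq)
  if (strand == "+") {
    lim <- min(L, start + cap_len - 1L)
    cod <- seq[start:lim]
  } else {
    lim <- max(1L, end - cap_len + 1L)
    cod <- revcomp_int(seq[lim:end])
  }
  k <- length(cod) %/% 3L
  if (k == 0) return(0L)
  m <- matrix(cod[seq_len(3L * k)], nrow = 3)
  stops <- which(is_stop_cols(m))
  if (length(stops) == 0) return(min(cap_len, 3L * k))
  3L * stops[1]
}

insert_segment <- function(state, pos, ins) {
  # insertion lands between pos and pos+1
  state$seq <- append(state$seq, ins, after = pos)
  len <- length(ins)
  g <- state$genes
  if (nrow(g) > 0) {
    within <- g$start <= pos & g$end > pos
    after <- g$start > pos
    g$start[after] <- g$start[after] + len
    g$end[after] <- g$end[after] + len
    g$end[within] <- g$end[within] + len
    state$genes <- g
  }
  state
}

delete_segment <- function(state, pos, len) {
  L <- length(state$seq)
  d_end <- min(L, pos + len - 1L)
  eff <- d_end - pos + 1L
  state$seq <- state$seq[-(pos:d_end)]
  g <- state$genes
  dropped <- character()
  if (nrow(g) > 0) {
    shift <- function(x, is_end) {
      out <- x
      out[x > d_end] <- x[x > d_end] - eff
      inside <- x >= pos & x <= d_end
      out[inside] <- if (is_end) pos - 1L else pos
      out
    }
    g$start <- shift(g$start, FALSE)
    g$end <- shift(g$end, TRUE)
    gone <- g$end < g$start
    dropped <- g$gene_id[gone]
    state$genes <- g[!gone, , drop = FALSE]
  }
  list(state = state, dropped = dropped)
}

apply_pseudogenization <- function(state, b, cfg, anc_len) {
  rec <- data.frame(gene_id = character(), mechanism = character(),
                    reference_length = integer(),
                    observed_intact_length = integer(),
                    fraction_lost = numeric())
  g <- state$genes
  active <- which(!g$pseudo & !is.na(anc_len[g$gene_id]))
  if (length(active) == 0 || cfg$pseudogenization_rate * b == 0)
    return(list(state = state, rec = rec))
  hit <- active[rpois(length(active), cfg$pseudogenization_rate * b) > 0]
  for (i in hit) {
    g <- state$genes
    gid <- g$gene_id[i]
    ref_len <- anc_len[[gid]]
    ncod <- (g$end[i] - g$start[i] + 1L) %/% 3L
    if (ncod < 4) next
    mech <- sample(c("premature_stop", "truncation"), 1)
    if (mech == "premature_stop") {
      # stop placed in the first 75% of codons so the event always loses >20%
      j <- sample(2:max(2L, floor(0.75 * ncod)), 1)
      stop_cod <- .STOP_INT[[sample.int(3L, 1)]]
      if (g$strand[i] == "+") {
        pos <- g$start[i] + 3L * (j - 1L) + 0:2
        state$seq[pos] <- stop_cod
      } else {
        pos <- (g$end[i] - 3L * (j - 1L)) - 0:2
        state$seq[rev(pos)] <- revcomp_int(stop_cod)
      }
    } else {
      cut <- 3L * floor(runif(1, 0.25, 0.55) * ncod)
      if (g$strand[i] == "+") {
        del <- delete_segment(state, g$end[i] - cut + 1L, cut)
      } else {
        del <- delete_segment(state, g$start[i], cut)
      }
      state <- del$state
    }
    gi <- match(gid, state$genes$gene_id)
    if (is.na(gi)) next
    state$genes$pseudo[gi] <- TRUE
    intact <- orf_intact_length(state$seq, state$genes$start[gi],
                                state$genes$end[gi], state$genes$strand[gi],
                                ref_len)
    rec <- rbind(rec, data.frame(
      gene_id = gid, mechanism = mech, reference_length = ref_len,
      observed_intact_length = intact,
      fraction_lost = max(0, 1 - intact / ref_len)))
  }
  list(state = state, rec = rec)
}

apply_indels <- function(state, b, cfg) {
  rec <- data.frame(site = integer(), length = integer(), sign = integer())
  dropped <- character()
  nev <- rpois(1, cfg$indel_rate * b * length(state$seq))
  if (nev == 0) return(list(state = state, rec = rec, dropped = dropped))
  p <- base_probs(cfg$gc_content)
  for (k in seq_len(nev)) {
    L <- length(state$seq)
    g <- state$genes
    in_gene <- nrow(g) > 0 && runif(1) < cfg$indel_gene_bias
    pos <- if (in_gene) {
      gi <- sample.int(nrow(g), 1)
      sample(g$start[gi]:g$end[gi], 1)
    } else sample.int(L, 1)
    len <- rgeom(1, 1 / cfg$indel_length_mean) + 1L
    sgn <- sample(c(-1L, 1L), 1)
    if (sgn > 0) {
      ins <- sample.int(4L, len, replace = TRUE, prob = p)
      state <- insert_segment(state, pos, ins)
    } else {
      del <- delete_segment(state, pos, len)
      state <- del$state
      dropped <- c(dropped, del$dropped)
    }
    rec <- rbind(rec, data.frame(site = pos, length = len, sign = sgn))
  }
  list(state = state, rec = rec, dropped = dropped)
}

#' Evolve genomes along the genealogy
#'
#' Walks the rooted tree from the ancestor, applying imports, substitutions,
#' pseudogenization and indels on each branch (in that fixed order) and
#' recording every event.
#'
#' @param ancestor the [simulate_ancestor()] genome.
#' @param genealogy rooted `phylo` from [simulate_genealogy()].
#' @param config the [sim_config()].
#' @return list with `genomes` (named list of [annotated_genome()] per leaf),
#'   `truth` (class `evolution_truth`: per-branch event tables), `tree`
#'   (the genealogy with internal node labels), and `ancestors` (internal
#'   node states, for oracle checks).
#' @export
evolve_genomes <- function(ancestor, genealogy, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  tr <- ape::reorder.phylo(genealogy, "cladewise")
  labs <- node_labels(tr)
  ntip <- length(tr$tip.label)
  states <- vector("list", ntip + tr$Nnode)
  states[[ntip + 1L]] <- list(seq = ancestor$seq, genes = ancestor$genes)
  anc_len <- setNames(ancestor$genes$end - ancestor$genes$start + 1L,
                      ancestor$genes$gene_id)
  branches <- list()
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; chi <- tr$edge[e, 2]
    b <- tr$edge.length[e]
    st <- states[[par]]
    imp <- apply_imports(st, b, config); st <- imp$state
    sub <- apply_substitutions(st, b, config); st <- sub$state
    psg <- apply_pseudogenization(st, b, config, anc_len); st <- psg$state
    ind <- apply_indels(st, b, config); st <- ind$state
    states[[chi]] <- st
    branches[[labs[chi]]] <- list(
      parent = labs[par], child = labs[chi], length = b,
      substitutions = sub$rec, imports = imp$rec,
      indels = ind$rec, pseudogenizations = psg$rec,
      dropped_genes = ind$dropped)
  }
  genomes <- lapply(seq_len(ntip), function(i)
    annotated_genome(labs[i], states[[i]]$seq, states[[i]]$genes))
  names(genomes) <- labs[seq_len(ntip)]
  ancestors <- lapply((ntip + 1L):(ntip + tr$Nnode), function(i) states[[i]])
  names(ancestors) <- labs[(ntip + 1L):(ntip + tr$Nnode)]
  truth <- structure(list(branches = branches, node_labels = labs,
                          config = config),
                     class = "evolution_truth")
  tr$node.label <- labs[(ntip + 1L):(ntip + tr$Nnode)]
  list(genomes = genomes, truth = truth, tree = tr, ancestors = ancestors)
}

#' Flatten one event type of the truth object into a table
#'
#' @param truth an `evolution_truth`.
#' @param what one of `"substitutions"`, `"imports"`, `"indels"`,
#'   `"pseudogenizations"`.
#' @return data.frame with a leading `branch` column (child-node label).
#' @export
truth_table <- function(truth, what = c("substitutions", "imports", "indels",
                                        "pseudogenizations")) {
  what <- match.arg(what)
  out <- lapply(truth$branches, function(br) {
    d <- br[[what]]
    if (nrow(d) == 0) return(NULL)
    cbind(branch = br$child, d, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- cbind(branch = character(0),
                 truth$branches[[1]][[what]][0, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Ground-truth r/m from the simulator event record
#'
#' Ratio of substitutions introduced by recombination imports to those
#' introduced by clonal point mutation, summed over all branches.
#'
#' @param truth an `evolution_truth`.
#' @return a single ratio (NaN when no clonal substitutions occurred).
#' @export
truth_r_over_m <- function(truth) {
  imp <- sum(vapply(truth$branches, function(b) sum(b$imports$n_changed), 0))
  mut <- sum(vapply(truth$branches, function(b) nrow(b$substitutions), 0))
  imp / mut
}

#' Simulate a complete dataset in one call
#'
#' @param config a [sim_config()].
#' @return as [evolve_genomes()], plus the `ancestor` genome.
#' @export
simulate_dataset <- function(config) {
  anc <- simulate_ancestor(config)
  tr <- simulate_genealogy(config)
  out <- evolve_genomes(anc, tr, config)
  out$ancestor <- anc
  out
}

#' Leaf alignment for indel-free simulations
#'
#' When the simulation produced no length changes the leaf genomes are
#' columnwise homologous and form a core alignment directly.
#'
#' @param genomes named list of leaf genomes.
#' @return character matrix, rows = taxa, columns = sites.
#' @export
leaf_alignment <- function(genomes) {
  lens <- vapply(genomes, function(g) length(g$seq), 0L)
  if (length(unique(lens)) != 1)
    stop("leaf genomes differ in length; build a core alignment instead")
  m <- t(vapply(genomes, function(g) BASES[g$seq], character(lens[1])))
  rownames(m) <- names(genomes)
  m
}
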