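# Clonal genealogy construction and ancestral state reconstruction.
#
# At the near-clonal divergences this package targets (core-genome distances
# well below 1%), a neighbor-joining tree on Jukes-Cantor distances recovers
# the same topology as a full maximum-likelihood search at a fraction of the
# cost, so NJ + JC is the default tree machinery.

#' Pairwise distance matrix from a core alignment
#'
#' Distances are computed over shared non-gap columns of each pair
#' (pairwise deletion). Under `"JC69"`, d = -(3/4) log(1 - (4/3) p); a
#' proportion p >= 0.75 makes the correction undefined and the entry is
#' returned as `NA` with a warning.
#'
#' @param alignment character matrix (rows = taxa) or `DNAbin`.
#' @param model `"JC69"` or `"raw"` (uncorrected p-distance).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
core_distances <- function(alignment, model = c("JC69", "raw")) {
  model <- match.arg(model)
  if (is.matrix(alignment) && is.character(alignment)) {
    alignment <- unclass(alignment)
    alignment <- ape::as.DNAbin(tolower(alignment))
  }
  if (nrow(alignment) < 2) stop("need at least two taxa")
  d <- ape::dist.dna(alignment, model = model, pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  if (any(!is.finite(d))) {
    warning("some pairwise distances undefined (p >= 0.75 under JC69); set to NA")
    d[!is.finite(d)] <- NA_real_
  }
  d
}

#' Neighbor-joining clonal genealogy
#'
#' Standard NJ agglomeration on the distance matrix, with any negative branch
#' produced by the algorithm clamped to zero and its length shifted onto the
#' sibling branch, then (optionally) midpoint-rooted.
#'
#' @param d symmetric distance matrix (n >= 3 taxa).
#' @param midpoint root the tree at the midpoint of its longest path
#'   (default `TRUE`); `FALSE` returns the unrooted NJ tree.
#' @return a `phylo`.
#' @export
nj_tree <- function(d, midpoint = TRUE) {
  if (nrow(as.matrix(d)) < 3) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    amt <- tr$edge.length[e]
    sib <- setdiff(which(tr$edge[, 1] == tr$edge[e, 1]), e)
    if (length(sib) > 0) tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + amt
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  if (midpoint) tr <- phangorn::midpoint(tr)
  tr
}

#' Bootstrap support for internal edges
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the reference tree the
#' fraction of replicates containing the same bipartition.
#'
#' @param alignment character matrix, rows = taxa.
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed RNG seed for the column resampling.
#' @param model distance model passed to [core_distances()].
#' @return the reference tree (`phylo`) with `node.label` set to support
#'   fractions in `[0, 1]`, and a `support` attribute (numeric per internal
#'   node).
#' @export
bootstrap_support <- function(alignment, n_replicates = 100, seed = 1,
                              model = "JC69") {
  stopifnot(n_replicates >= 1)
  ref <- nj_tree(core_distances(alignment, model))
  set.seed(seed)
  boots <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    cols <- sample.int(ncol(alignment), ncol(alignment), replace = TRUE)
    boots[[i]] <- nj_tree(core_distances(alignment[, cols, drop = FALSE], model))
  }
  class(boots) <- "multiPhylo"
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- counts / n_replicates
  ref$node.label <- formatC(support, format = "g")
  attr(ref, "support") <- support
  ref
}

# integer bitmask coding for Fitch sets: A=1 C=2 G=4 T=8, missing/gap = 15
.FITCH_CODE <- c(A = 1L, C = 2L, G = 4L, T = 8L)
.LOWEST_BIT_BASE <- c("A", "C", "A", "G", "A", "C", "A", "T",
                      "A", "C", "A", "G", "A", "C", "A")

fitch_mask <- function(chars) {
  m <- .FITCH_CODE[chars]
  m[is.na(m)] <- 15L   # gaps and ambiguity codes treated as missing
  unname(m)
}

#' Reconstruct ancestral sequences on the genealogy
#'
#' `"fitch"` (default) runs Fitch parsimony with fixed, documented
#' tie-breaks: on the downward pass a node takes its parent's state whenever
#' that state is in its candidate set, and the root resolves ambiguity
#' lexicographically (A < C < G < T). Gap/missing leaf states never constrain
#' the sets, so missing data inherits the parental state.
#' `"marginal-jc"` computes marginal maximum-likelihood states under the
#' Jukes-Cantor model (via phangorn) and takes the modal state per column.
#'
#' @param genealogy rooted binary `phylo` whose tips match the alignment rows.
#' @param alignment character matrix, rows = taxa.
#' @param method `"fitch"` or `"marginal-jc"`.
#' @return character matrix of ancestral sequences, one row per internal
#'   node, rownames = node labels (`node_labels()` convention).
#' @export
reconstruct_ancestors <- function(genealogy, alignment,
                                  method = c("fitch", "marginal-jc")) {
  method <- match.arg(method)
  if (!all(genealogy$tip.label %in% rownames(alignment)))
    stop("alignment rows do not cover the genealogy tips")
  tr <- ape::reorder.phylo(genealogy, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  labs <- if (!is.null(tr$node.label) && all(nzchar(tr$node.label)))
    c(tr$tip.label, tr$node.label)
  else
    node_labels(tr)
  ncols <- ncol(alignment)
  if (method == "marginal-jc") {
    return(marginal_jc_ancestors(tr, alignment, labs, ntip, nnode))
  }
  sets <- matrix(0L, nrow = ntip + nnode, ncol = ncols)
  for (i in seq_len(ntip))
    sets[i, ] <- fitch_mask(toupper(alignment[tr$tip.label[i], ]))
  # upward pass: parents in postorder (children of each are already set)
  for (par in unique(tr$edge[, 1])) {
    ch <- tr$edge[tr$edge[, 1] == par, 2]
    inter <- sets[ch[1], ]
    uni <- sets[ch[1], ]
    for (c2 in ch[-1]) {
      inter <- bitwAnd(inter, sets[c2, ])
      uni <- bitwOr(uni, sets[c2, ])
    }
    sets[par, ] <- ifelse(inter > 0L, inter, uni)
  }
  states <- matrix(0L, nrow = ntip + nnode, ncol = ncols)
  root <- ntip + 1L
  states[root, ] <- bitwAnd(sets[root, ], bitwNot(sets[root, ] - 1L)) # lowest bit
  # downward pass in preorder
  pre <- rev(seq_len(nrow(tr$edge)))
  for (e in pre) {
    par <- tr$edge[e, 1]; chi <- tr$edge[e, 2]
    if (chi <= ntip) next
    keep <- bitwAnd(sets[chi, ], states[par, ]) > 0L
    states[chi, ] <- ifelse(keep, states[par, ],
                            bitwAnd(sets[chi, ], bitwNot(sets[chi, ] - 1L)))
  }
  anc <- matrix(.LOWEST_BIT_BASE[states[(ntip + 1L):(ntip + nnode), ,
                                        drop = FALSE]],
                nrow = nnode)
  rownames(anc) <- labs[(ntip + 1L):(ntip + nnode)]
  anc
}

marginal_jc_ancestors <- function(tr, alignment, labs, ntip, nnode) {
  aln <- tolower(alignment[tr$tip.label, , drop = FALSE])
  dat <- phangorn::phyDat(aln, type = "DNA")
  tr2 <- tr
  tr2$edge.length[tr2$edge.length <= 0] <- 1e-9
  fit <- phangorn::pml(tr2, dat)
  anc <- phangorn::ancestral.pml(fit, type = "marginal")
  idx <- attr(anc, "index")
  lev <- attr(anc, "levels")
  out <- matrix("N", nrow = nnode, ncol = ncol(alignment))
  for (k in seq_len(nnode)) {
    p <- anc[[ntip + k]]  # list position = node number; nr x 4 probabilities
    full <- p[idx, , drop = FALSE]
    out[k, ] <- toupper(lev[max.col(full, ties.method = "first")])
  }
  rownames(out) <- labs[(ntip + 1L):(ntip + nnode)]
  out
}
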