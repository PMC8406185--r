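# Counting-based dN/dS on the in-frame core codon alignment.
#
# Nei & Gojobori (1986) estimator: expected synonymous/nonsynonymous site
# counts from single-step codon neighbourhoods under the standard genetic
# code; observed differences averaged over shortest mutational paths between
# codons (paths through stop codons excluded when any stop-free path
# exists); Jukes-Cantor correction of the per-site proportions.

.ng86 <- new.env(parent = emptyenv())

.codon_table <- function() {
  if (!is.null(.ng86$SD)) return(invisible())
  bases <- BASES
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  # codon index: positions vary fastest at the 3rd base
  idx <- function(c1, c2, c3) 16L * (c1 - 1L) + 4L * (c2 - 1L) + c3
  all_cod <- character(64)
  for (c1 in 1:4) for (c2 in 1:4) for (c3 in 1:4)
    all_cod[idx(c1, c2, c3)] <- paste0(bases[c1], bases[c2], bases[c3])
  gc <- Biostrings::GENETIC_CODE[all_cod]
  is_stop <- gc == "*"
  syn <- numeric(64)
  for (i in 1:64) {
    if (is_stop[i]) next
    cod <- strsplit(all_cod[i], "")[[1]]
    for (p in 1:3) {
      s_p <- 0L; v_p <- 0L
      for (b in bases[bases != cod[p]]) {
        nb <- cod; nb[p] <- b
        j <- match(paste(nb, collapse = ""), all_cod)
        if (is_stop[j]) next   # changes to stops excluded from site counting
        v_p <- v_p + 1L
        if (gc[j] == gc[i]) s_p <- s_p + 1L
      }
      if (v_p > 0L) syn[i] <- syn[i] + s_p / v_p
    }
  }
  SD <- matrix(0, 64, 64); ND <- matrix(0, 64, 64)
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in 1:64) {
    if (is_stop[i]) next
    ci <- strsplit(all_cod[i], "")[[1]]
    for (j in 1:64) {
      if (i == j || is_stop[j]) next
      cj <- strsplit(all_cod[j], "")[[1]]
      dpos <- which(ci != cj)
      k <- length(dpos)
      paths <- list()
      for (ord in perms[[as.character(k)]]) {
        cur <- ci; s <- 0; n <- 0; blocked <- FALSE
        for (p in dpos[ord]) {
          nxt <- cur; nxt[p] <- cj[p]
          a <- gc[match(paste(cur, collapse = ""), all_cod)]
          b <- gc[match(paste(nxt, collapse = ""), all_cod)]
          if (b == "*") blocked <- TRUE
          if (a == b && a != "*") s <- s + 1 else n <- n + 1
          cur <- nxt
        }
        paths[[length(paths) + 1]] <- c(s, n, blocked)
      }
      pm <- do.call(rbind, paths)
      use <- pm[pm[, 3] == 0, , drop = FALSE]
      if (nrow(use) == 0) use <- pm
      SD[i, j] <- mean(use[, 1]); ND[i, j] <- mean(use[, 2])
    }
  }
  .ng86$codons <- all_cod
  .ng86$is_stop <- is_stop
  .ng86$syn <- syn
  .ng86$SD <- SD
  .ng86$ND <- ND
  invisible()
}

#' Synonymous site fractions of all sense codons
#'
#' The per-codon expected number of synonymous sites (out of 3) used by the
#' counting dN/dS estimator: for each codon position, the fraction of the
#' three possible single-nucleotide changes that preserve the amino acid
#' (changes creating stop codons count as nonsynonymous).
#'
#' @return named numeric vector over the 61 sense codons.
#' @export
ng86_site_table <- function() {
  .codon_table()
  setNames(.ng86$syn[!.ng86$is_stop], .ng86$codons[!.ng86$is_stop])
}

codon_to_index <- function(codons) {
  # NA for anything that is not an unambiguous sense codon
  i <- match(codons, .ng86$codons)
  i[!is.na(i) & .ng86$is_stop[ifelse(is.na(i), 1L, i)]] <- NA_integer_
  i
}

#' Counting dN/dS between two codon sequences
#'
#' @param codons_a,codons_b equal-length character vectors of 3-letter
#'   codons; entries that are `NA`, ambiguous, gapped, or stop codons in
#'   either sequence are excluded pairwise.
#' @return list with expected site counts `N`, `S`, observed differences
#'   `Nd`, `Sd`, proportions `pN`, `pS`, Jukes-Cantor rates `dN`, `dS`,
#'   `omega` (`NA` with flag `"dS_zero"` when no synonymous changes; flag
#'   `"saturated"` when a proportion exceeds the JC domain), and
#'   `n_codons` compared.
#' @export
ng86_pair <- function(codons_a, codons_b) {
  if (length(codons_a) != length(codons_b))
    stop("codon sequences differ in length")
  .codon_table()
  ia <- codon_to_index(toupper(codons_a))
  ib <- codon_to_index(toupper(codons_b))
  ok <- !is.na(ia) & !is.na(ib)
  ia <- ia[ok]; ib <- ib[ok]
  n_cod <- length(ia)
  flags <- character(0)
  if (n_cod == 0)
    return(list(N = 0, S = 0, Nd = 0, Sd = 0, pN = NA, pS = NA,
                dN = NA, dS = NA, omega = NA, n_codons = 0,
                flags = "no_codons"))
  S <- (sum(.ng86$syn[ia]) + sum(.ng86$syn[ib])) / 2
  N <- 3 * n_cod - S
  diff <- ia != ib
  Sd <- sum(.ng86$SD[cbind(ia[diff], ib[diff])])
  Nd <- sum(.ng86$ND[cbind(ia[diff], ib[diff])])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) {
    if (!is.finite(p) || p >= 0.75) return(NA_real_)
    -0.75 * log1p(-4 * p / 3)
  }
  dS <- jc(pS); dN <- jc(pN)
  if (is.na(dS) || is.na(dN)) flags <- c(flags, "saturated")
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  if (!is.na(dS) && dS == 0) flags <- c(flags, "dS_zero")
  list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
       dN = dN, dS = dS, omega = omega, n_codons = n_cod, flags = flags)
}

#' In-frame codon view of a core alignment
#'
#' Groups alignment columns into codons using the reference row's non-gap
#' positions and each gene's frame; columns where the reference is gapped
#' (insertions relative to the reference) are ignored. A taxon's codon is
#' masked (`NA`) when any of its three aligned characters is a gap or
#' ambiguity. Genes whose reference row contains an internal stop are
#' dropped with a message.
#'
#' @param alignment a `core_alignment` (or character matrix with a
#'   `boundaries` attribute).
#' @param reference reference row name (default: first row).
#' @param extra optional additional character matrix of rows aligned to the
#'   same columns (e.g. reconstructed ancestors) to codonize alongside.
#' @return list of class `codon_alignment`: `codons` (character matrix,
#'   rows = taxa (+ extras), columns = codons), `gene` (family id per codon
#'   column), `dropped` (family ids dropped for reference-frame stops).
#' @export
codon_alignment <- function(alignment, reference = NULL, extra = NULL) {
  bd <- attr(alignment, "boundaries")
  if (is.null(bd)) stop("alignment lacks gene boundaries")
  if (is.null(reference)) reference <- rownames(alignment)[1]
  .codon_table()
  full <- alignment
  if (!is.null(extra)) full <- rbind(alignment, extra)
  taxa <- rownames(full)
  out <- list(); genecol <- list(); dropped <- character(0)
  for (i in seq_len(nrow(bd))) {
    cols <- bd$start[i]:bd$end[i]
    refchars <- toupper(alignment[reference, cols])
    inframe <- cols[refchars != "-"]
    k <- length(inframe) %/% 3
    if (k == 0) next
    inframe <- inframe[seq_len(3 * k)]
    sub <- toupper(full[, inframe, drop = FALSE])
    sub[!sub %in% BASES] <- NA
    c1 <- sub[, seq(1, 3 * k, by = 3), drop = FALSE]
    c2 <- sub[, seq(2, 3 * k, by = 3), drop = FALSE]
    c3 <- sub[, seq(3, 3 * k, by = 3), drop = FALSE]
    cod <- matrix(paste0(c1, c2, c3), nrow = length(taxa))
    cod[is.na(c1) | is.na(c2) | is.na(c3)] <- NA
    refcod <- cod[match(reference, taxa), ]
    ri <- match(refcod, .ng86$codons)
    internal_stop <- any(.ng86$is_stop[ri[-k]], na.rm = TRUE)
    if (internal_stop) {
      dropped <- c(dropped, bd$family_id[i])
      next
    }
    out[[bd$family_id[i]]] <- cod
    genecol[[bd$family_id[i]]] <- rep(bd$family_id[i], k)
  }
  codons <- do.call(cbind, out)
  rownames(codons) <- taxa
  if (length(dropped) > 0)
    message(length(dropped), " gene(s) dropped for internal stops in the reference frame")
  structure(list(codons = codons, gene = unlist(genecol, use.names = FALSE),
                 dropped = dropped, reference = reference),
            class = "codon_alignment")
}

#' Per-branch counting dN/dS over the genealogy
#'
#' Applies the counting estimator to every (parent, child) pair of the
#' rooted genealogy, using reconstructed ancestral sequences for internal
#' nodes; a genome's omega is its terminal branch's omega.
#'
#' @param genealogy rooted `phylo`.
#' @param alignment a `core_alignment` over the genealogy's tips.
#' @param ancestors matrix from [reconstruct_ancestors()]; computed here
#'   (Fitch) when `NULL`.
#' @param reference reference row for codon framing.
#' @return data.frame, one row per branch: `branch`, `is_tip`, `N`, `S`,
#'   `Nd`, `Sd`, `dN`, `dS`, `omega`, `n_codons`.
#' @export
per_branch_omega <- function(genealogy, alignment, ancestors = NULL,
                             reference = NULL) {
  if (is.null(ancestors))
    ancestors <- reconstruct_ancestors(genealogy, alignment)
  ca <- codon_alignment(alignment, reference = reference, extra = ancestors)
  cm <- ca$codons
  tr <- genealogy
  ntip <- length(tr$tip.label)
  labs <- c(tr$tip.label,
            if (!is.null(tr$node.label) && all(nzchar(tr$node.label)))
              tr$node.label else rownames(ancestors))
  rows <- list()
  for (e in seq_len(nrow(tr$edge))) {
    par <- labs[tr$edge[e, 1]]; chi <- labs[tr$edge[e, 2]]
    p <- ng86_pair(cm[par, ], cm[chi, ])
    rows[[chi]] <- data.frame(branch = chi, is_tip = tr$edge[e, 2] <= ntip,
                              N = p$N, S = p$S, Nd = p$Nd, Sd = p$Sd,
                              dN = p$dN, dS = p$dS, omega = p$omega,
                              n_codons = p$n_codons)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Group summary of per-genome omega
#'
#' @param branch_omega output of [per_branch_omega()].
#' @param grouping named vector taxon -> group.
#' @return data.frame of group, n, mean omega, sd omega (terminal branches
#'   with defined omega only).
#' @export
omega_group_summary <- function(branch_omega, grouping) {
  tips <- branch_omega[branch_omega$is_tip & !is.na(branch_omega$omega), ]
  g <- grouping[tips$branch]
  agg <- split(tips$omega, g)
  data.frame(group = names(agg),
             n = lengths(agg),
             mean_omega = vapply(agg, mean, 0),
             sd_omega = vapply(agg, sd, 0),
             row.names = NULL)
}
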