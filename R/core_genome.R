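# Single-copy orthology against a reference genome, per-gene alignment,
# core-genome concatenation, pangenome clustering and fragment ANI.

.AA_GAP_OPEN <- 10
.AA_GAP_EXT <- 0.5

#' Amino-acid similarity of two proteins
#'
#' Local alignment under BLOSUM62 with affine gaps (opening 10,
#' extension 0.5); similarity is the fraction of identical positions over
#' the aligned length (gap columns included), i.e. percent identity of the
#' local alignment, a fraction between 0 and 1.
#'
#' @param a,b amino-acid sequences (character or `AAString`).
#' @return similarity fraction.
#' @export
protein_similarity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty protein sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62",
    gapOpening = .AA_GAP_OPEN, gapExtension = .AA_GAP_EXT)
  w <- Biostrings::nchar(aln)
  if (w == 0) return(0)
  Biostrings::nmatch(aln) / w
}

# vectorized form: similarity and coverage of each pattern vs one subject.
# coverage = aligned length / length of the shorter sequence; a similarity
# hit without coverage is how unrelated proteins sneak over an identity
# threshold on short local segments.
.protein_hits <- function(patterns, subject) {
  if (length(patterns) == 0)
    return(data.frame(similarity = numeric(0), coverage = numeric(0)))
  subject <- Biostrings::AAString(as.character(subject))
  aln <- Biostrings::pairwiseAlignment(
    patterns, subject, type = "local",
    substitutionMatrix = "BLOSUM62",
    gapOpening = .AA_GAP_OPEN, gapExtension = .AA_GAP_EXT)
  w <- Biostrings::nchar(aln)
  shorter <- pmin(Biostrings::width(patterns), length(subject))
  data.frame(similarity = ifelse(w > 0, Biostrings::nmatch(aln) / w, 0),
             coverage = w / shorter)
}

.protein_similarity_many <- function(patterns, subject) {
  .protein_hits(patterns, subject)$similarity
}

#' Identify single-copy ortholog families against a reference genome
#'
#' Reference genes form a family when every query genome has exactly one
#' gene above the similarity threshold against them: reference genes hit by
#' multiple genes from one genome (paralogs) are excluded, as are genes
#' missing from any genome.
#'
#' @param genomes named list of [annotated_genome()] objects.
#' @param reference id of the reference genome; defaults to the first genome
#'   id in lexicographic order.
#' @param min_similarity exclusive lower bound on amino-acid similarity
#'   (default 0.30).
#' @param min_coverage a hit must additionally cover at least this fraction
#'   of the shorter protein (default 0.5), the counterpart of a BLASTp
#'   significance filter: unrelated proteins reach ~30% identity on short
#'   local segments but never at coverage.
#' @return data.frame (one row per family member) with columns `family_id`,
#'   `reference_gene`, `genome_id`, `gene_id`, `similarity`; the set of
#'   family ids is carried in the `families` attribute.
#' @export
identify_orthologs <- function(genomes, reference = NULL,
                               min_similarity = 0.30, min_coverage = 0.5) {
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, `[[`, "", "genome_id")
  if (is.null(reference)) reference <- sort(names(genomes))[1]
  if (!reference %in% names(genomes)) stop("reference genome not among inputs")
  if (any(vapply(genomes, function(g) nrow(g$genes), 0L) == 0))
    stop("every genome must carry at least one annotated gene")
  prots <- lapply(genomes, gene_proteins)
  ref_prot <- prots[[reference]]
  rows <- list()
  ok_ref <- rep(TRUE, length(ref_prot))
  hits <- vector("list", length(ref_prot))
  for (g in names(genomes)) {
    pg <- prots[[g]]
    for (j in seq_along(ref_prot)) {
      if (!ok_ref[j]) next
      h <- .protein_hits(pg, ref_prot[[j]])
      hit <- which(h$similarity > min_similarity & h$coverage >= min_coverage)
      if (length(hit) != 1) { ok_ref[j] <- FALSE; next }
      hits[[j]] <- rbind(hits[[j]], data.frame(
        genome_id = g, gene_id = names(pg)[hit],
        similarity = h$similarity[hit], stringsAsFactors = FALSE))
    }
  }
  out <- list()
  for (j in which(ok_ref)) {
    fam <- sprintf("fam_%s", names(ref_prot)[j])
    out[[fam]] <- cbind(family_id = fam,
                        reference_gene = names(ref_prot)[j],
                        hits[[j]], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(family_id = character(), reference_gene = character(),
                      genome_id = character(), gene_id = character(),
                      similarity = numeric())
  rownames(res) <- NULL
  attr(res, "families") <- unique(res$family_id)
  attr(res, "reference") <- reference
  res
}

#' Align the members of one gene family
#'
#' Center-star progressive alignment: every member is aligned globally
#' (affine gaps) against the center sequence — the reference member when
#' given, else the longest — and the pairwise alignments are merged on the
#' center's coordinates. Adequate for the >90% identical inputs of
#' near-clonal core genes.
#'
#' @param sequences named character vector (or `DNAStringSet`) of the
#'   family's nucleotide sequences; >= 2 entries.
#' @param center name of the center sequence (default: longest).
#' @return character matrix, rows = members, columns = alignment; the center
#'   row name is kept in the `center` attribute.
#' @export
align_family <- function(sequences, center = NULL) {
  seqs <- vapply(as.list(sequences), as.character, "")
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (any(!grepl("^[ACGTRYSWKMBDHVN]*$", toupper(seqs))))
    stop("sequence contains non-IUPAC symbols")
  if (is.null(center)) center <- names(seqs)[which.max(nchar(seqs))]
  cs <- toupper(seqs[[center]])
  others <- setdiff(names(seqs), center)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1)
  # per-sequence alignment to the center; record per-center-position inserts
  n <- nchar(cs)
  ins_len <- integer(n + 1)  # insertions *after* center position i (0..n)
  placed <- list()
  for (o in others) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(toupper(seqs[[o]])), Biostrings::DNAString(cs),
      type = "global", substitutionMatrix = mat,
      gapOpening = 10, gapExtension = 0.5)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    cpos <- 0L
    run <- 0L
    slots <- character(0)
    pos_main <- rep(NA_character_, n)
    ins <- list()
    for (t in seq_along(sa)) {
      if (sa[t] == "-") {
        run <- run + 1L
        slots[run] <- pa[t]
      } else {
        if (run > 0L) {
          ins[[as.character(cpos)]] <- slots[seq_len(run)]
          ins_len[cpos + 1L] <- max(ins_len[cpos + 1L], run)
          run <- 0L
        }
        cpos <- cpos + 1L
        pos_main[cpos] <- pa[t]
      }
    }
    if (run > 0L) {
      ins[[as.character(cpos)]] <- slots[seq_len(run)]
      ins_len[cpos + 1L] <- max(ins_len[cpos + 1L], run)
    }
    placed[[o]] <- list(main = pos_main, ins = ins)
  }
  width <- n + sum(ins_len)
  col_of <- cumsum(c(ins_len[1], rbind(1, ins_len[-1])))[2 * seq_len(n)]
  build_row <- function(main, ins) {
    row <- rep("-", width)
    row[col_of] <- ifelse(is.na(main), "-", main)
    for (key in names(ins)) {
      cpos <- as.integer(key)
      anchor <- if (cpos == 0L) 0L else col_of[cpos]
      seg <- ins[[key]]
      row[anchor + seq_along(seg)] <- seg
    }
    row
  }
  out <- matrix("-", nrow = length(seqs), ncol = width,
                dimnames = list(c(center, others), NULL))
  out[center, col_of] <- strsplit(cs, "")[[1]]
  for (o in others) out[o, ] <- build_row(placed[[o]]$main, placed[[o]]$ins)
  out <- out[names(seqs), , drop = FALSE]
  attr(out, "center") <- center
  out
}

#' Concatenate per-family alignments into a core alignment
#'
#' @param alignments named list of character matrices sharing a taxa set.
#' @return character matrix of class `core_alignment` with a `boundaries`
#'   attribute: data.frame(`family_id`, `start`, `end`) in 1-based inclusive
#'   alignment coordinates, tiling the alignment in input order.
#' @export
concatenate_core <- function(alignments) {
  if (length(alignments) == 0) stop("no alignments given")
  taxa <- rownames(alignments[[1]])
  for (a in alignments)
    if (!setequal(rownames(a), taxa)) stop("alignments do not share a taxa set")
  alignments <- lapply(alignments, function(a) a[taxa, , drop = FALSE])
  widths <- vapply(alignments, ncol, 0L)
  out <- do.call(cbind, alignments)
  ends <- cumsum(widths)
  bd <- data.frame(family_id = if (!is.null(names(alignments)))
    names(alignments) else sprintf("fam%04d", seq_along(alignments)),
    start = ends - widths + 1L, end = ends, stringsAsFactors = FALSE)
  rownames(out) <- taxa
  attr(out, "boundaries") <- bd
  class(out) <- c("core_alignment", class(out))
  out
}

#' Build the core-genome alignment from ortholog families
#'
#' Extracts each family's member sequences, aligns them with the reference
#' member as center, and concatenates.
#'
#' @param genomes named list of [annotated_genome()] objects.
#' @param orthologs family table from [identify_orthologs()].
#' @return a `core_alignment` whose rows are genome ids.
#' @export
core_alignment <- function(genomes, orthologs) {
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, `[[`, "", "genome_id")
  nt <- lapply(genomes, gene_sequences)
  ref <- attr(orthologs, "reference")
  alns <- list()
  for (fam in unique(orthologs$family_id)) {
    rows <- orthologs[orthologs$family_id == fam, ]
    seqs <- setNames(
      vapply(seq_len(nrow(rows)), function(i)
        as.character(nt[[rows$genome_id[i]]][[rows$gene_id[i]]]), ""),
      rows$genome_id)
    alns[[fam]] <- align_family(seqs, center = if (!is.null(ref)) ref)
  }
  concatenate_core(alns)
}

#' Cluster all genes of all genomes into a pangenome
#'
#' Single-linkage clustering on the protein-similarity graph: two genes are
#' linked when their amino-acid similarity exceeds the threshold, and
#' clusters are the connected components. At near-clonal divergences this
#' yields the same partition as inflation-based graph clustering. Reports
#' core clusters (members from every genome), flexible clusters (a strict
#' subset), singletons (one gene from one genome), and the singleton
#' fraction of the flexible genome.
#'
#' @param genomes named list of [annotated_genome()] objects.
#' @param identity_threshold exclusive link threshold (default 0.9).
#' @return list of class `pangenome`: `clusters` (list of gene-key vectors,
#'   keys `genome|gene`), `per_genome` totals, `n_core`, `n_flexible`,
#'   `singleton_count`, `singleton_fraction_of_flexible`.
#' @export
cluster_pangenome <- function(genomes, identity_threshold = 0.9) {
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, `[[`, "", "genome_id")
  prots <- lapply(genomes, gene_proteins)
  key <- unlist(lapply(names(prots), function(g)
    paste(g, names(prots[[g]]), sep = "|")))
  gnm <- unlist(lapply(names(prots), function(g)
    rep(g, length(prots[[g]]))))
  all_prot <- Biostrings::AAStringSet(unlist(lapply(prots, as.character)))
  names(all_prot) <- key
  N <- length(all_prot)
  parent <- seq_len(N)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  link <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  w <- Biostrings::width(all_prot)
  for (i in seq_len(N - 1)) {
    js <- (i + 1):N
    # cheap length prefilter: identity above t requires comparable lengths
    js <- js[pmin(w[js], w[i]) / pmax(w[js], w[i]) > identity_threshold / 2]
    js <- js[vapply(js, function(j) find(j) != find(i), TRUE)]
    if (length(js) == 0) next
    sim <- .protein_similarity_many(all_prot[js], all_prot[[i]])
    for (j in js[sim > identity_threshold]) link(i, j)
  }
  comp <- vapply(seq_len(N), find, 0L)
  clusters <- split(key, comp)
  names(clusters) <- sprintf("cl%04d", seq_along(clusters))
  sizes <- lengths(clusters)
  genomes_in <- vapply(clusters, function(k)
    length(unique(sub("\\|.*$", "", k))), 0L)
  n_genomes <- length(genomes)
  n_core <- sum(genomes_in == n_genomes)
  flexible <- genomes_in < n_genomes
  singles <- sizes == 1L
  structure(list(
    clusters = clusters,
    per_genome = table(gnm),
    n_clusters = length(clusters),
    n_core = n_core,
    n_flexible = sum(flexible),
    singleton_count = sum(singles),
    singleton_fraction_of_flexible =
      if (sum(flexible) > 0) sum(singles) / sum(flexible) else 0
  ), class = "pangenome")
}

#' @export
print.pangenome <- function(x, ...) {
  cat(sprintf("<pangenome> %d clusters: %d core, %d flexible (%d singletons, %.3g of flexible)\n",
              x$n_clusters, x$n_core, x$n_flexible, x$singleton_count,
              x$singleton_fraction_of_flexible))
  invisible(x)
}

#' Fragment-based average nucleotide identity
#'
#' Chops genome `a` into non-overlapping fragments, finds each fragment's
#' best local alignment against genome `b` (blastn), and averages the
#' percent identity of fragments whose best hit covers at least
#' `min_coverage` of their length — the classic ANIb convention.
#'
#' @param a,b [annotated_genome()] objects (or DNAString/character).
#' @param fragment fragment size in bp (default 1000).
#' @param min_coverage minimum aligned fraction of a fragment (default 0.7).
#' @return ANI as a percentage; `NA` (with a warning) when no fragment
#'   aligns at coverage.
#' @export
average_nucleotide_identity <- function(a, b, fragment = 1000,
                                        min_coverage = 0.7) {
  seq_of <- function(x) {
    if (inherits(x, "annotated_genome")) return(int_seq_to_char(x$seq))
    as.character(x)
  }
  sa <- seq_of(a); sb <- seq_of(b)
  if (nchar(sa) < fragment || nchar(sb) < fragment)
    stop("genomes must be at least one fragment long")
  nfrag <- nchar(sa) %/% fragment
  frags <- substring(sa, (seq_len(nfrag) - 1) * fragment + 1,
                     seq_len(nfrag) * fragment)
  qf <- tempfile(fileext = ".fasta"); sf <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(qf, sf)), add = TRUE)
  q <- Biostrings::DNAStringSet(frags)
  names(q) <- sprintf("frag%05d", seq_len(nfrag))
  Biostrings::writeXStringSet(q, qf)
  sset <- Biostrings::DNAStringSet(sb); names(sset) <- "subject"
  Biostrings::writeXStringSet(sset, sf)
  res <- system2("blastn",
                 c("-query", qf, "-subject", sf, "-outfmt",
                   shQuote("6 qseqid pident length bitscore"),
                   "-max_target_seqs", "5"),
                 stdout = TRUE, stderr = FALSE)
  if (length(res) == 0) {
    warning("no fragment aligned; ANI undefined")
    return(NA_real_)
  }
  tab <- read.table(text = res, sep = "\t", col.names =
                      c("qseqid", "pident", "length", "bitscore"))
  best <- tab[order(tab$qseqid, -tab$bitscore), ]
  best <- best[!duplicated(best$qseqid), ]
  best <- best[best$length >= min_coverage * fragment, ]
  if (nrow(best) == 0) {
    warning("no fragment aligned at the coverage threshold; ANI undefined")
    return(NA_real_)
  }
  mean(best$pident)
}

#' @export
`[.core_alignment` <- function(x, i, j, drop = FALSE) {
  y <- unclass(x)
  if (nargs() == 2L) return(y[i])  # single-index form x[i]
  bd <- attr(x, "boundaries")
  keep_bd <- missing(j)
  if (missing(i)) i <- seq_len(nrow(y))
  if (missing(j)) j <- seq_len(ncol(y))
  y <- y[i, j, drop = drop]
  if (keep_bd && is.matrix(y)) {
    attr(y, "boundaries") <- bd
    class(y) <- c("core_alignment", class(y))
  }
  y
}
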