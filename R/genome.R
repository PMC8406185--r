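# AnnotatedGenome container and accessors.
#
# A genome is one linear contig (standing in for a closed circular
# chromosome) plus a table of CDS gene models. Sequences are held internally
# as integer vectors (1=A, 2=C, 3=G, 4=T) so the simulator can mutate them
# cheaply; user-facing accessors return Biostrings objects.

#' Construct an annotated genome
#'
#' @param genome_id label for the genome.
#' @param seq nucleotide sequence: a single character string, a
#'   [Biostrings::DNAString], or an integer vector coded 1:4 = A,C,G,T.
#' @param genes data.frame with columns `gene_id`, `start`, `end` (1-based,
#'   inclusive), `strand` (`"+"`/`"-"`) and optionally `frame` (codon phase,
#'   default 0) and `pseudo` (logical disruption flag, default `FALSE`).
#' @return object of class `annotated_genome`.
#' @export
annotated_genome <- function(genome_id, seq, genes = NULL) {
  iseq <- as_int_seq(seq)
  if (is.null(genes) || nrow(genes) == 0) {
    genes <- data.frame(gene_id = character(), start = integer(),
                        end = integer(), strand = character(),
                        frame = integer(), pseudo = logical(),
                        stringsAsFactors = FALSE)
  } else {
    genes <- as.data.frame(genes, stringsAsFactors = FALSE)
    if (is.null(genes$frame)) genes$frame <- 0L
    if (is.null(genes$pseudo)) genes$pseudo <- FALSE
    stopifnot(all(c("gene_id", "start", "end", "strand") %in% names(genes)))
    if (any(genes$start < 1) || any(genes$end > length(iseq)) ||
        any(genes$end < genes$start))
      stop("gene intervals must lie within contig bounds")
    if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  }
  structure(list(genome_id = genome_id, seq = iseq, genes = genes),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %d bp, %d genes (%d flagged disrupted)\n",
              x$genome_id, length(x$seq), nrow(x$genes), sum(x$genes$pseudo)))
  invisible(x)
}

as_int_seq <- function(seq) {
  if (is.integer(seq)) return(seq)
  if (inherits(seq, "DNAString")) seq <- as.character(seq)
  if (is.character(seq) && length(seq) == 1) {
    m <- match(strsplit(toupper(seq), "")[[1]], BASES)
    if (anyNA(m)) stop("sequence contains non-ACGT symbols")
    return(m)
  }
  if (is.numeric(seq)) return(as.integer(seq))
  stop("unsupported sequence representation")
}

int_seq_to_char <- function(iseq) paste(BASES[iseq], collapse = "")

revcomp_int <- function(iseq) rev(5L - iseq)

#' Genome sequence as a DNAString
#' @param genome an `annotated_genome`.
#' @return a [Biostrings::DNAString].
#' @export
genome_sequence <- function(genome) {
  Biostrings::DNAString(int_seq_to_char(genome$seq))
}

#' Coding sequences of all genes
#'
#' Extracts each annotated CDS on its coding strand.
#'
#' @param genome an `annotated_genome`.
#' @return a named [Biostrings::DNAStringSet], one entry per gene.
#' @export
gene_sequences <- function(genome) {
  g <- genome$genes
  if (nrow(g) == 0) return(Biostrings::DNAStringSet())
  seqs <- vapply(seq_len(nrow(g)), function(i) {
    s <- genome$seq[g$start[i]:g$end[i]]
    if (g$strand[i] == "-") s <- revcomp_int(s)
    int_seq_to_char(s)
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- g$gene_id
  out
}

#' Translated gene products
#'
#' Translates each CDS with the standard code; trailing bases that do not
#' complete a codon (frameshifted genes) are dropped, internal stops are kept
#' as `*` so downstream similarity searches still see the intact prefix.
#'
#' @param genome an `annotated_genome`.
#' @return a named [Biostrings::AAStringSet].
#' @export
gene_proteins <- function(genome) {
  nt <- gene_sequences(genome)
  if (length(nt) == 0) return(Biostrings::AAStringSet())
  w <- Biostrings::width(nt)
  nt <- Biostrings::subseq(nt, 1, w - (w %% 3))
  Biostrings::translate(nt, if.fuzzy.codon = "solve")
}
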