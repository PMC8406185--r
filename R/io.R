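# Plain-text dataset I/O: FASTA + GFF3 per genome, TSV truth tables, newick
# genealogy, YAML manifest.

genes_to_granges <- function(genome) {
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = genome$genome_id,
    ranges = IRanges::IRanges(g$start, g$end),
    strand = g$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "clonalkit", type = "CDS", phase = as.integer(g$frame),
    ID = g$gene_id, pseudo = tolower(as.character(g$pseudo)))
  gr
}

#' Write a simulated dataset to disk
#'
#' One wrapped FASTA and one GFF3 per genome, the event-truth tables as TSV,
#' the true genealogy as newick, and the configuration echoed to a YAML
#' manifest.
#'
#' @param genomes named list of [annotated_genome()] objects.
#' @param truth the `evolution_truth` from [evolve_genomes()] (or `NULL`).
#' @param outdir output directory, created if needed.
#' @param tree optional `phylo` genealogy to write as `genealogy.nwk`.
#' @param config optional [sim_config()] echoed into `manifest.yaml`.
#' @return invisibly, the manifest list.
#' @export
write_dataset <- function(genomes, truth = NULL, outdir, tree = NULL,
                          config = NULL) {
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  files <- list()
  for (g in genomes) {
    fa <- file.path(outdir, paste0(g$genome_id, ".fasta"))
    dna <- Biostrings::DNAStringSet(int_seq_to_char(g$seq))
    names(dna) <- g$genome_id
    Biostrings::writeXStringSet(dna, fa, width = 80)
    gff <- file.path(outdir, paste0(g$genome_id, ".gff3"))
    rtracklayer::export(genes_to_granges(g), gff, format = "gff3")
    files[[g$genome_id]] <- c(fasta = basename(fa), gff3 = basename(gff))
  }
  if (!is.null(truth)) {
    for (what in c("substitutions", "imports", "indels", "pseudogenizations")) {
      write.table(truth_table(truth, what),
                  file.path(outdir, paste0("truth_", what, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(tree))
    ape::write.tree(tree, file.path(outdir, "genealogy.nwk"))
  manifest <- list(
    tool = "clonalkit",
    version = as.character(utils::packageVersion("clonalkit")),
    seed = if (!is.null(config)) config$seed else NA,
    config = if (!is.null(config)) unclass(config) else NULL,
    genomes = files)
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}

#' Read genomes back from a dataset directory
#'
#' @param dir a directory written by [write_dataset()], or any directory of
#'   paired `<id>.fasta` / `<id>.gff3` files.
#' @return named list of [annotated_genome()] objects.
#' @export
read_dataset <- function(dir) {
  fas <- sort(Sys.glob(file.path(dir, "*.fasta")))
  if (length(fas) == 0) stop("no FASTA files found in ", dir)
  out <- list()
  for (fa in fas) {
    id <- sub("\\.fasta$", "", basename(fa))
    dna <- Biostrings::readDNAStringSet(fa)
    gff <- file.path(dir, paste0(id, ".gff3"))
    genes <- NULL
    if (file.exists(gff)) {
      gr <- rtracklayer::import(gff, format = "gff3")
      gr <- gr[gr$type == "CDS"]
      if (length(gr) > 0) {
        genes <- data.frame(
          gene_id = gr$ID,
          start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
          strand = as.character(GenomicRanges::strand(gr)),
          frame = if (!is.null(gr$phase)) as.integer(as.character(gr$phase)) else 0L,
          pseudo = if (!is.null(gr$pseudo)) gr$pseudo == "true" else FALSE,
          stringsAsFactors = FALSE)
      }
    }
    out[[id]] <- annotated_genome(id, as.character(dna[[1]]), genes)
  }
  out
}
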