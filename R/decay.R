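# Pseudogene detection among closely related strains, group summaries, and
# the omega-vs-pseudogene-load regression.

#' Detect pseudogenes in a genome against reference gene lengths
#'
#' A gene is called a pseudogene when its realized intact ORF — scanning
#' codons from the annotated start in the coding frame, up to the reference
#' length, stopping at (and including) the first stop codon — has lost more
#' than `max_loss` (default 20%) of the reference ortholog's length.
#' Mechanisms: `frameshift` when the annotated CDS length is no longer a
#' codon multiple, `premature_stop` when an in-frame stop interrupts the
#' annotated CDS, `truncation` otherwise (shortened gene model). Reference
#' genes with no annotated copy in the genome are additionally screened
#' against the full genome sequence by local alignment (the intergenic
#' scan); a decayed fragment covering more than `min_fragment` of the
#' reference gene is called a `truncation`.
#'
#' @param genome an [annotated_genome()].
#' @param reference_genome the reference [annotated_genome()] supplying
#'   intact gene lengths (ortholog mapping by `gene_id`; pass an
#'   `orthologs` table to map differently named genes).
#' @param orthologs optional family table from [identify_orthologs()]; maps
#'   this genome's gene ids to reference genes. Without it, shared
#'   `gene_id`s are assumed (the simulator's convention).
#' @param max_loss call threshold on the lost fraction (default 0.20,
#'   exclusive).
#' @param min_fragment intergenic-scan coverage threshold (default 0.30).
#' @return data.frame with columns `genome_id`, `gene_id`, `mechanism`,
#'   `reference_length`, `observed_intact_length`, `fraction_lost`.
#' @export
detect_pseudogenes <- function(genome, reference_genome, orthologs = NULL,
                               max_loss = 0.20, min_fragment = 0.30) {
  ref_genes <- reference_genome$genes
  ref_len <- setNames(ref_genes$end - ref_genes$start + 1L, ref_genes$gene_id)
  if (!is.null(orthologs)) {
    mine <- orthologs[orthologs$genome_id == genome$genome_id, ]
    map <- setNames(mine$gene_id, sub("^fam_", "", mine$family_id))
  } else {
    map <- setNames(intersect(names(ref_len), genome$genes$gene_id),
                    intersect(names(ref_len), genome$genes$gene_id))
  }
  calls <- list()
  for (ref_id in names(map)) {
    gi <- match(map[[ref_id]], genome$genes$gene_id)
    if (is.na(gi)) next
    g <- genome$genes[gi, ]
    rl <- ref_len[[ref_id]]
    ann_len <- g$end - g$start + 1L
    intact <- orf_intact_length(genome$seq, g$start, g$end, g$strand, rl)
    lost <- max(0, 1 - intact / rl)
    if (lost <= max_loss) next
    mech <- if (ann_len %% 3L != 0L) "frameshift"
    else if (intact < min(ann_len, rl)) "premature_stop"
    else "truncation"
    calls[[length(calls) + 1]] <- data.frame(
      genome_id = genome$genome_id, gene_id = ref_id, mechanism = mech,
      reference_length = rl, observed_intact_length = intact,
      fraction_lost = lost, stringsAsFactors = FALSE)
  }
  # intergenic scan: reference genes absent from the annotation
  absent <- setdiff(names(ref_len), names(map)[!is.na(match(map, genome$genes$gene_id))])
  if (length(absent) > 0) {
    gseq <- Biostrings::DNAString(int_seq_to_char(genome$seq))
    ref_nt <- gene_sequences(reference_genome)
    # strict scoring so the local hit stops at the decayed fragment instead
    # of extending into unrelated flanking sequence
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
    for (ref_id in absent) {
      rl <- ref_len[[ref_id]]
      best <- 0
      for (qs in list(ref_nt[[ref_id]],
                      Biostrings::reverseComplement(ref_nt[[ref_id]]))) {
        aln <- Biostrings::pairwiseAlignment(
          qs, gseq, type = "local", substitutionMatrix = mat,
          gapOpening = 10, gapExtension = 0.5)
        cov <- Biostrings::nchar(aln) / rl
        if (Biostrings::pid(aln) > 80 && cov > best) best <- cov
      }
      if (best > min_fragment && best < 1) {
        calls[[length(calls) + 1]] <- data.frame(
          genome_id = genome$genome_id, gene_id = ref_id,
          mechanism = "truncation", reference_length = rl,
          observed_intact_length = as.integer(round(best * rl)),
          fraction_lost = 1 - best, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, calls)
  if (is.null(out))
    out <- data.frame(genome_id = character(), gene_id = character(),
                      mechanism = character(), reference_length = integer(),
                      observed_intact_length = integer(),
                      fraction_lost = numeric())
  out
}

#' Summarize pseudogene loads per group
#'
#' Per-genome counts, group means and SDs, a Welch two-sided t test between
#' the first two groups, and (when functional categories are supplied) the
#' per-category relative-abundance table.
#'
#' @param calls data.frame of pseudogene calls (rows may cover several
#'   genomes; genomes with zero calls must still appear in `genome_ids`).
#' @param grouping named vector genome_id -> group.
#' @param genome_ids all genome ids considered (defaults to
#'   `names(grouping)`), so zero-call genomes count as zeros.
#' @param categories optional named vector gene_id -> functional category.
#' @return list: `per_genome` (id, group, count), `groups` (group, n, mean,
#'   sd), `test` ([welch_t_test()] result or `NULL` with a flag when any
#'   group has size 1), `categories` (relative abundance per category per
#'   group, or `NULL`).
#' @export
pseudogene_summary <- function(calls, grouping, genome_ids = names(grouping),
                               categories = NULL) {
  counts <- table(factor(calls$genome_id, levels = genome_ids))
  per_genome <- data.frame(genome_id = genome_ids,
                           group = unname(grouping[genome_ids]),
                           count = as.integer(counts))
  spl <- split(per_genome$count, per_genome$group)
  groups <- data.frame(group = names(spl), n = lengths(spl),
                       mean = vapply(spl, mean, 0),
                       sd = vapply(spl, sd, 0), row.names = NULL)
  test <- NULL; flag <- character(0)
  if (length(spl) >= 2) {
    if (any(lengths(spl[1:2]) < 2)) flag <- "group_too_small_for_test"
    else test <- welch_t_test(spl[[1]], spl[[2]],
                              labels = names(spl)[1:2])
  }
  cat_tab <- NULL
  if (!is.null(categories)) {
    calls$category <- unname(categories[calls$gene_id])
    calls$category[is.na(calls$category)] <- "uncategorized"
    tab <- table(calls$genome_id, calls$category)
    rel <- sweep(tab, 1, pmax(rowSums(tab), 1), "/")
    grp <- grouping[rownames(rel)]
    cat_tab <- do.call(rbind, lapply(unique(grp), function(g) {
      m <- rel[grp == g, , drop = FALSE]
      data.frame(group = g, category = colnames(m),
                 mean_abundance = colMeans(m),
                 sd_abundance = apply(m, 2, sd), row.names = NULL)
    }))
  }
  list(per_genome = per_genome, groups = groups, test = test,
       categories = cat_tab, flags = flag)
}

#' Regression of pseudogene load on omega
#'
#' Ordinary least squares of pseudogene count against per-genome omega,
#' per group and pooled.
#'
#' @param omega named vector genome_id -> omega (terminal-branch dN/dS).
#' @param pseudo_counts named vector genome_id -> pseudogene count.
#' @param grouping named vector genome_id -> group.
#' @return data.frame with one row per group plus `"all"`: slope,
#'   intercept, Pearson r, two-sided p on the slope, n, and a `flag`
#'   (`"too_few_points"` / `"constant_x"` where the fit is degenerate).
#' @export
omega_vs_pseudogenes <- function(omega, pseudo_counts, grouping) {
  ids <- intersect(names(omega), names(pseudo_counts))
  sets <- c(split(ids, unname(grouping[ids])), list(all = ids))
  rows <- lapply(names(sets), function(g) {
    x <- omega[sets[[g]]]; y <- pseudo_counts[sets[[g]]]
    f <- ols_fit(x, y)
    data.frame(group = g, slope = f$slope, intercept = f$intercept,
               r = f$r, p = f$p, n = f$n,
               flag = if (length(f$flags) > 0) f$flags[1] else "")
  })
  do.call(rbind, rows)
}
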