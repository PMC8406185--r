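# End-to-end orchestration: simulate (or accept) genome sets per group, run
# core-genome -> tree -> recombination -> selection -> decay -> diversity ->
# stats, and emit a compact summary table shaped like the study's headline
# table (group, n, R/theta, delta, nu, r/m, pseudogenes, omega).

#' Analyze one group of annotated genomes
#'
#' The full within-group pipeline: orthologs, core alignment, NJ genealogy,
#' ancestral reconstruction, recombination HMM, per-branch omega, pseudogene
#' calls and pairwise diversity.
#'
#' @param genomes named list of [annotated_genome()] objects (>= 3 for a
#'   resolvable tree).
#' @param reference reference genome id for orthology and pseudogene
#'   lengths; defaults to the lexicographically first.
#' @param min_similarity ortholog similarity threshold.
#' @param hmm_tol,hmm_max_iter EM control for [fit_recombination_hmm()].
#' @return list: `orthologs`, `alignment`, `tree`, `ancestors`, `recomb`
#'   (a `recomb_fit`), `imports` (decoded segments), `branch_omega`,
#'   `pseudogenes`, `diversity`.
#' @export
analyze_group <- function(genomes, reference = NULL, min_similarity = 0.30,
                          hmm_tol = 1e-3, hmm_max_iter = 300) {
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, `[[`, "", "genome_id")
  if (is.null(reference)) reference <- sort(names(genomes))[1]
  ort <- identify_orthologs(genomes, reference = reference,
                            min_similarity = min_similarity)
  aln <- core_alignment(genomes, ort)
  tree <- nj_tree(core_distances(aln))
  anc <- reconstruct_ancestors(tree, aln)
  fit <- fit_recombination_hmm(mismatch_tracks(tree, aln, anc),
                               tol = hmm_tol, max_iter = hmm_max_iter)
  fit$tree <- tree
  imports <- decode_imports(fit)
  bo <- per_branch_omega(tree, aln, ancestors = anc, reference = reference)
  ps <- do.call(rbind, lapply(genomes, function(g)
    detect_pseudogenes(g, genomes[[reference]], orthologs = ort)))
  rownames(ps) <- NULL
  div <- pairwise_diversity(aln)
  list(orthologs = ort, alignment = aln, tree = tree, ancestors = anc,
       recomb = fit, imports = imports, branch_omega = bo,
       pseudogenes = ps, diversity = div, reference = reference)
}

#' Run the full multi-group pipeline
#'
#' @param group_configs named list of [sim_config()] objects, one per group
#'   (e.g. a low-recombination and a high-recombination preset); or a named
#'   list of genome lists to analyze directly.
#' @param outdir optional directory; when given, [make_report()] writes the
#'   stage outputs there.
#' @param ... passed to [analyze_group()].
#' @return list of class `pipeline_result`: per-group `analyses`, the
#'   `summary` table, cross-group `tests` (pseudogene t test, omega t test,
#'   pseudogene-composition ANOSIM, omega-vs-pseudogenes regression), and
#'   `truths` (simulator ground truth when simulated).
#' @export
run_pipeline <- function(group_configs, outdir = NULL, ...) {
  analyses <- list(); truths <- list()
  for (g in names(group_configs)) {
    gc <- group_configs[[g]]
    if (inherits(gc, "sim_config")) {
      ds <- simulate_dataset(gc)
      truths[[g]] <- ds$truth
      genomes <- ds$genomes
      names(genomes) <- paste(g, names(genomes), sep = "_")
      for (i in seq_along(genomes)) genomes[[i]]$genome_id <- names(genomes)[i]
    } else {
      genomes <- gc
    }
    analyses[[g]] <- analyze_group(genomes, ...)
  }
  summary <- do.call(rbind, lapply(names(analyses), function(g) {
    a <- analyses[[g]]
    tips <- a$branch_omega[a$branch_omega$is_tip & !is.na(a$branch_omega$omega), ]
    ids <- rownames(a$alignment)
    cnt <- table(factor(a$pseudogenes$genome_id, levels = ids))
    data.frame(group = g, n = length(ids),
               r_over_theta = a$recomb$r_over_theta,
               delta = a$recomb$delta, nu = a$recomb$nu,
               r_over_m = a$recomb$r_over_m,
               pseudogenes_mean = mean(cnt), pseudogenes_sd = sd(cnt),
               omega_mean = mean(tips$omega), omega_sd = sd(tips$omega))
  }))
  tests <- list()
  if (length(analyses) >= 2) {
    g1 <- names(analyses)[1]; g2 <- names(analyses)[2]
    count_of <- function(a) {
      ids <- rownames(a$alignment)
      as.integer(table(factor(a$pseudogenes$genome_id, levels = ids)))
    }
    omega_of <- function(a) {
      t <- a$branch_omega
      t$omega[t$is_tip & !is.na(t$omega)]
    }
    tests$pseudogene_t <- welch_t_test(count_of(analyses[[g1]]),
                                       count_of(analyses[[g2]]),
                                       labels = c(g1, g2))
    o1 <- omega_of(analyses[[g1]]); o2 <- omega_of(analyses[[g2]])
    if (length(o1) >= 2 && length(o2) >= 2)
      tests$omega_t <- welch_t_test(o1, o2, labels = c(g1, g2))
    # pooled omega-vs-pseudogene regression
    om <- unlist(lapply(analyses, function(a) {
      t <- a$branch_omega[a$branch_omega$is_tip, ]
      setNames(t$omega, t$branch)
    }))
    pc <- unlist(lapply(analyses, function(a) {
      ids <- rownames(a$alignment)
      setNames(as.integer(table(factor(a$pseudogenes$genome_id, levels = ids))), ids)
    }))
    grp <- unlist(lapply(names(analyses), function(g)
      setNames(rep(g, nrow(analyses[[g]]$alignment)),
               rownames(analyses[[g]]$alignment))))
    names(om) <- sub("^.*\\.", "", names(om))
    names(pc) <- sub("^.*\\.", "", names(pc))
    names(grp) <- sub("^.*\\.", "", names(grp))
    tests$regression <- omega_vs_pseudogenes(om, pc, grp)
    # clade-specific pseudogene composition
    pg <- do.call(rbind, lapply(analyses, `[[`, "pseudogenes"))
    if (nrow(pg) > 0 && length(unique(pg$gene_id)) > 1) {
      pa <- table(pg$genome_id, pg$gene_id) > 0
      grp2 <- grp[rownames(pa)]
      if (length(unique(grp2)) >= 2 && all(table(grp2) >= 2))
        tests$anosim <- anosim_test(presence_distance(pa), grp2)
    }
  }
  res <- structure(list(analyses = analyses, summary = summary,
                        tests = tests, truths = truths),
                   class = "pipeline_result")
  if (!is.null(outdir)) make_report(res, outdir)
  res
}

#' Write the pipeline report
#'
#' TSV tables shaped like the study's displays: the headline summary table,
#' per-branch import counts (the import histogram), import segment
#' positions, per-branch omega, pseudogene calls, pairwise diversity
#' matrices, regression and test results, plus a JSON digest.
#'
#' @param result a `pipeline_result`.
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
make_report <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    f <- file.path(outdir, name)
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, f)
  }
  wr(result$summary, "summary.tsv")
  for (g in names(result$analyses)) {
    a <- result$analyses[[g]]
    pb <- a$recomb$per_branch
    seg <- a$imports
    pb$n_imports <- as.integer(table(factor(seg$branch, levels = pb$branch)))
    wr(pb, paste0("import_counts_", g, ".tsv"))
    if (nrow(seg) > 0) wr(seg, paste0("import_segments_", g, ".tsv"))
    wr(a$branch_omega, paste0("branch_omega_", g, ".tsv"))
    if (nrow(a$pseudogenes) > 0) wr(a$pseudogenes, paste0("pseudogenes_", g, ".tsv"))
    wr(as.data.frame(a$diversity$snp), paste0("diversity_snp_", g, ".tsv"))
    wr(as.data.frame(a$diversity$indel_events), paste0("diversity_indels_", g, ".tsv"))
    bd <- attr(a$alignment, "boundaries")
    bd0 <- data.frame(family_id = bd$family_id, start = bd$start - 1L,
                      end = bd$end)  # BED-like half-open
    wr(bd0, paste0("core_boundaries_", g, ".tsv"))
    ape::write.tree(a$tree, file.path(outdir, paste0("tree_", g, ".nwk")))
  }
  if (!is.null(result$tests$regression))
    wr(result$tests$regression, "omega_vs_pseudogenes.tsv")
  digest <- list(summary = result$summary)
  for (nm in c("pseudogene_t", "omega_t", "anosim")) {
    t <- result$tests[[nm]]
    if (!is.null(t))
      digest[[nm]] <- list(statistic = t$statistic, p_value = t$p_value)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jf <- file.path(outdir, "report.json")
    jsonlite::write_json(digest, jf, auto_unbox = TRUE, digits = NA)
    files <- c(files, jf)
  }
  invisible(files)
}
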