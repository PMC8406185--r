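# reference genome with one intact 900-bp gene, plus a mutable copy
make_ref_pair <- function(seed = 61) {
  cfg <- sim_config(n_taxa = 2, genome_length = 5000, n_genes = 1,
                    mean_gene_length = 900, theta_site = 0, r_over_theta = 0,
                    seed = seed)
  simulate_ancestor(cfg)
}

test_that("the >20% length-loss rule decides the call", {
  ref <- make_ref_pair()
  g <- ref$genes[1, ]
  glen <- g$end - g$start + 1L
  ncod <- glen %/% 3L
  put_stop <- function(genome, j) {   # replace 0-based codon j with a stop
    pos <- if (g$strand == "+") g$start + 3 * j + 0:2 else (g$end - 3 * j) - 2:0
    stopc <- if (g$strand == "+") c(4L, 1L, 1L) else rev(5L - c(4L, 1L, 1L))
    genome$seq[pos] <- stopc
    genome
  }
  # stop near 77% of the ORF (~23% lost): called as premature_stop
  mut <- put_stop(ref, floor(0.77 * ncod))
  mut$genome_id <- "mut"
  calls <- detect_pseudogenes(mut, ref)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$mechanism, "premature_stop")
  expect_gt(calls$fraction_lost, 0.20)
  # stop near 89% of the ORF (~11% lost): below threshold, no call
  mut2 <- put_stop(ref, floor(0.89 * ncod))
  mut2$genome_id <- "mut2"
  expect_equal(nrow(detect_pseudogenes(mut2, ref)), 0)
})

test_that("simulator-injected decay events are recovered with full recall", {
  cfg <- sim_config(n_taxa = 6, genome_length = 40000, n_genes = 25,
                    theta_site = 0, r_over_theta = 0, indel_rate = 0,
                    pseudogenization_rate = 3, total_depth = 0.01, seed = 21)
  out <- simulate_dataset(cfg)
  tp <- truth_table(out$truth, "pseudogenizations")
  expect_gt(nrow(tp), 0)
  tr <- out$tree
  ntip <- length(tr$tip.label)
  labs <- c(tr$tip.label, tr$node.label)
  tips_below <- function(node) {
    if (node <= ntip) return(labs[node])
    unlist(lapply(tr$edge[tr$edge[, 1] == node, 2], tips_below))
  }
  expected <- list()
  for (i in seq_len(nrow(tp))) {
    if (tp$fraction_lost[i] <= 0.2) next
    for (leaf in tips_below(match(tp$branch[i], labs)))
      expected[[leaf]] <- union(expected[[leaf]], tp$gene_id[i])
  }
  for (leaf in names(out$genomes)) {
    got <- detect_pseudogenes(out$genomes[[leaf]], out$ancestor)$gene_id
    exp <- expected[[leaf]]
    if (is.null(exp)) exp <- character(0)
    expect_setequal(got, exp)   # 100% recall and 0 false positives
  }
})

test_that("no calls arise without any gene-disrupting process", {
  cfg <- sim_config(n_taxa = 4, genome_length = 30000, n_genes = 15,
                    theta_site = 0, r_over_theta = 0, indel_rate = 0,
                    pseudogenization_rate = 0, seed = 3)
  out <- simulate_dataset(cfg)
  for (g in out$genomes)
    expect_equal(nrow(detect_pseudogenes(g, out$ancestor)), 0)
})

test_that("the intergenic scan finds unannotated decayed fragments", {
  ref <- make_ref_pair(seed = 67)
  g <- ref$genes[1, ]
  # drop the annotation and delete the second half of the gene: a fragment
  # covering ~50% of the reference remains, with no annotated copy
  half <- (g$end - g$start + 1L) %/% 2L
  state <- list(seq = ref$seq, genes = ref$genes[0, ])
  del <- clonalkit:::delete_segment(state, g$start + half, half)
  frag <- annotated_genome("frag", del$state$seq, NULL)
  calls <- detect_pseudogenes(frag, ref)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$mechanism, "truncation")
  expect_gt(calls$fraction_lost, 0.3)
})

test_that("group summaries compare loads and respect degenerate groups", {
  grouping <- setNames(rep(c("A", "B"), each = 4),
                       sprintf("g%d", 1:8))
  # identical groups: no signal
  calls0 <- data.frame(genome_id = rep(names(grouping), each = 2),
                       gene_id = rep(c("x", "y"), 8))
  s0 <- pseudogene_summary(calls0, grouping)
  expect_equal(s0$groups$mean, c(2, 2))
  expect_gt(s0$test$p_value, 0.9)
  # 3x load in group A: direction recovered
  set.seed(71)
  mkcalls <- function(ids, lam) do.call(rbind, lapply(ids, function(id)
    if ((n <- rpois(1, lam)) == 0) NULL else
      data.frame(genome_id = id, gene_id = sprintf("d%02d", sample(40, n)))))
  calls1 <- rbind(mkcalls(names(grouping)[1:4], 15),
                  mkcalls(names(grouping)[5:8], 5))
  s1 <- pseudogene_summary(calls1, grouping)
  expect_gt(s1$groups$mean[s1$groups$group == "A"],
            s1$groups$mean[s1$groups$group == "B"])
  # counts conserved through the category table
  cats <- setNames(rep(c("motility", "transport"), 20), sprintf("d%02d", 1:40))
  s2 <- pseudogene_summary(calls1, grouping, categories = cats)
  expect_equal(sum(table(calls1$genome_id)), nrow(calls1))
  expect_true(all(abs(vapply(split(s2$categories$mean_abundance,
                                   s2$categories$group), sum, 0) - 1) < 1e-9))
  # singleton group: test skipped with a flag
  g1 <- setNames(c("A", rep("B", 4)), sprintf("g%d", 1:5))
  s3 <- pseudogene_summary(calls0[calls0$genome_id %in% names(g1), ], g1)
  expect_null(s3$test)
  expect_true("group_too_small_for_test" %in% s3$flags)
})

test_that("omega/pseudogene regression handles exact, joint and degenerate cases", {
  om <- setNames(c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06), sprintf("g%d", 1:6))
  cnt <- setNames(2 * om * 1000 + 1, names(om))   # perfectly collinear
  grp <- setNames(rep("A", 6), names(om))
  reg <- omega_vs_pseudogenes(om, cnt, grp)
  expect_equal(reg$r[reg$group == "all"], 1, tolerance = 1e-12)
  expect_equal(reg$slope[reg$group == "all"], 2000, tolerance = 1e-9)
  # joint elevation in one group: positive pooled slope
  om2 <- setNames(c(0.02, 0.021, 0.022, 0.04, 0.041, 0.042), sprintf("h%d", 1:6))
  cnt2 <- setNames(c(20, 22, 21, 47, 49, 50), names(om2))
  grp2 <- setNames(rep(c("low", "high"), each = 3), names(om2))
  reg2 <- omega_vs_pseudogenes(om2, cnt2, grp2)
  expect_gt(reg2$slope[reg2$group == "all"], 0)
  # constant x: flagged degenerate
  om3 <- setNames(rep(0.02, 4), sprintf("k%d", 1:4))
  cnt3 <- setNames(1:4, names(om3))
  reg3 <- omega_vs_pseudogenes(om3, cnt3, setNames(rep("A", 4), names(om3)))
  expect_equal(reg3$flag[reg3$group == "all"], "constant_x")
  expect_true(is.na(reg3$slope[reg3$group == "all"]))
})
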