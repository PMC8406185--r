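test_that("pairwise diversity counts SNPs and indel runs by hand", {
  a <- c("A", "C", "G", "T", "A", "A", "C", "G", "T", "A", "C", "G")
  b <- a
  b[c(2, 7, 12)] <- c("G", "T", "A")         # 3 SNPs
  b[4] <- "-"; b[5] <- "-"; b[6] <- "-"       # one 3-column gap run
  aln <- rbind(x = a, y = b)
  d <- pairwise_diversity(aln)
  expect_equal(d$snp["x", "y"], 3L)
  expect_equal(d$indel_events["x", "y"], 1L)
  expect_equal(d$snp, t(d$snp))
  expect_equal(diag(d$snp), setNames(c(0L, 0L), c("x", "y")))
  # identical rows
  d0 <- pairwise_diversity(rbind(x = a, y = a))
  expect_equal(d0$snp["x", "y"] + d0$indel_events["x", "y"], 0L)
  # adjacent runs separated by one non-gap column are distinct events
  c1 <- rep("A", 10)
  c2 <- c("A", "-", "-", "A", "-", "-", "A", "A", "A", "A")
  expect_equal(pairwise_diversity(rbind(x = c1, y = c2))$indel_events["x", "y"], 2L)
})

test_that("diversity on simulated pairs equals the truth event counts", {
  # substitutions only: columnwise homologous leaves, exact equality when no
  # site was hit twice
  cfg <- sim_config(n_taxa = 2, genome_length = 50000, n_genes = 10,
                    theta_site = 0.1, r_over_theta = 0, indel_rate = 0,
                    total_depth = 0.004, seed = 505)
  out <- simulate_dataset(cfg)
  subs <- truth_table(out$truth, "substitutions")
  expect_equal(anyDuplicated(subs$site), 0)   # the no-overlap regime
  ids <- names(out$genomes)
  d <- pairwise_diversity(leaf_alignment(out$genomes))
  expect_equal(d$snp[ids[1], ids[2]], nrow(subs))
  # sparse indels on a small pair: each event is one gap run after alignment
  cfg2 <- sim_config(n_taxa = 2, genome_length = 5000, n_genes = 3,
                     theta_site = 0.2, r_over_theta = 0, indel_rate = 0.05,
                     indel_length_mean = 4, total_depth = 0.004, seed = 521)
  out2 <- simulate_dataset(cfg2)
  inds <- truth_table(out2$truth, "indels")
  subs2 <- truth_table(out2$truth, "substitutions")
  expect_gt(nrow(inds), 0)
  ids2 <- names(out2$genomes)
  aln2 <- align_family(setNames(vapply(out2$genomes, function(g)
    int_seq_to_char(g$seq), ""), ids2), center = ids2[1])
  d2 <- pairwise_diversity(aln2)
  expect_equal(d2$indel_events[ids2[1], ids2[2]], nrow(inds))
  expect_equal(d2$snp[ids2[1], ids2[2]], nrow(subs2))
})

test_that("within-clade diversity is below between-clade diversity", {
  cfgA <- sim_config(n_taxa = 3, genome_length = 30000, n_genes = 0,
                     r_over_theta = 0, total_depth = 0.002, seed = 601)
  cfgB <- sim_config(n_taxa = 3, genome_length = 30000, n_genes = 0,
                     r_over_theta = 0, total_depth = 0.002, seed = 602)
  A <- leaf_alignment(simulate_dataset(cfgA)$genomes)
  B <- leaf_alignment(simulate_dataset(cfgB)$genomes)
  comb <- rbind(A, B)
  rownames(comb) <- c(paste0("A", 1:3), paste0("B", 1:3))
  d <- pairwise_diversity(comb)$snp
  within <- c(d[1:3, 1:3][upper.tri(diag(3))], d[4:6, 4:6][upper.tri(diag(3))])
  between <- as.vector(d[1:3, 4:6])
  expect_lt(max(within), min(between))
})

test_that("the drift model is linear and exactly invertible", {
  m <- drift_model(mu_bp = 1e-9, L = 4.7e6, pairwise_factor = 1)
  expect_equal(expected_diversity(m, 0), 0)
  expect_equal(expected_diversity(m, 1000), 4.7)
  expect_equal(expected_diversity(m, 2000), 2 * expected_diversity(m, 1000))
  for (G in c(1, 47.29, 4000))
    expect_equal(generations_required(m, expected_diversity(m, G)), G)
  # ~4255 generations for 20 observed differences, beyond the paper-scale
  # laboratory bound of a few thousand generations
  expect_equal(round(generations_required(m, 20)), 4255)
  expect_error(generations_required(m, 0), "positive")
  # Drake preset: one mutation per 300 genome replications
  expect_equal(drake_rate(4.7e6) * 4.7e6, 1 / 300)
})

test_that("generation arithmetic reproduces the culture-protocol numbers", {
  expect_equal(doublings_from_abundance(1, 1), 0)
  expect_equal(doublings_from_abundance(1, 8), 3)
  expect_equal(round(doublings_from_abundance(1, 3.3e9), 2), 31.62)
  expect_equal(round(cumulative_generations(
    list(list("fixed", 15.67), list("colony", 3.3e9))), 2), 47.29)
  expect_equal(round(cumulative_generations(
    list(list("fixed", 15.67), list("colony", 3.3e9),
         list("colony", 3.3e9))), 2), 78.91)
  expect_equal(cumulative_generations(list()), 0)
  expect_error(doublings_from_abundance(0, 10), "positive")
})

test_that("growth and oxygen arithmetic are exact", {
  expect_equal(growth_rate(0.1, 0.2, 0, 1), log(2))
  expect_equal(growth_rate(0.5, 0.5, 0, 2), 0)
  mu <- growth_rate(0.05, 0.4, 0, 10)
  expect_equal(doubling_time(mu), log(2) / mu)
  expect_equal(growth_rate(1, 2 ^ (24 / doubling_time(mu) * 1), 0, 24) , mu,
               tolerance = 1e-12)
  expect_error(growth_rate(0.1, 0.2, 5, 5), "exceed")
  expect_equal(o2_consumption_rate(10, 10, 100), 0)
  expect_equal(o2_consumption_rate(21.9, 0, 547.5), 0.04)
  expect_equal(o2_consumption_rate(30, 10, 10), 2 * o2_consumption_rate(20, 10, 10))
  expect_error(o2_consumption_rate(10, 5, 0), "positive")
})
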