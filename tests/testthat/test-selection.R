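test_that("the NG86 site table equals brute-force single-step enumeration", {
  # independent oracle: enumerate each sense codon's single-nucleotide
  # neighbours with the standard code; per position, the synonymous fraction
  # among non-stop changes
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  oracle <- vapply(sense, function(cod) {
    cs <- strsplit(cod, "")[[1]]
    total <- 0
    for (p in 1:3) {
      s <- 0L; v <- 0L
      for (b in setdiff(c("A", "C", "G", "T"), cs[p])) {
        nb <- cs; nb[p] <- b
        nbc <- paste(nb, collapse = "")
        if (gc[[nbc]] == "*") next
        v <- v + 1L
        if (gc[[nbc]] == gc[[cod]]) s <- s + 1L
      }
      if (v > 0) total <- total + s / v
    }
    total
  }, 0)
  tab <- ng86_site_table()
  expect_setequal(names(tab), sense)
  expect_equal(tab[sense], oracle[sense], tolerance = 1e-12)
})

test_that("pairwise counting handles the textbook single-difference case", {
  a <- c(rep("ATG", 5), "TTT", rep("GGG", 5))
  b <- a; b[6] <- "TTC"   # synonymous third-position change (Phe)
  p <- ng86_pair(a, b)
  expect_equal(p$Nd, 0)
  expect_equal(p$Sd, 1)
  expect_equal(p$N + p$S, 3 * p$n_codons)
  # identical sequences: no differences, omega undefined
  q <- ng86_pair(a, a)
  expect_equal(q$Nd + q$Sd, 0)
  expect_true(is.na(q$omega))
  expect_true("dS_zero" %in% q$flags)
  # stop codons and NAs are excluded pairwise
  r <- ng86_pair(c("ATG", "TAA", NA), c("ATG", "ATG", "CCC"))
  expect_equal(r$n_codons, 1)
  expect_error(ng86_pair(a, a[-1]), "length")
})

test_that("neutral codon evolution yields omega with CI covering 1", {
  set.seed(31)
  om <- replicate(15, {
    anc <- random_sense_codons(20000)
    ng86_pair(mutate_codons_neutral(anc, 0.02),
              mutate_codons_neutral(anc, 0.02))$omega
  })
  ci <- t.test(om)$conf.int
  expect_lte(ci[1], 1)
  expect_gte(ci[2], 1)
})

test_that("purifying selection drives omega into the expected band", {
  set.seed(37)
  om <- replicate(3, {
    anc <- random_sense_codons(12000)
    ng86_pair(mutate_codons_selected(anc, 0.03, w = 0.1),
              mutate_codons_selected(anc, 0.03, w = 0.1))$omega
  })
  expect_true(all(om > 0.05 & om < 0.2))
})

test_that("codon framing follows the reference row and masks gaps", {
  # mutation-free genomes: the reference row carries intact ORFs only, so
  # every gene contributes length/3 codons and none are dropped (with
  # mutations, stop-creating substitutions in the reference row correctly
  # trigger drops)
  cfg <- sim_config(n_taxa = 4, genome_length = 20000, n_genes = 8,
                    theta_site = 0, r_over_theta = 0, seed = 41)
  out <- simulate_dataset(cfg)
  ort <- identify_orthologs(out$genomes)
  aln <- core_alignment(out$genomes, ort)
  ca <- codon_alignment(aln)
  bd <- attr(aln, "boundaries")
  expect_equal(ncol(ca$codons), sum((bd$end - bd$start + 1L) %/% 3L))
  expect_length(ca$dropped, 0)
  # a hand-built block: 300 columns -> 100 codons; a gap masks one codon
  m <- matrix("A", 2, 300, dimnames = list(c("r", "s"), NULL))
  cc <- concatenate_core(list(f1 = m))
  expect_equal(ncol(codon_alignment(cc)$codons), 100)
  m2 <- m; m2["s", 5] <- "-"
  cc2 <- concatenate_core(list(f1 = m2))
  cd2 <- codon_alignment(cc2)
  expect_true(is.na(cd2$codons["s", 2]))
  expect_false(is.na(cd2$codons["r", 2]))
})

test_that("per-branch omega covers every branch and flags empty ones", {
  out <- clonal_dataset()
  ort <- identify_orthologs(out$genomes)
  aln <- core_alignment(out$genomes, ort)
  tree <- nj_tree(core_distances(aln))
  bo <- per_branch_omega(tree, aln)
  expect_equal(nrow(bo), nrow(tree$edge))
  expect_equal(sum(bo$is_tip), length(tree$tip.label))
  # a zero-length branch yields zero differences
  zero <- bo[bo$Nd + bo$Sd == 0, ]
  if (nrow(zero) > 0) expect_true(all(is.na(zero$omega)))
  expect_true(all(bo$N + bo$S == 3 * bo$n_codons))
})

test_that("a clade with elevated nonsynonymous input shows the highest omega", {
  # construct: two sister pairs; one pair's terminal branches receive extra
  # nonsynonymous changes
  set.seed(53)
  anc <- random_sense_codons(8000)
  drift <- function(x) mutate_codons_neutral(x, 0.01)
  nonsyn_boost <- function(x) mutate_codons_selected(x, 0.03, w = 1) # neutral
  t1 <- mutate_codons_selected(drift(anc), 0.02, w = 5 / 5)  # plain
  relaxed <- function(x) {
    # force amino-acid-changing updates by rejecting synonymous ones
    gc <- Biostrings::GENETIC_CODE
    m <- do.call(rbind, strsplit(x, ""))
    hit <- which(matrix(runif(length(m)) < 0.02, nrow = nrow(m)), arr.ind = TRUE)
    for (r in seq_len(nrow(hit))) {
      i <- hit[r, 1]; j <- hit[r, 2]
      cand <- m[i, ]
      cand[j] <- sample(setdiff(c("A", "C", "G", "T"), m[i, j]), 1)
      new <- paste(cand, collapse = "")
      if (new %in% c("TAA", "TAG", "TGA")) next
      if (gc[[new]] != gc[[paste(m[i, ], collapse = "")]]) m[i, ] <- cand
    }
    paste0(m[, 1], m[, 2], m[, 3])
  }
  om_plain <- ng86_pair(anc, drift(anc))$omega
  om_boost <- ng86_pair(anc, relaxed(drift(anc)))$omega
  expect_gt(om_boost, om_plain)
})
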