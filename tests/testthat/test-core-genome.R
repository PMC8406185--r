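test_that("protein similarity is identity-normalized, symmetric, and guarded", {
  p <- "MKVLWAALLVTFLAGCQAKVEQAVETEPEPELRQQTEWQSGQRWELALGRFWDYLRWVQTLSEQVQEELLSSQVTQELRALMDETMKELKAYKSELEEQLTPVAEETRARLSKELQAAQARLGADMEDVCGRLVQYRGEVQAMLGQSTEELRVRLASHLRKLRKRLLRDADDLQKRLAVYQAGA"
  expect_equal(protein_similarity(p, p), 1)
  q <- "MDEKRRAQHNEVERRRRDKINNWIVQLSKIIPDSSMESTKSGQSKGGILSKASDYIQELRQSNHR"
  expect_equal(protein_similarity(p, q), protein_similarity(q, p))
  expect_error(protein_similarity("", p), "empty")
})

test_that("an unrelated low-complexity pair stays below the 30% threshold", {
  # crafted pair: long stretches of incompatible composition; local identity
  # over the aligned length cannot reach 0.30
  a <- paste(rep("MKLVINEQ", 30), collapse = "")
  b <- paste(rep("WWPPGGCC", 30), collapse = "")
  expect_lt(protein_similarity(a, b), 0.30)
})

test_that("orthologs are recovered exactly on clonal simulated genomes", {
  out <- clonal_dataset()
  ort <- identify_orthologs(out$genomes)
  cfg <- out$truth$config
  expect_equal(length(unique(ort$family_id)), cfg$n_genes)
  # every family has exactly one member per genome
  tab <- table(ort$family_id, ort$genome_id)
  expect_true(all(tab == 1))
  expect_true(all(ort$similarity > 0.30))
})

test_that("a duplicated gene excludes its family; a diverged member drops it", {
  out <- clonal_dataset()
  genomes <- out$genomes
  g1 <- genomes[[1]]
  dup <- g1$genes[1, ]
  ref_ort <- identify_orthologs(genomes)
  fam1 <- unique(ref_ort$family_id)[1]
  # duplicate the first gene into intergenic space of the same genome
  gs <- gene_sequences(g1)[[dup$gene_id]]
  gap_start <- max(g1$genes$end) + 10L
  seq2 <- g1$seq
  ins <- as_int_seq(as.character(gs))
  if (gap_start + length(ins) <= length(seq2)) {
    seq2[gap_start:(gap_start + length(ins) - 1L)] <- ins
    genes2 <- rbind(g1$genes, data.frame(
      gene_id = "dup0001", start = gap_start,
      end = gap_start + length(ins) - 1L, strand = "+",
      frame = 0L, pseudo = FALSE))
    genomes[[1]] <- annotated_genome(g1$genome_id, seq2, genes2)
    ort <- identify_orthologs(genomes)
    expect_false(paste0("fam_", dup$gene_id) %in% ort$family_id)
    # all other families survive
    expect_equal(length(unique(ort$family_id)),
                 out$truth$config$n_genes - 1L)
  }
  # replace one member by an unrelated sequence: similarity below the
  # threshold, family excluded
  genomes2 <- out$genomes
  g2 <- genomes2[[2]]
  victim <- g2$genes$gene_id[2]
  vi <- match(victim, g2$genes$gene_id)
  set.seed(77)
  span <- g2$genes$start[vi]:g2$genes$end[vi]
  g2$seq[span] <- sample.int(4L, length(span), replace = TRUE)
  genomes2[[2]] <- g2
  ort2 <- identify_orthologs(genomes2)
  expect_false(paste0("fam_", victim) %in% ort2$family_id)
})

test_that("family alignment handles identical, indel and length cases", {
  s <- c(a = "ATGAAACCCGGGTTTACATAA", b = "ATGAAACCCGGGTTTACATAA",
         c = "ATGAAACCCGGGTTTACATAA")
  aln <- align_family(s)
  expect_equal(ncol(aln), 21)
  expect_false(any(aln == "-"))
  # one 3-bp deletion: a single 3-column gap run
  s2 <- c(a = "ATGAAACCCGGGTTTACATAA", b = "ATGAAAGGGTTTACATAA")
  a2 <- align_family(s2, center = "a")
  expect_equal(ncol(a2), 21)
  gaps <- rle(a2["b", ] == "-")
  expect_equal(sum(gaps$values), 1)
  expect_equal(gaps$lengths[gaps$values], 3)
  # alignment length >= longest input
  expect_gte(ncol(a2), max(nchar(s2)))
  expect_error(align_family(c(a = "ATG!!", b = "ATGAA")), "IUPAC")
})

test_that("concatenation is additive and order-stable", {
  mk <- function(w) matrix(sample(c("A", "C", "G", "T"), 3 * w, TRUE),
                           nrow = 3, dimnames = list(c("x", "y", "z"), NULL))
  set.seed(1)
  alns <- list(f1 = mk(300), f2 = mk(450), f3 = mk(600))
  cc <- concatenate_core(alns)
  expect_equal(ncol(cc), 1350)
  bd <- attr(cc, "boundaries")
  expect_equal(nrow(bd), 3)
  expect_equal(bd$end - bd$start + 1L, c(300L, 450L, 600L))
  # boundaries tile without gaps or overlaps
  expect_equal(bd$start[-1], bd$end[-3] + 1L)
  # single family: passthrough
  one <- concatenate_core(alns[2])
  expect_equal(unclass(one)[, ], alns$f2)
  # column count invariant to input order
  cc2 <- concatenate_core(rev(alns))
  expect_equal(ncol(cc2), ncol(cc))
  expect_error(concatenate_core(list(mk(10), mk(10)[1:2, ])), "taxa")
})

test_that("core alignment boundaries match the simulated gene count", {
  out <- clonal_dataset()
  ort <- identify_orthologs(out$genomes)
  aln <- core_alignment(out$genomes, ort)
  expect_equal(nrow(attr(aln, "boundaries")), out$truth$config$n_genes)
  expect_setequal(rownames(aln), names(out$genomes))
})

test_that("pangenome clustering partitions genes and counts singletons", {
  out <- clonal_dataset()
  pg <- cluster_pangenome(out$genomes)
  total_genes <- sum(vapply(out$genomes, function(g) nrow(g$genes), 0L))
  expect_equal(sum(lengths(pg$clusters)), total_genes)
  # clonal construction, no gain/loss: no singletons
  expect_equal(pg$singleton_count, 0)
  expect_equal(pg$n_core, pg$n_clusters)
  # inject one unique random gene into one genome
  genomes <- out$genomes
  g1 <- genomes[[1]]
  set.seed(5)
  orf <- c(1L, 4L, 3L, as.vector(clonalkit:::sample_sense_codons(99, rep(0.25, 4))),
           c(4L, 1L, 1L))
  pos <- length(g1$seq) - length(orf) - 10L
  g1$seq[pos:(pos + length(orf) - 1L)] <- orf
  g1$genes <- rbind(g1$genes, data.frame(
    gene_id = "uniq01", start = pos, end = pos + length(orf) - 1L,
    strand = "+", frame = 0L, pseudo = FALSE))
  genomes[[1]] <- annotated_genome(g1$genome_id, g1$seq, g1$genes)
  pg2 <- cluster_pangenome(genomes)
  expect_equal(pg2$singleton_count, 1)
  expect_equal(pg2$singleton_fraction_of_flexible, 1)
})

test_that("pangenome core clusters are no fewer than ortholog families", {
  out <- clonal_dataset()
  ort <- identify_orthologs(out$genomes)
  pg <- cluster_pangenome(out$genomes)
  expect_gte(pg$n_core, length(unique(ort$family_id)))
})

test_that("fragment ANI behaves on self, mutated and reversed comparisons", {
  out <- clonal_dataset()
  g <- out$genomes[[1]]
  expect_equal(average_nucleotide_identity(g, g), 100)
  # i.i.d. 5% mutated copy: ANI ~ 95
  set.seed(11)
  s <- g$seq
  idx <- sample(length(s), round(0.05 * length(s)))
  s[idx] <- (s[idx] - 1L + sample.int(3L, length(idx), TRUE)) %% 4L + 1L
  mut <- annotated_genome("mut", s)
  ani <- average_nucleotide_identity(g, mut)
  expect_lt(abs(ani - 95), 0.5)
  # near-symmetry on simulated pairs
  a <- out$genomes[[1]]; b <- out$genomes[[4]]
  expect_lt(abs(average_nucleotide_identity(a, b) -
                  average_nucleotide_identity(b, a)), 1)
  expect_error(average_nucleotide_identity(
    annotated_genome("tiny", "ACGT"), g), "fragment")
})
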