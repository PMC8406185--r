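test_that("r/m is the exact product of its three inputs", {
  expect_equal(compute_r_over_m(0.006, 500, 0.026), 0.078)
  expect_equal(round(compute_r_over_m(0.04, 333, 0.053), 2), 0.71)
  expect_equal(compute_r_over_m(0, 500, 0.026), 0)
  expect_error(compute_r_over_m(-1, 500, 0.026), "non-negative")
})

test_that("mismatch tracks count substitutions exactly", {
  g <- ape::read.tree(text = "((t1:0.01,t2:0.01):0.01,(t3:0.01,t4:0.01):0.01);")
  base <- rep("A", 200)
  child <- base; child[c(3, 50, 51, 120, 199)] <- "G"   # 5 substitutions
  aln <- rbind(t1 = child, t2 = base, t3 = base, t4 = base)
  anc <- reconstruct_ancestors(g, aln)
  tracks <- mismatch_tracks(g, aln, anc)
  expect_length(tracks[["t1"]], 200)
  expect_equal(sum(tracks[["t1"]]), 5)
  expect_equal(sum(tracks[["t2"]]), 0)
  # gap in the child: site is missing, not a mismatch
  aln2 <- aln; aln2["t1", 1] <- "-"
  tracks2 <- mismatch_tracks(g, aln2, reconstruct_ancestors(g, aln2))
  expect_true(is.na(tracks2[["t1"]][1]))
})

test_that("the EM fit is monotone, convergent, and degenerate-safe", {
  set.seed(42)
  v <- integer(50000)
  v[sample(50000, 60)] <- 1L
  v[seq(20000, 20400, by = 40)] <- 1L
  tracks <- list(b1 = v)
  attr(tracks, "lengths") <- c(b1 = 0.002)
  fit <- fit_recombination_hmm(tracks)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_true(fit$converged)
  expect_equal(fit$r_over_m,
               compute_r_over_m(fit$r_over_theta, fit$delta, fit$nu))
  # all-zero tracks: R/theta -> 0, nu undefined-flagged
  z <- list(b1 = integer(1000)); attr(z, "lengths") <- c(b1 = 0.01)
  fz <- fit_recombination_hmm(z)
  expect_equal(fz$r_over_theta, 0)
  expect_true(is.na(fz$nu))
  expect_true("no_mismatches" %in% fz$flags)
  expect_equal(nrow(decode_imports(fz)), 0)
})

test_that("decoding finds a clustered import as one segment", {
  # 10 mismatches clustered in 500 bp within a 100-kb silent background
  v <- integer(100000)
  cluster <- seq(50000, 50450, by = 50)
  v[cluster] <- 1L
  tracks <- list(tip = v)
  attr(tracks, "lengths") <- c(tip = 0.001)
  fit <- fit_recombination_hmm(tracks, max_iter = 200)
  segs <- decode_imports(fit)
  expect_equal(nrow(segs), 1)
  expect_lte(segs$start, min(cluster))
  expect_gte(segs$end, max(cluster))
  expect_equal(segs$n_mismatch, 10)
  # viterbi agrees on the obvious case
  segv <- decode_imports(fit, method = "viterbi")
  expect_equal(nrow(segv), 1)
  # segments are sorted and non-overlapping per branch
  out <- recomb_dataset()
  f2 <- estimate_recombination(leaf_alignment(out$genomes),
                               tol = 1e-3, max_iter = 200)
  s2 <- decode_imports(f2)
  for (br in unique(s2$branch)) {
    s <- s2[s2$branch == br, ]
    expect_true(all(diff(s$start) > 0))
    expect_true(all(s$start[-1] > s$end[-nrow(s)]))
    expect_true(all(s$end >= s$start))
  }
})

test_that("parameters are recovered and match the simulator truth", {
  out <- recomb_dataset()    # type preset: R/theta=0.04, delta=333, nu=0.053
  fit <- estimate_recombination(leaf_alignment(out$genomes),
                                tol = 1e-3, max_iter = 200)
  expect_lt(abs(fit$r_over_theta - 0.04) / 0.04, 0.3)
  expect_lt(abs(fit$delta - 333) / 333, 0.3)
  expect_lt(abs(fit$nu - 0.053) / 0.053, 0.3)
  # HMM r/m within 50% of the truth-based r/m
  rm_truth <- truth_r_over_m(out$truth)
  expect_lt(abs(fit$r_over_m - rm_truth) / rm_truth, 0.5)
})

test_that("decoded imports hit the true tracts with good sensitivity/precision", {
  out <- recomb_dataset()
  fit <- estimate_recombination(leaf_alignment(out$genomes),
                                tol = 1e-3, max_iter = 200)
  segs <- decode_imports(fit)
  imp <- truth_table(out$truth, "imports")
  # per terminal branch, compare detected vs true tract site sets
  site_set <- function(d, br, L) {
    x <- logical(L)
    dd <- d[d$branch == br, , drop = FALSE]
    for (i in seq_len(nrow(dd))) x[dd$start[i]:dd$end[i]] <- TRUE
    x
  }
  L <- out$truth$config$genome_length
  sens <- c(); prec <- c()
  for (br in intersect(unique(imp$branch), out$tree$tip.label)) {
    tru <- site_set(imp[imp$n_changed >= 3, ], br, L)  # detectable tracts
    det <- site_set(segs, br, L)
    if (sum(tru) == 0) next
    sens <- c(sens, sum(tru & det) / sum(tru))
    prec <- c(prec, if (sum(det) > 0) sum(det & tru) / sum(det) else NA)
  }
  expect_gte(mean(sens), 0.8)
  expect_gte(mean(prec, na.rm = TRUE), 0.8)
})

test_that("estimates are invariant to taxa row order", {
  out <- recomb_dataset()
  aln <- leaf_alignment(out$genomes)
  f1 <- estimate_recombination(aln, tol = 1e-3, max_iter = 100)
  set.seed(8)
  perm <- sample(rownames(aln))
  f2 <- estimate_recombination(aln[perm, ], tol = 1e-3, max_iter = 100)
  expect_equal(f1$r_over_m, f2$r_over_m, tolerance = 1e-6)
  expect_equal(f1$nu, f2$nu, tolerance = 1e-6)
})

test_that("per-group estimation orders the two presets and guards groups", {
  cfgs <- list(
    low = sim_config(n_taxa = 6, genome_length = 80000, n_genes = 0,
                     r_over_theta = 0.006, delta = 500, nu = 0.026,
                     total_depth = 0.01, seed = 401),
    high = sim_config(n_taxa = 6, genome_length = 80000, n_genes = 0,
                      r_over_theta = 0.04, delta = 333, nu = 0.053,
                      total_depth = 0.01, seed = 402))
  alns <- lapply(cfgs, function(cc) leaf_alignment(simulate_dataset(cc)$genomes))
  combined <- rbind(alns$low, alns$high)
  rownames(combined) <- c(paste0("low_", rownames(alns$low)),
                          paste0("high_", rownames(alns$high)))
  grouping <- setNames(sub("_.*", "", rownames(combined)), rownames(combined))
  fits <- group_recombination(combined, grouping, tol = 1e-3, max_iter = 200)
  expect_lt(fits$low$r_over_m, fits$high$r_over_m)
  summ <- attr(fits, "summary")
  expect_setequal(summ$group, c("low", "high"))
  # grouping = all taxa reproduces the single fit
  all_grp <- setNames(rep("all", nrow(alns$high)), rownames(alns$high))
  f_all <- group_recombination(alns$high, all_grp, tol = 1e-3, max_iter = 100)
  f_one <- estimate_recombination(alns$high, tol = 1e-3, max_iter = 100)
  expect_equal(f_all$all$r_over_m, f_one$r_over_m, tolerance = 1e-8)
  # singleton group errors
  bad <- all_grp; bad[1] <- "solo"
  expect_error(group_recombination(alns$high, bad, tol = 1e-3), "fewer than 2")
})
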