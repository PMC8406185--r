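# Per-branch two-state HMM over core-alignment sites: Unimported vs Imported.
#
# On the branch from a (reconstructed) ancestor to its descendant, the
# observation at each site is whether the two states differ. Unimported
# sites mismatch with probability 1 - exp(-b) (b = clonal branch length in
# substitutions/site, free per branch); imported sites mismatch with
# probability nu. The chain enters the Imported state at rate
# 1 - exp(-(R/theta) * b) per site and leaves it at rate 1/delta, so tract
# lengths are geometric with mean delta. R/theta, delta and nu are shared
# across branches and estimated jointly by EM (Baum-Welch E-step in C++, a
# coordinate-ascent generalized M-step in R, so the log-likelihood is
# non-decreasing). The summary statistic r/m = (R/theta) * delta * nu is the
# expected ratio of substitutions introduced by recombination to those
# introduced by point mutation.

#' Relative contribution of recombination versus mutation
#'
#' The r/m ratio: the product of the recombination-to-mutation initiation
#' ratio, the mean import length, and the mean divergence of imported DNA.
#'
#' @param r_over_theta recombination initiations per point mutation.
#' @param delta mean import tract length (bp).
#' @param nu mean per-site divergence of imported DNA.
#' @return `r_over_theta * delta * nu`, exactly.
#' @export
compute_r_over_m <- function(r_over_theta, delta, nu) {
  if (any(c(r_over_theta, delta, nu) < 0))
    stop("all r/m inputs must be non-negative")
  r_over_theta * delta * nu
}

#' Per-branch mismatch tracks
#'
#' For every branch of the rooted genealogy, records per alignment column
#' whether the parent and child states differ (1), agree (0), or cannot be
#' compared (NA, when either state is a gap or ambiguity).
#'
#' @param genealogy rooted `phylo` with (or without) internal node labels.
#' @param alignment character matrix, rows = taxa.
#' @param ancestors ancestral sequence matrix from [reconstruct_ancestors()].
#' @return named list (one entry per branch, keyed by child node label) of
#'   integer vectors of length `ncol(alignment)`; branch lengths attached as
#'   the `"lengths"` attribute.
#' @export
mismatch_tracks <- function(genealogy, alignment, ancestors) {
  tr <- genealogy
  ntip <- length(tr$tip.label)
  labs <- c(tr$tip.label,
            if (!is.null(tr$node.label) && all(nzchar(tr$node.label)))
              tr$node.label else sprintf("n%02d", (ntip + 1):(ntip + tr$Nnode)))
  get_seq <- function(node) {
    lab <- labs[node]
    if (node <= ntip) toupper(alignment[lab, ]) else toupper(ancestors[lab, ])
  }
  if (!all(labs[(ntip + 1):(ntip + tr$Nnode)] %in% rownames(ancestors)))
    stop("ancestors matrix does not cover the internal nodes; run reconstruct_ancestors() on this genealogy")
  tracks <- list()
  lens <- numeric(0)
  for (e in seq_len(nrow(tr$edge))) {
    par <- get_seq(tr$edge[e, 1])
    chi <- get_seq(tr$edge[e, 2])
    ok <- par %in% BASES & chi %in% BASES
    v <- rep(NA_integer_, length(par))
    v[ok] <- as.integer(par[ok] != chi[ok])
    lab <- labs[tr$edge[e, 2]]
    tracks[[lab]] <- v
    lens[lab] <- tr$edge.length[e]
  }
  attr(tracks, "lengths") <- lens
  tracks
}

# expected complete-data log-likelihood terms used by the generalized M-step
.ecll_branch_b <- function(b, rtheta, cnt) {
  e_u <- -expm1(-b)
  cnt$mmU * log(e_u) - (cnt$occU - cnt$mmU) * b -
    cnt$A[1] * rtheta * b + cnt$A[2] * log(-expm1(-rtheta * b))
}

.ecll_rtheta <- function(rtheta, bvec, counts) {
  s <- 0
  for (k in seq_along(counts)) {
    cnt <- counts[[k]]
    s <- s - cnt$A[1] * rtheta * bvec[k] +
      cnt$A[2] * log(max(-expm1(-rtheta * bvec[k]), 1e-300))
  }
  s
}

#' Fit the recombination HMM by EM
#'
#' @param tracks list of per-branch mismatch tracks from [mismatch_tracks()]
#'   (NA entries are skipped; the transition bridges the gap).
#' @param init optional named list overriding the default initialization
#'   (`r_over_theta = 0.01`, `delta = 200`, `nu` = 10x the mean mismatch
#'   density, `b` from each branch's raw mismatch density).
#' @param tol EM stops when the log-likelihood improves by less than this.
#' @param max_iter maximum EM iterations; hitting it sets `converged = FALSE`
#'   with a warning and returns the best fit so far.
#' @return object of class `recomb_fit`: shared parameter estimates
#'   (`r_over_theta`, `delta`, `nu`, `r_over_m`), a `per_branch` data.frame
#'   (branch, clonal length b, sites compared, mismatches, expected imported
#'   site fraction), the log-likelihood trace, posteriors per branch, and
#'   status flags.
#' @export
fit_recombination_hmm <- function(tracks, init = list(), tol = 1e-6,
                                  max_iter = 500) {
  lens <- attr(tracks, "lengths")
  obs <- lapply(tracks, function(v) as.integer(v[!is.na(v)]))
  maps <- lapply(tracks, function(v) which(!is.na(v)))
  keep <- vapply(obs, length, 0L) > 0
  obs <- obs[keep]; maps <- maps[keep]
  if (length(obs) == 0) stop("no branch has any comparable site")
  K <- length(obs)
  n_mm <- vapply(obs, sum, 0)
  n_sites <- vapply(obs, length, 0)

  if (sum(n_mm) == 0) {
    pb <- data.frame(branch = names(obs), b = 0, n_sites = n_sites,
                     n_mismatch = n_mm, imported_fraction = 0,
                     row.names = NULL)
    return(structure(list(r_over_theta = 0, delta = NA_real_, nu = NA_real_,
                          r_over_m = 0, per_branch = pb, loglik = 0,
                          loglik_trace = numeric(0), converged = TRUE,
                          iterations = 0L, posteriors = lapply(obs, function(o) o * 0),
                          maps = maps, obs = obs,
                          n_columns = length(tracks[[1]]),
                          flags = "no_mismatches"),
                     class = "recomb_fit"))
  }

  p_k <- pmin(pmax(n_mm / n_sites, 1e-8), 0.5)
  b <- -log(1 - p_k)
  rtheta <- if (!is.null(init$r_over_theta)) init$r_over_theta else 0.01
  delta <- if (!is.null(init$delta)) init$delta else 200
  nu <- if (!is.null(init$nu)) init$nu else
    min(max(10 * sum(n_mm) / sum(n_sites), 1e-4), 0.75)
  if (!is.null(init$b)) b <- rep_len(init$b, K)

  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  counts <- vector("list", K)
  for (iter in seq_len(max_iter)) {
    t_iu <- min(1 / delta, 1 - 1e-12)
    ll <- 0
    for (k in seq_len(K)) {
      fb <- .hmm_fb(obs[[k]], -expm1(-b[k]), nu,
                    max(-expm1(-rtheta * b[k]), 1e-300), t_iu, FALSE)
      counts[[k]] <- list(A = fb$A, occU = fb$occ[1], occI = fb$occ[2],
                          mmU = fb$mm[1], mmI = fb$mm[2])
      ll <- ll + fb$loglik
    }
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) { converged <- TRUE; break }
    ll_prev <- ll

    # --- generalized M-step (closed forms where separable, coordinate
    #     ascent for the coupled R/theta and per-branch b) ---
    occI <- sum(vapply(counts, `[[`, 0, "occI"))
    mmI <- sum(vapply(counts, `[[`, 0, "mmI"))
    if (occI > 1e-12) nu <- min(max(mmI / occI, 1e-8), 0.75)
    A_iu <- sum(vapply(counts, function(cn) cn$A[3], 0))
    A_ii <- sum(vapply(counts, function(cn) cn$A[4], 0))
    if (A_iu + A_ii > 1e-12 && A_iu > 0)
      delta <- max((A_iu + A_ii) / A_iu, 1 + 1e-9)
    for (pass in 1:2) {
      for (k in seq_len(K)) {
        cur <- .ecll_branch_b(b[k], rtheta, counts[[k]])
        opt <- optimize(.ecll_branch_b, interval = c(1e-9, 5),
                        rtheta = rtheta, cnt = counts[[k]], maximum = TRUE)
        if (opt$objective > cur) b[k] <- opt$maximum
      }
      cur <- .ecll_rtheta(rtheta, b, counts)
      opt <- optimize(.ecll_rtheta, interval = c(1e-9, 100), bvec = b,
                      counts = counts, maximum = TRUE)
      if (opt$objective > cur) rtheta <- opt$maximum
    }
  }
  if (!converged)
    warning("EM reached max_iter without meeting the log-likelihood tolerance; returning the current fit")

  # final E-step at the converged parameters, keeping posteriors
  t_iu <- min(1 / delta, 1 - 1e-12)
  post <- vector("list", K); names(post) <- names(obs)
  impfrac <- numeric(K); ll <- 0
  for (k in seq_len(K)) {
    fb <- .hmm_fb(obs[[k]], -expm1(-b[k]), nu,
                  max(-expm1(-rtheta * b[k]), 1e-300), t_iu, TRUE)
    post[[k]] <- fb$posterior
    impfrac[k] <- fb$occ[2] / n_sites[k]
    ll <- ll + fb$loglik
  }
  trace <- c(trace, ll)

  pb <- data.frame(branch = names(obs), b = unname(b), n_sites = n_sites,
                   n_mismatch = n_mm, imported_fraction = impfrac,
                   row.names = NULL)
  if (!is.null(lens)) pb$tree_length <- unname(lens[pb$branch])
  structure(list(r_over_theta = rtheta, delta = delta, nu = nu,
                 r_over_m = compute_r_over_m(rtheta, delta, nu),
                 per_branch = pb, loglik = ll, loglik_trace = trace,
                 converged = converged, iterations = length(trace) - 1L,
                 posteriors = post, maps = maps, obs = obs,
                 n_columns = length(tracks[[1]]), flags = character(0)),
            class = "recomb_fit")
}

#' @export
print.recomb_fit <- function(x, ...) {
  cat(sprintf("<recomb_fit> R/theta = %.4g, delta = %.4g, nu = %.4g, r/m = %.4g\n",
              x$r_over_theta, x$delta, x$nu, x$r_over_m))
  cat(sprintf("  %d branches, loglik %.2f, %s after %d EM iterations\n",
              nrow(x$per_branch), x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Decode import segments from a fitted HMM
#'
#' Maximal runs of sites whose posterior import probability exceeds the
#' threshold become segments; runs are reported in alignment coordinates, so
#' missing sites interior to a run are spanned (merged across).
#'
#' @param fit a `recomb_fit`.
#' @param threshold posterior probability cutoff (default 0.5).
#' @param method `"posterior"` (default; enables mean-posterior reporting)
#'   or `"viterbi"` (MAP state path).
#' @return data.frame with columns `branch`, `start`, `end` (1-based,
#'   inclusive, alignment coordinates), `posterior` (mean import probability
#'   across the run; 1 for viterbi), `n_mismatch`; segments per branch are
#'   sorted and non-overlapping.
#' @export
decode_imports <- function(fit, threshold = 0.5,
                           method = c("posterior", "viterbi")) {
  method <- match.arg(method)
  out <- list()
  for (k in seq_along(fit$posteriors)) {
    br <- names(fit$posteriors)[k]
    map <- fit$maps[[k]]
    if (method == "posterior") {
      flag <- fit$posteriors[[k]] > threshold
      score <- fit$posteriors[[k]]
    } else {
      b <- fit$per_branch$b[k]
      flag <- as.logical(.hmm_viterbi(
        fit$obs[[k]], -expm1(-b), fit$nu,
        max(-expm1(-fit$r_over_theta * b), 1e-300),
        min(1 / fit$delta, 1 - 1e-12)))
      score <- as.numeric(flag)
    }
    if (!any(flag)) next
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    ri <- which(r$values)
    seg <- data.frame(
      branch = br,
      start = map[starts[ri]], end = map[ends[ri]],
      posterior = vapply(ri, function(i)
        mean(score[starts[i]:ends[i]]), 0),
      n_mismatch = vapply(ri, function(i)
        sum(fit$obs[[k]][starts[i]:ends[i]]), 0))
    out[[br]] <- seg
  }
  if (length(out) == 0)
    return(data.frame(branch = character(), start = integer(),
                      end = integer(), posterior = numeric(),
                      n_mismatch = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$branch, res$start), ]
}

#' Estimate recombination parameters from an alignment and genealogy
#'
#' Convenience pipeline: reconstruct ancestors, build mismatch tracks, fit
#' the HMM.
#'
#' @param alignment character matrix, rows = taxa.
#' @param genealogy rooted `phylo`; built with [nj_tree()] on JC distances
#'   when `NULL`.
#' @param ... passed to [fit_recombination_hmm()].
#' @return a `recomb_fit` with the genealogy attached as `$tree`.
#' @export
estimate_recombination <- function(alignment, genealogy = NULL, ...) {
  if (is.null(genealogy))
    genealogy <- nj_tree(core_distances(alignment))
  anc <- reconstruct_ancestors(genealogy, alignment)
  fit <- fit_recombination_hmm(mismatch_tracks(genealogy, alignment, anc), ...)
  fit$tree <- genealogy
  fit
}

#' Independent recombination estimates per taxon group
#'
#' Fits the HMM separately on each group's induced sub-alignment and subtree
#' (rebuilt by NJ on the sub-alignment, mirroring separate per-group runs).
#'
#' @param alignment character matrix, rows = taxa.
#' @param grouping named character vector mapping taxon -> group label.
#' @param ... passed to [fit_recombination_hmm()].
#' @return named list of `recomb_fit` objects, with a `summary` attribute:
#'   a data.frame of group, n, R/theta, delta, nu and r/m.
#' @export
group_recombination <- function(alignment, grouping, ...) {
  grouping <- grouping[rownames(alignment)]
  fits <- list()
  for (g in unique(grouping)) {
    taxa <- names(grouping)[grouping == g]
    if (length(taxa) < 2) stop("group '", g, "' has fewer than 2 taxa")
    fits[[g]] <- estimate_recombination(alignment[taxa, , drop = FALSE], ...)
  }
  attr(fits, "summary") <- data.frame(
    group = names(fits),
    n = as.integer(table(grouping)[names(fits)]),
    r_over_theta = vapply(fits, `[[`, 0, "r_over_theta"),
    delta = vapply(fits, `[[`, 0, "delta"),
    nu = vapply(fits, `[[`, 0, "nu"),
    r_over_m = vapply(fits, `[[`, 0, "r_over_m"),
    row.names = NULL)
  fits
}
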