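# The statistical comparisons used throughout: Welch t test, permutation
# ANOSIM, ordinary least squares. Thin wrappers over the standard
# implementations, returning uniform result objects.

#' Welch two-sided t test
#'
#' @param a,b numeric samples (each n >= 2).
#' @param labels optional two group labels for reporting.
#' @return list of class `group_comparison`: labels, means, sds, `statistic`
#'   (t), `df` (Satterthwaite), `p_value`, `test`. When both samples are
#'   constant with equal means the convention p = 1, t = 0 applies.
#' @export
welch_t_test <- function(a, b, labels = c("a", "b")) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  res <- tryCatch(t.test(a, b, var.equal = FALSE),
                  error = function(e) NULL)
  if (is.null(res)) {   # zero variance in both samples
    same <- isTRUE(all.equal(mean(a), mean(b)))
    res <- list(statistic = if (same) 0 else Inf,
                parameter = length(a) + length(b) - 2,
                p.value = if (same) 1 else 0)
  }
  structure(list(labels = labels, means = c(mean(a), mean(b)),
                 sds = c(sd(a), sd(b)),
                 statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = res$p.value,
                 test = "Welch two-sided t test"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (!is.null(x$means)) {
    cat(sprintf("%s: %s %.4g (sd %.3g) vs %s %.4g (sd %.3g); t = %.4g, df = %.3g, p = %.3g\n",
                x$test, x$labels[1], x$means[1], x$sds[1],
                x$labels[2], x$means[2], x$sds[2],
                x$statistic, x$df, x$p_value))
  } else {
    cat(sprintf("%s: statistic = %.4g, p = %.3g\n",
                x$test, x$statistic, x$p_value))
  }
  invisible(x)
}

#' Analysis of similarity (ANOSIM)
#'
#' Clarke's R on a distance matrix with a permutation p-value (fraction of
#' permuted statistics >= observed, with the +1 correction), so the minimum
#' attainable p with 999 permutations is 1/1000.
#'
#' @param d distance matrix (or `dist`).
#' @param grouping group label per object (>= 2 groups, each n >= 2).
#' @param n_permutations number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return list of class `group_comparison`: `statistic` (R), `p_value`,
#'   `n_permutations`.
#' @export
anosim_test <- function(d, grouping, n_permutations = 999, seed = 1) {
  grouping <- as.factor(grouping)
  if (nlevels(grouping) < 2 || any(table(grouping) < 2))
    stop("ANOSIM needs >= 2 groups with >= 2 members each")
  set.seed(seed)
  res <- vegan::anosim(as.dist(as.matrix(d)), grouping,
                       permutations = n_permutations)
  structure(list(labels = levels(grouping),
                 statistic = unname(res$statistic),
                 p_value = res$signif,
                 n_permutations = n_permutations,
                 test = "ANOSIM"),
            class = "group_comparison")
}

#' Jaccard distance on a presence/absence matrix
#'
#' Convenience for composition comparisons (e.g. pseudogene complements):
#' rows are objects, columns are features.
#'
#' @param m logical or 0/1 matrix.
#' @param method `"jaccard"` (default) or `"bray"` (Bray-Curtis on counts).
#' @return a `dist`.
#' @export
presence_distance <- function(m, method = c("jaccard", "bray")) {
  method <- match.arg(method)
  if (method == "jaccard")
    vegan::vegdist(m > 0, method = "jaccard")
  else
    vegan::vegdist(m, method = "bray")
}

#' Ordinary least squares with Pearson correlation
#'
#' @param x,y paired observations (n >= 3).
#' @return list of class `ols_fit`: `slope`, `intercept`, `r`, `p`
#'   (two-sided on the slope), `n`, `flags` (`"too_few_points"`,
#'   `"constant_x"` mark degenerate fits with NA results).
#' @export
ols_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r = NA_real_, p = NA_real_, n = n,
                          flags = "too_few_points"), class = "ols_fit"))
  if (sd(x) == 0)
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r = NA_real_, p = NA_real_, n = n,
                          flags = "constant_x"), class = "ols_fit"))
  fit <- lm(y ~ x)
  # summary.lm warns on exactly collinear input; the fit itself is valid
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = cor(x, y),
                 p = if (nrow(sm) > 1) sm[2, 4] else NA_real_,
                 n = n, flags = character(0)),
            class = "ols_fit")
}
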