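## Community statistics: Bray-Curtis dissimilarity, ANOSIM and Mantel
## permutation tests (vegan backends, seeded), one-way ANOVA with
## unadjusted pairwise LSD comparisons and a compact letter display, and
## the genus-overlap (Venn) partition between treatments.

## run code under a temporary RNG state
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d(x, y) = \sum |x_i - y_i| / \sum (x_i + y_i)} over genus
#' abundances; 0 for identical samples, 1 for disjoint supports.
#'
#' @param object a \linkS4class{NemaExperiment} or a samples-by-variables
#'   numeric matrix.
#' @return a \code{dist} over samples.
#' @export
brayCurtis <- function(object) {
  m <- if (is(object, "NemaExperiment")) t(abundance(object)) else
    as.matrix(object)
  if (nrow(m) < 2L) stop("at least two samples are required")
  zero <- rowSums(m) == 0
  if (any(zero))
    stop("Bray-Curtis undefined for all-zero sample(s): ",
         paste(rownames(m)[zero], collapse = ", "))
  vegan::vegdist(m, method = "bray")
}

#' Euclidean distance on log(x+1) abundances
#'
#' Alternative community distance for ANOSIM/ordination.
#'
#' @inheritParams brayCurtis
#' @return a \code{dist} over samples.
#' @export
euclideanLog <- function(object) {
  m <- if (is(object, "NemaExperiment")) t(abundance(object)) else
    as.matrix(object)
  stats::dist(log1p(m))
}

#' ANOSIM statistic R
#'
#' \eqn{R = (\bar r_B - \bar r_W) / (M/2)} with \eqn{M = n(n-1)/2}
#' dissimilarities ranked jointly; \eqn{\bar r_B} and \eqn{\bar r_W} are
#' the mean ranks of between- and within-group dissimilarities.
#'
#' @param d a \code{dist} over samples.
#' @param groups group labels, one per sample.
#' @return the statistic, in [-1, 1].
#' @export
anosimStatistic <- function(d, groups) {
  d <- as.dist(d)
  n <- attr(d, "Size")
  stopifnot(length(groups) == n)
  rk <- rank(as.vector(d))
  same <- as.vector(as.dist(outer(groups, groups, "=="))) > 0
  (mean(rk[!same]) - mean(rk[same])) / (n * (n - 1) / 4)
}

.checkGrouping <- function(groups) {
  tab <- table(groups)
  if (length(tab) < 2L)
    stop("at least two groups are required")
  if (any(tab < 2L))
    stop("degenerate grouping: group(s) with fewer than 2 members: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
}

#' ANOSIM permutation test
#'
#' Seeded wrapper around \code{vegan::\link[vegan]{anosim}}. R > 0
#' indicates larger between- than within-group dissimilarity; the p-value
#' uses the add-one permutation estimator
#' \eqn{p = (1 + \#\{R^* \ge R\}) / (n_{perm} + 1)}.
#'
#' @param d a \code{dist} over samples.
#' @param groups group labels, one per sample; every group needs at least
#'   two members.
#' @param nPerm number of label permutations.
#' @param seed integer seed making the permutations reproducible.
#' @return list with \code{statistic} (R), \code{p.value} and
#'   \code{permutations}.
#' @export
anosimTest <- function(d, groups, nPerm = 999, seed = 1) {
  .checkGrouping(groups)
  fit <- .withSeed(seed,
                   vegan::anosim(as.dist(d), grouping = factor(groups),
                                 permutations = nPerm))
  list(statistic = unname(fit$statistic), p.value = fit$signif,
       permutations = nPerm)
}

#' Mantel permutation test between two distance matrices
#'
#' Seeded wrapper around \code{vegan::\link[vegan]{mantel}} (simple
#' Mantel; product-moment correlation by default, rank correlation
#' optional).
#'
#' @param d1,d2 \code{dist} objects over the same samples in the same
#'   order.
#' @param nPerm number of row/column permutations.
#' @param seed integer seed.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return list with \code{statistic} (r), \code{p.value} and
#'   \code{permutations}.
#' @export
mantelTest <- function(d1, d2, nPerm = 999, seed = 1,
                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  d1 <- as.dist(d1); d2 <- as.dist(d2)
  if (attr(d1, "Size") != attr(d2, "Size"))
    stop("distance matrices must cover the same samples")
  fit <- .withSeed(seed,
                   vegan::mantel(d1, d2, method = method,
                                 permutations = nPerm))
  list(statistic = unname(fit$statistic), p.value = fit$signif,
       permutations = nPerm)
}

#' One-way ANOVA with pairwise LSD comparisons and letter display
#'
#' Fisher's least-significant-difference procedure: a one-way ANOVA
#' provides the pooled error mean square; every group pair is compared
#' with an unadjusted t test on that pooled variance; groups sharing a
#' letter are not significantly different at \code{alpha}.
#'
#' @param values numeric response, one value per sample.
#' @param groups group labels; at least two groups with two replicates
#'   each.
#' @param alpha significance level of the pairwise tests.
#' @return list with \code{means} (named, sorted decreasing),
#'   \code{f_value}, \code{p_value}, \code{pairwise} (matrix of LSD
#'   p-values) and \code{letters} (named compact letter display).
#' @export
anovaLSD <- function(values, groups, alpha = 0.05) {
  ok <- !is.na(values)
  values <- values[ok]; groups <- as.character(groups)[ok]
  .checkGrouping(groups)
  fit <- stats::aov(values ~ factor(groups))
  an <- summary(fit)[[1L]]
  mse <- an["Residuals", "Mean Sq"]
  dfe <- an["Residuals", "Df"]
  if (!is.finite(mse) || mse <= 1e-12 * (abs(mean(values)) + 1)^2 *
        .Machine$double.eps)
    stop("zero within-group variance everywhere; LSD undefined")
  means <- sort(tapply(values, groups, mean), decreasing = TRUE)
  ns <- tapply(values, groups, length)[names(means)]
  k <- length(means)
  pmat <- matrix(NA_real_, k, k, dimnames = list(names(means), names(means)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    tstat <- (means[i] - means[j]) / se
    pmat[i, j] <- pmat[j, i] <- 2 * stats::pt(-abs(tstat), dfe)
  }
  list(means = means,
       f_value = an[1L, "F value"], p_value = an[1L, "Pr(>F)"],
       pairwise = pmat,
       letters = .letterDisplay(pmat, alpha))
}

## compact letter display: letters = maximal cliques of the
## "not significantly different" graph, ordered by the best group mean
## (rows of `pmat` are already mean-ordered). Two groups share a letter
## iff their pairwise p exceeds alpha.
.letterDisplay <- function(pmat, alpha) {
  k <- nrow(pmat)
  nsd <- !is.na(pmat) & pmat > alpha
  diag(nsd) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(nsd, mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g)
  first <- vapply(cliques, min, numeric(1))
  cliques <- cliques[order(first)]
  out <- stats::setNames(rep("", k), rownames(pmat))
  for (ci in seq_along(cliques)) {
    idx <- as.integer(cliques[[ci]])
    out[idx] <- paste0(out[idx], letters[ci])
  }
  out
}

#' Genus-overlap partition between treatments
#'
#' A genus is present in a treatment when its summed abundance over that
#' treatment's samples is positive. Returns the Venn partition of the
#' genus set over all presence signatures.
#'
#' @param object a \linkS4class{NemaExperiment}.
#' @return list with \code{membership} (genus-by-treatment logical
#'   matrix), \code{counts} (named integer vector over presence
#'   signatures such as \code{"CK&NM"}), \code{shared_all} (genera present
#'   in every treatment) and \code{unique} (named count of genera unique
#'   to each treatment).
#' @export
vennPartition <- function(object) {
  a <- abundance(object)
  tr <- treatments(object)
  lev <- unique(tr)
  pres <- vapply(lev, function(t)
    rowSums(a[, tr == t, drop = FALSE]) > 0, logical(nrow(a)))
  if (is.null(dim(pres)))
    pres <- matrix(pres, nrow = nrow(a), dimnames = list(rownames(a), lev))
  sig <- apply(pres, 1L, function(z)
    if (!any(z)) "absent" else paste(lev[z], collapse = "&"))
  counts <- table(sig)
  uniq <- vapply(lev, function(t)
    sum(sig == t), integer(1))
  list(membership = pres,
       counts = stats::setNames(as.integer(counts), names(counts)),
       shared_all = rownames(a)[rowSums(pres) == length(lev)],
       unique = uniq)
}
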