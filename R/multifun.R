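## Ecosystem multifunctionality.
##
## Each of the (by default 15) C/N/P function indicators is min-max
## standardized across all samples: f_ij = (x_ij - min_j) / (max_j - min_j).
## EF-C, EF-N, EF-P are the per-sample means of the standardized indicators
## of one category; EMF is the per-sample mean over all indicators, so
## N_total * EMF = sum over categories of n_cat * EF_cat holds exactly.
## Driver columns (soil water content, pH) never enter the scores.

#' Min-max standardize soil function indicators
#'
#' Standardizes every non-driver indicator across all samples of the
#' dataset (not per treatment, so scores stay comparable between
#' treatments). The column minimum maps to 0 and the maximum to 1; a
#' constant indicator maps to 0.5 everywhere with a warning. Missing
#' values are an error (no imputation).
#'
#' @param object a \linkS4class{SoilIndicators} with at least two samples.
#' @return indicator-by-sample matrix of standardized values in [0, 1]
#'   (EMF indicators only).
#' @export
standardizeIndicators <- function(object) {
  v <- assay(object, "value")
  if (ncol(v) < 2L) stop("standardization needs at least two samples")
  if (anyNA(v)) {
    bad <- which(is.na(v), arr.ind = TRUE)
    stop("missing value(s) at ",
         paste(sprintf("(%s, %s)", rownames(v)[bad[, 1L]],
                       colnames(v)[bad[, 2L]]), collapse = ", "))
  }
  keep <- rowData(object)$category != "driver"
  v <- v[keep, , drop = FALSE]
  rng <- apply(v, 1L, range)
  const <- rng[1L, ] == rng[2L, ]
  if (any(const))
    warning("constant indicator(s) mapped to 0.5: ",
            paste(rownames(v)[const], collapse = ", "))
  f <- (v - rng[1L, ]) / (rng[2L, ] - rng[1L, ])
  f[const, ] <- 0.5
  f
}

#' Per-sample single-function scores (EF-C, EF-N, EF-P)
#'
#' @param fij standardized indicator-by-sample matrix from
#'   \code{\link{standardizeIndicators}}.
#' @param categories named character vector mapping each row of \code{fij}
#'   to its category (\code{"C"}, \code{"N"} or \code{"P"}).
#' @return category-by-sample matrix of per-category means.
#' @export
efScores <- function(fij, categories) {
  categories <- categories[rownames(fij)]
  if (anyNA(categories))
    stop("no category for indicator(s): ",
         paste(rownames(fij)[is.na(categories)], collapse = ", "))
  cats <- sort(unique(categories))
  out <- matrix(NA_real_, length(cats), ncol(fij),
                dimnames = list(cats, colnames(fij)))
  for (k in cats) {
    rows <- which(categories == k)
    if (!length(rows)) stop("empty category: ", k)
    out[k, ] <- colMeans(fij[rows, , drop = FALSE])
  }
  out
}

#' Per-sample ecosystem multifunctionality (mean method)
#'
#' @param fij standardized indicator-by-sample matrix.
#' @return named numeric vector, the unweighted mean over all indicators
#'   per sample.
#' @export
emfScore <- function(fij) {
  if (nrow(fij) < 1L) stop("at least one indicator is required")
  colMeans(fij)
}

#' Full function-score table for a soil indicator dataset
#'
#' @param object a \linkS4class{SoilIndicators}.
#' @return list with \code{fij} (standardized matrix), \code{ef}
#'   (category-by-sample means), \code{emf} (per-sample vector), \code{n}
#'   (indicator count per category) and \code{table} (per-sample
#'   data.frame with \code{ef_C}, \code{ef_N}, \code{ef_P}, \code{emf}).
#' @export
functionScores <- function(object) {
  fij <- standardizeIndicators(object)
  categories <- stats::setNames(rowData(object)$category, rownames(object))
  ef <- efScores(fij, categories)
  emf <- emfScore(fij)
  tab <- data.frame(sample = colnames(fij), t(ef), emf = emf,
                    row.names = colnames(fij), check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(tab)[2:(1 + nrow(ef))] <- paste0("ef_", rownames(ef))
  tr <- treatments(object)
  if (!is.null(tr)) tab$treatment <- unname(tr[tab$sample])
  list(fij = fij, ef = ef, emf = emf,
       n = table(categories[rownames(fij)]), table = tab)
}

#' Per-treatment means and LSD letters for EF and EMF scores
#'
#' Runs a one-way ANOVA with pairwise LSD comparisons
#' (\code{\link{anovaLSD}}) on each score column.
#'
#' @param scores result of \code{\link{functionScores}}.
#' @param treatments per-sample treatment labels (taken from the scores
#'   table when present).
#' @param alpha significance level for the letter display.
#' @return data.frame with one row per treatment-by-score combination:
#'   \code{score}, \code{treatment}, \code{mean}, \code{letter},
#'   \code{f_value}, \code{p_value}.
#' @export
treatmentFunctionSummary <- function(scores, treatments = NULL,
                                     alpha = 0.05) {
  tab <- scores$table
  if (is.null(treatments)) treatments <- tab$treatment
  if (is.null(treatments)) stop("treatment labels are required")
  cols <- setdiff(colnames(tab)[vapply(tab, is.numeric, logical(1))], "sample")
  out <- lapply(cols, function(cn) {
    fit <- anovaLSD(tab[[cn]], treatments, alpha = alpha)
    data.frame(score = cn, treatment = names(fit$means),
               mean = unname(fit$means),
               letter = unname(fit$letters[names(fit$means)]),
               f_value = fit$f_value, p_value = fit$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
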