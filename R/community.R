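## Relative abundances, abundance classes, trait-based aggregation, and
## whole-survey summary for a community experiment.

#' Classify relative abundances into dominance classes
#'
#' Dominant genera have relative abundance strictly above 10\%, common
#' genera lie in the closed band 1--10\%, rare genera below 1\%.
#'
#' @param p numeric vector of proportions in [0, 1].
#' @return factor with levels \code{dominant}, \code{common}, \code{rare}.
#' @examples
#' classifyAbundance(c(0.1075, 0.10, 0.005))  # dominant, common, rare
#' @export
classifyAbundance <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("proportions must lie in [0, 1]")
  factor(ifelse(p > 0.10, "dominant", ifelse(p >= 0.01, "common", "rare")),
         levels = c("dominant", "common", "rare"))
}

#' Per-sample relative abundances, group shares, and dominance classes
#'
#' @param object a \linkS4class{NemaExperiment} with traits attached (the
#'   trait registry is needed for trophic-group shares; pass
#'   \code{groupShare = FALSE} to skip them).
#' @param groupShare compute per-trophic-group shares (requires traits).
#' @return list with \code{pi} (genus-by-sample share matrix),
#'   \code{class} (genus-by-sample dominance class matrix) and, when
#'   requested, \code{group_share} (trophic-group-by-sample share matrix).
#' @export
relativeAbundance <- function(object, groupShare = !is.null(traits(object))) {
  a <- abundance(object)
  tot <- colSums(a)
  if (any(tot == 0))
    stop("relative abundance undefined for all-zero sample(s): ",
         paste(colnames(a)[tot == 0], collapse = ", "))
  pi <- sweep(a, 2L, tot, "/")
  cls <- matrix(as.character(classifyAbundance(as.vector(pi))),
                nrow = nrow(pi), dimnames = dimnames(pi))
  out <- list(pi = pi, class = cls)
  if (groupShare) {
    g <- aggregateAbundance(object, by = "trophic")
    out$group_share <- sweep(g, 2L, tot, "/")
  }
  out
}

#' Aggregate abundances by trophic group or c-p band
#'
#' Sums genus abundances per sample either over the four trophic groups
#' (\code{BF}, \code{FF}, \code{PP}, \code{OP}) or over the colonizer
#' (c-p 1--2) and persister (c-p 3--5) bands. Groups with no member genus
#' yield a zero row; group sums always equal the sample total.
#'
#' @param object a \linkS4class{NemaExperiment} with traits attached.
#' @param by \code{"trophic"} or \code{"cp_band"}.
#' @return group-by-sample abundance matrix.
#' @export
aggregateAbundance <- function(object, by = c("trophic", "cp_band")) {
  by <- match.arg(by)
  tr <- .requireTraits(object)
  a <- abundance(object)
  if (by == "trophic") {
    keys <- factor(tr$trophic_group, levels = TROPHIC_GROUPS)
  } else {
    keys <- factor(ifelse(tr$cp_value <= 2, "cp1-2", "cp3-5"),
                   levels = c("cp1-2", "cp3-5"))
  }
  out <- rowsum(a, keys)                  # drops absent levels
  full <- matrix(0, nrow = nlevels(keys), ncol = ncol(a),
                 dimnames = list(levels(keys), colnames(a)))
  full[rownames(out), ] <- out
  full
}

#' Survey-level abundance summary
#'
#' @param object a \linkS4class{NemaExperiment}.
#' @return list with \code{total} (individuals over all samples),
#'   \code{n_samples}, and \code{mean_density} (individuals per 100 g dry
#'   soil, total / sample count).
#' @examples
#' # 29,280 individuals over 16 composite samples -> 1830 per 100 g
#' @export
summarizeCommunity <- function(object) {
  a <- abundance(object)
  list(total = sum(a), n_samples = ncol(a),
       mean_density = sum(a) / ncol(a))
}
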