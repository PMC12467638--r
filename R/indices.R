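## The eight per-sample ecological/functional indices.
##
## H'  = -sum pi ln pi          Shannon-Wiener diversity (nats)
## lam = sum pi^2               Simpson dominance
## TD  = 1 / sum p'_g^2         trophic diversity over group shares
## SR  = (S - 1) / ln N         Margalef richness
## MI  = sum v_i f_i            c-p-weighted mean over free-living taxa
## PPI = sum v_i f'_i           c-p-weighted mean over plant parasites
## NCR = BF / (BF + FF)         channel ratio; > 0.75 = bacterial pathway
## WI  = (BF + FF) / PP         Wasilewska index; > 1 = healthy food web
##
## Undefined values (SR at N <= 1, MI with no free-living individuals, PPI
## with no plant parasites, NCR with BF+FF = 0, WI with PP = 0) are carried
## as NA and listed in the 'undefined' column, never coerced to zero.

.freeLiving <- c("BF", "FF", "OP")

#' Diversity indices of one sample
#'
#' @param x named non-negative abundance vector (one sample); zero-abundance
#'   genera are excluded from S and from the share sums.
#' @param traits a \linkS4class{NemaTraits} covering the named genera
#'   (needed for trophic diversity; may be \code{NULL} if \code{tdLevel}
#'   is \code{"taxon"}).
#' @param tdLevel compute trophic diversity over the four trophic-group
#'   shares (\code{"group"}, default: four equal groups give TD = 4) or
#'   over taxon shares (\code{"taxon"}: TD = 1/lambda).
#' @return named numeric vector \code{c(shannon, lambda, td, sr)}; \code{sr}
#'   is \code{NA} when \eqn{N \le 1}.
#' @export
diversityIndices <- function(x, traits = NULL, tdLevel = c("group", "taxon")) {
  tdLevel <- match.arg(tdLevel)
  stopifnot(all(x >= 0))
  x <- x[x > 0]
  N <- sum(x)
  if (N == 0) stop("sample total must be positive")
  S <- length(x)
  pi <- x / N
  h <- -sum(pi * log(pi))
  lam <- sum(pi^2)
  if (tdLevel == "group") {
    if (is.null(traits)) stop("traits required for group-level TD")
    g <- rowsum(as.numeric(x), traits[names(x), "trophic_group"])[, 1L]
    pg <- g / N
    td <- 1 / sum(pg^2)
  } else {
    td <- 1 / lam
  }
  sr <- if (N > 1) (S - 1) / log(N) else NA_real_
  c(shannon = h, lambda = lam, td = td, sr = sr)
}

#' Maturity and plant-parasite indices of one sample
#'
#' MI is the c-p-weighted mean over the free-living (BF/FF/OP)
#' sub-community, PPI over the plant-parasitic sub-community; shares are
#' taken within each sub-community so both indices lie in [1, 5]. An index
#' is \code{NA} when its sub-community is empty.
#'
#' @inheritParams diversityIndices
#' @return named numeric vector \code{c(mi, ppi)}.
#' @export
maturityIndices <- function(x, traits) {
  x <- x[x > 0]
  tg <- traits[names(x), "trophic_group"]
  cp <- traits[names(x), "cp_value"]
  wmean <- function(sel) {
    tot <- sum(x[sel])
    if (tot == 0) NA_real_ else sum(cp[sel] * x[sel]) / tot
  }
  c(mi = wmean(tg %in% .freeLiving), ppi = wmean(tg == "PP"))
}

#' Channel ratio, Wasilewska index, and their interpretation labels
#'
#' @inheritParams diversityIndices
#' @return list with \code{ncr}, \code{wi} (either may be \code{NA}),
#'   \code{pathway} (\code{"bacterial"} when NCR > 0.75, else
#'   \code{"fungal-leaning"}) and \code{health} (\code{"good"} when
#'   WI > 1, else \code{"poor"}).
#' @export
channelHealth <- function(x, traits) {
  tg <- traits[names(x), "trophic_group"]
  bf <- sum(x[tg == "BF"]); ff <- sum(x[tg == "FF"]); pp <- sum(x[tg == "PP"])
  ncr <- if (bf + ff > 0) bf / (bf + ff) else NA_real_
  wi <- if (pp > 0) (bf + ff) / pp else NA_real_
  list(ncr = ncr, wi = wi,
       pathway = if (is.na(ncr)) NA_character_ else
         if (ncr > 0.75) "bacterial" else "fungal-leaning",
       health = if (is.na(wi)) NA_character_ else
         if (wi > 1) "good" else "poor")
}

#' Per-sample index table
#'
#' Computes all eight indices for every sample of a community experiment.
#' Undefined entries are \code{NA}, named in the \code{undefined} column,
#' and reported once via \code{warning()}; they are never coerced to zero.
#'
#' @param object a \linkS4class{NemaExperiment} with traits attached.
#' @param tdLevel see \code{\link{diversityIndices}}.
#' @return \code{data.frame} with one row per sample and columns
#'   \code{sample}, \code{treatment}, \code{shannon}, \code{lambda},
#'   \code{td}, \code{sr}, \code{mi}, \code{ppi}, \code{ncr}, \code{wi},
#'   \code{pathway}, \code{health}, \code{undefined}.
#' @export
indexTable <- function(object, tdLevel = c("group", "taxon")) {
  tdLevel <- match.arg(tdLevel)
  tr <- .requireTraits(object)
  a <- abundance(object)
  rows <- lapply(seq_len(ncol(a)), function(j) {
    x <- a[, j]
    d <- diversityIndices(x, tr, tdLevel)
    m <- maturityIndices(x, tr)
    ch <- channelHealth(x, tr)
    vals <- c(d, m, ncr = ch$ncr, wi = ch$wi)
    undef <- names(vals)[is.na(vals)]
    data.frame(sample = colnames(a)[j],
               treatment = unname(treatments(object)[j]),
               t(vals), pathway = ch$pathway, health = ch$health,
               undefined = paste(undef, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$sample
  flagged <- out$sample[nzchar(out$undefined)]
  if (length(flagged))
    warning("undefined index value(s) in sample(s): ",
            paste(flagged, collapse = ", "),
            " (flagged NA, excluded from group means)")
  out
}

#' Per-treatment means of an index table
#'
#' Undefined (NA) entries are excluded from the means.
#'
#' @param indices result of \code{\link{indexTable}} (or any data.frame
#'   with a \code{treatment} column and numeric index columns).
#' @return data.frame of treatment means.
#' @export
indexMeans <- function(indices) {
  num <- vapply(indices, is.numeric, logical(1))
  agg <- stats::aggregate(indices[num], by = list(treatment = indices$treatment),
                          FUN = mean, na.rm = TRUE)
  agg
}
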