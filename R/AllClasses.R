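#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   rowData<- colData colData<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

TROPHIC_GROUPS <- c("BF", "FF", "PP", "OP")

#' Per-genus nematode trait registry
#'
#' A \linkS4class{DFrame} keyed by genus (rownames) with columns
#' \code{trophic_group} (one of \code{"BF"} bacterivore, \code{"FF"}
#' fungivore, \code{"PP"} plant parasite, \code{"OP"} omnivore/predator),
#' \code{cp_value} (colonizer-persister score, integer 1--5) and
#' \code{biomass} (fresh weight per individual, micrograms).
#'
#' @aliases NemaTraits-class
#' @exportClass NemaTraits
setClass("NemaTraits", contains = "DFrame")

setValidity("NemaTraits", function(object) {
  msgs <- character()
  req <- c("trophic_group", "cp_value", "biomass")
  if (!all(req %in% colnames(object)))
    return(paste("missing column(s):",
                 paste(setdiff(req, colnames(object)), collapse = ", ")))
  if (is.null(rownames(object)))
    msgs <- c(msgs, "genus names (rownames) are required")
  else if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, paste("duplicate genus:",
                          paste(unique(rownames(object)[duplicated(rownames(object))]),
                                collapse = ", ")))
  tg <- object$trophic_group
  if (!all(tg %in% TROPHIC_GROUPS))
    msgs <- c(msgs, paste("unknown trophic_group code(s):",
                          paste(unique(tg[!tg %in% TROPHIC_GROUPS]), collapse = ", ")))
  cp <- object$cp_value
  if (!all(cp %in% 1:5))
    msgs <- c(msgs, paste("cp_value outside 1-5 for genus:",
                          paste(rownames(object)[!cp %in% 1:5], collapse = ", ")))
  w <- object$biomass
  if (!is.numeric(w) || any(!is.finite(w)) || any(w <= 0))
    msgs <- c(msgs, "biomass must be finite and > 0 for every genus")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a trait registry
#'
#' @param genus character vector of genus names (unique).
#' @param trophic_group character vector, one of \code{"BF"}, \code{"FF"},
#'   \code{"PP"}, \code{"OP"} per genus.
#' @param cp_value integer vector of colonizer-persister scores in 1--5.
#' @param biomass numeric vector of per-individual fresh weights
#'   (micrograms), strictly positive.
#' @return A \linkS4class{NemaTraits} object.
#' @examples
#' NemaTraits(genus = c("Filenchus", "Cephalobus"),
#'            trophic_group = c("FF", "BF"),
#'            cp_value = c(2L, 2L), biomass = c(0.4, 0.65))
#' @export
NemaTraits <- function(genus, trophic_group, cp_value, biomass) {
  df <- DataFrame(trophic_group = as.character(trophic_group),
                  cp_value = as.integer(cp_value),
                  biomass = as.numeric(biomass),
                  row.names = as.character(genus))
  new("NemaTraits", df)
}

#' Genus-by-sample nematode community container
#'
#' Extends \linkS4class{SummarizedExperiment}: the \code{"abundance"} assay
#' holds non-negative genus-by-sample counts (individuals per 100 g dry
#' soil), \code{colData} carries the \code{treatment} label of each sample,
#' and \code{rowData} carries the per-genus traits once
#' \code{\link{attachTraits}} has been called.
#'
#' @aliases NemaExperiment-class
#' @exportClass NemaExperiment
setClass("NemaExperiment", contains = "SummarizedExperiment")

setValidity("NemaExperiment", function(object) {
  msgs <- character()
  if (!"abundance" %in% names(assays(object)))
    return("an 'abundance' assay is required")
  a <- assay(object, "abundance")
  if (nrow(a) < 1L || ncol(a) < 1L)
    msgs <- c(msgs, "at least one genus and one sample are required")
  if (is.null(rownames(a)) || is.null(colnames(a)))
    msgs <- c(msgs, "genus rownames and sample colnames are required")
  else {
    if (anyDuplicated(rownames(a)))
      msgs <- c(msgs, paste("duplicate genus:",
                            paste(unique(rownames(a)[duplicated(rownames(a))]),
                                  collapse = ", ")))
    if (anyDuplicated(colnames(a)))
      msgs <- c(msgs, "duplicate sample names")
  }
  if (any(!is.finite(a)))
    msgs <- c(msgs, "abundances must be finite and non-missing")
  else if (any(a < 0)) {
    bad <- which(a < 0, arr.ind = TRUE)[1L, ]
    msgs <- c(msgs, sprintf("negative abundance at genus '%s', sample '%s'",
                            rownames(a)[bad[1L]], colnames(a)[bad[2L]]))
  }
  if (!"treatment" %in% colnames(colData(object)))
    msgs <- c(msgs, "colData must contain a 'treatment' column")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a community experiment
#'
#' @param abundance numeric matrix, genera as rows and samples as columns,
#'   non-negative entries. Non-integer densities are allowed.
#' @param treatment character vector of per-sample treatment labels (any
#'   label set; \code{CK}/\code{NM}/\code{PM}/\code{LM} is the default field
#'   design but not a closed set).
#' @param traits optional \linkS4class{NemaTraits}; attached to
#'   \code{rowData} and checked for full genus coverage.
#' @param basis the soil mass basis of the counts in grams; abundances are
#'   rescaled to the canonical 100 g dry-soil basis.
#' @return A \linkS4class{NemaExperiment}.
#' @examples
#' a <- matrix(c(5, 3, 2, 4, 4, 2), nrow = 3,
#'             dimnames = list(c("Ga", "Gb", "Gc"), c("S1", "S2")))
#' NemaExperiment(a, treatment = c("CK", "NM"))
#' @export
NemaExperiment <- function(abundance, treatment, traits = NULL, basis = 100) {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (!is.numeric(basis) || length(basis) != 1L || basis <= 0)
    stop("'basis' must be a single positive mass in grams")
  if (basis != 100) abundance <- abundance * (100 / basis)
  if (length(treatment) != ncol(abundance))
    stop("'treatment' must have one label per sample")
  obj <- SummarizedExperiment(
    assays = list(abundance = abundance),
    colData = DataFrame(treatment = as.character(treatment),
                        row.names = colnames(abundance)))
  obj <- new("NemaExperiment", obj)
  validObject(obj)
  if (!is.null(traits)) obj <- attachTraits(obj, traits)
  obj
}

#' Sample-by-indicator soil function container
#'
#' Extends \linkS4class{SummarizedExperiment} with indicators as rows and
#' samples as columns (assay \code{"value"}). \code{rowData$category}
#' assigns each indicator to \code{"C"}, \code{"N"}, \code{"P"} (the
#' ecosystem-function categories entering EMF) or \code{"driver"}
#' (covariates such as soil water content and pH, excluded from EMF).
#'
#' @aliases SoilIndicators-class
#' @exportClass SoilIndicators
setClass("SoilIndicators", contains = "SummarizedExperiment")

setValidity("SoilIndicators", function(object) {
  msgs <- character()
  if (!"value" %in% names(assays(object)))
    return("a 'value' assay is required")
  if (!"category" %in% colnames(rowData(object)))
    return("rowData must contain a 'category' column")
  cat <- rowData(object)$category
  ok <- c("C", "N", "P", "driver")
  if (!all(cat %in% ok))
    msgs <- c(msgs, paste("unknown category:",
                          paste(unique(cat[!cat %in% ok]), collapse = ", ")))
  if (!any(cat %in% c("C", "N", "P")))
    msgs <- c(msgs, "at least one C/N/P function indicator is required")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a soil indicator container
#'
#' @param values numeric matrix of observed indicator values, either
#'   indicators-by-samples or samples-by-indicators (orientation is
#'   resolved against \code{names(categories)}).
#' @param categories named character vector mapping each indicator name to
#'   \code{"C"}, \code{"N"}, \code{"P"} or \code{"driver"}.
#' @param treatment optional per-sample treatment labels.
#' @return A \linkS4class{SoilIndicators}.
#' @export
SoilIndicators <- function(values, categories, treatment = NULL) {
  values <- as.matrix(values)
  if (!all(rownames(values) %in% names(categories)) &&
      all(colnames(values) %in% names(categories)))
    values <- t(values)
  missing_cat <- setdiff(rownames(values), names(categories))
  if (length(missing_cat))
    stop("no category declared for indicator(s): ",
         paste(missing_cat, collapse = ", "))
  cd <- DataFrame(row.names = colnames(values))
  if (!is.null(treatment)) cd$treatment <- as.character(treatment)
  obj <- SummarizedExperiment(
    assays = list(value = values),
    rowData = DataFrame(category = unname(categories[rownames(values)]),
                        row.names = rownames(values)),
    colData = cd)
  obj <- new("SoilIndicators", obj)
  validObject(obj)
  obj
}
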