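#' @describeIn NemaExperiment-class genus-by-sample abundance matrix
#'   (individuals per 100 g dry soil).
#' @param object a \linkS4class{NemaExperiment}.
#' @export
setGeneric("abundance", function(object) standardGeneric("abundance"))

#' @export
setMethod("abundance", "NemaExperiment",
          function(object) assay(object, "abundance"))

#' @describeIn NemaExperiment-class per-sample treatment labels.
#' @export
setGeneric("treatments", function(object) standardGeneric("treatments"))

#' @export
setMethod("treatments", "NemaExperiment", function(object) {
  stats::setNames(colData(object)$treatment, colnames(object))
})

#' @export
setMethod("treatments", "SoilIndicators", function(object) {
  if (!"treatment" %in% colnames(colData(object)))
    return(NULL)
  stats::setNames(colData(object)$treatment, colnames(object))
})

#' @describeIn NemaExperiment-class genus names.
#' @export
setGeneric("genera", function(object) standardGeneric("genera"))

#' @export
setMethod("genera", "NemaExperiment", function(object) rownames(object))

#' @describeIn NemaExperiment-class the attached trait registry
#'   (\code{NULL} when none is attached).
#' @export
setGeneric("traits", function(object) standardGeneric("traits"))

#' @export
setMethod("traits", "NemaExperiment", function(object) {
  rd <- rowData(object)
  if (!all(c("trophic_group", "cp_value", "biomass") %in% colnames(rd)))
    return(NULL)
  new("NemaTraits", rd[, c("trophic_group", "cp_value", "biomass")])
})

#' Attach a trait registry to a community experiment
#'
#' Checks that every genus of the community is resolvable in the registry
#' and stores the trait columns in \code{rowData}.
#'
#' @param object a \linkS4class{NemaExperiment}.
#' @param traits a \linkS4class{NemaTraits}.
#' @return The experiment with traits in \code{rowData}.
#' @export
attachTraits <- function(object, traits) {
  stopifnot(is(object, "NemaExperiment"), is(traits, "NemaTraits"))
  validObject(traits)
  missing_g <- setdiff(rownames(object), rownames(traits))
  if (length(missing_g))
    stop("genera missing from trait registry: ",
         paste(missing_g, collapse = ", "))
  rd <- rowData(object)
  tr <- traits[rownames(object), , drop = FALSE]
  rd$trophic_group <- tr$trophic_group
  rd$cp_value <- tr$cp_value
  rd$biomass <- tr$biomass
  rowData(object) <- rd
  object
}

.requireTraits <- function(object) {
  tr <- traits(object)
  if (is.null(tr))
    stop("no trait registry attached; call attachTraits() first")
  tr
}

setMethod("show", "NemaExperiment", function(object) {
  tl <- table(treatments(object))
  cat(sprintf("NemaExperiment: %d genera x %d samples (per 100 g dry soil)\n",
              nrow(object), ncol(object)))
  cat("treatments:",
      paste(sprintf("%s(%d)", names(tl), tl), collapse = " "), "\n")
  cat("traits attached:", !is.null(traits(object)), "\n")
})

setMethod("show", "SoilIndicators", function(object) {
  ct <- table(rowData(object)$category)
  cat(sprintf("SoilIndicators: %d indicators x %d samples [%s]\n",
              nrow(object), ncol(object),
              paste(sprintf("%s:%d", names(ct), ct), collapse = " ")))
})
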