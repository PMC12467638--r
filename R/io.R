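## Table I/O. Community tables are genera-as-rows TSV/CSV with a "genus"
## first column; treatments travel either as a "#treatment" second line or
## as a two-column (sample, treatment) sidecar.

.sepFor <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a genus-by-sample community table
#'
#' The file has a header of sample IDs, a first column named \code{genus},
#' and a numeric body. Treatment labels are taken (in this priority) from
#' the \code{treatments} argument (a named character vector or the path of
#' a two-column \code{sample<TAB>treatment} sidecar file), or from an
#' optional second line of the form \code{#treatment<sep>CK<sep>NM...}.
#'
#' @param path path of the TSV/CSV file.
#' @param sep field separator; inferred from the extension when \code{NULL}.
#' @param treatments named character vector, sidecar file path, or
#'   \code{NULL}.
#' @param basis soil-mass basis in grams of the stored counts (rescaled to
#'   100 g).
#' @return A \linkS4class{NemaExperiment}.
#' @export
readCommunityMatrix <- function(path, sep = NULL, treatments = NULL,
                                basis = 100) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sepFor(path, sep)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("community table needs a header and a body")
  tr_row <- NULL
  if (startsWith(lines[2L], "#treatment")) {
    tr_row <- strsplit(lines[2L], sep, fixed = TRUE)[[1L]][-1L]
    lines <- lines[-2L]
  }
  tab <- utils::read.table(text = lines, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  if (tolower(colnames(tab)[1L]) != "genus")
    stop("first column must be named 'genus', got '", colnames(tab)[1L], "'")
  genus <- tab[[1L]]
  if (anyDuplicated(genus))
    stop("duplicate genus name(s): ",
         paste(unique(genus[duplicated(genus)]), collapse = ", "))
  body <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(genus, colnames(body))))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell '%s' at genus '%s', sample '%s'",
                 body[bad[1L], bad[2L]], genus[bad[1L]],
                 colnames(num)[bad[2L]]))
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance %s at genus '%s', sample '%s'",
                 format(num[bad[1L], bad[2L]]), genus[bad[1L]],
                 colnames(num)[bad[2L]]))
  }
  tr <- .resolveTreatments(treatments, tr_row, colnames(num))
  NemaExperiment(num, treatment = tr, basis = basis)
}

.resolveTreatments <- function(treatments, tr_row, samples) {
  if (is.character(treatments) && length(treatments) == 1L &&
      file.exists(treatments)) {
    side <- utils::read.table(treatments, header = FALSE, sep = "\t",
                              col.names = c("sample", "treatment"),
                              colClasses = "character")
    treatments <- stats::setNames(side$treatment, side$sample)
  }
  if (!is.null(treatments)) {
    if (is.null(names(treatments)) && length(treatments) == length(samples))
      return(unname(treatments))
    miss <- setdiff(samples, names(treatments))
    if (length(miss))
      stop("no treatment label for sample(s): ", paste(miss, collapse = ", "))
    return(unname(treatments[samples]))
  }
  if (!is.null(tr_row)) {
    if (length(tr_row) != length(samples))
      stop("'#treatment' row has ", length(tr_row), " labels for ",
           length(samples), " samples")
    return(tr_row)
  }
  stop("no treatment labels: supply 'treatments' or a '#treatment' row")
}

#' Write a community table (round-trip format of
#' \code{\link{readCommunityMatrix}})
#'
#' @param object a \linkS4class{NemaExperiment}.
#' @param path output path; separator inferred from the extension.
#' @param sep optional explicit separator.
#' @return \code{path}, invisibly.
#' @export
writeCommunityMatrix <- function(object, path, sep = NULL) {
  sep <- .sepFor(path, sep)
  a <- abundance(object)
  header <- paste(c("genus", colnames(a)), collapse = sep)
  tr <- paste(c("#treatment", treatments(object)), collapse = sep)
  body <- vapply(seq_len(nrow(a)), function(i) {
    paste(c(rownames(a)[i],
            format(a[i, ], trim = TRUE, scientific = FALSE, digits = 15)),
          collapse = sep)
  }, character(1))
  writeLines(c(header, tr, body), path)
  invisible(path)
}

#' Read a per-genus trait table
#'
#' Expects columns \code{genus}, \code{trophic_group}, \code{cp_value} and
#' \code{biomass_ug} (or \code{biomass}).
#'
#' @param path path of the TSV/CSV file.
#' @param sep field separator; inferred from the extension when \code{NULL}.
#' @return A \linkS4class{NemaTraits}.
#' @export
readTraitTable <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = .sepFor(path, sep),
                           check.names = FALSE, stringsAsFactors = FALSE)
  bcol <- intersect(c("biomass_ug", "biomass"), colnames(tab))
  req <- c("genus", "trophic_group", "cp_value")
  if (!all(req %in% colnames(tab)) || !length(bcol))
    stop("trait table needs columns genus, trophic_group, cp_value, ",
         "biomass_ug")
  NemaTraits(tab$genus, tab$trophic_group, tab$cp_value, tab[[bcol[1L]]])
}

#' Write a trait table
#'
#' @param traits a \linkS4class{NemaTraits}.
#' @param path output path.
#' @param sep optional explicit separator.
#' @return \code{path}, invisibly.
#' @export
writeTraitTable <- function(traits, path, sep = NULL) {
  df <- data.frame(genus = rownames(traits),
                   trophic_group = traits$trophic_group,
                   cp_value = traits$cp_value,
                   biomass_ug = traits$biomass)
  utils::write.table(df, path, sep = .sepFor(path, sep), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample-by-indicator soil function table
#'
#' @param path TSV/CSV with a first column \code{sample} and one column per
#'   indicator.
#' @param categories named character vector (indicator -> C/N/P/driver) or
#'   path of a YAML file with that mapping.
#' @param treatments optional named character vector or sidecar path, as in
#'   \code{\link{readCommunityMatrix}}.
#' @param sep field separator; inferred when \code{NULL}.
#' @return A \linkS4class{SoilIndicators}.
#' @export
readSoilIndicators <- function(path, categories, treatments = NULL,
                               sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(categories) && length(categories) == 1L &&
      file.exists(categories))
    categories <- unlist(yaml::read_yaml(categories))
  tab <- utils::read.table(path, header = TRUE, sep = .sepFor(path, sep),
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (tolower(colnames(tab)[1L]) != "sample")
    stop("first column must be named 'sample'")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  if (!is.numeric(m)) stop("non-numeric value in soil indicator table")
  tr <- if (is.null(treatments)) NULL else
    .resolveTreatments(treatments, NULL, rownames(m))
  SoilIndicators(t(m), categories = categories, treatment = tr)
}

#' Write a sample-by-indicator soil table (round-trip of
#' \code{\link{readSoilIndicators}})
#'
#' @param object a \linkS4class{SoilIndicators}.
#' @param path output path.
#' @param sep optional explicit separator.
#' @return \code{path}, invisibly.
#' @export
writeSoilIndicators <- function(object, path, sep = NULL) {
  m <- t(assay(object, "value"))
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = .sepFor(path, sep), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the category map of a soil table as YAML
#'
#' @param object a \linkS4class{SoilIndicators}.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
writeCategoryMap <- function(object, path) {
  yaml::write_yaml(as.list(stats::setNames(rowData(object)$category,
                                           rownames(object))), path)
  invisible(path)
}
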