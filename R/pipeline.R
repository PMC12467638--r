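## One-shot orchestration of the analysis stages. The run configuration is
## a plain list (or YAML file): input paths or a simulation scenario,
## thresholds, a seed for every stochastic stage, and an output directory.
## All stage outputs are TSV; a manifest JSON records the configuration,
## package version, stage warnings (undefined indices, constant indicator
## columns, ...) and the files written, so reruns are auditable and, for a
## fixed seed, byte-identical.

.defaultConfig <- function() {
  list(tdLevel = "group", distance = "braycurtis",
       r_min = 0.6, p_max = 0.05, alpha = 0.05, n_perm = 999,
       seed = 1, out_dir = "nemafun-out")
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: \code{simulate} (when the config carries a \code{scenario}:
#' a \linkS4class{SyntheticDesign}, the path of a design YAML, or the
#' string \code{"field-contrast"}), \code{indices}, \code{footprints} (with
#' the faunal profile), \code{emf}, and \code{stats} (ANOSIM, Mantel of
#' community vs. soil distances, genus-overlap partition, per-treatment
#' co-occurrence networks, per-treatment index/function summaries).
#'
#' @param config list or YAML path. Recognized fields: \code{community},
#'   \code{traits}, \code{treatments}, \code{soil}, \code{categories}
#'   (input paths), \code{scenario}, \code{tdLevel}, \code{distance}
#'   (\code{"braycurtis"} or \code{"euclidean-log"}), \code{r_min},
#'   \code{p_max}, \code{alpha}, \code{n_perm}, \code{seed},
#'   \code{out_dir}.
#' @param stages subset of stages to run (dependencies are loaded from
#'   the configured inputs).
#' @return invisibly, a list with the computed tables and the manifest.
#' @export
runPipeline <- function(config = list(),
                        stages = c("simulate", "indices", "footprints",
                                   "emf", "stats")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.defaultConfig(), config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  outputs <- character()
  note <- function(p) { outputs <<- c(outputs, p); p }
  withW <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  com <- NULL; soil <- NULL
  if ("simulate" %in% stages && !is.null(cfg$scenario)) {
    design <- cfg$scenario
    if (is.character(design))
      design <- if (identical(design, "field-contrast"))
        fieldContrastDesign(seed = cfg$seed) else readDesign(design)
    traits <- generateTraits(design)
    com <- generateCommunity(design, traits)
    soil <- generateSoil(design, com)
    note(writeCommunityMatrix(com, file.path(out, "community.tsv")))
    note(writeTraitTable(traits, file.path(out, "traits.tsv")))
    note(writeSoilIndicators(soil, file.path(out, "soil.tsv")))
    note(writeCategoryMap(soil, file.path(out, "categories.yaml")))
    cfg$community <- file.path(out, "community.tsv")
  }
  if (is.null(com)) {
    if (is.null(cfg$community)) stop("no community input configured")
    com <- readCommunityMatrix(cfg$community, treatments = cfg$treatments)
    if (!is.null(cfg$traits))
      com <- attachTraits(com, readTraitTable(cfg$traits))
  }
  if (is.null(soil) && !is.null(cfg$soil))
    soil <- readSoilIndicators(cfg$soil, categories = cfg$categories)

  res <- list(community = com, soil = soil)
  if ("indices" %in% stages) {
    res$indices <- withW(indexTable(com, tdLevel = cfg$tdLevel))
    note(.writeTSV(res$indices, file.path(out, "indices.tsv")))
    note(.writeTSV(indexMeans(res$indices),
                   file.path(out, "index_means.tsv")))
  }
  if ("footprints" %in% stages) {
    res$footprints <- footprintTable(com)
    res$faunal <- withW(faunalProfile(com))
    note(.writeTSV(res$footprints, file.path(out, "footprints.tsv")))
    note(.writeTSV(res$faunal, file.path(out, "faunal.tsv")))
  }
  if ("emf" %in% stages && !is.null(soil)) {
    res$functions <- withW(functionScores(soil))
    note(.writeTSV(res$functions$table,
                   file.path(out, "function_scores.tsv")))
    tfs <- try(treatmentFunctionSummary(res$functions, treatments(soil),
                                        alpha = cfg$alpha), silent = TRUE)
    if (!inherits(tfs, "try-error")) {
      res$function_summary <- tfs
      note(.writeTSV(tfs, file.path(out, "function_summary.tsv")))
    } else warnings_log <- c(warnings_log,
                             "treatment function summary skipped: no replication")
  }
  if ("stats" %in% stages) {
    d <- if (identical(cfg$distance, "euclidean-log")) euclideanLog(com)
         else brayCurtis(com)
    res$anosim <- anosimTest(d, treatments(com), nPerm = cfg$n_perm,
                             seed = cfg$seed)
    res$venn <- vennPartition(com)
    if (!is.null(soil)) {
      dsoil <- stats::dist(scale(t(assay(soil, "value"))))
      res$mantel <- mantelTest(d, dsoil, nPerm = cfg$n_perm,
                               seed = cfg$seed)
    }
    res$networks <- lapply(networksByTreatment(com, rMin = cfg$r_min,
                                               pMax = cfg$p_max),
                           identity)
    for (t in names(res$networks))
      note(writeNetwork(res$networks[[t]],
                        file.path(out, paste0("network_", t, ".tsv"))))
  }

  cfgOut <- cfg
  if (isS4(cfgOut$scenario)) cfgOut$scenario <- class(cfgOut$scenario)[1L]
  manifest <- list(package = "nemafun",
                   version = as.character(utils::packageVersion("nemafun")),
                   config = cfgOut[order(names(cfgOut))],
                   warnings = warnings_log, outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
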