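## Metabolic footprints and the faunal profile.
##
## Per-taxon footprint: F_t = N_t * (0.1 * W_t / m_t + 0.273 * W_t^0.75)
## (carbon equivalents in the unit of the supplied biomass W_t). The first
## term approximates carbon lost to production (lifetime biomass turnover
## scales inversely with the c-p value m_t), the second respiration with
## the 3/4-power metabolic scaling.
##
## Enrichment footprint Fe and structure footprint Fs restrict the sum to
## the enrichment-indicator guilds (c-p 1 bacterivores + c-p 2 fungivores)
## and structure-indicator guilds (c-p 3-5 bacterivores, fungivores,
## omnivores/predators); the functional footprint FMF = Fs * Fe / 2.
## The faunal profile weights abundances, not footprints:
##   e = 3.2 Ba1 + 0.8 Fu2,  b = 0.8 (Ba2 + Fu2),
##   s = sum over structure guilds with weights 1.8 (c-p 3), 3.2 (c-p 4),
##       5.0 (c-p 5);  EI = 100 e/(e+b), SI = 100 s/(s+b).
## All guild definitions and weights live in one configurable table
## (faunalWeights()) so alternative conventions are a config change.

#' Per-taxon metabolic footprint contribution
#'
#' @param Nt non-negative abundance of the taxon.
#' @param Wt per-individual fresh-weight biomass (micrograms), > 0.
#' @param mt colonizer-persister value of the taxon, in 1--5.
#' @return \code{Nt * (0.1 * Wt / mt + 0.273 * Wt^0.75)}, vectorized.
#' @examples
#' taxonFootprint(1, 1, 1)       # 0.373
#' taxonFootprint(100, 16, 2)    # 298.4
#' @export
taxonFootprint <- function(Nt, Wt, mt) {
  if (any(!is.finite(Wt)) || any(Wt <= 0)) stop("biomass Wt must be > 0")
  if (any(!mt %in% 1:5)) stop("c-p value mt must be in 1-5")
  if (any(Nt < 0)) stop("abundance Nt must be non-negative")
  Nt * (0.1 * Wt / mt + 0.273 * Wt^0.75)
}

#' Default faunal-analysis guild weights and footprint guild sets
#'
#' Returns the configuration consumed by \code{\link{footprintTable}} and
#' \code{\link{faunalProfile}}: data frames \code{enrichment},
#' \code{basal} and \code{structure} (columns \code{group}, \code{cp},
#' \code{weight}) for the EI/SI weighting, and \code{fe_guilds} /
#' \code{fs_guilds} (columns \code{group}, \code{cp}) naming the guilds
#' summed into the enrichment and structure footprints. Plant parasites
#' are excluded throughout by default.
#'
#' @param file optional YAML file to load the configuration from (as
#'   written by \code{\link{writeFaunalWeights}}).
#' @return named list of data frames.
#' @export
faunalWeights <- function(file = NULL) {
  if (!is.null(file)) {
    raw <- yaml::read_yaml(file)
    return(lapply(raw, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
  }
  structure_df <- expand.grid(group = c("BF", "FF", "OP"), cp = 3:5,
                              stringsAsFactors = FALSE)
  structure_df$weight <- c(1.8, 3.2, 5.0)[structure_df$cp - 2L]
  list(
    enrichment = data.frame(group = c("BF", "FF"), cp = c(1L, 2L),
                            weight = c(3.2, 0.8)),
    basal = data.frame(group = c("BF", "FF"), cp = c(2L, 2L),
                       weight = c(0.8, 0.8)),
    structure = structure_df,
    fe_guilds = data.frame(group = c("BF", "FF"), cp = c(1L, 2L)),
    fs_guilds = expand.grid(group = c("BF", "FF", "OP"), cp = 3:5,
                            stringsAsFactors = FALSE))
}

#' Write a faunal weight configuration as YAML
#'
#' @param weights a configuration list as returned by
#'   \code{\link{faunalWeights}}.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
writeFaunalWeights <- function(weights, path) {
  yaml::write_yaml(lapply(weights, as.list), path)
  invisible(path)
}

## guild membership mask: genera whose (group, cp) pair appears in `guilds`
.guildMask <- function(tr, guilds) {
  key <- paste(tr$trophic_group, tr$cp_value)
  key %in% paste(guilds$group, guilds$cp)
}

#' Per-sample metabolic footprints
#'
#' Group footprints (\code{bfmf}, \code{ffmf}, \code{ppmf}, \code{opmf}),
#' total (\code{tnmf}), enrichment and structure footprints (\code{fe},
#' \code{fs}) and the functional footprint \code{fmf = fs * fe / 2}.
#'
#' @param object a \linkS4class{NemaExperiment} with traits attached.
#' @param weights guild configuration, see \code{\link{faunalWeights}}.
#' @return data.frame with one row per sample.
#' @export
footprintTable <- function(object, weights = faunalWeights()) {
  tr <- .requireTraits(object)
  a <- abundance(object)
  fp <- a * taxonFootprint(1, tr$biomass, tr$cp_value)  # per-genus footprints
  bygrp <- rowsum(fp, factor(tr$trophic_group, levels = TROPHIC_GROUPS))
  grp <- matrix(0, 4L, ncol(a), dimnames = list(TROPHIC_GROUPS, colnames(a)))
  grp[rownames(bygrp), ] <- bygrp
  fe <- colSums(fp[.guildMask(tr, weights$fe_guilds), , drop = FALSE])
  fs <- colSums(fp[.guildMask(tr, weights$fs_guilds), , drop = FALSE])
  data.frame(sample = colnames(a),
             treatment = unname(treatments(object)),
             bfmf = grp["BF", ], ffmf = grp["FF", ], ppmf = grp["PP", ],
             opmf = grp["OP", ], tnmf = colSums(fp),
             fe = fe, fs = fs, fmf = fs * fe / 2,
             row.names = colnames(a), stringsAsFactors = FALSE)
}

#' Per-sample faunal profile (enrichment and structure indices)
#'
#' EI = 100 e/(e+b) and SI = 100 s/(s+b) from weighted guild abundances
#' (weights in \code{\link{faunalWeights}}). Quadrants follow the 50/50
#' convention: A (EI >= 50, SI < 50) enriched but unstructured, B (both
#' >= 50) enriched and structured, C (EI < 50, SI >= 50) structured with
#' low enrichment, D (both < 50) degraded. EI (SI) is \code{NA}, with a
#' warning, when e+b (s+b) is zero.
#'
#' @param object a \linkS4class{NemaExperiment} with traits attached.
#' @param weights guild configuration, see \code{\link{faunalWeights}}.
#' @return data.frame with columns \code{sample}, \code{treatment},
#'   \code{ei}, \code{si}, \code{quadrant}.
#' @export
faunalProfile <- function(object, weights = faunalWeights()) {
  tr <- .requireTraits(object)
  a <- abundance(object)
  wsum <- function(spec) {
    m <- .guildMask(tr, spec)
    w <- numeric(nrow(a))
    w[m] <- spec$weight[match(paste(tr$trophic_group, tr$cp_value)[m],
                              paste(spec$group, spec$cp))]
    colSums(a * w)
  }
  e <- wsum(weights$enrichment)
  b <- wsum(weights$basal)
  s <- wsum(weights$structure)
  ei <- ifelse(e + b > 0, 100 * e / (e + b), NA_real_)
  si <- ifelse(s + b > 0, 100 * s / (s + b), NA_real_)
  quad <- ifelse(is.na(ei) | is.na(si), NA_character_,
                 ifelse(ei >= 50,
                        ifelse(si >= 50, "B", "A"),
                        ifelse(si >= 50, "C", "D")))
  if (any(is.na(ei) | is.na(si)))
    warning("faunal profile undefined (empty basal+indicator guilds) in: ",
            paste(colnames(a)[is.na(ei) | is.na(si)], collapse = ", "))
  data.frame(sample = colnames(a), treatment = unname(treatments(object)),
             ei = ei, si = si, quadrant = quad,
             row.names = colnames(a), stringsAsFactors = FALSE)
}
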