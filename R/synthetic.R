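## Seeded synthetic data with the field study's structure: 4 treatments x
## 4 replicates, ~19 genera in four trophic groups with c-p 1-5 and
## per-individual biomass, lognormal rank-abundance baselines, treatment
## multipliers on total abundance and on trophic/c-p composition,
## replicate-level lognormal noise, and 15 C/N/P soil indicators driven
## positively by soil water content (N, P) and negatively by pH (C).

.lnormPars <- function(cv) {
  sdlog <- sqrt(log(1 + cv^2))
  c(meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean exactly 1
}

#' Synthetic study design
#'
#' Describes a multi-treatment community + soil scenario: replication,
#' genus pool size, lognormal baseline rank-abundance, per-treatment
#' multipliers on total abundance and on trophic-group / c-p-band / rare
#' -genus composition, replicate noise, and the linear soil model tying C
#' indicators (negatively) to pH and N/P indicators (positively) to soil
#' water content.
#'
#' @aliases SyntheticDesign-class
#' @exportClass SyntheticDesign
setClass("SyntheticDesign", representation(
  treatments = "character", replicates = "integer", nGenera = "integer",
  seed = "integer", baselineTotal = "numeric", baselineSdlog = "numeric",
  totalMultiplier = "numeric", groupMultiplier = "list",
  cpBandMultiplier = "list", rareMultiplier = "numeric",
  noiseCV = "numeric", soilModel = "list"))

setValidity("SyntheticDesign", function(object) {
  msgs <- character()
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "a single integer seed is mandatory")
  if (any(object@totalMultiplier <= 0) || any(object@rareMultiplier <= 0))
    msgs <- c(msgs, "multipliers must be positive")
  if (!setequal(names(object@totalMultiplier), object@treatments))
    msgs <- c(msgs, "totalMultiplier must be named by treatment")
  if (object@replicates < 1L) msgs <- c(msgs, "replicates must be >= 1")
  if (object@noiseCV < 0) msgs <- c(msgs, "noiseCV must be >= 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a synthetic design
#'
#' Defaults describe a null scenario (no treatment effect) on the field
#' study's frame: 4 treatments (CK, NM, PM, LM) x 4 replicates, 19
#' genera, expected total 1830 individuals per 100 g dry soil, and equal
#' soil drivers across treatments.
#'
#' @param treatments treatment labels.
#' @param replicates replicates per treatment.
#' @param nGenera number of genera (>= 4; one per trophic group is
#'   guaranteed).
#' @param seed mandatory integer seed; all generators are deterministic
#'   given the design.
#' @param baselineTotal expected total individuals per 100 g dry soil in
#'   the reference treatment.
#' @param baselineSdlog lognormal sd (log scale) of the genus
#'   rank-abundance baseline.
#' @param totalMultiplier named per-treatment multiplier on expected total
#'   abundance.
#' @param groupMultiplier named list (per treatment) of named multipliers
#'   on trophic-group composition (BF/FF/PP/OP), applied before rescaling
#'   to the target total.
#' @param cpBandMultiplier named list (per treatment) of multipliers on
#'   the \code{cp1-2} and \code{cp3-5} bands.
#' @param rareMultiplier named per-treatment multiplier applied to genera
#'   in the bottom tercile of the baseline rank-abundance (values < 1
#'   thin rare genera, raising dominance).
#' @param noiseCV replicate-level coefficient of variation (applied as a
#'   whole-sample lognormal factor and as independent per-genus factors).
#' @param soilModel list with per-treatment \code{sw_mean} and
#'   \code{ph_mean}, their replicate sds \code{sw_sd}, \code{ph_sd}, and
#'   \code{noise_frac} scaling the indicator residual sd relative to the
#'   indicator's driver slope.
#' @return A \linkS4class{SyntheticDesign}.
#' @export
syntheticDesign <- function(treatments = c("CK", "NM", "PM", "LM"),
                            replicates = 4, nGenera = 19, seed,
                            baselineTotal = 1830, baselineSdlog = 1,
                            totalMultiplier = NULL, groupMultiplier = NULL,
                            cpBandMultiplier = NULL, rareMultiplier = NULL,
                            noiseCV = 0.15, soilModel = NULL) {
  ones <- stats::setNames(rep(1, length(treatments)), treatments)
  fill <- function(x, template) {
    if (is.null(x)) return(template)
    out <- template; out[names(x)] <- x; out
  }
  grp1 <- stats::setNames(rep(1, 4), TROPHIC_GROUPS)
  band1 <- c("cp1-2" = 1, "cp3-5" = 1)
  asList <- function(x, template) {
    out <- stats::setNames(rep(list(template), length(treatments)), treatments)
    for (t in names(x)) out[[t]] <- fill(x[[t]], template)
    out
  }
  if (is.null(soilModel)) soilModel <- list()
  sm <- utils::modifyList(
    list(sw_mean = stats::setNames(rep(0.28, length(treatments)), treatments),
         ph_mean = stats::setNames(rep(7.2, length(treatments)), treatments),
         sw_sd = 0.02, ph_sd = 0.12, noise_frac = 0.35),
    soilModel)
  new("SyntheticDesign",
      treatments = treatments, replicates = as.integer(replicates),
      nGenera = as.integer(nGenera), seed = as.integer(seed),
      baselineTotal = baselineTotal, baselineSdlog = baselineSdlog,
      totalMultiplier = fill(totalMultiplier, ones),
      groupMultiplier = asList(groupMultiplier, grp1),
      cpBandMultiplier = asList(cpBandMultiplier, band1),
      rareMultiplier = fill(rareMultiplier, ones),
      noiseCV = noiseCV, soilModel = sm)
}

#' Field-contrast disturbance scenario
#'
#' A named scenario encoding the directions of the field study's
#' contrasts: PM raises total abundance by 37.74\% with the persister band
#' rising slightly faster than the colonizer band; NM shifts composition
#' toward bacterivores and omnivores/predators and thins rare genera
#' (raising dominance and the channel ratio, lowering diversity); LM
#' raises the plant-parasite share and thins high-c-p free-living taxa.
#' Soil drivers order the functions CK > PM > NM > LM (moisture highest
#' in CK, pH highest in LM).
#'
#' @param seed integer seed.
#' @param ... further arguments to \code{\link{syntheticDesign}}.
#' @return A \linkS4class{SyntheticDesign}.
#' @export
fieldContrastDesign <- function(seed, ...) {
  syntheticDesign(
    seed = seed,
    totalMultiplier = c(CK = 1, NM = 1.0, PM = 1.3774, LM = 0.9),
    groupMultiplier = list(
      NM = c(BF = 1.6, FF = 0.8, PP = 0.6, OP = 1.4),
      PM = c(FF = 1.2),
      LM = c(PP = 1.7, BF = 0.9)),
    cpBandMultiplier = list(
      PM = c("cp1-2" = 1.3654 / 1.3774, "cp3-5" = 1.3937 / 1.3774),
      LM = c("cp3-5" = 0.75)),
    rareMultiplier = c(NM = 0.35),
    soilModel = list(
      sw_mean = c(CK = 0.33, NM = 0.22, PM = 0.29, LM = 0.23),
      ph_mean = c(CK = 6.9, NM = 7.5, PM = 7.1, LM = 7.9)),
    ...)
}

#' Generate a synthetic trait registry
#'
#' Every trophic group is represented; c-p values span the group-typical
#' ranges (bacterivores 1--4, fungivores 2--4, plant parasites 2--5,
#' omnivores/predators 4--5); biomass is lognormal around group-typical
#' magnitudes. Deterministic given the design seed.
#'
#' @param design a \linkS4class{SyntheticDesign} with \code{nGenera >= 4}.
#' @return A \linkS4class{NemaTraits}.
#' @export
generateTraits <- function(design) {
  n <- design@nGenera
  if (n < 4L) stop("nGenera must be at least 4 (one genus per group)")
  .withSeed(design@seed, {
    grp <- c(TROPHIC_GROUPS,
             sample(TROPHIC_GROUPS, n - 4L, replace = TRUE,
                    prob = c(0.35, 0.25, 0.25, 0.15)))
    cp <- vapply(grp, function(g) switch(g,
      BF = sample(1:4, 1L, prob = c(0.3, 0.4, 0.2, 0.1)),
      FF = sample(2:4, 1L, prob = c(0.7, 0.2, 0.1)),
      PP = sample(2:5, 1L, prob = c(0.3, 0.4, 0.2, 0.1)),
      OP = sample(4:5, 1L)), integer(1))
    typ <- c(BF = 0.5, FF = 0.3, PP = 1.2, OP = 3.5)
    w <- stats::rlnorm(n, meanlog = log(typ[grp]), sdlog = 0.6)
    NemaTraits(sprintf("Genus%02d", seq_len(n)), grp, cp, w)
  })
}

## expected genus abundance per treatment (the injected signal)
.expectedCommunity <- function(design, traits) {
  n <- design@nGenera
  base_share <- .withSeed(design@seed + 1L, {
    z <- stats::rlnorm(n, 0, design@baselineSdlog)
    z / sum(z)
  })
  rare <- base_share <= stats::quantile(base_share, 1 / 3)
  band <- ifelse(traits$cp_value <= 2, "cp1-2", "cp3-5")
  vapply(design@treatments, function(t) {
    mult <- design@groupMultiplier[[t]][traits$trophic_group] *
      design@cpBandMultiplier[[t]][band] *
      ifelse(rare, design@rareMultiplier[[t]], 1)
    e <- base_share * mult
    e * (design@baselineTotal * design@totalMultiplier[[t]] / sum(e))
  }, numeric(n))
}

#' Generate a synthetic community matrix
#'
#' Genus expectations follow the design's baseline rank-abundance and
#' per-treatment multipliers; each treatment's expected total equals the
#' baseline total times its multiplier exactly. Replicates multiply the
#' expectation by a whole-sample lognormal factor and independent
#' per-genus lognormal factors, both mean 1 with coefficient of variation
#' \code{noiseCV}. Counts are rounded to integers by default (downstream
#' formulas accept reals). Deterministic given the design seed.
#'
#' @param design a \linkS4class{SyntheticDesign}.
#' @param traits optional \linkS4class{NemaTraits}; generated from the
#'   design when \code{NULL}.
#' @param round round counts to integers.
#' @return A \linkS4class{NemaExperiment} with traits attached.
#' @export
generateCommunity <- function(design, traits = NULL, round = TRUE) {
  if (is.null(traits)) traits <- generateTraits(design)
  expected <- .expectedCommunity(design, traits)
  p <- .lnormPars(design@noiseCV)
  .withSeed(design@seed + 2L, {
    cols <- list(); labels <- character()
    for (t in design@treatments) for (r in seq_len(design@replicates)) {
      sf <- if (design@noiseCV > 0)
        stats::rlnorm(1, p["meanlog"], p["sdlog"]) else 1
      gf <- if (design@noiseCV > 0)
        stats::rlnorm(design@nGenera, p["meanlog"], p["sdlog"]) else
          rep(1, design@nGenera)
      x <- expected[, t] * sf * gf
      if (round) x <- round(x)
      cols[[length(cols) + 1L]] <- x
      labels <- c(labels, t)
    }
    a <- do.call(cbind, cols)
    dimnames(a) <- list(rownames(traits),
                        paste0(labels, "_",
                               sequence(rep(design@replicates,
                                            length(design@treatments)))))
    NemaExperiment(a, treatment = labels, traits = traits)
  })
}

## C/N/P function indicators: 5 C (negative pH slope), 7 N and 2 P
## (positive SW slope)
.soilCoefs <- function() {
  list(C = data.frame(indicator = c("SOC", "MBC", "EOC", "DOC", "POC"),
                      intercept = c(75, 9, 18, 5, 12),
                      slope = -c(6, 0.8, 1.5, 0.4, 1.0)),
       N = data.frame(indicator = c("TN", "MBN", "AHN", "AAN", "AASN",
                                    "ASN", "HUN"),
                      intercept = c(1.0, 0.05, 0.3, 0.05, 0.08, 0.04, 0.10),
                      slope = c(8, 0.8, 2.5, 0.5, 0.8, 0.3, 0.9)),
       P = data.frame(indicator = c("TP", "AP"),
                      intercept = c(0.3, 0.01),
                      slope = c(2.0, 0.15)))
}

#' Generate synthetic soil function indicators
#'
#' Per sample, soil water content (SW) and pH are drawn around their
#' treatment means; the five carbon indicators decrease linearly with pH,
#' the seven nitrogen and two phosphorus indicators increase linearly
#' with SW, with Gaussian residuals scaled by
#' \code{soilModel$noise_frac} times the indicator's slope. Coefficients
#' are recorded in \code{metadata()$soil_model}. Deterministic given the
#' design seed.
#'
#' @param design a \linkS4class{SyntheticDesign}.
#' @param community a \linkS4class{NemaExperiment} supplying sample names
#'   and treatments (generated from the design when \code{NULL}).
#' @return A \linkS4class{SoilIndicators} with the 14 C/N/P function
#'   indicators (5 carbon, 7 nitrogen, 2 phosphorus) plus \code{SW} and
#'   \code{pH} driver rows.
#' @export
generateSoil <- function(design, community = NULL) {
  if (is.null(community)) community <- generateCommunity(design)
  tr <- treatments(community)
  sm <- design@soilModel
  coefs <- .soilCoefs()
  .withSeed(design@seed + 3L, {
    sw <- stats::rnorm(length(tr), sm$sw_mean[tr], sm$sw_sd)
    ph <- stats::rnorm(length(tr), sm$ph_mean[tr], sm$ph_sd)
    rows <- lapply(names(coefs), function(cat) {
      cf <- coefs[[cat]]
      driver <- if (cat == "C") ph else sw
      v <- t(vapply(seq_len(nrow(cf)), function(i) {
        cf$intercept[i] + cf$slope[i] * driver +
          stats::rnorm(length(driver), 0, sm$noise_frac * abs(cf$slope[i]) *
                         (if (cat == "C") sm$ph_sd else sm$sw_sd) * 3)
      }, numeric(length(driver))))
      rownames(v) <- cf$indicator
      v
    })
    values <- rbind(do.call(rbind, rows), SW = sw, pH = ph)
    colnames(values) <- names(tr)
    categories <- c(stats::setNames(rep(names(coefs),
                                        vapply(coefs, nrow, integer(1))),
                                    unlist(lapply(coefs, `[[`, "indicator"))),
                    SW = "driver", pH = "driver")
    si <- SoilIndicators(values, categories = categories,
                         treatment = unname(tr))
    metadata(si)$soil_model <- c(sm, list(coefficients = coefs))
    si
  })
}

#' End-to-end parameter-recovery report
#'
#' Generates a dataset from the design, runs the pipeline, and compares
#' estimated treatment effects with the injected ones: percent change in
#' total, cp1-2 and cp3-5 abundance relative to the reference (first)
#' treatment, the one-way ANOVA p-value on sample totals, and the
#' EMF treatment ordering.
#'
#' @param design a \linkS4class{SyntheticDesign}.
#' @param tolPct tolerance (percentage points) for flagging total-
#'   abundance recovery.
#' @param alpha ANOVA significance level.
#' @return list with \code{injected} and \code{estimated} percent-change
#'   tables, \code{recovery_error} (estimated minus injected, percentage
#'   points), \code{anova_p}, \code{emf_order} (treatments by decreasing
#'   mean EMF), and \code{pass} flags.
#' @export
recoveryReport <- function(design, tolPct = 2, alpha = 0.05) {
  traits <- generateTraits(design)
  com <- generateCommunity(design, traits)
  soil <- generateSoil(design, com)
  ref <- design@treatments[1L]
  expected <- .expectedCommunity(design, traits)
  band <- ifelse(traits$cp_value <= 2, "cp1-2", "cp3-5")
  injBands <- rowsum(expected, band)
  inj <- rbind(total = colSums(expected), injBands)
  injPct <- 100 * (inj / inj[, ref] - 1)

  tr <- treatments(com)
  totals <- colSums(abundance(com))
  bands <- aggregateAbundance(com, by = "cp_band")
  estMeans <- rbind(total = tapply(totals, tr, mean)[design@treatments],
                    tapply(bands["cp1-2", ], tr, mean)[design@treatments],
                    tapply(bands["cp3-5", ], tr, mean)[design@treatments])
  rownames(estMeans) <- c("total", "cp1-2", "cp3-5")
  estPct <- 100 * (estMeans / estMeans[, ref] - 1)

  aovp <- anovaLSD(totals, tr, alpha = alpha)$p_value
  emf <- functionScores(soil)
  emfMeans <- tapply(emf$emf, tr, mean)[design@treatments]
  err <- estPct - injPct
  list(injected = injPct, estimated = estPct, recovery_error = err,
       anova_p = aovp,
       emf_order = names(sort(emfMeans, decreasing = TRUE)),
       pass = list(
         total_recovery = all(abs(err["total", ]) <= tolPct),
         any_treatment_effect = aovp < alpha))
}

#' Serialize / load a synthetic design as YAML
#'
#' @param design a \linkS4class{SyntheticDesign}.
#' @param path YAML path.
#' @return \code{path} (write) or a \linkS4class{SyntheticDesign} (read).
#' @export
writeDesign <- function(design, path) {
  mapify <- function(v) {         # named vectors -> YAML maps, recursively
    if (is.list(v)) lapply(v, mapify)
    else if (!is.null(names(v))) as.list(v)
    else v
  }
  sl <- lapply(slotNames(design), function(s) mapify(slot(design, s)))
  names(sl) <- slotNames(design)
  yaml::write_yaml(sl, path)
  invisible(path)
}

#' @rdname writeDesign
#' @export
readDesign <- function(path) {
  raw <- yaml::read_yaml(path)
  num <- function(x) unlist(x)
  syntheticDesign(
    treatments = raw$treatments, replicates = raw$replicates,
    nGenera = raw$nGenera, seed = raw$seed,
    baselineTotal = raw$baselineTotal, baselineSdlog = raw$baselineSdlog,
    totalMultiplier = num(raw$totalMultiplier),
    groupMultiplier = lapply(raw$groupMultiplier, num),
    cpBandMultiplier = lapply(raw$cpBandMultiplier, num),
    rareMultiplier = num(raw$rareMultiplier),
    noiseCV = raw$noiseCV,
    soilModel = utils::modifyList(raw$soilModel, list(
      sw_mean = num(raw$soilModel$sw_mean),
      ph_mean = num(raw$soilModel$ph_mean))))
}

setMethod("show", "SyntheticDesign", function(object) {
  cat(sprintf("SyntheticDesign: %d treatments x %d replicates, %d genera, seed %d\n",
              length(object@treatments), object@replicates,
              object@nGenera, object@seed))
  cat("total multipliers:",
      paste(sprintf("%s=%.4g", names(object@totalMultiplier),
                    object@totalMultiplier), collapse = " "), "\n")
})
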