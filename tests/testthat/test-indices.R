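# Diversity, maturity, and channel indices against closed forms and
# independent direct-summation oracles.

test_that("degenerate and symmetric communities hit closed forms", {
  tr <- NemaTraits(paste0("G", 1:4), c("BF", "FF", "PP", "OP"),
                   c(2, 2, 3, 4), rep(1, 4))
  # single genus
  d1 <- diversityIndices(c(G1 = 50), tr)
  expect_equal(unname(d1["shannon"]), 0)
  expect_equal(unname(d1["lambda"]), 1)
  # four equal genera, one per trophic group
  x <- setNames(rep(10, 4), paste0("G", 1:4))
  d4 <- diversityIndices(x, tr)
  expect_equal(unname(d4["shannon"]), log(4), tolerance = 1e-12)
  expect_equal(unname(d4["lambda"]), 0.25, tolerance = 1e-12)
  expect_equal(unname(d4["td"]), 4, tolerance = 1e-12)
  # equal-abundance community of S genera: H' = ln S, lambda = 1/S
  for (S in c(2, 7, 13)) {
    trS <- NemaTraits(paste0("G", 1:S),
                      rep(c("BF", "FF", "PP", "OP"), length.out = S),
                      rep(2, S), rep(1, S))
    dS <- diversityIndices(setNames(rep(3, S), paste0("G", 1:S)), trS)
    expect_equal(unname(dS["shannon"]), log(S), tolerance = 1e-12)
    expect_equal(unname(dS["lambda"]), 1 / S, tolerance = 1e-12)
  }
})

test_that("hand-computed 3-genus sample matches (all bacterivores)", {
  tr <- NemaTraits(paste0("G", 1:3), rep("BF", 3), rep(2, 3), rep(1, 3))
  d <- diversityIndices(c(G1 = 5, G2 = 3, G3 = 2), tr)
  expect_equal(unname(d["shannon"]),
               -(0.5 * log(0.5) + 0.3 * log(0.3) + 0.2 * log(0.2)),
               tolerance = 1e-12)
  expect_equal(unname(d["lambda"]), 0.38, tolerance = 1e-12)
  expect_equal(unname(d["td"]), 1, tolerance = 1e-12)
  expect_equal(unname(d["sr"]), 2 / log(10), tolerance = 1e-12)
})

test_that("maturity indices are sub-community-weighted c-p means", {
  tr <- NemaTraits(paste0("G", 1:4), c("BF", "BF", "PP", "PP"),
                   c(1, 2, 3, 2), rep(1, 4))
  m <- maturityIndices(c(G1 = 60, G2 = 40, G3 = 30, G4 = 10), tr)
  expect_equal(unname(m["mi"]), 1 * 0.6 + 2 * 0.4)
  expect_equal(unname(m["ppi"]), 3 * 0.75 + 2 * 0.25)
  # constant c-p: MI equals it regardless of abundances
  tr2 <- NemaTraits(paste0("G", 1:3), c("BF", "FF", "OP"),
                    c(2, 2, 2), rep(1, 3))
  expect_equal(unname(maturityIndices(c(G1 = 1, G2 = 99, G3 = 5), tr2)["mi"]),
               2)
  # empty sub-communities flag NA
  expect_true(is.na(maturityIndices(c(G1 = 3, G2 = 1, G3 = 0), tr2)["ppi"]))
})

test_that("channel ratio and Wasilewska rules use strict thresholds", {
  tr <- NemaTraits(paste0("G", 1:3), c("BF", "FF", "PP"),
                   c(2, 2, 3), rep(1, 3))
  ch <- channelHealth(c(G1 = 10, G2 = 10, G3 = 0), tr)
  expect_equal(ch$ncr, 0.5)
  expect_equal(ch$pathway, "fungal-leaning")
  expect_true(is.na(ch$wi))
  # NCR exactly 0.75 is not bacterial (strict >)
  ch2 <- channelHealth(c(G1 = 30, G2 = 10, G3 = 0), tr)
  expect_equal(ch2$ncr, 0.75)
  expect_equal(ch2$pathway, "fungal-leaning")
  expect_equal(channelHealth(c(G1 = 31, G2 = 10, G3 = 0), tr)$pathway,
               "bacterial")
  # WI = 3 > 1: healthy food web
  ch3 <- channelHealth(c(G1 = 50, G2 = 25, G3 = 25), tr)
  expect_equal(ch3$wi, 3)
  expect_equal(ch3$health, "good")
  expect_equal(channelHealth(c(G1 = 5, G2 = 5, G3 = 25), tr)$health, "poor")
})

test_that("all indices match the direct-summation oracle on random communities", {
  for (seed in 1:40) {
    rc <- random_community(seed)
    tr <- traits(rc)
    suppressWarnings(it <- indexTable(rc))
    a <- abundance(rc)
    for (j in seq_len(ncol(a))) {
      x <- a[, j]
      grp <- tr$trophic_group; cp <- tr$cp_value
      expect_equal(it$shannon[j], oracle_shannon(x), tolerance = 1e-10)
      expect_equal(it$lambda[j], oracle_lambda(x), tolerance = 1e-10)
      expect_equal(it$td[j], oracle_td(x, grp), tolerance = 1e-10)
      expect_equal(it$sr[j], oracle_sr(x), tolerance = 1e-10)
      expect_equal(it$mi[j], oracle_mi(x, cp, grp), tolerance = 1e-10)
      expect_equal(it$ppi[j], oracle_ppi(x, cp, grp), tolerance = 1e-10)
      expect_equal(it$ncr[j], oracle_ncr(x, grp), tolerance = 1e-10)
      expect_equal(it$wi[j], oracle_wi(x, grp), tolerance = 1e-10)
    }
  }
})

test_that("index properties: scaling invariance, majorization, NCR bounds", {
  for (seed in 1:20) {
    rc <- random_community(seed + 100)
    tr <- traits(rc)
    x <- abundance(rc)[, 1]
    # MI/PPI invariant to uniform scaling
    expect_equal(maturityIndices(x, tr), maturityIndices(7.3 * x, tr),
                 tolerance = 1e-12)
    # an abundance-concentrating transfer raises lambda and lowers H'
    pos <- which(x > 0)
    if (length(pos) >= 2) {
      hi <- pos[which.max(x[pos])]; lo <- pos[which.min(x[pos])]
      if (hi != lo && x[lo] > 0) {
        y <- x; eps <- x[lo] / 2
        y[hi] <- y[hi] + eps; y[lo] <- y[lo] - eps
        dx <- diversityIndices(x, tr); dy <- diversityIndices(y, tr)
        expect_gt(dy["lambda"], dx["lambda"])
        expect_lt(dy["shannon"], dx["shannon"])
      }
    }
    ch <- channelHealth(x, tr)
    if (!is.na(ch$ncr)) expect_true(ch$ncr >= 0 && ch$ncr <= 1)
  }
  # replacing FF with BF drives NCR monotonically to 1
  tr <- NemaTraits(c("Ga", "Gb"), c("BF", "FF"), c(2, 2), c(1, 1))
  ncrs <- sapply(seq(0, 40, by = 10), function(k)
    channelHealth(c(Ga = 10 + k, Gb = 40 - k), tr)$ncr)
  expect_true(all(diff(ncrs) > 0))
  expect_equal(ncrs[5], 1)
})

test_that("index table flags undefined entries instead of zeroing them", {
  tr <- NemaTraits(paste0("G", 1:4), c("BF", "FF", "PP", "OP"),
                   c(2, 2, 3, 4), rep(1, 4))
  a <- matrix(c(10, 5, 3, 2,
                10, 5, 0, 2), nrow = 4,
              dimnames = list(paste0("G", 1:4), c("S1", "S2")))
  com <- NemaExperiment(a, c("CK", "CK"), traits = tr)
  expect_warning(it <- indexTable(com), "undefined")
  expect_true(is.na(it["S2", "wi"]))
  expect_false(is.na(it["S1", "wi"]))
  expect_match(it["S2", "undefined"], "wi")
  expect_equal(it["S1", "undefined"], "")
  # undefined values are dropped from treatment means, not coerced to 0
  m <- indexMeans(it)
  expect_equal(m$wi[m$treatment == "CK"], it["S1", "wi"])
})

test_that("taxon-level TD switch gives the reciprocal Simpson over taxa", {
  rc <- random_community(5)
  x <- abundance(rc)[, 1]
  d <- diversityIndices(x, traits(rc), tdLevel = "taxon")
  expect_equal(unname(d["td"]), 1 / oracle_lambda(x), tolerance = 1e-12)
})
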