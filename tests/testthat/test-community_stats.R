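# Distances, ANOSIM/Mantel permutation tests, LSD letters, the genus
# Venn partition, and co-occurrence networks.

test_that("Bray-Curtis matches hand evaluation and bounds", {
  m <- rbind(S1 = c(5, 3, 2), S2 = c(2, 3, 5))
  expect_equal(as.numeric(brayCurtis(m)), 6 / 20)
  m2 <- rbind(S1 = c(5, 0), S2 = c(5, 0), S3 = c(0, 7))
  d <- as.matrix(brayCurtis(m2))
  expect_equal(d["S1", "S2"], 0)   # identical samples
  expect_equal(d["S1", "S3"], 1)   # disjoint supports
  expect_error(brayCurtis(rbind(S1 = c(1, 2), S2 = c(0, 0))), "all-zero")
  # random matrices stay in [0,1] and match the pairwise loop oracle
  set.seed(1)
  m3 <- matrix(rpois(6 * 5, 4), nrow = 6,
               dimnames = list(paste0("S", 1:6), NULL))
  d3 <- as.matrix(brayCurtis(m3))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(d3[i, j], oracle_bray(m3[i, ], m3[j, ]), tolerance = 1e-12)
})

test_that("ANOSIM gives R = 1 for perfectly separated groups", {
  # all between-group distances exceed all within-group distances
  m <- rbind(A1 = c(10, 0, 0), A2 = c(11, 1, 0), A3 = c(10, 0, 1),
             B1 = c(0, 10, 10), B2 = c(1, 11, 10), B3 = c(0, 10, 11))
  d <- brayCurtis(m)
  g <- rep(c("A", "B"), each = 3)
  expect_equal(anosimStatistic(d, g), 1)
  fit <- anosimTest(d, g, nPerm = 999, seed = 1)
  expect_equal(fit$statistic, 1)
  # only the 2 of 20 distinct labelings reproducing the split reach R = 1
  expect_lt(abs(fit$p.value - 0.1), 0.03)
})

test_that("seeded permutation p matches the exhaustive-enumeration p", {
  set.seed(42)
  m <- matrix(runif(6 * 4), nrow = 6,
              dimnames = list(paste0("S", 1:6), NULL))
  d <- brayCurtis(m)
  g <- rep(c("A", "B"), each = 3)
  p_exact <- oracle_anosim_exact_p(as.matrix(d), g)
  fit <- anosimTest(d, g, nPerm = 9999, seed = 7)
  expect_lt(abs(fit$p.value - p_exact), 0.02)
  # the package statistic agrees with the pair-loop oracle
  expect_equal(anosimStatistic(d, g), oracle_anosim_R(as.matrix(d), g),
               tolerance = 1e-12)
})

test_that("ANOSIM R stays in [-1, 1] over random instances", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(6:10, 1)
    m <- matrix(runif(n * 3), nrow = n)
    rownames(m) <- paste0("S", 1:n)
    g <- sample(rep(c("A", "B"), length.out = n))
    if (min(table(g)) < 2) next
    r <- anosimStatistic(brayCurtis(m), g)
    expect_true(r >= -1 && r <= 1)
  }
})

test_that("ANOSIM rejects degenerate groupings", {
  m <- matrix(runif(12), nrow = 4, dimnames = list(paste0("S", 1:4), NULL))
  d <- brayCurtis(m)
  expect_error(anosimTest(d, c("A", "A", "A", "B")), "fewer than 2")
  expect_error(anosimTest(d, rep("A", 4)), "two groups")
})

test_that("Mantel detects exact linear relations and respects symmetry", {
  set.seed(3)
  m <- matrix(runif(7 * 4), nrow = 7, dimnames = list(paste0("S", 1:7), NULL))
  d1 <- brayCurtis(m)
  fit <- mantelTest(d1, 2 * d1, nPerm = 99, seed = 1)
  expect_equal(fit$statistic, 1, tolerance = 1e-12)
  # symmetric in its arguments; invariant to positive scaling
  m2 <- matrix(runif(7 * 4), nrow = 7, dimnames = list(paste0("S", 1:7), NULL))
  d2 <- brayCurtis(m2)
  f12 <- mantelTest(d1, d2, nPerm = 99, seed = 5)
  f21 <- mantelTest(d2, d1, nPerm = 99, seed = 5)
  expect_equal(f12$statistic, f21$statistic, tolerance = 1e-12)
  fscaled <- mantelTest(d1, d2 * 3.7, nPerm = 99, seed = 5)
  expect_equal(fscaled$statistic, f12$statistic, tolerance = 1e-12)
  expect_true(abs(f12$statistic) <= 1)
  expect_error(mantelTest(d1, brayCurtis(m[1:5, ])), "same samples")
})

test_that("independent distance matrices give small r and well-spread p", {
  set.seed(8)
  rs <- ps <- numeric(20)
  for (k in 1:20) {
    m1 <- matrix(runif(8 * 5), nrow = 8, dimnames = list(paste0("S", 1:8), NULL))
    m2 <- matrix(runif(8 * 5), nrow = 8, dimnames = list(paste0("S", 1:8), NULL))
    fit <- mantelTest(brayCurtis(m1), brayCurtis(m2), nPerm = 199, seed = k)
    rs[k] <- fit$statistic; ps[k] <- fit$p.value
  }
  expect_lt(abs(mean(rs)), 0.25)
  expect_gt(mean(ps > 0.05), 0.6)  # mostly non-significant under the null
})

test_that("LSD letters separate clear effects and merge identical groups", {
  set.seed(2)
  # two essentially identical groups share a letter
  v <- c(rnorm(4, 10, 0.01), rnorm(4, 10, 0.01))
  g <- rep(c("A", "B"), each = 4)
  expect_equal(unname(anovaLSD(v, g)$letters), c("a", "a"))
  # 100-sigma separation yields distinct letters
  v2 <- c(rnorm(4, 0, 1), rnorm(4, 100, 1))
  lt2 <- anovaLSD(v2, g)$letters
  expect_equal(unname(lt2[c("B", "A")]), c("a", "b"))
  expect_error(anovaLSD(rep(5, 8), g), "zero within-group variance")
})

test_that("letter partition recovers known mean structure (simulation)", {
  hits <- 0
  for (seed in 1:100) {
    set.seed(seed)
    v <- c(rnorm(4, 0, 1), rnorm(4, 0, 1), rnorm(4, 5, 1), rnorm(4, 10, 1))
    g <- rep(c("g0a", "g0b", "g5", "g10"), each = 4)
    lt <- anovaLSD(v, g)$letters
    ok <- lt[["g0a"]] == lt[["g0b"]] &&
      !grepl(lt[["g5"]], lt[["g10"]], fixed = TRUE) &&
      lt[["g5"]] != lt[["g0a"]] && lt[["g10"]] != lt[["g0a"]]
    hits <- hits + ok
  }
  # letter-sharing of the two null groups alone passes ~95% of the time;
  # allow binomial noise around that expectation
  expect_gte(hits, 90)
})

test_that("letter displays are consistent with pairwise p-values", {
  for (seed in 1:25) {
    set.seed(seed + 40)
    k <- sample(3:5, 1)
    v <- rnorm(4 * k, mean = rep(runif(k, 0, 4), each = 4))
    g <- rep(paste0("T", 1:k), each = 4)
    fit <- anovaLSD(v, g, alpha = 0.05)
    for (i in names(fit$means)) for (j in names(fit$means)) {
      if (i == j) next
      share <- any(strsplit(fit$letters[[i]], "")[[1]] %in%
                     strsplit(fit$letters[[j]], "")[[1]])
      expect_equal(share, fit$pairwise[i, j] > 0.05)
    }
  }
})

test_that("Venn partition matches brute-force set algebra", {
  com <- fixture_community()
  v <- vennPartition(com)
  expect_equal(length(v$shared_all), sum(v$counts["CK&NM"]))
  expect_equal(sum(v$counts), nrow(com))
  # one genus present in only one treatment
  a <- abundance(com)
  a["Eudorylaimus", treatments(com) == "NM"] <- 0
  com2 <- NemaExperiment(a, treatments(com))
  v2 <- vennPartition(com2)
  expect_equal(unname(v2$unique["CK"]), 1L)
  expect_equal(v2$counts[["CK"]], 1L)
  # random presence fixtures vs. direct set algebra
  for (seed in 1:10) {
    set.seed(seed)
    a3 <- matrix(rbinom(8 * 6, 1, 0.6) * rpois(8 * 6, 3), nrow = 8,
                 dimnames = list(paste0("G", 1:8), paste0("S", 1:6)))
    a3[1, ] <- a3[1, ] + 1   # keep every sample non-empty
    tr3 <- rep(c("X", "Y", "Z"), each = 2)
    com3 <- NemaExperiment(a3, tr3)
    v3 <- vennPartition(com3)
    for (gi in 1:8) {
      pres <- sapply(c("X", "Y", "Z"), function(t)
        sum(a3[gi, tr3 == t]) > 0)
      sig <- if (!any(pres)) "absent" else
        paste(c("X", "Y", "Z")[pres], collapse = "&")
      expect_true(v3$membership[gi, "X"] == pres[["X"]])
      expect_true(sig %in% names(v3$counts))
    }
    expect_equal(sum(v3$counts), 8L)
  }
})

test_that("all-shared communities report no unique genera", {
  d <- fieldContrastDesign(seed = 2)
  com <- generateCommunity(d)
  v <- vennPartition(com)
  if (all(abundance(com) %*% rep(1, ncol(com)) > 0)) {
    expect_equal(sum(v$unique), sum(v$counts[nchar(names(v$counts)) == 2]))
  }
  expect_equal(sum(v$counts), nrow(com))
})

test_that("co-occurrence networks recover constructed correlation pairs", {
  set.seed(5)
  base <- rnorm(50)
  a <- rbind(G1 = base, G2 = base + rnorm(50, 0, 1e-3),
             G3 = -base, G4 = -base + rnorm(50, 0, 1e-3),
             G5 = rnorm(50))
  a <- a - min(a)  # non-negative abundances
  net <- cooccurrenceNetwork(a, rMin = 0.8, pMax = 0.01)
  key <- paste(net$edges$source, net$edges$target)
  expect_true("G1 G2" %in% key)
  expect_true("G3 G4" %in% key)
  pos <- net$edges$sign[match(c("G1 G2", "G3 G4"), key)]
  expect_equal(pos, c("positive", "positive"))
  neg <- net$edges[net$edges$source == "G1" & net$edges$target == "G3", ]
  expect_equal(neg$sign, "negative")
  expect_equal(net$metrics$average_degree,
               2 * net$metrics$edges / net$metrics$nodes)
})

test_that("independent noise yields empty networks at strict thresholds", {
  set.seed(9)
  a <- matrix(rpois(12 * 50, 10), nrow = 12,
              dimnames = list(paste0("G", 1:12), NULL))
  net <- cooccurrenceNetwork(a, rMin = 0.99, pMax = 0.05)
  expect_equal(net$metrics$edges, 0)
  expect_true(is.na(net$metrics$modularity))
  expect_error(cooccurrenceNetwork(a[, 1:3]), "four samples")
})

test_that("network metrics are invariant to sample order", {
  d <- fieldContrastDesign(seed = 4)
  com <- generateCommunity(d)
  a <- abundance(com)
  net1 <- cooccurrenceNetwork(a, rMin = 0.6)
  net2 <- cooccurrenceNetwork(a[, sample(ncol(a))], rMin = 0.6)
  expect_equal(net1$metrics, net2$metrics)
  o1 <- net1$edges[order(net1$edges$source, net1$edges$target), ]
  o2 <- net2$edges[order(net2$edges$source, net2$edges$target), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1[, c("source", "target", "sign")],
               o2[, c("source", "target", "sign")])
})
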