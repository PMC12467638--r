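# Independent direct-summation oracles: plain loops, no reuse of package
# internals. Used to cross-check every index, footprint, and profile value.

oracle_shannon <- function(x) {
  x <- unname(x[x > 0]); N <- sum(x); h <- 0
  for (xi in x) h <- h - (xi / N) * log(xi / N)
  h
}

oracle_lambda <- function(x) {
  x <- unname(x[x > 0]); N <- sum(x); s <- 0
  for (xi in x) s <- s + (xi / N)^2
  s
}

oracle_td <- function(x, group) {
  x <- unname(x)
  N <- sum(x); s <- 0
  for (g in unique(group[x > 0])) {
    pg <- sum(x[group == g]) / N
    s <- s + pg^2
  }
  1 / s
}

oracle_sr <- function(x) {
  x <- unname(x[x > 0]); N <- sum(x)
  if (N <= 1) return(NA_real_)
  (length(x) - 1) / log(N)
}

oracle_wmean_cp <- function(x, cp, sel) {
  x <- unname(x); cp <- unname(cp)
  tot <- sum(x[sel])
  if (tot == 0) return(NA_real_)
  s <- 0
  for (i in which(sel)) s <- s + cp[i] * x[i] / tot
  s
}

oracle_mi <- function(x, cp, group)
  oracle_wmean_cp(x, cp, group %in% c("BF", "FF", "OP") & x > 0)

oracle_ppi <- function(x, cp, group)
  oracle_wmean_cp(x, cp, group == "PP" & x > 0)

oracle_ncr <- function(x, group) {
  x <- unname(x)
  bf <- sum(x[group == "BF"]); ff <- sum(x[group == "FF"])
  if (bf + ff == 0) NA_real_ else bf / (bf + ff)
}

oracle_wi <- function(x, group) {
  x <- unname(x)
  pp <- sum(x[group == "PP"])
  if (pp == 0) return(NA_real_)
  (sum(x[group == "BF"]) + sum(x[group == "FF"])) / pp
}

oracle_footprint_group <- function(x, W, cp, group, which_group) {
  x <- unname(x); W <- unname(W); cp <- unname(cp)
  s <- 0
  for (i in seq_along(x))
    if (group[i] == which_group)
      s <- s + x[i] * (0.1 * W[i] / cp[i] + 0.273 * W[i]^0.75)
  s
}

# guild-restricted footprint sum; guilds = list of c(group, cp) pairs
oracle_footprint_guilds <- function(x, W, cp, group, guilds) {
  x <- unname(x); W <- unname(W); cp <- unname(cp)
  s <- 0
  for (i in seq_along(x))
    for (g in guilds)
      if (group[i] == g[[1]] && cp[i] == as.integer(g[[2]]))
        s <- s + x[i] * (0.1 * W[i] / cp[i] + 0.273 * W[i]^0.75)
  s
}

fe_guild_list <- list(c("BF", 1), c("FF", 2))
fs_guild_list <- c(lapply(3:5, function(k) c("BF", k)),
                   lapply(3:5, function(k) c("FF", k)),
                   lapply(3:5, function(k) c("OP", k)))

# Ferris-convention weighted guild sums for EI/SI
oracle_eisi <- function(x, cp, group) {
  x <- unname(x); cp <- unname(cp)
  e <- b <- s <- 0
  sw <- c("3" = 1.8, "4" = 3.2, "5" = 5.0)
  for (i in seq_along(x)) {
    g <- group[i]; k <- cp[i]
    if (g == "BF" && k == 1) e <- e + 3.2 * x[i]
    if (g == "FF" && k == 2) e <- e + 0.8 * x[i]
    if (g %in% c("BF", "FF") && k == 2) b <- b + 0.8 * x[i]
    if (g %in% c("BF", "FF", "OP") && k >= 3)
      s <- s + sw[as.character(k)] * x[i]
  }
  c(ei = if (e + b > 0) unname(100 * e / (e + b)) else NA_real_,
    si = if (s + b > 0) unname(100 * s / (s + b)) else NA_real_)
}

oracle_bray <- function(x, y) {
  x <- unname(x); y <- unname(y)
  num <- den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  num / den
}

# ANOSIM R by explicit pair loops over a full distance matrix
oracle_anosim_R <- function(dmat, labels) {
  n <- nrow(dmat)
  pairs_d <- c(); pairs_within <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pairs_d <- c(pairs_d, dmat[i, j])
    pairs_within <- c(pairs_within, labels[i] == labels[j])
  }
  rk <- rank(pairs_d)
  (mean(rk[!pairs_within]) - mean(rk[pairs_within])) /
    (n * (n - 1) / 4)
}

# exhaustive permutation p over all distinct 2-group labelings
oracle_anosim_exact_p <- function(dmat, labels) {
  n <- nrow(dmat)
  g1 <- sum(labels == labels[1])
  obs <- oracle_anosim_R(dmat, labels)
  combs <- utils::combn(n, g1)
  rs <- apply(combs, 2, function(idx) {
    lab <- rep("B", n); lab[idx] <- "A"
    oracle_anosim_R(dmat, lab)
  })
  mean(rs >= obs - 1e-12)
}

# seeded random community with full trait coverage (3-30 genera; at least
# one genus per trophic group, c-p spanning 1-5 possible)
random_community <- function(seed, n_samples = 2) {
  set.seed(seed)
  n <- sample(4:30, 1)
  grp <- c("BF", "FF", "PP", "OP",
           sample(c("BF", "FF", "PP", "OP"), n - 4, replace = TRUE))
  cp <- sample(1:5, n, replace = TRUE)
  W <- round(stats::rlnorm(n, log(0.8), 0.7), 4)
  tr <- NemaTraits(sprintf("G%02d", 1:n), grp, cp, W)
  a <- matrix(rpois(n * n_samples, 8) * rbinom(n * n_samples, 1, 0.8),
              nrow = n,
              dimnames = list(rownames(tr),
                              paste0("S", seq_len(n_samples))))
  for (j in seq_len(n_samples)) if (sum(a[, j]) < 2) a[1, j] <- a[1, j] + 5
  NemaExperiment(a, treatment = rep("CK", n_samples), traits = tr)
}

# small deterministic fixture shared across tests
fixture_community <- function() {
  tr <- NemaTraits(
    genus = c("Filenchus", "Cephalobus", "Acrobeles", "Pratylenchus",
              "Eudorylaimus", "Aphelenchus"),
    trophic_group = c("FF", "BF", "BF", "PP", "OP", "FF"),
    cp_value = c(2L, 2L, 1L, 3L, 4L, 2L),
    biomass = c(0.40, 0.65, 0.25, 1.10, 3.20, 0.30))
  a <- matrix(c(30, 25, 20, 15, 5, 5,
                10, 40, 30, 10, 8, 2,
                20, 20, 20, 20, 10, 10,
                 5, 10,  5, 60, 2, 18),
              nrow = 6,
              dimnames = list(rownames(tr), c("S1", "S2", "S3", "S4")))
  NemaExperiment(a, treatment = c("CK", "CK", "NM", "NM"), traits = tr)
}
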