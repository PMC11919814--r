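# Shared fixtures and independent oracles, all built in code.

# A corpus of >= 50 names spanning every registry class and all separator
# dialects. Deterministic.
fixture_corpus <- function() {
  c(
    # species level, one per registry class
    "TAG 48:0", "DAG 36:2", "MG 18:1", "PC 34:1", "PE 38:4", "PS 36:1",
    "PI 38:5", "PG 34:2", "PA 36:3", "LPC 18:0", "LPE 18:1", "LPS 18:0",
    "LPI 18:1", "LPG 16:0", "LPA 16:0", "SM 34:1", "Cer 34:1",
    "HexCer 40:1", "CE 18:2", "FA 16:0",
    # synonyms and parenthesized dialect
    "TG 52:3", "DG(34:1)", "MAG 16:0", "LysoPC 16:0", "GlcCer 42:2",
    "FFA 18:1", "CE(20:4)",
    # molecular species with every separator
    "PE 18:0_20:4", "PC 16:0/18:1", "PA 16:0-18:2", "PS 18:0_18:1",
    "PI 18:0/20:3", "PG 16:1_18:1", "TAG 16:0_18:1_18:1",
    "TG 14:0/16:0/18:1", "DAG 16:0_18:2", "MG 20:4",
    # ether lipids
    "PC O-36:4", "PC O-16:1-20:3", "PC P-38:4", "PE O-34:2",
    "PE P-36:1", "LPC O-18:1", "PC(O-16:0/18:1)",
    # sphingoid chains with hydroxyl prefixes
    "Cer d18:1/16:0", "SM d18:1_18:0", "HexCer d18:1/24:1",
    "Cer t18:0/22:0", "SM(d18:1/16:0)",
    # stated-total dialect
    "TAG 52:2(16:0_18:1_18:1)", "PC 34:1(16:0/18:1)"
  )
}

# Groups of dialect variants that must collapse to one canonical name.
dialect_variants <- function() {
  list(
    c("TAG 48:0", "TG 48:0", "TAG(48:0)", "TG(48:0)"),
    c("PC O-16:1-20:3", "PC O-16:1_20:3", "PC O-20:3/16:1",
      "PC(O-16:1/20:3)", "PC O\u2013 16:1\u201320:3"),
    c("PE 18:0_20:4", "PE 18:0/20:4", "PE 20:4-18:0", "PE(18:0/20:4)"),
    c("Cer d18:1/16:0", "Cer 16:0_d18:1", "Cer(d18:1/16:0)"),
    c("LPC 18:0", "LysoPC 18:0", "LPC(18:0)"),
    c("DAG 16:0_18:2", "DG 18:2/16:0")
  )
}

# Small deterministic experiment on the log2 scale (values chosen by hand).
toy_experiment <- function() {
  mat <- rbind(
    "TAG 48:0" = c(4, 5, 6, 1, 2, 3),
    "TAG 50:1" = c(2, 2, 3, 2, 3, 2),
    "PC 34:1"  = c(5, 5, 5, 5, 5, 5),
    "PE 38:4"  = c(3, 4, 3, 6, 5, 7)
  )
  colnames(mat) <- c("case_1", "case_2", "case_3", "ctl_1", "ctl_2", "ctl_3")
  groups <- c(rep("case", 3), rep("control", 3))
  names(groups) <- colnames(mat)
  new_experiment(mat, groups)
}

# Random experiment for property tests: n_lipids parseable names,
# n/group samples, N(mu, sd) log2 values, optional planted shift on a
# subset of case columns.
random_experiment <- function(n_lipids = 30, n_per_group = 5, seed = 1,
                              shift_rows = integer(0), shift = 0) {
  set.seed(seed)
  classes <- c("TAG", "PC", "PE", "SM", "Cer", "CE")
  nm <- character(0)
  while (length(unique(nm)) < n_lipids) {
    nm <- unique(c(nm, paste0(sample(classes, n_lipids, TRUE), " ",
                              sample(30:50, n_lipids, TRUE), ":",
                              sample(0:6, n_lipids, TRUE))))
  }
  nm <- nm[seq_len(n_lipids)]
  n <- 2 * n_per_group
  mat <- matrix(rnorm(n_lipids * n, 10, 1), n_lipids, n)
  groups <- c(rep("case", n_per_group), rep("control", n_per_group))
  if (length(shift_rows) > 0) {
    mat[shift_rows, groups == "case"] <- mat[shift_rows, groups == "case"] + shift
  }
  rownames(mat) <- nm
  colnames(mat) <- paste0("s", seq_len(n))
  names(groups) <- colnames(mat)
  new_experiment(mat, groups)
}

# Independent brute-force running-sum enrichment score (literal loop, kept
# separate from the package's vectorized implementation).
oracle_es <- function(stat, hit, weight_p) {
  N <- length(stat)
  nh <- sum(hit)
  denom <- sum(abs(stat[hit])^weight_p)
  run <- 0
  hi <- -Inf
  lo <- Inf
  for (i in seq_len(N)) {
    if (hit[i]) {
      run <- run + if (denom > 0) abs(stat[i])^weight_p / denom else 1 / nh
    } else {
      run <- run - 1 / (N - nh)
    }
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  if (hi >= -lo - 1e-12) hi else lo
}

# Independent step-up BH oracle.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hypergeometric upper-tail oracle by direct enumeration of the density.
oracle_hyper_tail <- function(N, K, n, a) {
  ks <- a:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
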