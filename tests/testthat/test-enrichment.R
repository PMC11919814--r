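de_from <- function(features, direction) {
  d <- data.table::data.table(
    feature = features, mean_case = 0, mean_control = 0, log2_fc = 0,
    statistic = 0, p_value = 0.5, fdr = 0.5, direction = direction)
  data.table::setattr(d, "class", c("differential_result", class(d)))
  d
}

test_that("characteristic-derived sets match a group-by oracle and split ethers", {
  nms <- c("TAG 48:0", "TAG 50:1", "PC 34:1", "PC O-36:4", "PC O-34:2",
           "Cer d18:1/16:0")
  rec <- characterize(recognize_batch(nms)$parsed)
  sets <- derive_lipid_sets(rec, "class")
  expect_setequal(names(sets$sets), c("TAG", "PC", "PC O-", "Cer"))
  expect_setequal(sets$sets[["PC O-"]], c("PC O-36:4", "PC O-34:2"))
  # the class sets partition the universe
  expect_setequal(unlist(sets$sets), rec$canonical_name)

  binned <- derive_lipid_sets(rec, "total_carbons_bin")
  for (nm in names(binned$sets)) {
    rng <- as.integer(strsplit(sub("^C", "", nm), "-")[[1]])
    members <- rec[rec$canonical_name %in% binned$sets[[nm]], ]
    expect_true(all(members$total_carbons >= rng[1] &
                      members$total_carbons <= rng[2]))
  }
})

test_that("user set files load and drop unknown members", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("storage\tneutral lipids\tTAG 48:0\tTAG 50:1\tNOPE 1:1",
               "membrane\tphospholipids\tPC 34:1\tPE 38:4"), path)
  sets <- read_lipid_sets(path, universe = c("TAG 48:0", "TAG 50:1",
                                             "PC 34:1", "PE 38:4"))
  expect_equal(length(sets$sets), 2L)
  expect_equal(sets$dropped, "NOPE 1:1")
  expect_setequal(sets$sets$storage, c("TAG 48:0", "TAG 50:1"))
})

test_that("ORA reproduces the exact hypergeometric tail on a worked example", {
  universe <- sprintf("L%02d", 1:20)
  de <- de_from(universe, ifelse(seq_along(universe) <= 6, "up", "ns"))
  # set of 5 overlapping the 6-feature query in 4
  set_members <- universe[c(1, 2, 3, 4, 7)]
  sets <- structure(list(sets = list(S = set_members), source = "user_file",
                         dropped = character(0)),
                    class = "lipid_set_collection")
  res <- ora(de, sets, "up")
  expect_equal(res$overlap, 4L)
  expect_equal(res$p_value, 540 / 38760, tolerance = 1e-12)
  expect_equal(res$p_value, oracle_hyper_tail(20, 5, 6, 4), tolerance = 1e-14)

  # empty query: p = 1 everywhere, flagged
  de0 <- de_from(universe, rep("ns", 20))
  res0 <- ora(de0, sets, "up")
  expect_equal(res0$p_value, 1)
  expect_true(attr(res0, "empty_query"))

  # set identical to the query reaches the minimal achievable p
  de_q <- de_from(universe, ifelse(seq_along(universe) <= 5, "up", "ns"))
  sets_q <- structure(list(sets = list(S = universe[1:5]),
                           source = "user_file", dropped = character(0)),
                      class = "lipid_set_collection")
  res_q <- ora(de_q, sets_q, "up")
  expect_equal(res_q$p_value, oracle_hyper_tail(20, 5, 5, 5), tolerance = 1e-14)
})

test_that("ORA equals tail enumeration across random configurations", {
  set.seed(7)
  for (i in 1:300) {
    N <- sample(10:60, 1)
    universe <- sprintf("L%03d", 1:N)
    qs <- sample(0:N, 1)
    ms <- sample(1:N, 1)
    de <- de_from(universe, ifelse(seq_len(N) %in% sample(N, qs), "up", "ns"))
    sets <- structure(list(sets = list(S = sample(universe, ms)),
                           source = "user_file", dropped = character(0)),
                      class = "lipid_set_collection")
    res <- ora(de, sets, "up")
    if (qs == 0) { expect_equal(res$p_value, 1); next }
    a <- res$overlap
    expect_equal(res$p_value, oracle_hyper_tail(N, ms, qs, a),
                 tolerance = 1e-12)
  }
})

test_that("LSEA endpoints: a set at the head scores +1, at the tail -1 (weight 0)", {
  ranked <- data.frame(lipid = sprintf("L%02d", 1:20),
                       statistic = seq(10, -9))
  top <- structure(list(sets = list(S = sprintf("L%02d", 1:5)),
                        source = "user_file", dropped = character(0)),
                   class = "lipid_set_collection")
  bottom <- structure(list(sets = list(S = sprintf("L%02d", 16:20)),
                           source = "user_file", dropped = character(0)),
                      class = "lipid_set_collection")
  rt <- lsea(ranked, top, weight_p = 0, n_perm = 100, seed = 1)
  rb <- lsea(ranked, bottom, weight_p = 0, n_perm = 100, seed = 1)
  expect_equal(rt$es, 1)
  expect_equal(rt$direction, "up")
  expect_equal(rb$es, -1)
  expect_equal(rb$direction, "down")
})

test_that("LSEA ES matches the brute-force running-sum oracle", {
  set.seed(23)
  for (i in 1:100) {
    N <- 50
    stat <- sort(rnorm(N, 0, 2), decreasing = TRUE)
    lip <- sprintf("L%02d", 1:N)
    hit_idx <- sample(N, 10)
    wp <- sample(c(0, 1, 1.5), 1)
    sets <- structure(list(sets = list(S = lip[hit_idx]),
                           source = "user_file", dropped = character(0)),
                      class = "lipid_set_collection")
    res <- lsea(data.frame(lipid = lip, statistic = stat), sets,
                weight_p = wp, n_perm = 100, seed = i)
    expect_equal(res$es, oracle_es(stat, seq_len(N) %in% hit_idx, wp),
                 tolerance = 1e-12)
    expect_true(abs(res$es) <= 1 + 1e-12)
    expect_true(res$p_value >= 1 / 101 && res$p_value <= 1)
  }
})

test_that("LSEA is reproducible given a seed and respects size filters", {
  set.seed(77)
  exp <- random_experiment(n_lipids = 40, n_per_group = 5, seed = 19)
  de <- differential_species(exp)
  rec <- characterize(recognize_batch(exp$lipid_names)$parsed)
  sets <- derive_lipid_sets(rec, "class")
  ranked <- data.frame(lipid = de$feature, statistic = de$statistic)
  a <- lsea(ranked, sets, n_perm = 200, seed = 5)
  b <- lsea(ranked, sets, n_perm = 200, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  small <- structure(list(sets = list(tiny = de$feature[1:2]),
                          source = "user_file", dropped = character(0)),
                     class = "lipid_set_collection")
  expect_error(lsea(ranked, small, n_perm = 100, seed = 1), "size filters")
  expect_error(lsea(ranked, sets, n_perm = 10, seed = 1), "at least 100")
  expect_error(lsea(rbind(ranked, ranked[1, ]), sets, n_perm = 100, seed = 1),
               "duplicated")
})
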