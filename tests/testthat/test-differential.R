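test_that("Welch species test agrees with stats::t.test on a printed 3v3 toy", {
  exp <- toy_experiment()
  de <- differential_species(exp)
  row <- de[de$feature == "TAG 48:0", ]
  expect_equal(row$log2_fc, 3)
  oracle <- t.test(c(4, 5, 6), c(1, 2, 3), var.equal = FALSE)
  expect_equal(row$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(row$p_value, oracle$p.value, tolerance = 1e-12)
  # identical case and control values -> zero effect, ns
  flat <- de[de$feature == "PC 34:1", ]
  expect_equal(flat$log2_fc, 0)
  expect_equal(flat$direction, "ns")
  # fdr >= p everywhere
  expect_true(all(de$fdr >= de$p_value - 1e-15))
})

test_that("group-label swap negates effects and preserves p-values", {
  exp <- random_experiment(n_lipids = 40, n_per_group = 6, seed = 4,
                           shift_rows = 1:8, shift = 1.5)
  swapped <- new_experiment(exp$matrix,
                            setNames(ifelse(exp$group_of == "case",
                                            "control", "case"),
                                     names(exp$group_of)))
  a <- differential_species(exp)
  b <- differential_species(swapped)
  expect_identical(a$feature, b$feature)
  expect_identical(a$log2_fc, -b$log2_fc)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$direction == "up", b$direction == "down")
})

test_that("BH adjustment matches a step-up brute-force oracle", {
  set.seed(99)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_lt(max(abs(p.adjust(p, "BH") - oracle_bh(p))), 1e-12)
  }
})

test_that("the Wilcoxon option and the zero-variance fallback behave", {
  exp <- toy_experiment()
  dw <- differential_species(exp, test = "wilcoxon")
  o <- suppressWarnings(wilcox.test(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(dw$p_value[dw$feature == "TAG 48:0"], o$p.value)
  # constant-in-both-groups lipid triggers the exact-comparison fallback
  d <- differential_species(exp)
  expect_true("PC 34:1" %in% attr(d, "fallback_features"))
  expect_true(all(d$p_value >= 0 & d$p_value <= 1))
})

test_that("characteristic-level testing inherits the machinery", {
  exp <- toy_experiment()
  rec <- characterize(recognize_batch(exp$lipid_names)$parsed)
  cm <- aggregate_by_characteristic(exp, rec, "class")
  dc <- differential_characteristic(exp, cm)
  expect_setequal(dc$feature, c("TAG", "PC", "PE"))
  # single-level characteristic: BH with m = 1 leaves p untouched
  cat_m <- aggregate_by_characteristic(exp, rec, "ether_type")
  d1 <- differential_characteristic(exp, cat_m)
  expect_equal(d1$fdr, d1$p_value)
})

test_that("a planted two-fold class shift is recovered at the class level", {
  set.seed(31)
  found <- 0L
  for (rep in 1:5) {
    exp <- random_experiment(n_lipids = 60, n_per_group = 10,
                             seed = 100 + rep)
    tag_rows <- which(grepl("^TAG ", exp$lipid_names))
    mat <- exp$matrix
    mat[tag_rows, exp$group_of == "case"] <-
      mat[tag_rows, exp$group_of == "case"] + 1
    exp2 <- new_experiment(mat, exp$group_of)
    rec <- characterize(recognize_batch(exp2$lipid_names)$parsed)
    cm <- aggregate_by_characteristic(exp2, rec, "class")
    dc <- differential_characteristic(exp2, cm, fc_cut = 0.5)
    tag <- dc[dc$feature == "TAG", ]
    if (abs(tag$log2_fc - 1) < 0.35 && tag$fdr < 0.05) found <- found + 1L
  }
  expect_gte(found, 4L)
})

test_that("the dual grid partitions the class and reduces to species results", {
  exp <- toy_experiment()
  rec <- characterize(recognize_batch(exp$lipid_names)$parsed)
  grid <- dual_characteristic_grid(exp, rec, "TAG")
  # cell_n covers every analyzed species of the class exactly once
  expect_equal(sum(grid$cell_n), 2L)
  de <- differential_species(exp)
  # one species per cell: cell value equals that species' log2 fold change
  expect_equal(unname(grid$cell_value["48", "0"]),
               de$log2_fc[de$feature == "TAG 48:0"])
  expect_equal(unname(grid$cell_value["50", "1"]),
               de$log2_fc[de$feature == "TAG 50:1"])
  # significance implies small fdr
  expect_true(all(grid$cell_fdr[grid$significant] < grid$alpha, na.rm = TRUE))
  expect_error(dual_characteristic_grid(exp, rec, "CE"), "no species")
})

test_that("a corner-confined planted shift is flagged in expectation, not elsewhere", {
  # shift +2 log2 on TAG species with C <= 50 and DB <= 2 only; across
  # seeds the flagged cells concentrate in exactly that corner
  corner_rate <- ncorner_rate <- numeric(20)
  for (s in 1:20) {
    spec <- sim_spec(
      n_lipids_per_class = c(TAG = 40, PC = 20, PE = 20),
      planted_effects = list(list(class = "TAG", max_carbons = 50,
                                  max_double_bonds = 2, shift = 2)),
      seed = 7000 + s)
    sim <- generate_experiment(spec)
    exp <- preprocess(sim$abundance, sim$metadata)
    rec <- characterize(recognize_batch(exp$lipid_names)$parsed)
    g <- as.data.frame(dual_characteristic_grid(exp, rec, "TAG")$cells)
    corner <- g$total_carbons <= 50 & g$total_double_bonds <= 2
    corner_rate[s] <- mean(g$significant[corner])
    ncorner_rate[s] <- mean(g$significant[!corner])
  }
  expect_lte(mean(ncorner_rate), 0.05)             # unshifted cells stay quiet
  expect_gt(mean(corner_rate) - mean(ncorner_rate), 0.3)
})

test_that("top-k selection matches a brute-force sort oracle", {
  set.seed(12)
  for (rep in 1:20) {
    n <- 50
    fake <- data.table::data.table(
      feature = sprintf("L%02d", 1:n),
      mean_case = 0, mean_control = 0,
      log2_fc = round(rnorm(n), 2),
      statistic = rnorm(n),
      p_value = runif(n),
      fdr = round(runif(n), 2),
      direction = sample(c("up", "down", "ns"), n, TRUE)
    )
    data.table::setattr(fake, "class",
                        c("differential_result", class(fake)))
    got <- top_k_table(fake, 5)
    for (dir in c("up", "down")) {
      sub <- as.data.frame(fake)[fake$direction == dir, ]
      sub <- sub[order(-abs(sub$log2_fc), sub$fdr, sub$feature), ]
      expect_equal(got[[dir]]$feature, head(sub$feature, 5))
    }
  }
  # no significant features -> empty lists
  none <- fake[fake$direction == "nothing", ]
  data.table::setattr(none, "class", c("differential_result", class(none)))
  empty <- top_k_table(none, 10)
  expect_equal(nrow(empty$up), 0L)
  expect_equal(nrow(empty$down), 0L)
})
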