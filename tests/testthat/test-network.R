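test_that("the curated default graph is well-formed and covers the core routes", {
  g <- builtin_reaction_graph()
  key <- paste(g$edges$substrate, g$edges$product, sep = ">")
  expected <- c("PA>DAG", "DAG>TAG", "TAG>DAG", "DAG>PC", "DAG>PE", "PE>PC",
                "PC>PE", "PE>PS", "PS>PE", "PC>PA", "PC>LPC", "PE>LPE",
                "Cer>SM", "SM>Cer", "Cer>HexCer")
  expect_true(all(expected %in% key))
  expect_true(all(g$edges$substrate != g$edges$product))
  expect_true(all(c(g$edges$substrate, g$edges$product) %in%
                    default_class_registry()$class_code))
})

test_that("user graphs are validated against the class registry", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("substrate\tproduct\tlabel", "PC\tPE\tx", "PE\tNOPE\ty"), path)
  expect_error(read_reaction_graph(path), "NOPE")
  writeLines(c("substrate\tproduct\tlabel", "PC\tPC\tx"), path)
  expect_error(read_reaction_graph(path), "self-loops")
  writeLines(c("substrate\tproduct\tlabel", "PC\tPE\tx", "PE\tPC\ty"), path)
  g <- read_reaction_graph(path)
  expect_equal(nrow(g$edges), 2L)
})

# 3v3 experiment with hand-chosen class totals: PC 2,2,2 (case) / 4,4,4
# (control), PE constant 4 everywhere.
ratio_toy <- function() {
  mat <- rbind("PC 34:1" = log2(c(2, 2, 2, 4, 4, 4)),
               "PE 38:4" = log2(c(4, 4, 4, 4, 4, 4)))
  colnames(mat) <- paste0("s", 1:6)
  g <- setNames(rep(c("case", "control"), each = 3), colnames(mat))
  new_experiment(mat, g)
}

test_that("edge activity reproduces hand-computed log-ratios and the degenerate fallback", {
  exp <- ratio_toy()
  rec <- characterize(recognize_batch(exp$lipid_names)$parsed)
  graph <- reaction_graph(data.frame(substrate = "PE", product = "PC",
                                     label = "PEMT"))
  expect_warning(act <- edge_activity(exp, rec, graph), "degenerate")
  lr <- attr(act, "log_ratios")
  expect_equal(unname(lr["PE->PC", ]), c(-1, -1, -1, 0, 0, 0))
  # point-mass ratios: sentinel z with the sign of the mean difference
  expect_lt(act$z_score, 0)
  expect_equal(act$call, "repressed")

  # identical groups give z = 0, neutral
  mat0 <- exp$matrix
  mat0["PC 34:1", ] <- log2(4)
  exp0 <- new_experiment(mat0, exp$group_of)
  expect_warning(act0 <- edge_activity(exp0, rec, graph), "degenerate")
  expect_equal(act0$z_score, 0)
  expect_equal(act0$call, "neutral")
})

test_that("group swap negates z-scores and path scores exactly", {
  exp <- random_experiment(n_lipids = 40, n_per_group = 6, seed = 13)
  rec <- characterize(recognize_batch(exp$lipid_names)$parsed)
  swapped <- new_experiment(exp$matrix,
                            setNames(ifelse(exp$group_of == "case",
                                            "control", "case"),
                                     names(exp$group_of)))
  a <- edge_activity(exp, rec)
  b <- edge_activity(swapped, rec)
  expect_identical(a$z_score, -b$z_score)
  expect_identical(a$p_value, b$p_value)
  pa <- pathway_activity(a)
  pb <- pathway_activity(b)
  expect_identical(pa$path, pb$path)
  expect_identical(pa$score, -pb$score)
})

test_that("edges with absent classes are skipped with a log entry", {
  exp <- ratio_toy()
  rec <- characterize(recognize_batch(exp$lipid_names)$parsed)
  graph <- reaction_graph(data.frame(substrate = c("PE", "Cer"),
                                     product = c("PC", "SM")))
  act <- suppressWarnings(edge_activity(exp, rec, graph))
  expect_equal(nrow(act), 1L)
  expect_equal(attr(act, "skipped_edges"), "Cer->SM")
})

test_that("path scores match an exhaustive igraph simple-path oracle", {
  set.seed(55)
  for (rep in 1:12) {
    n_nodes <- sample(4:7, 1)
    nodes <- c("PC", "PE", "PS", "PA", "TAG", "DAG", "Cer")[seq_len(n_nodes)]
    pairs <- expand.grid(s = nodes, p = nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$s != pairs$p, ]
    pairs <- pairs[runif(nrow(pairs)) < 0.4, ]
    if (nrow(pairs) == 0) next
    act <- data.table::data.table(substrate = pairs$s, product = pairs$p,
                                  label = "", z_score = rnorm(nrow(pairs)),
                                  p_value = 0.5, call = "neutral")
    data.table::setattr(act, "class", c("edge_activity", class(act)))
    got <- pathway_activity(act, max_path_len = 4)

    ig <- igraph::graph_from_data_frame(pairs[, c("s", "p")], directed = TRUE)
    zl <- setNames(act$z_score, paste(act$substrate, act$product, sep = ">"))
    oracle <- list()
    for (from in nodes) for (to in setdiff(nodes, from)) {
      if (!from %in% igraph::V(ig)$name || !to %in% igraph::V(ig)$name) next
      sp <- igraph::all_simple_paths(ig, from, to, cutoff = 4)
      for (pth in sp) {
        nm <- igraph::V(ig)$name[pth]
        zz <- zl[paste(nm[-length(nm)], nm[-1], sep = ">")]
        oracle[[paste(nm, collapse = "->")]] <- mean(zz)
      }
    }
    expect_equal(sort(got$path), sort(names(oracle)))
    expect_equal(got$score[match(names(oracle), got$path)],
                 unname(unlist(oracle)), tolerance = 1e-12)
    # ordering and highlighting contract
    expect_true(all(diff(abs(got$score)) <= 1e-12))
    expect_identical(got$highlighted, abs(got$score) > 1.5)
  }
})

test_that("all-zero activities highlight nothing; single edges score themselves", {
  act <- data.table::data.table(substrate = c("PE", "PC"),
                                product = c("PC", "PA"), label = "",
                                z_score = c(0, 0), p_value = 1,
                                call = "neutral")
  data.table::setattr(act, "class", c("edge_activity", class(act)))
  p <- pathway_activity(act)
  expect_false(any(p$highlighted))
  act$z_score <- c(2.5, -0.5)
  p2 <- pathway_activity(act)
  expect_equal(p2$score[p2$path == "PE->PC"], 2.5)
  expect_equal(p2$score[p2$path == "PE->PC->PA"], 1.0)
})

test_that("GraphML export round-trips through igraph", {
  exp <- random_experiment(n_lipids = 40, n_per_group = 5, seed = 99)
  rec <- characterize(recognize_batch(exp$lipid_names)$parsed)
  act <- edge_activity(exp, rec)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(act, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(act))
  expect_equal(sort(igraph::edge_attr(g, "z_score")), sort(act$z_score),
               tolerance = 1e-9)
})
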