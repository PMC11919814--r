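# Two-group differential analysis at species and characteristic level, plus
# the per-class chain-length x double-bond grid.

# Internal testing engine shared by all levels: rows of `mat` (log2 scale)
# are features, columns samples. Welch t is vectorized across rows; the
# Wilcoxon rank-sum test is exact where sample sizes permit. Rows with zero
# within-group variance under Welch fall back to the exact Wilcoxon
# comparison (recorded in the "fallback_features" attribute).
diff_test_matrix <- function(mat, groups, test = c("welch_t", "wilcoxon"),
                             alpha = 0.05, fc_cut = 1) {
  test <- match.arg(test)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (fc_cut < 0) stop("fc_cut must be nonnegative")
  ci <- which(groups == "case")
  ki <- which(groups == "control")
  if (length(ci) < 2L || length(ki) < 2L) stop("each group needs >= 2 samples")
  Xc <- mat[, ci, drop = FALSE]
  Xk <- mat[, ki, drop = FALSE]
  m1 <- rowMeans(Xc); m2 <- rowMeans(Xk)
  lfc <- m1 - m2
  n1 <- length(ci); n2 <- length(ki)
  fallback <- character(0)

  wilcox_row <- function(i) {
    wt <- suppressWarnings(stats::wilcox.test(Xc[i, ], Xk[i, ],
                                              alternative = "two.sided"))
    # complete ties leave the normal approximation undefined: no evidence
    p <- wt$p.value
    if (is.na(p)) p <- 1
    c(stat = unname(wt$statistic), p = p)
  }

  if (test == "welch_t") {
    v1 <- apply(Xc, 1L, stats::var)
    v2 <- apply(Xk, 1L, stats::var)
    se2 <- v1 / n1 + v2 / n2
    stat <- rep(NA_real_, nrow(mat)); p <- rep(NA_real_, nrow(mat))
    ok <- se2 > 0
    stat[ok] <- lfc[ok] / sqrt(se2[ok])
    df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
    p[ok] <- 2 * stats::pt(-abs(stat[ok]), df)
    if (any(!ok)) {
      fallback <- rownames(mat)[!ok]
      for (i in which(!ok)) {
        wr <- wilcox_row(i)
        stat[i] <- wr["stat"]; p[i] <- wr["p"]
      }
    }
  } else {
    res <- vapply(seq_len(nrow(mat)), wilcox_row, numeric(2))
    stat <- res["stat", ]; p <- res["p", ]
  }

  fdr <- stats::p.adjust(p, method = "BH")
  direction <- rep("ns", nrow(mat))
  direction[fdr < alpha & lfc > fc_cut] <- "up"
  direction[fdr < alpha & lfc < -fc_cut] <- "down"
  out <- data.table::data.table(
    feature = rownames(mat),
    mean_case = m1, mean_control = m2, log2_fc = lfc,
    statistic = stat, p_value = p, fdr = fdr, direction = direction
  )
  data.table::setattr(out, "class", c("differential_result", class(out)))
  data.table::setattr(out, "test", test)
  data.table::setattr(out, "alpha", alpha)
  data.table::setattr(out, "fc_cut", fc_cut)
  data.table::setattr(out, "fallback_features", fallback)
  out[]
}

#' Species-level differential abundance
#'
#' Tests every lipid species for a between-group difference of its log2
#' abundance with a two-sided Welch t test (default) or Wilcoxon rank-sum
#' test, adjusts p-values by Benjamini-Hochberg across all species, and
#' calls each species `up` / `down` / `ns` by the joint FDR and fold-change
#' rule (`fdr < alpha` and `|log2_fc| > fc_cut`).
#'
#' Under Welch, a species with zero variance in both groups is compared by
#' the exact Wilcoxon test instead (division by a zero standard error is
#' never performed); the affected features are listed in the
#' `fallback_features` attribute.
#'
#' @param exp A preprocessed `lipid_experiment` (log2 scale).
#' @param test `"welch_t"` or `"wilcoxon"`.
#' @param alpha BH-FDR significance threshold (default 0.05).
#' @param fc_cut Minimal `|log2_fc|` for an up/down call (default 1, i.e.
#'   two-fold).
#' @return A `differential_result` data.table with one row per species:
#'   `feature`, `mean_case`, `mean_control`, `log2_fc` (case minus control
#'   on the log2 scale), `statistic`, `p_value`, `fdr`, `direction`.
#' @export
differential_species <- function(exp, test = c("welch_t", "wilcoxon"),
                                 alpha = 0.05, fc_cut = 1) {
  stopifnot(inherits(exp, "lipid_experiment"))
  diff_test_matrix(exp$matrix, exp$group_of, test = match.arg(test),
                   alpha = alpha, fc_cut = fc_cut)
}

#' Characteristic-level differential abundance
#'
#' Applies the species-level testing machinery to the log2 of a
#' characteristic-aggregated abundance matrix (see
#' [aggregate_by_characteristic()]); BH adjustment is performed within the
#' characteristic's levels.
#'
#' @param exp The `lipid_experiment` the aggregation came from (supplies
#'   the group assignment).
#' @param charmatrix A `characteristic_matrix`.
#' @inheritParams differential_species
#' @return A `differential_result` with one row per characteristic level.
#' @export
differential_characteristic <- function(exp, charmatrix,
                                        test = c("welch_t", "wilcoxon"),
                                        alpha = 0.05, fc_cut = 1) {
  stopifnot(inherits(exp, "lipid_experiment"),
            inherits(charmatrix, "characteristic_matrix"))
  if (!identical(charmatrix$samples, exp$samples)) {
    stop("characteristic matrix and experiment have different samples")
  }
  if (any(charmatrix$values <= 0)) {
    stop("aggregated abundances must be strictly positive for the log2 scale")
  }
  diff_test_matrix(log2(charmatrix$values), exp$group_of,
                   test = match.arg(test), alpha = alpha, fc_cut = fc_cut)
}

#' Dual-characteristic grid: chain length x double bonds within a class
#'
#' For one lipid class, bins its species into cells indexed by total chain
#' carbons (x) and total double bonds (y). Each cell reports the mean
#' species-level log2 fold change of its members, and a p-value from
#' testing the cell's summed (linear) abundance between groups, BH-adjusted
#' across the non-empty cells of the grid.
#'
#' @param exp A preprocessed `lipid_experiment`.
#' @param records `characteristic_records` covering the experiment lipids.
#' @param lipid_class Class code, e.g. `"TAG"`. An ether-qualified label
#'   such as `"PC O-"` restricts the grid to the ether variant; a plain
#'   code covers all variants of the class.
#' @param alpha BH-FDR threshold for the per-cell significance flag.
#' @param test Test applied to the summed cell abundance.
#' @return A `dual_grid` object: `lipid_class`, `x_levels` (carbons),
#'   `y_levels` (double bonds), matrices `cell_value`, `cell_p`,
#'   `cell_fdr` (NA for empty cells), `cell_n` (0 for empty cells),
#'   `significant` (FALSE for empty cells), and `cells`, a long-format
#'   data.table of the non-empty cells.
#' @export
dual_characteristic_grid <- function(exp, records, lipid_class,
                                     alpha = 0.05,
                                     test = c("welch_t", "wilcoxon")) {
  stopifnot(inherits(exp, "lipid_experiment"))
  test <- match.arg(test)
  idx <- match(exp$lipid_names, records$canonical_name)
  lm <- regmatches(lipid_class, regexec("^(.+) ([OP])-$", lipid_class))[[1L]]
  if (length(lm) > 0L) {
    in_class <- !is.na(idx) & records$lipid_class[idx] == lm[2L] &
      records$ether_type[idx] == lm[3L]
  } else {
    in_class <- !is.na(idx) & records$lipid_class[idx] == lipid_class
  }
  if (!any(in_class)) stop("no species of class ", lipid_class, " in the experiment")
  rec <- records[idx[in_class], ]
  sub <- exp$matrix[in_class, , drop = FALSE]

  ci <- exp$group_of == "case"
  lfc <- rowMeans(sub[, ci, drop = FALSE]) - rowMeans(sub[, !ci, drop = FALSE])

  xs <- sort(unique(rec$total_carbons))
  ys <- sort(unique(rec$total_double_bonds))
  key <- paste(rec$total_carbons, rec$total_double_bonds)
  cells <- split(seq_len(nrow(sub)), key)

  # one summed-abundance profile per non-empty cell, tested like a feature
  cell_mat <- do.call(rbind, lapply(cells, function(rows) {
    log2(colSums(2^sub[rows, , drop = FALSE]))
  }))
  rownames(cell_mat) <- names(cells)
  ct <- diff_test_matrix(cell_mat, exp$group_of, test = test, alpha = alpha,
                         fc_cut = 0)

  dims <- list(as.character(xs), as.character(ys))
  empty_num <- matrix(NA_real_, length(xs), length(ys), dimnames = dims)
  cell_value <- cell_p <- cell_fdr <- empty_num
  cell_n <- matrix(0L, length(xs), length(ys), dimnames = dims)
  significant <- matrix(FALSE, length(xs), length(ys), dimnames = dims)

  parts <- strsplit(names(cells), " ", fixed = TRUE)
  for (j in seq_along(cells)) {
    xi <- parts[[j]][1L]; yi <- parts[[j]][2L]
    cell_value[xi, yi] <- mean(lfc[cells[[j]]])
    cell_n[xi, yi] <- length(cells[[j]])
    row <- which(ct$feature == names(cells)[j])
    cell_p[xi, yi] <- ct$p_value[row]
    cell_fdr[xi, yi] <- ct$fdr[row]
    significant[xi, yi] <- ct$fdr[row] < alpha
  }

  long <- data.table::data.table(
    lipid_class = lipid_class,
    total_carbons = as.integer(vapply(parts, `[`, character(1), 1L)),
    total_double_bonds = as.integer(vapply(parts, `[`, character(1), 2L)),
    mean_log2_fc = vapply(seq_along(cells), function(j) mean(lfc[cells[[j]]]), numeric(1)),
    n_species = lengths(cells),
    p_value = ct$p_value[match(names(cells), ct$feature)],
    fdr = ct$fdr[match(names(cells), ct$feature)]
  )
  long$significant <- long$fdr < alpha
  data.table::setorder(long, total_carbons, total_double_bonds)

  structure(
    list(lipid_class = lipid_class, x_levels = xs, y_levels = ys,
         cell_value = cell_value, cell_p = cell_p, cell_fdr = cell_fdr,
         cell_n = cell_n, significant = significant, alpha = alpha,
         cells = long),
    class = "dual_grid"
  )
}

#' @export
print.dual_grid <- function(x, ...) {
  cat("<dual_grid> ", x$lipid_class, ": ", length(x$x_levels),
      " chain-length x ", length(x$y_levels), " double-bond levels, ",
      sum(x$cell_n), " species, ", sum(x$significant),
      " significant cells (alpha ", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' Top-k up- and down-regulated features
#'
#' Ranks the significant features of a differential result by absolute
#' log2 fold change (descending), breaking ties by smaller FDR and then by
#' feature name, and returns the top `k` in each direction. Lists may be
#' shorter than `k` when fewer features are significant.
#'
#' @param results A `differential_result`.
#' @param k Maximal number of features per direction (default 10).
#' @return A list with `up` and `down`, each a `differential_result` subset.
#' @export
top_k_table <- function(results, k = 10L) {
  stopifnot(inherits(results, "differential_result"), k >= 1L)
  pick <- function(dir) {
    sub <- results[results$direction == dir, ]
    ord <- order(-abs(sub$log2_fc), sub$fdr, sub$feature)
    sub[utils::head(ord, k), ]
  }
  list(up = pick("up"), down = pick("down"))
}
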