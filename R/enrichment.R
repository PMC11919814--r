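# Lipid-set enrichment: set derivation, over-representation analysis (Fisher
# exact) and ranked running-sum enrichment with a permutation null.

new_lipid_set_collection <- function(sets, source, dropped = character(0)) {
  if (length(sets) == 0L) stop("no lipid sets derived")
  structure(list(sets = sets, source = source, dropped = dropped),
            class = "lipid_set_collection")
}

#' @export
print.lipid_set_collection <- function(x, ...) {
  cat("<lipid_set_collection> ", length(x$sets), " sets (source: ",
      x$source, ")\n", sep = "")
  invisible(x)
}

# Ether variants get their own class label ("PC O-", "PC P-"): ether species
# behave as a distinct functional family in enrichment readouts.
class_set_label <- function(records) {
  ifelse(records$ether_type == "none", records$lipid_class,
         paste0(records$lipid_class, " ", records$ether_type, "-"))
}

#' Derive lipid sets from structural characteristics
#'
#' Builds named sets of canonical lipid names, one per characteristic
#' level. For `by = "class"` ether variants form their own sets (e.g.
#' `"PC O-"` separate from `"PC"`). Numeric characteristics are binned
#' into fixed-width intervals.
#'
#' @param records `characteristic_records` for the analysis universe.
#' @param by One of `"class"`, `"ether_type"`, `"total_carbons_bin"`,
#'   `"total_double_bonds_bin"`.
#' @param bin_width Bin width for the numeric characteristics (default 4
#'   for carbons, 2 for double bonds).
#' @return A `lipid_set_collection`.
#' @export
derive_lipid_sets <- function(records, by = c("class", "ether_type",
                                              "total_carbons_bin",
                                              "total_double_bonds_bin"),
                              bin_width = NULL) {
  by <- match.arg(by)
  labels <- switch(by,
    class = class_set_label(records),
    ether_type = records$ether_type,
    total_carbons_bin = {
      w <- if (is.null(bin_width)) 4L else as.integer(bin_width)
      lo <- (records$total_carbons %/% w) * w
      sprintf("C%d-%d", lo, lo + w - 1L)
    },
    total_double_bonds_bin = {
      w <- if (is.null(bin_width)) 2L else as.integer(bin_width)
      lo <- (records$total_double_bonds %/% w) * w
      sprintf("DB%d-%d", lo, lo + w - 1L)
    })
  sets <- split(records$canonical_name, labels)
  sets <- lapply(sets, unique)
  if (length(sets) == 1L) {
    warning("characteristic '", by, "' has a single level; enrichment is degenerate")
  }
  new_lipid_set_collection(sets[order(names(sets))], source = by)
}

#' Read user-supplied lipid sets (GMT-style TSV)
#'
#' Each line: set name, description, then member lipid names, tab-separated.
#' Members outside `universe` (when given) are dropped and reported in the
#' collection's `dropped` field.
#'
#' @param path File path.
#' @param universe Optional character vector restricting memberships.
#' @return A `lipid_set_collection` with source `"user_file"`.
#' @export
read_lipid_sets <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty lipid set file: ", path)
  sets <- list(); dropped <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed set line (need name, description, members): ", ln)
    members <- unique(f[-(1:2)])
    if (!is.null(universe)) {
      out <- setdiff(members, universe)
      dropped <- c(dropped, out)
      members <- intersect(members, universe)
    }
    if (length(members) > 0L) sets[[f[1L]]] <- members
  }
  new_lipid_set_collection(sets, source = "user_file", dropped = unique(dropped))
}

#' Over-representation analysis of differential calls
#'
#' For each lipid set, tests whether features called in the requested
#' direction are over-represented in the set, relative to the universe of
#' all tested features, with a one-sided Fisher exact test on the 2x2
#' membership table. Odds ratios are computed from the same table, with a
#' Haldane correction of 0.5 per cell when any cell is zero. P-values are
#' BH-adjusted across sets.
#'
#' @param de A `differential_result` (its features define the universe).
#' @param sets A `lipid_set_collection`; memberships are intersected with
#'   the universe.
#' @param direction `"up"` or `"down"`: which differential call forms the
#'   query.
#' @return An `enrichment_result` data.table: `set_name`, `method`,
#'   `direction`, `size` (set members within the universe), `overlap`,
#'   `odds_ratio`, `p_value`, `fdr`. With an empty query every p-value is
#'   1 and the `empty_query` attribute is set.
#' @export
ora <- function(de, sets, direction = c("up", "down")) {
  stopifnot(inherits(de, "differential_result"),
            inherits(sets, "lipid_set_collection"))
  direction <- match.arg(direction)
  universe <- unique(de$feature)
  query <- unique(de$feature[de$direction == direction])
  N <- length(universe); qs <- length(query)
  res <- lapply(names(sets$sets), function(nm) {
    members <- intersect(sets$sets[[nm]], universe)
    ms <- length(members)
    a <- length(intersect(members, query))
    if (qs == 0L || ms == 0L) {
      return(data.table::data.table(set_name = nm, size = ms, overlap = a,
                                    odds_ratio = NA_real_, p_value = 1))
    }
    tab <- matrix(c(a, ms - a, qs - a, N - ms - qs + a), 2L, 2L)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    if (any(tab == 0)) tab <- tab + 0.5
    or <- (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2])
    data.table::data.table(set_name = nm, size = ms, overlap = a,
                           odds_ratio = or, p_value = p)
  })
  out <- data.table::rbindlist(res)
  out <- data.table::data.table(
    set_name = out$set_name, method = "ora", direction = direction,
    size = out$size, overlap = out$overlap, odds_ratio = out$odds_ratio,
    es = NA_real_, nes = NA_real_,
    p_value = out$p_value, fdr = stats::p.adjust(out$p_value, "BH")
  )
  data.table::setorder(out, p_value, set_name)
  data.table::setattr(out, "class", c("enrichment_result", class(out)))
  data.table::setattr(out, "empty_query", qs == 0L)
  out[]
}

# Weighted running-sum enrichment score of one set against a ranked list.
# `stat` is in ranking order (descending), `hit` marks set members.
running_sum_es <- function(stat, hit, weight_p) {
  N <- length(stat); nh <- sum(hit)
  w <- abs(stat)^weight_p
  hw <- w * hit
  denom <- sum(hw)
  inc <- if (denom > 0) hw / denom else hit / nh
  inc[!hit] <- -1 / (N - nh)
  cs <- cumsum(inc)
  hi <- max(cs); lo <- min(cs)
  # maximum signed deviation; near-exact ties resolve toward the positive
  # extreme so the choice is stable under floating-point noise
  if (hi >= -lo - 1e-12) hi else lo
}

#' Lipid set enrichment analysis on a ranked list
#'
#' GSEA-family running-sum enrichment: walking down the ranking, the score
#' rises by `|statistic|^weight_p` (normalized over set members) at each
#' set member and falls by `1/(N - set size)` otherwise; the enrichment
#' score (ES) is the maximum signed deviation of this running sum. The
#' null is generated by permuting which lipids carry the set label;
#' `p = (b + 1) / (n_perm + 1)` where `b` counts permuted scores of the
#' same sign with `|ES|` at least as large, and `NES` is the ES divided by
#' the mean `|ES|` of same-sign permutations. P-values are BH-adjusted
#' across the retained sets. Fully reproducible given `seed`.
#'
#' @param ranked Data frame with columns `lipid` and `statistic` (no
#'   duplicated lipids); it is ranked by `statistic` descending (ties by
#'   lipid name) if not already sorted.
#' @param sets A `lipid_set_collection`.
#' @param weight_p Weighting exponent on `|statistic|` (default 1; 0 gives
#'   the classical Kolmogorov-Smirnov running sum).
#' @param n_perm Number of label permutations, at least 100 (default 1000).
#' @param seed Integer seed.
#' @param min_size,max_size Sets whose intersection with the ranking falls
#'   outside `[min_size, max_size]` are skipped (reported in the
#'   `skipped_sets` attribute).
#' @return An `enrichment_result` data.table with `es`, `nes`, `p_value`,
#'   `fdr` per retained set.
#' @export
lsea <- function(ranked, sets, weight_p = 1, n_perm = 1000L, seed = 0L,
                 min_size = 3L, max_size = 500L) {
  stopifnot(inherits(sets, "lipid_set_collection"))
  if (!all(c("lipid", "statistic") %in% names(ranked))) {
    stop("'ranked' needs columns 'lipid' and 'statistic'")
  }
  if (anyDuplicated(ranked$lipid)) stop("duplicated lipids in ranking")
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) stop("n_perm must be at least 100")
  ord <- order(-ranked$statistic, ranked$lipid)
  lipid <- as.character(ranked$lipid)[ord]
  stat <- as.numeric(ranked$statistic)[ord]
  N <- length(lipid)

  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)

  skipped <- character(0)
  rows <- list()
  for (nm in sort(names(sets$sets))) {
    members <- intersect(sets$sets[[nm]], lipid)
    nh <- length(members)
    if (nh < min_size || nh > max_size || nh == N) {
      skipped <- c(skipped, nm)
      next
    }
    hit <- lipid %in% members
    es <- running_sum_es(stat, hit, weight_p)
    perm_es <- vapply(seq_len(n_perm), function(i) {
      ph <- logical(N)
      ph[sample.int(N, nh)] <- TRUE
      running_sum_es(stat, ph, weight_p)
    }, numeric(1))
    if (es == 0) {
      p <- 1; nes <- 0
    } else {
      # sign-matched null: the observed ES is ranked among the permuted
      # scores of the same sign, so p is uniform under a random set
      same <- sign(perm_es) == sign(es)
      b <- sum(same & abs(perm_es) >= abs(es))
      p <- (b + 1) / (sum(same) + 1)
      nes <- if (any(same)) es / mean(abs(perm_es[same])) else NA_real_
    }
    rows[[nm]] <- data.table::data.table(
      set_name = nm, method = "lsea",
      direction = if (es > 0) "up" else if (es < 0) "down" else "two_sided",
      size = nh, overlap = NA_integer_, odds_ratio = NA_real_,
      es = es, nes = nes, p_value = p)
  }
  if (length(rows) == 0L) stop("no set passed the size filters")
  out <- data.table::rbindlist(rows)
  out$fdr <- stats::p.adjust(out$p_value, "BH")
  out <- out[order(out$p_value, -abs(out$nes), out$set_name), ]
  data.table::setattr(out, "class", c("enrichment_result", class(out)))
  data.table::setattr(out, "skipped_sets", skipped)
  out[]
}
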