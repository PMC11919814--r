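# Lipid-class reaction network: curated default topology, per-edge activity
# z-scores from two-group class totals, and simple-path activity scores.

#' Construct a reaction graph from an edge table
#'
#' @param edges Data frame with columns `substrate`, `product` and
#'   optionally `label` (reaction annotation). Self-loops are rejected;
#'   every endpoint must be a class code of `registry`.
#' @param registry Class registry used to validate endpoints.
#' @return A `reaction_graph`: list with `nodes` (character) and `edges`
#'   (data.table `substrate`, `product`, `label`).
#' @export
reaction_graph <- function(edges, registry = default_class_registry()) {
  edges <- data.table::as.data.table(edges)
  if (!all(c("substrate", "product") %in% names(edges))) {
    stop("edge table needs 'substrate' and 'product' columns")
  }
  if (!"label" %in% names(edges)) edges$label <- ""
  edges <- edges[, c("substrate", "product", "label")]
  if (any(edges$substrate == edges$product)) stop("self-loops are not allowed")
  known <- registry$class_code
  bad <- setdiff(unique(c(edges$substrate, edges$product)), known)
  if (length(bad) > 0L) {
    stop("edge endpoints are not registry classes: ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(edges[, c("substrate", "product")])) {
    stop("duplicated edges in graph")
  }
  structure(list(nodes = sort(unique(c(edges$substrate, edges$product))),
                 edges = edges[]),
            class = "reaction_graph")
}

#' Curated default lipid-class conversion graph
#'
#' A small directed graph of well-established class-conversion reactions
#' across the glycerolipid, glycerophospholipid and sphingolipid backbones
#' (e.g. the Kennedy-pathway route PA -> DAG -> PC/PE, the PEMT methylation
#' PE -> PC, phospholipase remodeling to lyso species, and the
#' ceramide/sphingomyelin cycle). It is a convenience topology: replace it
#' with [read_reaction_graph()] where a study-specific network is
#' available.
#'
#' @return A `reaction_graph`.
#' @export
builtin_reaction_graph <- function() {
  edges <- data.table::data.table(
    substrate = c("LPA", "PA",  "DAG", "TAG", "DAG", "MG",  "DAG", "DAG",
                  "PE",  "PC",  "PE",  "PS",  "PC",  "PC",  "PC",  "LPC",
                  "PE",  "LPE", "Cer", "SM",  "Cer", "HexCer"),
    product   = c("PA",  "DAG", "TAG", "DAG", "MG",  "DAG", "PC",  "PE",
                  "PC",  "PE",  "PS",  "PE",  "PS",  "PA",  "LPC", "PC",
                  "LPE", "PE",  "SM",  "Cer", "HexCer", "Cer"),
    label = c("LPAAT", "PA phosphatase", "DGAT", "TAG lipase", "DAG lipase",
              "MGAT", "CPT (Kennedy)", "EPT (Kennedy)", "PEMT",
              "PC->PE base exchange", "PSS2", "PSD", "PSS1", "PLD",
              "PLA2", "LPCAT", "PLA2", "LPEAT", "SM synthase", "SMase",
              "GlcCer synthase", "cerebrosidase")
  )
  reaction_graph(edges)
}

#' Read a reaction graph from an edge-list TSV
#'
#' Columns: `substrate`, `product`, optional `label`.
#' @param path File path.
#' @param registry Class registry used to validate endpoints.
#' @return A `reaction_graph`.
#' @export
read_reaction_graph <- function(path, registry = default_class_registry()) {
  reaction_graph(data.table::fread(path, sep = "\t", header = TRUE), registry)
}

#' Per-edge reaction activity between groups
#'
#' For every graph edge, forms the per-sample log2 ratio of total
#' product-class to total substrate-class abundance and z-scores the
#' case-control difference of this ratio (difference of group means over
#' the Welch standard error; two-sided normal p). An edge is called
#' `active` when `z > threshold`, `repressed` when `z < -threshold`, else
#' `neutral`. Edges whose substrate or product class has no annotated
#' species are skipped and reported in the `skipped_edges` attribute.
#'
#' When the ratio is constant within both groups the standard error is
#' zero; such edges receive `sign(mean difference) * 1e6` as a sentinel
#' z-score (0 when the means are equal too), with a warning.
#'
#' @param exp A preprocessed `lipid_experiment`.
#' @param records `characteristic_records` mapping species to classes.
#' @param graph A `reaction_graph` (default: [builtin_reaction_graph()]).
#' @param threshold Call threshold on `|z|` (default 1.96).
#' @return An `edge_activity` data.table: `substrate`, `product`, `label`,
#'   `z_score`, `p_value`, `call`. The per-sample log-ratios are attached
#'   as the `log_ratios` attribute (edges x samples matrix).
#' @export
edge_activity <- function(exp, records, graph = builtin_reaction_graph(),
                          threshold = 1.96) {
  stopifnot(inherits(exp, "lipid_experiment"),
            inherits(graph, "reaction_graph"))
  if (threshold <= 0) stop("threshold must be positive")
  cls <- aggregate_by_characteristic(exp, records, "class")
  totals <- cls$values  # classes x samples, linear scale, strictly positive
  ci <- exp$group_of == "case"
  n1 <- sum(ci); n2 <- sum(!ci)

  rows <- list(); ratios <- list(); skipped <- character(0)
  sentinel_used <- character(0)
  for (j in seq_len(nrow(graph$edges))) {
    e <- graph$edges[j, ]
    if (!(e$substrate %in% rownames(totals)) ||
        !(e$product %in% rownames(totals))) {
      skipped <- c(skipped, paste0(e$substrate, "->", e$product))
      next
    }
    r <- log2(totals[e$product, ]) - log2(totals[e$substrate, ])
    d <- mean(r[ci]) - mean(r[!ci])
    se <- sqrt(stats::var(r[ci]) / n1 + stats::var(r[!ci]) / n2)
    if (se == 0) {
      z <- if (d == 0) 0 else sign(d) * 1e6
      sentinel_used <- c(sentinel_used, paste0(e$substrate, "->", e$product))
    } else {
      z <- d / se
    }
    p <- 2 * stats::pnorm(-abs(z))
    call <- if (z > threshold) "active" else if (z < -threshold) "repressed" else "neutral"
    rows[[j]] <- data.table::data.table(
      substrate = e$substrate, product = e$product, label = e$label,
      z_score = z, p_value = p, call = call)
    ratios[[length(rows)]] <- r
  }
  if (length(rows) == 0L) stop("no edge with both classes represented in the data")
  if (length(sentinel_used) > 0L) {
    warning("degenerate (zero-variance) ratio on edges: ",
            paste(sentinel_used, collapse = ", "),
            "; sentinel z-scores assigned")
  }
  out <- data.table::rbindlist(rows)
  lr <- do.call(rbind, ratios[!vapply(ratios, is.null, logical(1))])
  rownames(lr) <- paste0(out$substrate, "->", out$product)
  data.table::setattr(out, "class", c("edge_activity", class(out)))
  data.table::setattr(out, "log_ratios", lr)
  data.table::setattr(out, "skipped_edges", skipped)
  data.table::setattr(out, "threshold", threshold)
  out[]
}

# All simple paths with 1..max_len edges over the given edge list.
# Returns a list of integer vectors of edge indices.
enumerate_simple_paths <- function(substrate, product, max_len) {
  out_edges <- split(seq_along(substrate), substrate)
  paths <- list()
  walk <- function(node, visited, edge_idx) {
    if (length(edge_idx) > 0L) paths[[length(paths) + 1L]] <<- edge_idx
    if (length(edge_idx) >= max_len) return(invisible())
    for (j in out_edges[[node]]) {
      nxt <- product[j]
      if (nxt %in% visited) next
      walk(nxt, c(visited, nxt), c(edge_idx, j))
    }
    invisible()
  }
  for (start in names(out_edges)) walk(start, start, integer(0))
  paths
}

#' Path-level activity scores
#'
#' Enumerates all simple paths of up to `max_path_len` edges through the
#' scored network and assigns each path the mean z-score of its member
#' edges. Paths with `|score| > highlight_threshold` are flagged, matching
#' the convention of highlighting strong routes in network diagrams.
#'
#' @param activities An `edge_activity` table.
#' @param max_path_len Maximal number of edges per path (default 4).
#' @param highlight_threshold Highlighting cutoff on `|score|`
#'   (default 1.5).
#' @return A `path_score` data.table sorted by `|score|` descending (ties:
#'   path string ascending): `path` (nodes joined by `"->"`), `n_edges`,
#'   `score`, `highlighted`.
#' @export
pathway_activity <- function(activities, max_path_len = 4L,
                             highlight_threshold = 1.5) {
  stopifnot(inherits(activities, "edge_activity"))
  max_path_len <- as.integer(max_path_len)
  if (max_path_len < 1L) stop("max_path_len must be at least 1")
  idx_paths <- enumerate_simple_paths(activities$substrate,
                                      activities$product, max_path_len)
  if (length(idx_paths) == 0L) {
    return(structure(data.table::data.table(
      path = character(0), n_edges = integer(0), score = numeric(0),
      highlighted = logical(0)),
      class = c("path_score", "data.table", "data.frame")))
  }
  path_str <- vapply(idx_paths, function(ix) {
    paste(c(activities$substrate[ix[1L]], activities$product[ix]),
          collapse = "->")
  }, character(1))
  score <- vapply(idx_paths, function(ix) mean(activities$z_score[ix]),
                  numeric(1))
  out <- data.table::data.table(
    path = path_str,
    n_edges = lengths(idx_paths),
    score = score,
    highlighted = abs(score) > highlight_threshold
  )
  out <- out[order(-abs(out$score), out$path), ]
  data.table::setattr(out, "class", c("path_score", class(out)))
  out[]
}

#' Export a scored network to GraphML
#'
#' Writes the directed class-conversion graph with `z_score`, `p_value`,
#' `call` edge attributes, readable by standard network tools.
#'
#' @param activities An `edge_activity` table.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_graphml <- function(activities, path) {
  stopifnot(inherits(activities, "edge_activity"))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = activities$substrate, to = activities$product,
                   label = activities$label, z_score = activities$z_score,
                   p_value = activities$p_value, call = activities$call),
    directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
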