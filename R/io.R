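# Table readers, run configuration and the end-to-end pipeline.

#' Read an abundance table and its sample metadata
#'
#' The abundance file is CSV or TSV (dialect auto-detected): first column
#' lipid names, header row sample IDs, cells nonnegative abundances
#' (empty / NA for missing). The metadata file needs `sample_id` and a
#' group column. Sample sets must match exactly (order-insensitive).
#'
#' @param path Abundance table path.
#' @param metadata_path Metadata table path.
#' @param group_col Name of the metadata column holding the group label
#'   (default `"group"`; renamed to `group` in the result).
#' @return A list: `abundance` (lipids x samples numeric matrix with `NA`
#'   for missing) and `metadata` (data.table with `sample_id`, `group`).
#' @export
read_abundance_table <- function(path, metadata_path, group_col = "group") {
  tab <- data.table::fread(path, header = TRUE)
  if (ncol(tab) < 2L) stop("abundance table needs a lipid column plus samples")
  lipids <- as.character(tab[[1L]])
  dup <- which(duplicated(lipids))
  if (length(dup) > 0L) {
    stop("duplicated lipid names at rows ", paste(dup, collapse = ", "),
         ": ", paste(unique(lipids[dup]), collapse = ", "))
  }
  vals <- as.data.frame(tab)[, -1L, drop = FALSE]
  bad_col <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad_col) > 0L) {
    stop("non-numeric abundance values in column(s): ",
         paste(bad_col, collapse = ", "))
  }
  mat <- as.matrix(vals)
  rownames(mat) <- lipids
  if (anyDuplicated(colnames(mat))) stop("duplicated sample IDs in abundance table")

  meta <- data.table::fread(metadata_path, header = TRUE)
  if (!"sample_id" %in% names(meta)) stop("metadata needs a 'sample_id' column")
  if (!group_col %in% names(meta)) {
    stop("metadata has no group column '", group_col, "'")
  }
  meta <- data.table::data.table(sample_id = as.character(meta$sample_id),
                                 group = as.character(meta[[group_col]]))
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample IDs in metadata")
  only_meta <- setdiff(meta$sample_id, colnames(mat))
  only_mat <- setdiff(colnames(mat), meta$sample_id)
  if (length(only_meta) > 0L || length(only_mat) > 0L) {
    stop("sample mismatch between matrix and metadata",
         if (length(only_meta)) paste0("; metadata-only: ",
                                       paste(only_meta, collapse = ", ")),
         if (length(only_mat)) paste0("; matrix-only: ",
                                      paste(only_mat, collapse = ", ")))
  }
  list(abundance = mat, metadata = meta)
}

#' Build and validate a pipeline run configuration
#'
#' @param abundance,metadata Input file paths (must exist), or `NULL` when
#'   `data` is supplied directly to [run_pipeline()].
#' @param output_dir Directory for all outputs (created if absent).
#' @param group_col Metadata column holding the group label.
#' @param case Which group level is the case group (`NULL`: auto when the
#'   labels are case/control).
#' @param test,alpha,fc_cut Differential-testing parameters (see
#'   [differential_species()]).
#' @param grid_class Lipid class for the dual chain-length x double-bond
#'   grid (`NULL`: the most abundant class by species count).
#' @param enrichment_method `"both"`, `"ora"` or `"lsea"`.
#' @param weight_p,n_perm LSEA parameters.
#' @param normalization,max_missing_fraction Preprocessing parameters.
#' @param embed_method Profiling embedding method.
#' @param highlight_threshold,call_threshold,max_path_len Network
#'   parameters.
#' @param seed Single integer seed fanned out deterministically to every
#'   stochastic stage.
#' @return A validated `run_config` list.
#' @export
run_config <- function(abundance = NULL, metadata = NULL, output_dir,
                       group_col = "group", case = NULL,
                       test = "welch_t", alpha = 0.05, fc_cut = 1,
                       grid_class = NULL, enrichment_method = "both",
                       weight_p = 1, n_perm = 1000L,
                       normalization = "none", max_missing_fraction = 0.5,
                       embed_method = "pca",
                       highlight_threshold = 1.5, call_threshold = 1.96,
                       max_path_len = 4L, seed = 1L) {
  if (!is.null(abundance) && !file.exists(abundance)) {
    stop("abundance file not found: ", abundance)
  }
  if (!is.null(metadata) && !file.exists(metadata)) {
    stop("metadata file not found: ", metadata)
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (fc_cut < 0) stop("fc_cut must be nonnegative")
  if (!test %in% c("welch_t", "wilcoxon")) stop("unknown test: ", test)
  if (!enrichment_method %in% c("both", "ora", "lsea")) {
    stop("unknown enrichment method: ", enrichment_method)
  }
  if (!embed_method %in% c("pca", "tsne", "umap")) {
    stop("unknown embedding method: ", embed_method)
  }
  if (highlight_threshold <= 0 || call_threshold <= 0) {
    stop("network thresholds must be positive")
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  structure(list(abundance = abundance, metadata = metadata,
                 output_dir = output_dir, group_col = group_col, case = case,
                 test = test, alpha = alpha, fc_cut = fc_cut,
                 grid_class = grid_class,
                 enrichment_method = enrichment_method,
                 weight_p = weight_p, n_perm = as.integer(n_perm),
                 normalization = normalization,
                 max_missing_fraction = max_missing_fraction,
                 embed_method = embed_method,
                 highlight_threshold = highlight_threshold,
                 call_threshold = call_threshold,
                 max_path_len = as.integer(max_path_len),
                 seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' YAML keys mirror the arguments of [run_config()].
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

write_tsv <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", na = "NA")
  path
}

#' Run the full analysis pipeline
#'
#' Executes recognition, characterization, preprocessing, differential
#' analysis (species, class level, dual grid), enrichment (ORA and LSEA),
#' reaction-network scoring and profiling, writing every result as TSV
#' (plus GraphML for the network) under `config$output_dir` together with
#' a JSON manifest recording package version, parameters, seeds, the
#' recognition report and the processing log. Identical config and seed
#' give byte-identical outputs.
#'
#' @param config A `run_config`.
#' @param data Optional list with `abundance` (matrix) and `metadata`
#'   (data frame), bypassing the file inputs.
#' @return Invisibly, a list with `status` (0 on success) and `manifest`.
#' @export
run_pipeline <- function(config, data = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    message(paste0(...))
  }

  if (is.null(data)) {
    data <- stage("read", read_abundance_table(config$abundance,
                                               config$metadata,
                                               config$group_col))
  }
  raw <- data$abundance
  metadata <- data$metadata

  # --- recognition ----------------------------------------------------------
  rec <- stage("recognize", recognize_batch(rownames(raw)))
  report <- rec$report
  if (report$n_failed > 0L) {
    note("WARN: ", report$n_failed, " lipid name(s) not recognized: ",
         paste(utils::head(report$failures$raw_name, 10L), collapse = ", "))
  }
  canon <- vapply(rec$parsed, `[[`, character(1), "canonical_name")
  raw_names <- vapply(rec$parsed, `[[`, character(1), "raw_name")
  keep <- !duplicated(canon)
  if (any(!keep)) {
    note("WARN: dropping ", sum(!keep),
         " duplicate canonical species (first occurrence kept): ",
         paste(unique(canon[!keep]), collapse = ", "))
  }
  raw <- raw[raw_names[keep], , drop = FALSE]
  rownames(raw) <- canon[keep]
  parsed <- rec$parsed[keep]
  records <- stage("characterize", characterize(parsed))
  outputs <- c(outputs, write_tsv(parsed_lipid_table(parsed),
                                  file.path(config$output_dir, "parsed.tsv")))

  # --- preprocessing --------------------------------------------------------
  exp <- stage("preprocess", preprocess(
    raw, metadata, case = config$case,
    max_missing_fraction = config$max_missing_fraction,
    normalization = config$normalization))
  proc <- data.table::data.table(lipid = exp$lipid_names)
  proc <- cbind(proc, data.table::as.data.table(exp$matrix))
  outputs <- c(outputs, write_tsv(proc, file.path(config$output_dir,
                                                  "processed.tsv")))

  # --- differential analysis ------------------------------------------------
  de <- stage("differential", differential_species(
    exp, test = config$test, alpha = config$alpha, fc_cut = config$fc_cut))
  outputs <- c(outputs, write_tsv(de, file.path(config$output_dir,
                                                "de_species.tsv")))
  topk <- top_k_table(de, 10L)
  outputs <- c(outputs, write_tsv(
    rbind(topk$up, topk$down),
    file.path(config$output_dir, "de_top10.tsv")))

  class_mat <- stage("differential", aggregate_by_characteristic(
    exp, records, "class"))
  de_class <- stage("differential", differential_characteristic(
    exp, class_mat, test = config$test, alpha = config$alpha,
    fc_cut = config$fc_cut))
  outputs <- c(outputs, write_tsv(de_class, file.path(config$output_dir,
                                                      "de_class.tsv")))

  grid_class <- config$grid_class
  if (is.null(grid_class)) {
    # default: the largest class by species count (ether variants separate)
    idx <- match(exp$lipid_names, records$canonical_name)
    grid_class <- names(sort(table(class_set_label(records[idx, ])),
                             decreasing = TRUE))[1L]
  }
  grid <- stage("differential", dual_characteristic_grid(
    exp, records, grid_class, alpha = config$alpha, test = config$test))
  outputs <- c(outputs, write_tsv(grid$cells, file.path(
    config$output_dir, paste0("dual_grid_", gsub("[^A-Za-z0-9]", "_", grid_class), ".tsv"))))

  # --- enrichment -----------------------------------------------------------
  exp_records <- records[match(exp$lipid_names, records$canonical_name), ]
  sets <- stage("enrichment", derive_lipid_sets(exp_records, by = "class"))
  if (config$enrichment_method %in% c("both", "ora")) {
    ora_up <- stage("enrichment", ora(de, sets, "up"))
    ora_down <- stage("enrichment", ora(de, sets, "down"))
    outputs <- c(outputs, write_tsv(rbind(ora_up, ora_down),
                                    file.path(config$output_dir, "ora.tsv")))
  }
  if (config$enrichment_method %in% c("both", "lsea")) {
    ranked <- data.table::data.table(lipid = de$feature,
                                     statistic = de$statistic)
    ls <- stage("enrichment", lsea(
      ranked, sets, weight_p = config$weight_p, n_perm = config$n_perm,
      seed = (config$seed + 1L) %% .Machine$integer.max))
    outputs <- c(outputs, write_tsv(ls, file.path(config$output_dir,
                                                  "lsea.tsv")))
  }

  # --- reaction network -----------------------------------------------------
  act <- stage("network", edge_activity(
    exp, records, threshold = config$call_threshold))
  if (length(attr(act, "skipped_edges")) > 0L) {
    note("WARN: network edges skipped (class absent): ",
         paste(attr(act, "skipped_edges"), collapse = ", "))
  }
  paths <- stage("network", pathway_activity(
    act, max_path_len = config$max_path_len,
    highlight_threshold = config$highlight_threshold))
  outputs <- c(outputs, write_tsv(act, file.path(config$output_dir,
                                                 "network_edges.tsv")))
  outputs <- c(outputs, write_tsv(paths, file.path(config$output_dir,
                                                   "network_paths.tsv")))
  outputs <- c(outputs, stage("network", export_graphml(
    act, file.path(config$output_dir, "network.graphml"))))

  # --- profiling ------------------------------------------------------------
  emb <- stage("profiling", reduce_dimensions(
    exp, method = config$embed_method, k = 2L,
    seed = (config$seed + 2L) %% .Machine$integer.max))
  emb_tab <- data.table::data.table(sample_id = rownames(emb$coordinates),
                                    group = exp$group_of[rownames(emb$coordinates)])
  emb_tab <- cbind(emb_tab, data.table::as.data.table(emb$coordinates))
  outputs <- c(outputs, write_tsv(emb_tab, file.path(config$output_dir,
                                                     "embedding.tsv")))
  sc <- stage("profiling", sample_correlation(exp))
  cor_tab <- data.table::data.table(sample_id = rownames(sc$correlation))
  cor_tab <- cbind(cor_tab, data.table::as.data.table(sc$correlation))
  outputs <- c(outputs, write_tsv(cor_tab, file.path(config$output_dir,
                                                     "correlation.tsv")))

  # --- manifest -------------------------------------------------------------
  manifest <- list(
    package = "lipidomix",
    version = as.character(utils::packageVersion("lipidomix")),
    parameters = config[setdiff(names(config), c("abundance", "metadata"))],
    inputs = list(abundance = config$abundance, metadata = config$metadata),
    seed = config$seed,
    stage_seeds = list(lsea = (config$seed + 1L) %% .Machine$integer.max,
                       embedding = (config$seed + 2L) %% .Machine$integer.max),
    recognition = list(n_input = report$n_input,
                       n_recognized = report$n_recognized,
                       n_failed = report$n_failed,
                       failures = as.data.frame(report$failures)),
    processing_log = exp$processing_log,
    grid_class = grid_class,
    warnings = log_lines,
    outputs = basename(outputs)
  )
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(list(status = 0L, manifest = manifest,
                 outputs = c(outputs, manifest_path)))
}
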