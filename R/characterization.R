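# Structural characterization of parsed lipids and abundance aggregation by
# characteristic value.

#' Derive characteristic records from parsed lipids
#'
#' Extracts the structural characteristics used throughout the analysis
#' stack (class, category, ether linkage, total chain carbons, total double
#' bonds, per-chain composition) into a one-row-per-lipid table keyed by
#' canonical name. Duplicate canonical names are collapsed to a single
#' record.
#'
#' @param parsed List of `parsed_lipid` objects (see [recognize_batch()]).
#' @return A `data.table` of class `characteristic_records` with columns
#'   `canonical_name`, `lipid_class`, `category`, `ether_type`,
#'   `total_carbons`, `total_double_bonds`, `parse_level` and a list column
#'   `chains` holding the per-chain data.frame of each lipid (zero rows at
#'   species level).
#' @export
characterize <- function(parsed) {
  if (length(parsed) == 0L) stop("'parsed' must contain at least one lipid")
  tab <- data.table::data.table(
    canonical_name = vapply(parsed, `[[`, character(1), "canonical_name"),
    lipid_class = vapply(parsed, `[[`, character(1), "lipid_class"),
    category = vapply(parsed, `[[`, character(1), "category"),
    ether_type = vapply(parsed, `[[`, character(1), "ether_type"),
    total_carbons = vapply(parsed, `[[`, integer(1), "total_carbons"),
    total_double_bonds = vapply(parsed, `[[`, integer(1), "total_double_bonds"),
    parse_level = vapply(parsed, `[[`, character(1), "parse_level"),
    chains = lapply(parsed, `[[`, "chains")
  )
  tab <- tab[!duplicated(tab$canonical_name), ]
  data.table::setattr(tab, "class", c("characteristic_records", class(tab)))
  tab[]
}

# Characteristics that partition the annotated species (each species maps to
# exactly one level) versus chain-level ones where a molecular-species lipid
# contributes to every distinct chain value it contains.
partition_characteristics <- c("class", "category", "ether_type",
                               "total_carbons", "total_double_bonds")
chain_characteristics <- c("chain_carbons", "chain_double_bonds")

characteristic_value <- function(records, characteristic) {
  switch(characteristic,
         class = records$lipid_class,
         category = records$category,
         ether_type = records$ether_type,
         total_carbons = as.character(records$total_carbons),
         total_double_bonds = as.character(records$total_double_bonds),
         stop("unknown characteristic: ", characteristic))
}

#' Aggregate abundances by a lipid characteristic
#'
#' Sums (linear-scale) abundances of all species sharing a characteristic
#' value, per sample. For the partition characteristics (`class`,
#' `category`, `ether_type`, `total_carbons`, `total_double_bonds`) every
#' annotated species contributes to exactly one level, so level sums per
#' sample equal the total annotated abundance. For the chain-level
#' characteristics (`chain_carbons`, `chain_double_bonds`) a
#' molecular-species lipid contributes its full abundance to every distinct
#' chain value it contains, so levels overlap by design and species-level
#' lipids (no resolved chains) do not contribute.
#'
#' @param exp A `lipid_experiment` (see [preprocess()]); abundances are
#'   taken on the linear scale (`2^matrix`, minus nothing).
#' @param records `characteristic_records` from [characterize()]. Species
#'   in the experiment without a record are ignored.
#' @param characteristic One of the names above.
#' @return A `characteristic_matrix`: list with `characteristic`, `levels`
#'   (ordered character vector; numeric characteristics sorted
#'   numerically), `samples`, and `values`, a levels x samples matrix of
#'   nonnegative reals.
#' @export
aggregate_by_characteristic <- function(exp, records, characteristic) {
  stopifnot(inherits(exp, "lipid_experiment"))
  if (!characteristic %in% c(partition_characteristics, chain_characteristics)) {
    stop("unknown characteristic: ", characteristic)
  }
  linear <- 2^exp$matrix
  idx <- match(exp$lipid_names, records$canonical_name)
  keep <- which(!is.na(idx))
  if (length(keep) == 0L) stop("no experiment lipid has a characteristic record")
  rec <- records[idx[keep], ]
  abun <- linear[keep, , drop = FALSE]

  if (characteristic %in% partition_characteristics) {
    key <- characteristic_value(rec, characteristic)
    rows <- split(seq_len(nrow(abun)), key)
  } else {
    field <- if (characteristic == "chain_carbons") "carbons" else "double_bonds"
    vals <- lapply(rec$chains, function(ch) unique(ch[[field]]))
    long_row <- rep(seq_along(vals), lengths(vals))
    long_key <- as.character(unlist(vals))
    if (length(long_row) == 0L) stop("no molecular-species lipid available for chain-level aggregation")
    rows <- split(long_row, long_key)
  }

  levels <- names(rows)
  if (characteristic %in% c("total_carbons", "total_double_bonds",
                            chain_characteristics)) {
    levels <- levels[order(as.numeric(levels))]
  } else {
    levels <- sort(levels)
  }
  values <- do.call(rbind, lapply(levels, function(l) {
    colSums(abun[rows[[l]], , drop = FALSE])
  }))
  dimnames(values) <- list(levels, exp$samples)
  structure(
    list(characteristic = characteristic, levels = levels,
         samples = exp$samples, values = values),
    class = "characteristic_matrix"
  )
}

#' @export
print.characteristic_matrix <- function(x, ...) {
  cat("<characteristic_matrix> ", x$characteristic, ": ",
      length(x$levels), " levels x ", length(x$samples), " samples\n", sep = "")
  invisible(x)
}

#' Write a characteristic matrix to TSV
#'
#' @param x A `characteristic_matrix`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_characteristic_matrix <- function(x, path) {
  out <- data.table::data.table(level = x$levels)
  out <- cbind(out, data.table::as.data.table(x$values))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
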