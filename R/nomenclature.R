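# Lipid shorthand nomenclature: parsing, canonical serialization, batch
# recognition.
#
# Supported grammar (per registry class):
#   species level:            "TAG 48:0", "PC(36:4)", "PC O-36:4"
#   molecular-species level:  "PE 18:0_20:4", "PC(O-16:1/20:3)",
#                             "Cer d18:1/16:0", "PC O-16:1-20:3"
# Chain separators "/", "_", "-" and the en-dash are equivalent; all are
# normalized to "_" in the canonical name (sn-position information is not
# retained). "d"/"t" prefixes on sphingoid chains encode 2/3 hydroxyls.

parse_error <- function(reason, msg) {
  structure(
    class = c("lipidomix_parse_error", "error", "condition"),
    list(message = msg, call = NULL, reason = reason)
  )
}

hydroxyl_prefix <- c(`0` = "", `2` = "d", `3` = "t")

chain_token <- function(carbons, double_bonds, hydroxyls) {
  paste0(hydroxyl_prefix[as.character(hydroxyls)],
         carbons, ":", double_bonds)
}

# Parse one chain token such as "16:0", "d18:1". Returns a list or NULL.
parse_chain_token <- function(token) {
  m <- regmatches(token, regexec("^([dt]?)([0-9]+):([0-9]+)$", token))[[1L]]
  if (length(m) == 0L) return(NULL)
  hydroxyls <- switch(m[2L], d = 2L, t = 3L, 0L)
  list(carbons = as.integer(m[3L]), double_bonds = as.integer(m[4L]),
       hydroxyls = hydroxyls)
}

#' Parse a lipid shorthand name
#'
#' Parses a single lipid name in shorthand nomenclature into a structured
#' record. Both sum-composition ("species") names like `"TAG 48:0"` and
#' molecular-species names like `"PE 18:0_20:4"` are supported, in the
#' space-delimited and parenthesized dialects, with `/`, `_`, `-` or an
#' en-dash as chain separator, with `O-`/`P-` ether prefixes on classes
#' that admit them, and with `d`/`t` hydroxylation prefixes on sphingoid
#' chains. Class synonyms (e.g. `TG` for `TAG`) are resolved through the
#' registry.
#'
#' @param name A single non-empty lipid name.
#' @param registry A class registry from [load_class_registry()]; defaults
#'   to the bundled registry.
#' @return A `parsed_lipid` object: a list with fields `raw_name`,
#'   `lipid_class`, `category`, `ether_type` ("none", "O" or "P"),
#'   `total_carbons`, `total_double_bonds`, `chains` (a data.frame with
#'   columns `carbons`, `double_bonds`, `hydroxyls`; zero rows at species
#'   level), `parse_level` ("species" or "molecular_species") and
#'   `canonical_name`.
#' @details On failure a classed condition of class `lipidomix_parse_error`
#'   is signalled carrying a `reason` field, one of `"empty_name"`,
#'   `"unknown_class"`, `"malformed_composition"` or
#'   `"inconsistent_totals"`. A partial record is never returned.
#' @examples
#' parse_lipid_name("TAG 48:0")
#' parse_lipid_name("PC O-16:1-20:3")$canonical_name
#' @export
parse_lipid_name <- function(name, registry = default_class_registry()) {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !nzchar(trimws(name))) {
    stop(parse_error("empty_name", "lipid name must be a non-empty string"))
  }
  raw <- name
  s <- trimws(gsub("\u2013|\u2014", "-", name))  # en/em dash -> hyphen
  s <- gsub("[[:space:]]+", " ", s)

  # Split class token from composition: "CLASS rest" or "CLASS(rest)".
  m <- regmatches(s, regexec("^([A-Za-z][A-Za-z0-9]*)\\((.+)\\)$", s))[[1L]]
  if (length(m) == 0L) {
    m <- regmatches(s, regexec("^([A-Za-z][A-Za-z0-9]*) (.+)$", s))[[1L]]
  }
  if (length(m) == 0L) {
    # a bare token: distinguish an unknown class from a missing composition
    if (grepl("^[A-Za-z][A-Za-z0-9]*$", s) &&
        is.null(resolve_class(s, registry))) {
      stop(parse_error("unknown_class",
                       paste0("unknown lipid class '", s, "'")))
    }
    stop(parse_error("malformed_composition",
                     paste0("cannot split class and composition in '", raw, "'")))
  }
  class_token <- m[2L]
  rest <- trimws(m[3L])

  cls <- resolve_class(class_token, registry)
  if (is.null(cls)) {
    stop(parse_error("unknown_class",
                     paste0("unknown lipid class '", class_token, "' in '", raw, "'")))
  }

  ether_type <- "none"
  em <- regmatches(rest, regexec("^([OP])-(.+)$", rest))[[1L]]
  if (length(em) > 0L) {
    if (!cls$ether_ok) {
      stop(parse_error("malformed_composition",
                       paste0("class ", cls$class_code, " does not admit ether variants ('", raw, "')")))
    }
    ether_type <- em[2L]
    rest <- trimws(em[3L])
  }

  # Optional stated-total form "C:DB(chain/chain/...)".
  stated <- NULL
  tm <- regmatches(rest, regexec("^([0-9]+):([0-9]+)\\((.+)\\)$", rest))[[1L]]
  if (length(tm) > 0L) {
    stated <- c(as.integer(tm[2L]), as.integer(tm[3L]))
    rest <- tm[4L]
  }

  tokens <- strsplit(rest, "[/_-]", perl = TRUE)[[1L]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    stop(parse_error("malformed_composition",
                     paste0("no chain composition in '", raw, "'")))
  }
  chains <- lapply(tokens, parse_chain_token)
  if (any(vapply(chains, is.null, logical(1)))) {
    stop(parse_error("malformed_composition",
                     paste0("malformed composition token in '", raw, "'")))
  }
  chain_df <- data.frame(
    carbons = vapply(chains, `[[`, integer(1), "carbons"),
    double_bonds = vapply(chains, `[[`, integer(1), "double_bonds"),
    hydroxyls = vapply(chains, `[[`, integer(1), "hydroxyls")
  )

  if (any(chain_df$hydroxyls > 0L) && !cls$sphingoid) {
    stop(parse_error("malformed_composition",
                     paste0("hydroxyl prefix is only valid for sphingoid classes ('", raw, "')")))
  }

  if (nrow(chain_df) == 1L && is.null(stated)) {
    # Sum-composition (species) level.
    if (chain_df$hydroxyls[1L] > 0L) {
      stop(parse_error("malformed_composition",
                       paste0("hydroxyl prefix requires molecular-species chains ('", raw, "')")))
    }
    level <- "species"
    total_c <- chain_df$carbons[1L]
    total_db <- chain_df$double_bonds[1L]
    chain_df <- chain_df[0L, ]
  } else {
    level <- "molecular_species"
    if (nrow(chain_df) != cls$backbone_chains) {
      stop(parse_error("malformed_composition",
                       paste0("class ", cls$class_code, " expects ", cls$backbone_chains,
                              " chains, got ", nrow(chain_df), " ('", raw, "')")))
    }
    if (any(chain_df$carbons < 1L)) {
      stop(parse_error("malformed_composition",
                       paste0("every chain needs at least one carbon ('", raw, "')")))
    }
    total_c <- sum(chain_df$carbons)
    total_db <- sum(chain_df$double_bonds)
    if (!is.null(stated) && (stated[1L] != total_c || stated[2L] != total_db)) {
      stop(parse_error("inconsistent_totals",
                       paste0("stated totals ", stated[1L], ":", stated[2L],
                              " do not match chain sums ", total_c, ":", total_db,
                              " ('", raw, "')")))
    }
  }

  if (total_c < 1L || total_db > total_c) {
    stop(parse_error("malformed_composition",
                     paste0("implausible sum composition ", total_c, ":", total_db,
                            " ('", raw, "')")))
  }

  lipid <- structure(
    list(raw_name = raw,
         lipid_class = cls$class_code,
         category = cls$category,
         ether_type = ether_type,
         total_carbons = total_c,
         total_double_bonds = total_db,
         chains = chain_df,
         parse_level = level,
         canonical_name = NA_character_),
    class = "parsed_lipid"
  )
  lipid$canonical_name <- canonicalize(lipid)
  lipid
}

#' Canonical serialization of a parsed lipid
#'
#' Produces the deterministic canonical shorthand name: the registry class
#' code, an `O-`/`P-` ether prefix where present, and either the
#' `carbons:double_bonds` sum composition (species level) or the chains
#' sorted by (carbons, double bonds, hydroxyls) ascending and joined with
#' `"_"` (molecular-species level). `parse_lipid_name(canonicalize(x))`
#' reproduces `x` up to the raw input string.
#'
#' @param lipid A `parsed_lipid` object.
#' @return A single string.
#' @export
canonicalize <- function(lipid) {
  stopifnot(inherits(lipid, "parsed_lipid"))
  ether <- if (lipid$ether_type == "none") "" else paste0(lipid$ether_type, "-")
  if (lipid$parse_level == "species" || nrow(lipid$chains) == 0L) {
    comp <- paste0(lipid$total_carbons, ":", lipid$total_double_bonds)
  } else {
    ch <- lipid$chains
    ord <- order(ch$carbons, ch$double_bonds, ch$hydroxyls)
    ch <- ch[ord, , drop = FALSE]
    comp <- paste(chain_token(ch$carbons, ch$double_bonds, ch$hydroxyls),
                  collapse = "_")
  }
  paste0(lipid$lipid_class, " ", ether, comp)
}

#' @export
print.parsed_lipid <- function(x, ...) {
  cat("<parsed_lipid> ", x$canonical_name, "\n", sep = "")
  cat("  class ", x$lipid_class, " (", x$category, ")",
      if (x$ether_type != "none") paste0(", ether ", x$ether_type), "\n", sep = "")
  cat("  totals ", x$total_carbons, ":", x$total_double_bonds,
      ", level ", x$parse_level, "\n", sep = "")
  if (nrow(x$chains) > 0L) {
    cat("  chains ", paste(chain_token(x$chains$carbons, x$chains$double_bonds,
                                       x$chains$hydroxyls), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Recognize a batch of lipid names
#'
#' Parses each name in turn, collecting failures instead of raising them,
#' and returns the successfully parsed lipids (input order preserved)
#' together with a recognition report.
#'
#' @param names Non-empty character vector of lipid names.
#' @param registry Class registry (bundled default).
#' @return A list with elements `parsed` (list of `parsed_lipid`) and
#'   `report`, a `recognition_report`: `n_input`, `n_recognized`,
#'   `n_failed`, `failures` (data.table of `raw_name`, `reason`) and
#'   `duplicates` (canonical names occurring more than once).
#' @export
recognize_batch <- function(names, registry = default_class_registry()) {
  if (!is.character(names) || length(names) == 0L) {
    stop("'names' must be a non-empty character vector")
  }
  parsed <- vector("list", length(names))
  fail_name <- character(0)
  fail_reason <- character(0)
  for (i in seq_along(names)) {
    res <- tryCatch(parse_lipid_name(names[[i]], registry),
                    lipidomix_parse_error = function(e) e)
    if (inherits(res, "lipidomix_parse_error")) {
      fail_name <- c(fail_name, names[[i]])
      fail_reason <- c(fail_reason, res$reason)
    } else {
      parsed[[i]] <- res
    }
  }
  parsed <- parsed[!vapply(parsed, is.null, logical(1))]
  canon <- vapply(parsed, `[[`, character(1), "canonical_name")
  dup <- unique(canon[duplicated(canon)])
  report <- structure(
    list(n_input = length(names),
         n_recognized = length(parsed),
         n_failed = length(fail_name),
         failures = data.table::data.table(raw_name = fail_name,
                                           reason = fail_reason),
         duplicates = dup),
    class = "recognition_report"
  )
  list(parsed = parsed, report = report)
}

#' @export
print.recognition_report <- function(x, ...) {
  cat("<recognition_report> ", x$n_recognized, "/", x$n_input,
      " names recognized (", x$n_failed, " failed)\n", sep = "")
  if (x$n_failed > 0L) print(x$failures)
  if (length(x$duplicates) > 0L) {
    cat("  duplicated canonical names: ",
        paste(x$duplicates, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Tabulate parsed lipids
#'
#' Flattens a list of parsed lipids to a one-row-per-lipid table suitable
#' for TSV export.
#'
#' @param parsed List of `parsed_lipid` objects.
#' @return A `data.table` with columns `raw_name`, `canonical_name`,
#'   `lipid_class`, `category`, `ether_type`, `total_carbons`,
#'   `total_double_bonds`, `parse_level`, `chain_composition`.
#' @export
parsed_lipid_table <- function(parsed) {
  data.table::data.table(
    raw_name = vapply(parsed, `[[`, character(1), "raw_name"),
    canonical_name = vapply(parsed, `[[`, character(1), "canonical_name"),
    lipid_class = vapply(parsed, `[[`, character(1), "lipid_class"),
    category = vapply(parsed, `[[`, character(1), "category"),
    ether_type = vapply(parsed, `[[`, character(1), "ether_type"),
    total_carbons = vapply(parsed, `[[`, integer(1), "total_carbons"),
    total_double_bonds = vapply(parsed, `[[`, integer(1), "total_double_bonds"),
    parse_level = vapply(parsed, `[[`, character(1), "parse_level"),
    chain_composition = vapply(parsed, function(p) {
      if (nrow(p$chains) == 0L) return("")
      paste(chain_token(p$chains$carbons, p$chains$double_bonds,
                        p$chains$hydroxyls), collapse = "_")
    }, character(1))
  )
}
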