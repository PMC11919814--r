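# Lipid class registry: the controlled vocabulary the parser recognizes.

.lipidomix_env <- new.env(parent = emptyenv())

#' Load a lipid class registry
#'
#' The registry defines the lipid classes the nomenclature parser accepts:
#' canonical class codes, accepted synonyms, the lipid category each class
#' belongs to, the number of backbone chains, and whether ether ("O-"/"P-")
#' or sphingoid (hydroxylated long-chain base, "d"/"t" prefix) variants are
#' valid for the class.
#'
#' @param path Path to a tab-separated registry file with columns
#'   `class_code`, `synonyms` (comma-separated, may be empty), `category`
#'   (one of GL, GP, SP, ST, FA), `backbone_chains` (positive integer),
#'   `ether_ok`, `sphingoid` (logicals). When `NULL`, the bundled default
#'   registry of 20 common classes is loaded.
#' @return A `data.table` with one row per class, of class `class_registry`.
#' @export
load_class_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "class_registry.tsv", package = "lipidomix")
  }
  if (!file.exists(path)) stop("class registry file not found: ", path)
  reg <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = c("class_code", "synonyms", "category")))
  required <- c("class_code", "synonyms", "category", "backbone_chains",
                "ether_ok", "sphingoid")
  missing <- setdiff(required, names(reg))
  if (length(missing) > 0L) {
    stop("class registry is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(reg$class_code)) stop("class registry has duplicated class codes")
  if (!all(reg$category %in% c("GL", "GP", "SP", "ST", "FA"))) {
    stop("class registry has unknown categories")
  }
  if (!all(reg$backbone_chains >= 1L)) stop("backbone_chains must be >= 1")
  data.table::setattr(reg, "class", c("class_registry", class(reg)))
  reg[]
}

#' Default class registry (cached)
#' @return The bundled registry, loaded once per session.
#' @export
default_class_registry <- function() {
  if (is.null(.lipidomix_env$registry)) {
    .lipidomix_env$registry <- load_class_registry()
  }
  .lipidomix_env$registry
}

# Resolve a class token (code or synonym, case-insensitive) to the registry
# row, or NULL when unknown.
resolve_class <- function(token, registry) {
  up <- toupper(token)
  hit <- which(toupper(registry$class_code) == up)
  if (length(hit) == 0L) {
    syn <- strsplit(registry$synonyms, ",", fixed = TRUE)
    hit <- which(vapply(syn, function(s) up %in% toupper(trimws(s)), logical(1)))
  }
  if (length(hit) == 0L) return(NULL)
  registry[hit[1L], ]
}
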