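# Seeded synthetic lipidomics experiments with known (planted) group
# effects, used for power, calibration and end-to-end testing.

# Plausible sum-composition ranges per class for random species generation.
composition_ranges <- list(
  TAG = list(carbons = 40:58, db = 0:10),
  DAG = list(carbons = 28:40, db = 0:6),
  MG = list(carbons = 14:22, db = 0:4),
  PC = list(carbons = 30:44, db = 0:8),
  PE = list(carbons = 30:44, db = 0:8),
  PS = list(carbons = 30:44, db = 0:8),
  PI = list(carbons = 30:44, db = 0:8),
  PG = list(carbons = 30:44, db = 0:8),
  PA = list(carbons = 30:44, db = 0:8),
  LPC = list(carbons = 14:22, db = 0:4),
  LPE = list(carbons = 14:22, db = 0:4),
  LPS = list(carbons = 14:22, db = 0:4),
  LPI = list(carbons = 14:22, db = 0:4),
  LPG = list(carbons = 14:22, db = 0:4),
  LPA = list(carbons = 14:22, db = 0:4),
  SM = list(carbons = 30:44, db = 0:4),
  Cer = list(carbons = 30:44, db = 0:4),
  HexCer = list(carbons = 30:44, db = 0:4),
  CE = list(carbons = 14:22, db = 0:6),
  FA = list(carbons = 12:24, db = 0:6)
)

#' Specification of a synthetic two-group lipidomics experiment
#'
#' The defaults describe the reference study design used throughout the
#' package's simulations: a 10 vs 10 case-control comparison of ~200
#' species over the common lipid classes, log-normal abundances, 5%
#' values missing completely at random, and planted case-group effects
#' mirroring a heart-failure-like remodeling: all triacylglycerols shifted
#' up one log2 unit, with one extra log2 unit for short-chain
#' low-unsaturation TAG species (total carbons <= 50 and double bonds
#' <= 2), and all ether phosphatidylcholines (PC O-) shifted down 1.5
#' log2 units.
#'
#' Class labels of the form `"PC O-"` denote the ether variant of the
#' class. A planted effect is a list with `class`, `shift` (log2 units,
#' added to case means) and optional `max_carbons` / `max_double_bonds`
#' restricting it to a structural subset; effects are cumulative.
#'
#' @param n_lipids_per_class Named integer vector: species per class.
#' @param n_case,n_control Samples per group (default 10 each).
#' @param base_log2_mean,base_log2_sd Mean and SD of the per-lipid baseline
#'   log2 abundance (defaults 20 and 2).
#' @param noise_sd Within-lipid between-sample SD on the log2 scale
#'   (default 1).
#' @param planted_effects List of planted effects (see above); `list()`
#'   for null data.
#' @param missing_rate MCAR missingness probability in `[0, 1)`.
#' @param seed Integer seed; the generator is a deterministic function of
#'   the spec including the seed.
#' @return A `sim_spec` object.
#' @export
sim_spec <- function(n_lipids_per_class = c(
                       TAG = 40, DAG = 12, PC = 25, `PC O-` = 18, PE = 22,
                       PS = 10, PI = 10, PG = 8, PA = 8, LPC = 8, LPE = 6,
                       SM = 14, Cer = 12, HexCer = 8, CE = 10),
                     n_case = 10L, n_control = 10L,
                     base_log2_mean = 20, base_log2_sd = 2,
                     noise_sd = 1,
                     planted_effects = list(
                       list(class = "TAG", shift = 1),
                       list(class = "TAG", max_carbons = 50,
                            max_double_bonds = 2, shift = 1),
                       list(class = "PC O-", shift = -1.5)),
                     missing_rate = 0.05, seed = 1L) {
  if (length(n_lipids_per_class) == 0L || is.null(names(n_lipids_per_class))) {
    stop("n_lipids_per_class must be a named vector with at least one class")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (n_case < 2L || n_control < 2L) stop("each group needs at least 2 samples")
  for (eff in planted_effects) {
    if (is.null(eff$class) || is.null(eff$shift) || !is.finite(eff$shift)) {
      stop("each planted effect needs a class and a finite shift")
    }
  }
  structure(list(n_lipids_per_class = n_lipids_per_class,
                 n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 base_log2_mean = base_log2_mean,
                 base_log2_sd = base_log2_sd,
                 noise_sd = noise_sd,
                 planted_effects = planted_effects,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

split_class_label <- function(label) {
  m <- regmatches(label, regexec("^(.+) ([OP])-$", label))[[1L]]
  if (length(m) > 0L) list(class = m[2L], ether = m[3L])
  else list(class = label, ether = "none")
}

#' Generate a synthetic lipidomics experiment
#'
#' Draws species names with valid random sum compositions from the class
#' registry, log-normal abundances with the spec's planted case-group
#' shifts, and MCAR missing values. Every generated name parses with
#' [parse_lipid_name()].
#'
#' @param spec A `sim_spec`.
#' @return A list: `abundance` (lipids x samples matrix, `NA` for missing),
#'   `metadata` (data.table `sample_id`, `group` with values
#'   case/control), and `truth` (data.table `lipid`, `class_label`,
#'   `shift` listing every planted lipid and its total log2 shift).
#' @export
generate_experiment <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  registry <- default_class_registry()
  old_seed <- set_local_seed(spec$seed)
  on.exit(restore_seed(old_seed), add = TRUE)

  names_all <- character(0)
  class_label_all <- character(0)
  carbons_all <- integer(0)
  db_all <- integer(0)
  for (label in names(spec$n_lipids_per_class)) {
    n <- spec$n_lipids_per_class[[label]]
    if (n < 1L) next
    parts <- split_class_label(label)
    if (is.null(resolve_class(parts$class, registry))) {
      stop("class '", parts$class, "' is not in the registry")
    }
    rng <- composition_ranges[[parts$class]]
    if (is.null(rng)) rng <- list(carbons = 24:40, db = 0:6)
    grid <- expand.grid(carbons = rng$carbons, db = rng$db)
    grid <- grid[grid$db <= grid$carbons, ]
    if (n > nrow(grid)) stop("requested more ", label,
                             " species than distinct compositions available")
    pick <- grid[sample.int(nrow(grid), n), ]
    ether <- if (parts$ether == "none") "" else paste0(parts$ether, "-")
    nm <- paste0(parts$class, " ", ether, pick$carbons, ":", pick$db)
    names_all <- c(names_all, nm)
    class_label_all <- c(class_label_all, rep(label, n))
    carbons_all <- c(carbons_all, pick$carbons)
    db_all <- c(db_all, pick$db)
  }
  n_lipids <- length(names_all)
  if (n_lipids == 0L) stop("spec generates no lipids")

  shift <- numeric(n_lipids)
  for (eff in spec$planted_effects) {
    sel <- class_label_all == eff$class
    if (!is.null(eff$max_carbons)) sel <- sel & carbons_all <= eff$max_carbons
    if (!is.null(eff$max_double_bonds)) sel <- sel & db_all <= eff$max_double_bonds
    shift[sel] <- shift[sel] + eff$shift
  }

  n_samples <- spec$n_case + spec$n_control
  group <- c(rep("case", spec$n_case), rep("control", spec$n_control))
  sample_id <- sprintf("%s_%02d", group, c(seq_len(spec$n_case),
                                           seq_len(spec$n_control)))
  baseline <- stats::rnorm(n_lipids, spec$base_log2_mean, spec$base_log2_sd)
  log2_mat <- baseline +
    outer(shift, as.numeric(group == "case")) +
    matrix(stats::rnorm(n_lipids * n_samples, 0, spec$noise_sd),
           n_lipids, n_samples)
  abundance <- 2^log2_mat
  if (spec$missing_rate > 0) {
    miss <- matrix(stats::runif(n_lipids * n_samples) < spec$missing_rate,
                   n_lipids, n_samples)
    abundance[miss] <- NA_real_
  }
  dimnames(abundance) <- list(names_all, sample_id)

  truth <- data.table::data.table(
    lipid = names_all[shift != 0],
    class_label = class_label_all[shift != 0],
    shift = shift[shift != 0]
  )
  list(abundance = abundance,
       metadata = data.table::data.table(sample_id = sample_id, group = group),
       truth = truth)
}
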