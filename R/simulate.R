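#' Configuration for the synthetic breeding-design generator
#'
#' Describes a paternal half-sib nested design with repeated measures: each
#' sire is mated to several dams, each mating yields one full-sib family,
#' every offspring is measured in year 1 (young adults, ~3 years old) and a
#' random subset again in year 2 (near-harvest adults, ~4 years old), and
#' each measurement is taken on two haemolymph fractions (intracellular =
#' haemocytes, extracellular = serum). Defaults follow the study design the
#' package targets: 20 sires x 3 dams = 60 full-sib families with 5-10
#' measured offspring each, year-1/year-2 retention of 357/492, and
#' fraction-by-age trait means on the observed scale (ug HSP70 / mg total
#' protein).
#'
#' The trait model behind the generator is the generative counterpart of the
#' animal model: phenotype = fixed part (age trend + sampling-order effect)
#' + breeding value + family common-environment effect + permanent
#' environment effect + residual. Breeding values are drawn founder-wise
#' from N(0, V_A) and offspring-wise as the parent average plus a Mendelian
#' sampling deviation N(0, V_A/2) (no inbreeding in the design). Variances
#' are per haemolymph fraction.
#'
#' @param n_sires number of sires.
#' @param n_dams_per_sire dams nested within each sire (one full-sib family
#'   per dam).
#' @param offspring_range integer range (min, max) of measured offspring per
#'   family; family sizes are drawn uniformly from it.
#' @param components named list with elements \code{intracellular} and
#'   \code{extracellular}, each a numeric vector with entries \code{V_A},
#'   \code{V_C}, \code{V_PE}, \code{V_R} (trait units squared).
#' @param means named list as above, each a length-2 vector of trait means
#'   for year 1 and year 2.
#' @param n_order number of sampling-order batches per measurement year.
#' @param order_slope linear trait shift per sampling-order batch step
#'   (centred over batches); mirrors a haemolymph-sampling-order effect.
#' @param age_spread width (years) of the uniform within-year spread of
#'   exact age at measurement (families were produced over ~3 months).
#' @param attrition fraction of year-1 animals remeasured in year 2.
#' @param challenge_multiplier fold-increase of the immunostimulated group
#'   over controls in the challenge experiment.
#' @param challenge_sdlog lognormal dispersion of challenge-experiment
#'   measurements.
#' @param seed integer seed; all stages derive their own sub-seed from it.
#' @return validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_sires = 20,
                       n_dams_per_sire = 3,
                       offspring_range = c(5L, 10L),
                       components = list(
                         intracellular = c(V_A = 5, V_C = 0, V_PE = 0, V_R = 46),
                         extracellular = c(V_A = 18, V_C = 0, V_PE = 0, V_R = 200)),
                       means = list(
                         intracellular = c(16.40, 32.27),
                         extracellular = c(26.59, 30.87)),
                       n_order = 4,
                       order_slope = 1.5,
                       age_spread = 0.25,
                       attrition = 357 / 492,
                       challenge_multiplier = 3.0,
                       challenge_sdlog = 0.3,
                       seed = 1L) {
  cfg <- list(n_sires = as.integer(n_sires),
              n_dams_per_sire = as.integer(n_dams_per_sire),
              offspring_range = as.integer(offspring_range),
              components = lapply(components, function(v) {
                v <- v[c("V_A", "V_C", "V_PE", "V_R")]
                v[is.na(v)] <- 0
                names(v) <- c("V_A", "V_C", "V_PE", "V_R")
                v
              }),
              means = means,
              n_order = as.integer(n_order),
              order_slope = order_slope,
              age_spread = age_spread,
              attrition = attrition,
              challenge_multiplier = challenge_multiplier,
              challenge_sdlog = challenge_sdlog,
              seed = as.integer(seed))
  if (cfg$n_sires < 1 || cfg$n_dams_per_sire < 1)
    stop("design must have at least one sire and one dam per sire")
  if (length(cfg$offspring_range) != 2 ||
      cfg$offspring_range[1] > cfg$offspring_range[2] ||
      cfg$offspring_range[1] < 1 || cfg$offspring_range[2] > 50)
    stop("offspring_range must be an increasing pair within [1, 50]")
  for (v in cfg$components)
    if (any(v < 0)) stop("variance components must be non-negative")
  if (cfg$attrition <= 0 || cfg$attrition > 1)
    stop("attrition must be in (0, 1]")
  if (cfg$challenge_multiplier <= 0)
    stop("challenge_multiplier must be positive")
  class(cfg) <- "sim_config"
  cfg
}

# Stage-specific sub-seed, derived so adding a stage never perturbs the
# draws of earlier stages. Kept below 2^31.
stage_seed <- function(cfg, stage) {
  (cfg$seed %% 100000L) * 16384L + match(stage,
    c("pedigree", "effects", "records", "challenge")) * 997L
}

#' Simulate a paternal half-sib nested pedigree
#'
#' Unrelated founders (sires then dams) followed by full-sib offspring,
#' family sizes drawn uniformly from the configured range. Each dam is
#' mated to exactly one sire.
#'
#' @param config a [sim_config()].
#' @return a [pedigree()] with attributes \code{"family"} (offspring family
#'   labels, named by animal) and \code{"config"}.
#' @export
simulate_pedigree <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "pedigree"))
  ns <- config$n_sires
  nd <- config$n_dams_per_sire
  nfam <- ns * nd
  sires <- sprintf("S%02d", seq_len(ns))
  dams <- sprintf("D%02d", seq_len(nfam))
  fam_sire <- rep(sires, each = nd)
  fam_dam <- dams
  size_values <- seq(config$offspring_range[1], config$offspring_range[2])
  sizes <- size_values[sample.int(length(size_values), nfam, replace = TRUE)]
  off <- sprintf("O%04d", seq_len(sum(sizes)))
  off_fam <- rep(seq_len(nfam), times = sizes)
  ped <- pedigree(animal = c(sires, dams, off),
                  sire = c(rep(NA, ns + nfam), fam_sire[off_fam]),
                  dam = c(rep(NA, ns + nfam), fam_dam[off_fam]))
  fam <- stats::setNames(sprintf("F%02d", off_fam), off)
  attr(ped, "family") <- fam
  attr(ped, "config") <- config
  ped
}

#' Simulate repeated-measure phenotypes on a simulated pedigree
#'
#' Draws breeding values down the pedigree, family common-environment and
#' permanent-environment effects, then records: year 1 on every offspring
#' and year 2 on a random subset (configured attrition), for both haemolymph
#' fractions. Fixed effects are an age trend (the slope implied by the two
#' configured year means) and a centred linear sampling-order effect;
#' sampling order is a random permutation of batches within each year. All
#' realised effects are stored in a truth table for recovery checks.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param config the same [sim_config()].
#' @return object of class \code{"synthetic_dataset"}: list with
#'   \code{pedigree}, \code{phenotypes} (animal, fraction, year, age,
#'   order, family, value), \code{truth} (per animal x fraction: breeding
#'   value, family effect, permanent-environment effect) and \code{config}.
#' @export
simulate_phenotypes <- function(ped, config = attr(ped, "config")) {
  stopifnot(inherits(ped, "pedigree"), inherits(config, "sim_config"))
  fam <- attr(ped, "family")
  if (is.null(fam)) stop("pedigree lacks family labels; use simulate_pedigree()")
  n <- nrow(ped)
  off <- names(fam)
  fractions <- names(config$components)

  set.seed(stage_seed(config, "effects"))
  truth <- list()
  bv <- list()
  for (fr in fractions) {
    vc <- config$components[[fr]]
    a <- numeric(n)
    for (i in seq_len(n)) {
      s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
      a[i] <- if (s == 0L && d == 0L) {
        stats::rnorm(1, 0, sqrt(vc[["V_A"]]))
      } else {
        mid <- (if (s > 0L) a[s] else 0) / 2 + (if (d > 0L) a[d] else 0) / 2
        mid + stats::rnorm(1, 0, sqrt(vc[["V_A"]] / 2))
      }
    }
    names(a) <- ped$animal
    fam_levels <- sort(unique(fam))
    f_eff <- stats::setNames(stats::rnorm(length(fam_levels), 0,
                                          sqrt(vc[["V_C"]])), fam_levels)
    pe <- stats::setNames(stats::rnorm(length(off), 0, sqrt(vc[["V_PE"]])), off)
    bv[[fr]] <- a
    truth[[fr]] <- data.frame(animal = off, fraction = fr,
                              bv = a[off], family_effect = f_eff[fam[off]],
                              pe = pe, row.names = NULL)
  }

  set.seed(stage_seed(config, "records"))
  n_off <- length(off)
  keep2 <- sort(sample(n_off, round(config$attrition * n_off)))
  age1 <- 3 + stats::runif(n_off, 0, config$age_spread)
  order1 <- sample(rep_len(seq_len(config$n_order), n_off))
  order2 <- sample(rep_len(seq_len(config$n_order), length(keep2)))
  rows <- list()
  for (fr in fractions) {
    vc <- config$components[[fr]]
    mns <- config$means[[fr]]
    slope <- mns[2] - mns[1]              # per year of age
    tr <- truth[[fr]]
    base <- tr$bv + tr$family_effect + tr$pe
    ord_eff <- function(o) config$order_slope * (o - (config$n_order + 1) / 2)
    mu1 <- mns[1] + slope * (age1 - 3) + ord_eff(order1) + base
    y1 <- mu1 + stats::rnorm(n_off, 0, sqrt(vc[["V_R"]]))
    mu2 <- mns[1] + slope * (age1[keep2] + 1 - 3) + ord_eff(order2) + base[keep2]
    y2 <- mu2 + stats::rnorm(length(keep2), 0, sqrt(vc[["V_R"]]))
    rows[[fr]] <- rbind(
      data.frame(animal = off, fraction = fr, year = 1L, age = age1,
                 order = order1, family = fam[off], value = y1,
                 row.names = NULL),
      data.frame(animal = off[keep2], fraction = fr, year = 2L,
                 age = age1[keep2] + 1, order = order2,
                 family = fam[off][keep2], value = y2, row.names = NULL))
  }
  phen <- do.call(rbind, rows)
  rownames(phen) <- NULL
  out <- list(pedigree = ped, phenotypes = phen,
              truth = do.call(rbind, truth), config = config)
  rownames(out$truth) <- NULL
  class(out) <- "synthetic_dataset"
  out
}

#' Simulate a full synthetic dataset
#'
#' Convenience wrapper: [simulate_pedigree()] then [simulate_phenotypes()].
#'
#' @param config a [sim_config()].
#' @return a \code{synthetic_dataset}.
#' @export
simulate_dataset <- function(config = sim_config()) {
  simulate_phenotypes(simulate_pedigree(config), config)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("Synthetic half-sib dataset: %d animals, ",
                     "%d phenotype records (%d fractions), seed %d\n"),
              nrow(x$pedigree), nrow(x$phenotypes),
              length(unique(x$phenotypes$fraction)), x$config$seed))
  invisible(x)
}

#' Simulate an immune-challenge experiment
#'
#' Independent individuals in three treatment groups (not injected, sham
#' injection with sterilised seawater, and immunostimulant injection) per
#' haemolymph fraction, with group sizes drawn uniformly from 6-10. Control
#' groups sit at the young-adult baseline mean of their fraction; the
#' stimulated group is shifted to multiplier x baseline. Measurements are
#' lognormal around the group mean.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns \code{individual}, \code{group} (factor:
#'   \code{not_injected}, \code{SSW}, \code{zymosan}), \code{fraction},
#'   \code{hsp70}.
#' @export
simulate_challenge_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "challenge"))
  groups <- c("not_injected", "SSW", "zymosan")
  out <- list()
  k <- 0L
  for (fr in names(config$means)) {
    baseline <- config$means[[fr]][1]
    for (g in groups) {
      ng <- sample(6:10, 1)
      mu <- baseline * if (g == "zymosan") config$challenge_multiplier else 1
      sdl <- config$challenge_sdlog
      vals <- stats::rlnorm(ng, meanlog = log(mu) - sdl^2 / 2, sdlog = sdl)
      out[[length(out) + 1L]] <- data.frame(
        individual = sprintf("C%03d", k + seq_len(ng)),
        group = g, fraction = fr, hsp70 = vals, row.names = NULL)
      k <- k + ng
    }
  }
  res <- do.call(rbind, out)
  res$group <- factor(res$group, levels = groups)
  res
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits \code{pedigree.csv}, \code{phenotypes.csv} and \code{truth.csv}
#' into \code{dir}, each preceded by a comment line recording the seed.
#'
#' @param ds a \code{synthetic_dataset}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("pedigree.csv", "phenotypes.csv", "truth.csv"))
  tabs <- list(as.data.frame(ds$pedigree)[c("animal", "sire", "dam")],
               ds$phenotypes, ds$truth)
  for (i in seq_along(paths)) {
    con <- file(paths[i], "w")
    writeLines(sprintf("# seed %d", ds$config$seed), con)
    utils::write.table(tabs[[i]], con, sep = ",", quote = FALSE,
                       row.names = FALSE, na = "")
    close(con)
  }
  invisible(paths)
}
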