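#' Fit a per-age-class genetic model
#'
#' Filters the phenotypes to one haemolymph fraction and one measurement
#' year, then fits either the simple model \code{"S-m"} (intercept +
#' additive genetic effect) or \code{"SO-m"} (adds sampling order as a
#' fixed factor), optionally with a full-sib family common-environment
#' random term for model-reduction screens.
#'
#' @param ds a \code{synthetic_dataset} or a list with elements
#'   \code{pedigree} and \code{phenotypes} (columns \code{animal},
#'   \code{fraction}, \code{year}, \code{order}, \code{family},
#'   \code{value}).
#' @param fraction haemolymph fraction label.
#' @param year measurement year (age class): 1 = young adults, 2 =
#'   near-harvest adults.
#' @param model \code{"S-m"} or \code{"SO-m"}.
#' @param include_family add the family common-environment random term.
#' @param control a [reml_control()].
#' @return list with \code{fit} ([reml_fit()]) and \code{parameters} (one
#'   [parameter_table()] row).
#' @export
run_per_age <- function(ds, fraction, year, model = c("S-m", "SO-m"),
                        include_family = FALSE, control = reml_control()) {
  model <- match.arg(model)
  phen <- ds$phenotypes
  phen <- phen[phen$fraction == fraction & phen$year == year, , drop = FALSE]
  if (!nrow(phen))
    stop("no observations for fraction '", fraction, "', year ", year)
  if (model == "SO-m" && !"order" %in% names(phen))
    stop("SO-m requires a sampling-order column named 'order'")
  fixed <- if (model == "SO-m") ~ factor(order) else ~ 1
  extra <- if (include_family) c(family = "family") else character(0)
  spec <- mm_spec("value", fixed = fixed, animal = "animal",
                  pedigree = ds$pedigree, extra_random = extra)
  fit <- reml_fit(spec, phen, control)
  label <- sprintf("%s year %d (%s)", fraction, year, model)
  list(fit = fit, parameters = parameter_table(list(fit), label))
}

#' Fit a combined-years genetic model with repeatability
#'
#' Uses both measurement years for one fraction. \code{"Model 1"} takes
#' sampling order nested in year as the fixed part; \code{"Model 2"} takes
#' the exact age at measurement as a covariate. Both include the additive
#' genetic term and, by default, a permanent-environment term on animal
#' identity so that repeatability is estimable from the repeated measures.
#'
#' @inheritParams run_per_age
#' @param model \code{"Model 1"} or \code{"Model 2"}.
#' @param include_pe include the permanent-environment random term.
#' @param include_family add the family common-environment random term.
#' @return list with \code{fit} and \code{parameters} (a row including R).
#' @export
run_combined <- function(ds, fraction, model = c("Model 1", "Model 2"),
                         include_pe = TRUE, include_family = FALSE,
                         control = reml_control()) {
  model <- match.arg(model)
  phen <- ds$phenotypes
  phen <- phen[phen$fraction == fraction, , drop = FALSE]
  if (!nrow(phen)) stop("no observations for fraction '", fraction, "'")
  if (length(unique(phen$year)) < 2)
    stop("combined models need records from both measurement years")
  if (model == "Model 2" && !"age" %in% names(phen))
    stop("Model 2 requires an 'age' column")
  fixed <- if (model == "Model 1") {
    ~ factor(year) + factor(year):factor(order)
  } else {
    ~ age
  }
  extra <- c(if (include_family) c(family = "family"),
             if (include_pe) c(pe = "animal"))
  spec <- mm_spec("value", fixed = fixed, animal = "animal",
                  pedigree = ds$pedigree, extra_random = extra)
  fit <- reml_fit(spec, phen, control)
  label <- sprintf("%s (%s)", fraction, model)
  list(fit = fit,
       parameters = parameter_table(list(fit), label,
                                    with_repeatability = TRUE))
}

#' Random-effect screen by boundary likelihood-ratio tests
#'
#' Mirrors the model-reduction step of half-sib heritability analyses:
#' starting from a model with additive plus family common-environment
#' terms, tests (i) the family term by dropping it from the full model and
#' (ii) the additive term (the significance of heritability) by dropping
#' it from the family-free model.
#'
#' @inheritParams run_per_age
#' @param year measurement year, or \code{NULL} for both years combined.
#' @return data.frame with one row per tested term: term, statistic, df,
#'   p_value, null.
#' @export
run_random_effect_screen <- function(ds, fraction, year = NULL,
                                     control = reml_control()) {
  phen <- ds$phenotypes
  phen <- phen[phen$fraction == fraction, , drop = FALSE]
  if (!is.null(year)) phen <- phen[phen$year == year, , drop = FALSE]
  if (!nrow(phen)) stop("empty stratum")
  full_spec <- mm_spec("value", fixed = ~1, animal = "animal",
                       pedigree = ds$pedigree,
                       extra_random = c(family = "family"))
  add_spec <- mm_spec("value", fixed = ~1, animal = "animal",
                      pedigree = ds$pedigree)
  fam_spec <- mm_spec("value", fixed = ~1,
                      extra_random = c(family = "family"))
  fit_full <- reml_fit(full_spec, phen, control)
  fit_add <- reml_fit(add_spec, phen, control)
  fit_fam <- reml_fit(fam_spec, phen, control)
  t_family <- loglik_ratio_test(fit_full, fit_add)
  t_additive <- loglik_ratio_test(fit_full, fit_fam)
  out <- data.frame(
    term = c("family", "additive"),
    statistic = c(t_family$statistic, t_additive$statistic),
    df = c(t_family$df, t_additive$df),
    p_value = c(t_family$p_value, t_additive$p_value),
    null = c(t_family$null, t_additive$null))
  attr(out, "fits") <- list(full = fit_full, additive_only = fit_add,
                            family_only = fit_fam)
  out
}

#' Reproduce the full study workflow on synthetic data
#'
#' Simulates a seeded dataset, fits the four per-age models (simple model
#' for young adults, sampling-order model for near-harvest adults, per
#' fraction), the two combined repeated-measures models per fraction, and
#' the top-fraction truncation-selection scenario for each per-age row;
#' writes \code{table1.tsv} (per-age), \code{table2.tsv} (combined, with
#' repeatability), \code{selection_response.tsv} and \code{manifest.json}
#' to \code{outdir}.
#'
#' @param seed integer seed for the synthetic dataset.
#' @param outdir output directory.
#' @param config optional [sim_config()] (its seed is overridden by
#'   \code{seed}).
#' @param selected_proportion truncation-selection fraction for the
#'   response scenarios.
#' @param allow_nonconverged raise an error if any model fails to converge
#'   (default) or keep going.
#' @return invisibly, list with \code{table1}, \code{table2},
#'   \code{selection}, \code{manifest}.
#' @export
reproduce_tables <- function(seed = 1L, outdir = "results",
                             config = NULL, selected_proportion = 0.05,
                             allow_nonconverged = FALSE) {
  if (is.null(config)) config <- sim_config(seed = seed)
  else { config$seed <- as.integer(seed) }
  ds <- simulate_dataset(config)
  fractions <- names(config$components)

  per_age <- list()
  for (fr in fractions) {
    per_age[[paste0(fr, "_y1")]] <- run_per_age(ds, fr, 1, "S-m")
    per_age[[paste0(fr, "_y2")]] <- run_per_age(ds, fr, 2, "SO-m")
  }
  table1 <- do.call(rbind, lapply(per_age, `[[`, "parameters"))
  rownames(table1) <- NULL

  combined <- list()
  for (fr in fractions) {
    combined[[paste0(fr, "_m1")]] <- run_combined(ds, fr, "Model 1")
    combined[[paste0(fr, "_m2")]] <- run_combined(ds, fr, "Model 2")
  }
  table2 <- do.call(rbind, lapply(combined, `[[`, "parameters"))
  rownames(table2) <- NULL

  conv <- c(vapply(per_age, function(x) x$fit$convergence$converged, TRUE),
            vapply(combined, function(x) x$fit$convergence$converged, TRUE))
  if (!all(conv) && !allow_nonconverged)
    stop("model(s) failed to converge: ",
         paste(names(conv)[!conv], collapse = ", "))

  selection <- do.call(rbind, lapply(seq_len(nrow(table1)), function(i) {
    row <- table1[i, ]
    cbind(label = row$label,
          predicted_response(selected_proportion, row$h2,
                             sqrt(row$V_P), row$mean))
  }))

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(table1 = file.path(outdir, "table1.tsv"),
             table2 = file.path(outdir, "table2.tsv"),
             selection = file.path(outdir, "selection_response.tsv"))
  write_parameter_table(table1, paths["table1"])
  write_parameter_table(table2, paths["table2"])
  sel_out <- selection
  num <- vapply(sel_out, is.numeric, TRUE)
  sel_out[num] <- lapply(sel_out[num], signif, digits = 6)
  utils::write.table(sel_out, paths["selection"], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "immunoQG",
    version = as.character(utils::packageVersion("immunoQG")),
    seed = config$seed,
    config = config[setdiff(names(config), "seed")],
    n_records = nrow(ds$phenotypes),
    models = stats::setNames(as.list(conv), names(conv)),
    outputs = as.list(paths),
    output_md5 = as.list(tools::md5sum(unname(paths))))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(table1 = table1, table2 = table2, selection = selection,
                 manifest = manifest, dataset = ds))
}
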