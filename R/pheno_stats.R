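#' Fixed-effects ANOVA for phenotypic group comparisons
#'
#' One- or two-way ANOVA (optionally with interaction) on a cell-means
#' style parameterisation. With unbalanced data and two factors, sums of
#' squares are type III (computed with sum-to-zero contrasts), matching the
#' least-squares-means logic used for the follow-up pairwise comparisons;
#' on balanced data these coincide with sequential sums of squares.
#'
#' @param data data.frame of observations.
#' @param response response column name.
#' @param factors one or two factor column names.
#' @param interaction include the two-way interaction (ignored for one
#'   factor).
#' @return list of class \code{"pheno_anova"}: \code{table} (term, df,
#'   sum_sq, mean_sq, F, p), \code{residual} (df, mean square),
#'   \code{grand_mean}, \code{model} (the underlying \code{lm} fit),
#'   \code{ss_type}.
#' @export
pheno_anova <- function(data, response, factors, interaction = TRUE) {
  stopifnot(length(factors) %in% 1:2)
  data <- droplevels(stats::na.omit(data[c(response, factors)]))
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2)
      stop("factor '", f, "' has fewer than 2 levels")
  }
  rhs <- if (length(factors) == 1) {
    factors
  } else if (interaction) {
    paste(factors[1], "*", factors[2])
  } else {
    paste(factors[1], "+", factors[2])
  }
  form <- stats::as.formula(paste(response, "~", rhs))
  contr <- stats::setNames(rep(list("contr.sum"), length(factors)), factors)
  fit <- stats::lm(form, data = data, contrasts = contr)
  if (fit$df.residual < 1) stop("no residual degrees of freedom")
  if (length(factors) == 2 && interaction) {
    cells <- table(data[[factors[1]]], data[[factors[2]]])
    if (any(cells == 0)) {
      warning("empty cells; interaction dropped from the model")
      return(pheno_anova(data, response, factors, interaction = FALSE))
    }
  }
  tab <- if (length(factors) == 1) {
    a <- stats::anova(fit)
    data.frame(term = rownames(a)[1], df = a$Df[1], sum_sq = a$`Sum Sq`[1],
               F = a$`F value`[1], p = a$`Pr(>F)`[1])
  } else {
    a <- car::Anova(fit, type = 3)
    keep <- !rownames(a) %in% c("(Intercept)", "Residuals")
    data.frame(term = rownames(a)[keep], df = a$Df[keep],
               sum_sq = a$`Sum Sq`[keep], F = a$`F value`[keep],
               p = a$`Pr(>F)`[keep])
  }
  tab$mean_sq <- tab$sum_sq / tab$df
  tab <- tab[c("term", "df", "sum_sq", "mean_sq", "F", "p")]
  rownames(tab) <- NULL
  res <- list(table = tab,
              residual = list(df = fit$df.residual,
                              mean_sq = sum(stats::resid(fit)^2) /
                                fit$df.residual),
              grand_mean = mean(data[[response]]),
              model = fit,
              ss_type = if (length(factors) == 1) "I" else "III")
  class(res) <- "pheno_anova"
  res
}

#' @export
print.pheno_anova <- function(x, ...) {
  cat(sprintf("ANOVA (type %s sums of squares)\n", x$ss_type))
  print(x$table, row.names = FALSE)
  cat(sprintf("Residual: df = %d, MS = %.4g\n",
              x$residual$df, x$residual$mean_sq))
  invisible(x)
}

#' Levene test for homogeneity of group variances
#'
#' By default the robust median-centred (Brown-Forsythe) variant: an ANOVA
#' on absolute deviations from group medians. \code{center = "mean"} gives
#' the classical mean-centred form.
#'
#' @param data data.frame.
#' @param response response column name.
#' @param group grouping column name.
#' @param center \code{"median"} (default) or \code{"mean"}.
#' @return list with \code{W}, \code{df} (numerator, denominator),
#'   \code{p_value}, \code{center}.
#' @export
levene_test <- function(data, response, group, center = c("median", "mean")) {
  center <- match.arg(center)
  data <- droplevels(stats::na.omit(data[c(response, group)]))
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 observations")
  res <- car::leveneTest(data[[response]], g,
                         center = if (center == "median") stats::median else mean)
  list(W = res$`F value`[1], df = c(res$Df[1], res$Df[2]),
       p_value = res$`Pr(>F)`[1], center = center)
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper with the argument checks the phenotypic workflow needs
#' (sample size in [3, 5000], non-degenerate input).
#'
#' @param residuals numeric vector (typically model residuals).
#' @return list with \code{statistic} (W) and \code{p_value}.
#' @export
normality_check <- function(residuals) {
  residuals <- residuals[!is.na(residuals)]
  n <- length(residuals)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires between 3 and 5000 observations")
  if (stats::sd(residuals) == 0) stop("input is constant")
  sw <- stats::shapiro.test(residuals)
  list(statistic = unname(sw$statistic), p_value = sw$p.value)
}

#' Sequential Bonferroni (Holm step-down) adjustment
#'
#' Holm's step-down procedure: order the m p-values increasingly, multiply
#' the k-th by (m - k + 1), enforce monotonicity by running maxima, and cap
#' at 1.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return adjusted p-values, in the input order.
#' @export
sequential_bonferroni <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "holm")
}

#' Pairwise least-squares-means comparisons
#'
#' Fits the cell-means model implied by the factors, forms all pairwise
#' LS-mean contrasts with standard errors from the residual mean square,
#' applies the sequential Bonferroni (Holm) correction, and summarises the
#' result as a compact letter display (groups sharing no letter differ
#' significantly at \code{alpha}).
#'
#' @inheritParams pheno_anova
#' @param alpha significance level for the flags and letters.
#' @param adjust \code{"holm"} (sequential Bonferroni), \code{"bonferroni"}
#'   or \code{"none"}.
#' @return list of class \code{"lsmeans_pairwise"}: \code{means} (group,
#'   lsmean, SE, letters), \code{comparisons} (group_i, group_j, estimate,
#'   SE, raw p, adjusted p, significant), \code{alpha}, \code{adjust}.
#' @export
lsmeans_pairwise <- function(data, response, factors, alpha = 0.05,
                             adjust = c("holm", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  data <- droplevels(stats::na.omit(data[c(response, factors)]))
  for (f in factors) data[[f]] <- factor(data[[f]])
  rhs <- paste(factors, collapse = " * ")
  fit <- stats::lm(stats::as.formula(paste(response, "~", rhs)), data = data)
  emm <- emmeans::emmeans(fit, specs = factors)
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  emm_df <- as.data.frame(emm)
  group_label <- apply(emm_df[, factors, drop = FALSE], 1, paste,
                       collapse = " ")
  sides <- strsplit(as.character(prs$contrast), " - ", fixed = TRUE)
  strip <- function(z) gsub("[()]", "", z)
  comparisons <- data.frame(
    group_i = strip(vapply(sides, `[`, "", 1)),
    group_j = strip(vapply(sides, `[`, "", 2)),
    estimate = prs$estimate, se = prs$SE, p_raw = prs$p.value)
  comparisons$p_adjusted <- switch(adjust,
    holm = sequential_bonferroni(comparisons$p_raw),
    bonferroni = stats::p.adjust(comparisons$p_raw, "bonferroni"),
    none = comparisons$p_raw)
  comparisons$significant <- comparisons$p_adjusted <= alpha

  means <- data.frame(group = group_label, lsmean = emm_df$emmean,
                      se = emm_df$SE)
  means$letters <- letter_display(means$group, means$lsmean, comparisons)
  out <- list(means = means, comparisons = comparisons, alpha = alpha,
              adjust = adjust)
  class(out) <- "lsmeans_pairwise"
  out
}

#' @export
print.lsmeans_pairwise <- function(x, ...) {
  cat(sprintf("LS-means pairwise comparisons (%s adjustment, alpha = %g)\n",
              x$adjust, x$alpha))
  print(x$means, row.names = FALSE)
  invisible(x)
}

# Compact letter display: groups sorted by ascending mean; a letter spans
# the maximal contiguous run of mutually non-significant groups; runs
# contained in an earlier run are absorbed.
letter_display <- function(groups, means, comparisons) {
  ord <- order(means, groups)
  g <- groups[ord]
  k <- length(g)
  sig <- matrix(FALSE, k, k, dimnames = list(g, g))
  for (r in seq_len(nrow(comparisons))) {
    i <- comparisons$group_i[r]
    j <- comparisons$group_j[r]
    if (i %in% g && j %in% g)
      sig[i, j] <- sig[j, i] <- comparisons$significant[r]
  }
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[i:(j + 1), i:(j + 1)])) j <- j + 1
    run <- i:j
    contained <- any(vapply(runs, function(r) all(run %in% r), TRUE))
    if (!contained) runs[[length(runs) + 1L]] <- run
  }
  letters_out <- stats::setNames(rep("", k), g)
  for (li in seq_along(runs))
    letters_out[runs[[li]]] <- paste0(letters_out[runs[[li]]],
                                      letters[li])
  unname(letters_out[match(groups, g)])
}

#' Write ANOVA and pairwise-comparison tables as TSV
#'
#' @param anova_res a [pheno_anova()] result.
#' @param pairwise_res a [lsmeans_pairwise()] result (or NULL).
#' @param dir output directory.
#' @return invisibly, written paths.
#' @export
write_pheno_stats <- function(anova_res, pairwise_res = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "anova.tsv")
  utils::write.table(anova_res$table, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- p1
  if (!is.null(pairwise_res)) {
    p2 <- file.path(dir, "pairwise.tsv")
    utils::write.table(pairwise_res$comparisons, p2, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p3 <- file.path(dir, "lsmeans.tsv")
    utils::write.table(pairwise_res$means, p3, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p2, p3)
  }
  invisible(paths)
}
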