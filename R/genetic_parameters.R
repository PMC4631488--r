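#' Narrow-sense heritability from a fitted model
#'
#' \eqn{h^2 = V_A / V_P}, with V_P the sum of all estimated variance
#' components. The standard error is first-order delta method on the
#' component covariance matrix (inverse average-information at
#' convergence).
#'
#' @param fit a [reml_fit()] containing an additive term.
#' @return list with \code{h2} and \code{se}.
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  if (!"additive" %in% fit$components$term)
    stop("the model has no additive genetic term")
  ratio_of_components(fit, numerator = "additive")
}

#' Repeatability from a fitted repeated-measures model
#'
#' Pools all permanent between-individual variance:
#' \eqn{R = (V_A + V_{PE} + V_C) / V_P}; terms absent from the model
#' contribute zero. R upper-bounds \eqn{h^2} whenever the pooled extra
#' components are non-negative.
#'
#' @param fit a [reml_fit()].
#' @param terms names of the components counted as permanent
#'   between-individual variance; defaults to the additive term plus every
#'   non-residual random term in the model.
#' @return list with \code{R} and \code{se}.
#' @export
repeatability <- function(fit, terms = NULL) {
  stopifnot(inherits(fit, "reml_fit"))
  if (is.null(terms))
    terms <- setdiff(fit$components$term, "residual")
  res <- ratio_of_components(fit, numerator = terms)
  list(R = res$h2, se = res$se)
}

# Delta-method SE of (sum of selected components) / V_P.
ratio_of_components <- function(fit, numerator) {
  comp <- fit$components
  theta <- comp$variance
  VP <- sum(theta)
  if (VP <= 0) stop("total phenotypic variance is not positive")
  num <- sum(theta[comp$term %in% numerator])
  ratio <- num / VP
  Vmat <- fit$ai_cov
  se <- NA_real_
  if (!is.null(Vmat)) {
    g <- (as.numeric(comp$term %in% numerator) * VP - num) / VP^2
    ok <- !is.na(diag(Vmat))
    if (any(ok)) {
      se <- sqrt(max(0, as.numeric(t(g[ok]) %*% Vmat[ok, ok] %*% g[ok])))
    }
  }
  list(h2 = ratio, se = se)
}

#' Coefficient of additive genetic variation
#'
#' \eqn{CV_A = 100\sqrt{V_A}/\bar X}: the additive genetic standard
#' deviation as a percentage of the trait mean; a mean-standardised measure
#' of evolvability.
#'
#' @param V_A additive genetic variance (trait units squared).
#' @param mean trait mean (must be positive; the CV is undefined on a
#'   non-ratio scale).
#' @return percentage.
#' @export
cv_additive <- function(V_A, mean) {
  if (any(mean <= 0)) stop("CV requires a positive trait mean")
  if (any(V_A < 0)) stop("V_A must be non-negative")
  100 * sqrt(V_A) / mean
}

#' Coefficient of residual variation
#'
#' \eqn{CV_R = 100\sqrt{V_P - V_A}/\bar X}: the non-additive remainder of
#' the phenotypic standard deviation as a percentage of the trait mean.
#'
#' @param V_P phenotypic variance.
#' @param V_A additive genetic variance; must not exceed \code{V_P}.
#' @param mean trait mean (positive).
#' @return percentage.
#' @export
cv_residual <- function(V_P, V_A, mean) {
  if (any(mean <= 0)) stop("CV requires a positive trait mean")
  if (any(V_P < V_A)) stop("V_P must be at least V_A")
  100 * sqrt(V_P - V_A) / mean
}

#' Selection intensity under truncation selection
#'
#' The mean deviation, in phenotypic standard-deviation units, of the
#' selected fraction from the population mean when the top proportion
#' \code{p} of a normal distribution is kept:
#' \eqn{i = \phi(z_p)/p} with \eqn{z_p} the upper-p standard-normal
#' quantile. Selecting the top 5\% gives i = 2.063.
#'
#' @param p selected proportion, in (0, 1).
#' @return selection intensity (dimensionless).
#' @export
selection_intensity <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)")
  z <- stats::qnorm(p, lower.tail = FALSE)
  stats::dnorm(z) / p
}

#' Predicted per-generation response to truncation selection
#'
#' Breeder's equation: \eqn{G = i h^2 \sigma_P}, reported both in trait
#' units and as a percentage of the trait mean.
#'
#' @param p selected proportion.
#' @param h2 narrow-sense heritability.
#' @param sigma_P phenotypic standard deviation (trait units); by
#'   convention the square root of the model-estimated V_P.
#' @param mean trait mean (positive, for the percentage form).
#' @return data.frame with columns \code{p}, \code{i}, \code{h2},
#'   \code{sigma_P}, \code{mean}, \code{response}, \code{response_percent}.
#' @export
predicted_response <- function(p, h2, sigma_P, mean) {
  if (any(!is.finite(c(p, h2, sigma_P, mean)))) stop("inputs must be finite")
  if (any(mean <= 0)) stop("percentage response requires a positive mean")
  i <- selection_intensity(p)
  G <- i * h2 * sigma_P
  data.frame(p = p, i = i, h2 = h2, sigma_P = sigma_P, mean = mean,
             response = G, response_percent = 100 * G / mean)
}

#' Summarise fits as a genetic-parameters table
#'
#' One row per fitted model: trait mean (SD), variance components with
#' standard errors, heritability, repeatability (when the model carries
#' permanent between-individual terms), and the coefficients of additive
#' and residual variation. Mirrors the layout of per-age and combined
#' genetic-estimates tables in half-sib heritability studies.
#'
#' @param fits list of [reml_fit()] objects.
#' @param labels character vector of row labels, same length as
#'   \code{fits}.
#' @param with_repeatability include a repeatability column (for
#'   repeated-measures fits).
#' @return data.frame; full precision is retained (round for display).
#' @export
parameter_table <- function(fits, labels, with_repeatability = FALSE) {
  if (length(fits) != length(labels))
    stop("fits and labels must have equal length")
  cols <- c("label", "n", "mean", "sd", "V_A", "V_A_se", "V_C", "V_PE",
            "V_R", "V_R_se", "V_P", "V_P_se", "h2", "h2_se",
            if (with_repeatability) c("R", "R_se"), "CV_A", "CV_R", "converged")
  if (!length(fits)) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                         cols))
    out$label <- character(0)
    out$converged <- logical(0)
    return(out)
  }
  rows <- lapply(seq_along(fits), function(i) {
    fit <- fits[[i]]
    comp <- fit$components
    get_se <- function(tm) {
      j <- match(tm, comp$term)
      if (is.na(j)) NA_real_ else comp$se[j]
    }
    VA <- varcomp(fit, "additive")
    VP <- fit$V_P
    h2 <- heritability(fit)
    xbar <- fit$ybar
    sdy <- stats::sd(fit$bundle$y)
    VP_se <- if (!is.null(fit$ai_cov)) {
      ok <- !is.na(diag(fit$ai_cov))
      sqrt(max(0, sum(fit$ai_cov[ok, ok])))
    } else NA_real_
    row <- data.frame(label = labels[i], n = fit$n_obs, mean = xbar,
                      sd = sdy, V_A = VA, V_A_se = get_se("additive"),
                      V_C = varcomp(fit, "family"),
                      V_PE = varcomp(fit, "pe"),
                      V_R = varcomp(fit, "residual"),
                      V_R_se = get_se("residual"),
                      V_P = VP, V_P_se = VP_se,
                      h2 = h2$h2, h2_se = h2$se)
    if (with_repeatability) {
      R <- repeatability(fit)
      row$R <- R$R
      row$R_se <- R$se
    }
    row$CV_A <- cv_additive(VA, xbar)
    row$CV_R <- cv_residual(VP, VA, xbar)
    row$converged <- fit$convergence$converged
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a genetic-parameters table as TSV
#'
#' @param tab table from [parameter_table()].
#' @param path output path.
#' @param digits decimals used for display columns (full-precision values
#'   are what the in-memory table holds).
#' @export
write_parameter_table <- function(tab, path, digits = 2) {
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits = digits)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
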