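#' Likelihood-ratio test for a variance component
#'
#' Compares two REML fits whose specifications differ by exactly one random
#' term (same data, same fixed part). The statistic is
#' \eqn{2(\ell_{full} - \ell_{reduced})}, clipped at zero. Because the null
#' value of a variance lies on the boundary of the parameter space, the
#' default null distribution is the equal mixture
#' \eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1} (Self-Liang), so
#' \eqn{p = \tfrac12 P(\chi^2_1 \ge \Lambda)}; a zero statistic is reported
#' as p = 0.5 under this convention. Set \code{mixture = FALSE} for a plain
#' \eqn{\chi^2_1} reference.
#'
#' @param full,reduced [reml_fit()] objects; \code{reduced} must drop
#'   exactly one random term from \code{full}.
#' @param mixture use the boundary mixture null (default) or plain
#'   chi-squared with 1 df.
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{term} (the dropped term) and \code{null} (the reference
#'   distribution used).
#' @export
loglik_ratio_test <- function(full, reduced, mixture = TRUE) {
  stopifnot(inherits(full, "reml_fit"), inherits(reduced, "reml_fit"))
  if (full$n_obs != reduced$n_obs)
    stop("fits use different numbers of observations")
  if (!identical(full$term_labels, reduced$term_labels))
    stop("fits have different fixed parts; the REML likelihoods are not comparable")
  ft <- full$components$term
  rt <- reduced$components$term
  dropped <- setdiff(ft, rt)
  if (length(dropped) != 1 || length(setdiff(rt, ft)) != 0)
    stop("reduced model must drop exactly one random term of the full model")
  stat <- max(0, 2 * (full$logLik - reduced$logLik))
  p <- if (mixture) {
    0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(statistic = stat, df = 1L, p_value = p, term = dropped,
       null = if (mixture) "0.5*chisq(0) + 0.5*chisq(1)" else "chisq(1)")
}

#' Wald F test for a fixed-effect term
#'
#' Tests that all (estimable, post-pruning) coefficients of a fixed term
#' are zero, at the converged REML variance components:
#' \eqn{F = \hat b_C' [C \,\mathrm{var}(\hat b)\, C']^{-1} \hat b_C / r}.
#' The denominator degrees of freedom use the residual convention
#' \eqn{ddf = n - \mathrm{rank}(X)}, which is reported with the result
#' (more elaborate adjusted-df methods are deliberately out of scope).
#'
#' @param fit a [reml_fit()].
#' @param term a term label from the fixed formula (as in
#'   \code{attr(terms(fixed), "term.labels")}).
#' @return list with \code{F}, \code{ndf}, \code{ddf}, \code{p_value},
#'   \code{term}.
#' @export
wald_f <- function(fit, term) {
  stopifnot(inherits(fit, "reml_fit"))
  ti <- match(term, fit$term_labels)
  if (is.na(ti))
    stop("term '", term, "' is not in the fixed part (available: ",
         paste(fit$term_labels, collapse = ", "), ")")
  cols <- which(fit$assign == ti)
  if (!length(cols))
    stop("term '", term, "' was aliased out entirely during pruning")
  b <- fit$beta[cols]
  Vb <- fit$beta_cov[cols, cols, drop = FALSE]
  r <- length(cols)
  Fstat <- as.numeric(crossprod(b, solve(Vb, b))) / r
  ddf <- fit$n_obs - fit$n_fixed_rank
  list(F = Fstat, ndf = r, ddf = ddf,
       p_value = stats::pf(Fstat, r, ddf, lower.tail = FALSE), term = term)
}

#' Estimated breeding values (BLUP of the additive term)
#'
#' Back-solves the additive random effects for every pedigree animal,
#' including unphenotyped founders: \eqn{\hat a = \hat\sigma^2_A A Z' P y}.
#' Prediction-error variances are
#' \eqn{\mathrm{diag}(\hat\sigma^2_A A - \hat\sigma^4_A A Z'PZ A)}.
#'
#' @param fit a [reml_fit()] whose model contains the additive term.
#' @return data.frame with columns \code{animal}, \code{ebv}, \code{pev}.
#' @export
extract_breeding_values <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  tm <- fit$bundle$terms$additive
  if (is.null(tm)) stop("the model has no additive genetic term")
  sA <- varcomp(fit, "additive")
  A <- tm$A
  N <- nrow(A)
  if (sA == 0) {
    return(data.frame(animal = tm$labels, ebv = 0, pev = 0,
                      row.names = NULL))
  }
  Py <- fit$internal$Py
  ztpy <- numeric(N)
  tab <- rowsum(Py, tm$idx)
  ztpy[as.integer(rownames(tab))] <- tab[, 1]
  ebv <- sA * as.vector(A %*% ztpy)

  # Z'PZ via P applied to the columns of Z in the working space
  st <- fit$internal$st
  ev <- fit$internal$ev
  n <- fit$n_obs
  Z <- matrix(0, n, N)
  Z[cbind(seq_len(n), tm$idx)] <- 1
  if (st$kind == "diag") {
    Zw <- crossprod(st$U, Z)
    v <- as.vector(st$D %*% fit$components$variance)
    PZ <- Zw / v - ev$W %*% (ev$XtViX_inv %*% crossprod(ev$W, Zw))
    ZtPZ <- crossprod(Zw, PZ)
  } else {
    Vsum <- matrix(0, n, n)
    th <- fit$components$variance
    for (k in seq_along(st$K)) Vsum <- Vsum + th[k] * st$K[[k]]
    Vi <- chol2inv(chol(Vsum))
    PZ <- Vi %*% Z - (Vi %*% fit$bundle$X) %*%
      (ev$XtViX_inv %*% crossprod(fit$bundle$X, Vi %*% Z))
    ZtPZ <- crossprod(Z, PZ)
  }
  AZtPZ <- A %*% ZtPZ
  pev <- sA * diag(A) - sA^2 * rowSums(AZtPZ * A)
  data.frame(animal = tm$labels, ebv = ebv, pev = pmax(pev, 0),
             row.names = NULL)
}
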