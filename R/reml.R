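#' Specify a single-trait animal model
#'
#' Describes the mixed linear model y = Xb + Z_a a + Z_m f + e: a fixed part
#' given as a one-sided formula (factors, nested factors via interactions
#' such as \code{~ year + year:order}, and numeric covariates), at most one
#' additive genetic term whose covariance is V_A times the numerator
#' relationship matrix of a pedigree, and any number of further independent
#' (identity-covariance) random terms such as a full-sib family
#' common-environment effect or a permanent-environment effect for repeated
#' measures. The residual is always independent with variance V_R.
#'
#' @param response name of the trait column.
#' @param fixed one-sided formula for the fixed part; an intercept is
#'   required and enforced.
#' @param animal name of the column holding animal ids for the additive
#'   genetic term, or \code{NULL} for a model without one (e.g. a sire
#'   model).
#' @param pedigree a [pedigree()]; required when \code{animal} is given.
#' @param extra_random named character vector mapping random-term names to
#'   grouping columns, each with identity covariance, e.g.
#'   \code{c(family = "family", pe = "animal")}.
#' @return object of class \code{"mm_spec"}.
#' @export
mm_spec <- function(response, fixed = ~1, animal = NULL, pedigree = NULL,
                    extra_random = character(0)) {
  stopifnot(is.character(response), length(response) == 1)
  tt <- stats::terms(fixed)
  if (attr(tt, "intercept") != 1)
    stop("the fixed part must include an intercept")
  if (!is.null(animal) && !inherits(pedigree, "pedigree"))
    stop("an additive term requires a pedigree")
  if (length(extra_random) && is.null(names(extra_random)))
    stop("extra_random must be a named vector (term name -> column)")
  # a spec without random terms is permitted: it is the residual-only
  # reduced model of a boundary LR test (closed-form fit)
  spec <- list(response = response, fixed = fixed, animal = animal,
               pedigree = pedigree, extra_random = extra_random)
  class(spec) <- "mm_spec"
  spec
}

#' Build design matrices for a mixed-model specification
#'
#' Assembles y, the fixed-effect matrix X (pruned to full column rank, with
#' pruned columns reported), and for each random term the incidence mapping
#' and covariance structure: the additive term maps observations to
#' pedigree positions and carries the relationship matrix A; identity terms
#' map observations to grouping-factor levels. Rows with a missing response
#' or missing model variables are dropped and counted.
#'
#' @param spec an [mm_spec()].
#' @param data phenotype data.frame.
#' @return a design bundle (list) with elements \code{y}, \code{X},
#'   \code{assign}, \code{term_labels}, \code{pruned}, \code{terms} (per
#'   random term: name, kind, index map, number of levels, and A for the
#'   additive term), \code{n_dropped}.
#' @export
build_design <- function(spec, data) {
  stopifnot(inherits(spec, "mm_spec"))
  needed <- unique(c(spec$response, all.vars(spec$fixed), spec$animal,
                     unname(spec$extra_random)))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "))
  complete <- stats::complete.cases(data[needed])
  n_dropped <- sum(!complete)
  data <- data[complete, , drop = FALSE]
  if (!nrow(data)) stop("no complete observations (all rows missing)")

  y <- data[[spec$response]]
  if (!is.numeric(y)) stop("response must be numeric")

  mf <- stats::model.frame(spec$fixed, data)
  for (v in names(mf)) {
    if (is.character(mf[[v]])) mf[[v]] <- factor(mf[[v]])
    if (is.factor(mf[[v]]) && nlevels(droplevels(mf[[v]])) < 2)
      stop("fixed factor '", v, "' has a single level")
    if (is.factor(mf[[v]])) mf[[v]] <- droplevels(mf[[v]])
  }
  X <- stats::model.matrix(stats::terms(spec$fixed), mf)
  asgn <- attr(X, "assign")
  qrX <- qr(X)
  keep <- sort(qrX$pivot[seq_len(qrX$rank)])
  pruned <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  X <- X[, keep, drop = FALSE]
  asgn <- asgn[keep]

  terms <- list()
  if (!is.null(spec$animal)) {
    ids <- as.character(data[[spec$animal]])
    idx <- match(ids, spec$pedigree$animal)
    if (anyNA(idx))
      stop("animal id(s) absent from the pedigree: ",
           paste(unique(ids[is.na(idx)]), collapse = ", "))
    A <- additive_relationship(spec$pedigree)
    terms$additive <- list(name = "additive", kind = "additive",
                           idx = idx, n_levels = nrow(A), A = A,
                           labels = spec$pedigree$animal)
  }
  for (nm in names(spec$extra_random)) {
    f <- factor(data[[spec$extra_random[[nm]]]])
    terms[[nm]] <- list(name = nm, kind = "identity",
                        idx = as.integer(f), n_levels = nlevels(f),
                        labels = levels(f))
  }
  list(y = y, X = X, assign = asgn,
       term_labels = attr(stats::terms(spec$fixed), "term.labels"),
       pruned = pruned, terms = terms, n_dropped = n_dropped,
       data = data)
}

#' REML solver options
#'
#' @param maxit iteration cap.
#' @param tol_logl relative restricted-log-likelihood change declaring
#'   convergence.
#' @param tol_theta relative variance-component change declaring
#'   convergence.
#' @param verbose print one line per iteration.
#' @return list of class \code{"reml_control"}.
#' @export
reml_control <- function(maxit = 200L, tol_logl = 1e-8, tol_theta = 1e-6,
                         verbose = FALSE) {
  structure(list(maxit = as.integer(maxit), tol_logl = tol_logl,
                 tol_theta = tol_theta, verbose = verbose),
            class = "reml_control")
}

# One REML likelihood evaluation at variance components theta.
# Works on either a diagonalised single-term representation (D: n x M
# matrix of per-component diagonal covariance contributions) or the dense
# representation (K: list of n x n covariance contributions incl. residual
# identity). Returns logL, Py, and the pieces needed for scores/AI.
reml_eval <- function(st, theta) {
  n <- length(st$y); p <- ncol(st$X); M <- st$M
  if (st$kind == "diag") {
    v <- as.vector(st$D %*% theta)
    if (any(v <= 0)) return(NULL)
    vi <- 1 / v
    W <- st$X * vi
    XtViX <- crossprod(st$X, W)
    ch <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Wty <- crossprod(W, st$y)
    beta <- backsolve(ch, backsolve(ch, Wty, transpose = TRUE))
    Py <- vi * st$y - W %*% beta
    logdetV <- sum(log(v))
    logdetX <- 2 * sum(log(diag(ch)))
    yPy <- sum(st$y * Py)
    XtViX_inv <- chol2inv(ch)
    Pmul <- function(z) vi * z - W %*% (XtViX_inv %*% crossprod(W, z))
    trPK <- vapply(seq_len(M), function(k) {
      dk <- st$D[, k]
      sum(vi * dk) - sum(XtViX_inv * crossprod(W, dk * W))
    }, 0)
    Ku <- lapply(seq_len(M), function(k) st$D[, k] * Py)
  } else {
    V <- matrix(0, n, n)
    for (k in seq_len(M)) V <- V + theta[k] * st$K[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    W <- Vi %*% st$X
    XtViX <- crossprod(st$X, W)
    ch2 <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(ch2)) return(NULL)
    XtViX_inv <- chol2inv(ch2)
    beta <- XtViX_inv %*% crossprod(W, st$y)
    Py <- Vi %*% st$y - W %*% beta
    logdetV <- 2 * sum(log(diag(ch)))
    logdetX <- 2 * sum(log(diag(ch2)))
    yPy <- sum(st$y * Py)
    Pmul <- function(z) Vi %*% z - W %*% (XtViX_inv %*% crossprod(W, z))
    trPK <- vapply(seq_len(M), function(k) {
      Kk <- st$K[[k]]
      sum(Vi * Kk) - sum(XtViX_inv * crossprod(W, Kk %*% W))
    }, 0)
    Ku <- lapply(seq_len(M), function(k) as.vector(st$K[[k]] %*% Py))
  }
  logL <- -0.5 * ((n - p) * log(2 * pi) + logdetV + logdetX + yPy)
  yPKPy <- vapply(Ku, function(u) sum(u * Py), 0)
  score <- 0.5 * (yPKPy - trPK)
  PKu <- lapply(Ku, Pmul)
  AI <- matrix(0, M, M)
  for (k in seq_len(M)) for (l in k:M) {
    AI[k, l] <- AI[l, k] <- 0.5 * sum(Ku[[k]] * PKu[[l]])
  }
  list(logL = logL, score = score, AI = AI, yPKPy = yPKPy, trPK = trPK,
       Py = as.vector(Py), beta = as.vector(beta), XtViX_inv = XtViX_inv,
       W = W)
}

#' Fit an animal model by restricted maximum likelihood
#'
#' Maximises the restricted log-likelihood
#' \deqn{-\tfrac12[\log|V| + \log|X'V^{-1}X| + y'Py] + \mathrm{const}}
#' over non-negative variance components, where
#' \eqn{V = \sum_k \sigma^2_k Z_k G_k Z_k' + \sigma^2_R I}. Updates are
#' average-information (AI) steps with an expectation-maximisation fallback
#' whenever the AI proposal leaves the parameter space or decreases the
#' likelihood; components driven to the boundary are pinned at zero and
#' flagged. The fit is deterministic: components are initialised at an
#' equal partition of the (fixed-effects-adjusted) phenotypic variance.
#'
#' When the model has exactly one non-residual random term the computation
#' is carried out in the eigenbasis of its covariance contribution, where V
#' is diagonal; this is algebraically identical to the dense path but far
#' cheaper per iteration.
#'
#' @param spec an [mm_spec()].
#' @param data phenotype data.frame.
#' @param control a [reml_control()].
#' @return object of class \code{"reml_fit"} with components table
#'   (variance, SE, boundary flag), restricted log-likelihood, BLUE table
#'   and covariance, AI matrix and its inverse over free components,
#'   convergence report, and the internal state needed by [wald_f()] and
#'   [extract_breeding_values()].
#' @export
reml_fit <- function(spec, data, control = reml_control()) {
  bundle <- build_design(spec, data)
  y <- bundle$y
  X <- bundle$X
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("fewer observations than fixed-effect parameters")
  terms <- bundle$terms
  m <- length(terms)

  # residual-only closed form (used as the reduced model in LR tests)
  if (m == 0L) {
    qrX <- qr(X)
    r <- qr.resid(qrX, y)
    rss <- sum(r^2)
    s2 <- rss / (n - p)
    XtX <- crossprod(X)
    # log|X'V^-1 X| = log|X'X| - p*log(s2); log|V| = n log s2; y'Py = rss/s2
    logL <- -0.5 * ((n - p) * log(2 * pi) + n * log(s2) +
                      as.numeric(determinant(XtX)$modulus) - p * log(s2) +
                      rss / s2)
    beta <- qr.coef(qrX, y)
    comp <- data.frame(term = "residual", variance = s2,
                       se = sqrt(2 * s2^2 / (n - p)), boundary = FALSE)
    beta_cov <- s2 * chol2inv(chol(XtX))
    dimnames(beta_cov) <- list(colnames(X), colnames(X))
    fit <- list(spec = spec, components = comp, V_P = s2, logLik = logL,
                beta = beta, beta_cov = beta_cov,
                assign = bundle$assign, term_labels = bundle$term_labels,
                pruned = bundle$pruned, n_obs = n, n_fixed_rank = p,
                n_dropped = bundle$n_dropped,
                convergence = list(converged = TRUE, iterations = 0L,
                                   steps = character(0)),
                ai = NULL, ai_cov = matrix(2 * s2^2 / (n - p), 1, 1,
                                           dimnames = list("residual",
                                                           "residual")),
                internal = list(kind = "ols"), bundle = bundle,
                ybar = mean(y))
    class(fit) <- "reml_fit"
    return(fit)
  }

  # covariance contribution of each random term on the observation scale
  Kmats <- lapply(terms, function(tm) {
    if (tm$kind == "additive") {
      tm$A[tm$idx, tm$idx, drop = FALSE]
    } else {
      Z <- outer(tm$idx, seq_len(tm$n_levels), "==") * 1
      tcrossprod(Z)
    }
  })
  M <- m + 1L
  q_levels <- c(vapply(terms, `[[`, 0L, "n_levels"), n)

  if (m == 1L) {
    E <- eigen(Kmats[[1]], symmetric = TRUE)
    U <- E$vectors
    d <- pmax(E$values, 0)
    st <- list(kind = "diag", y = as.vector(crossprod(U, y)),
               X = crossprod(U, X), D = cbind(d, 1), M = M, U = U)
  } else {
    Klist <- c(Kmats, list(diag(n)))
    st <- list(kind = "dense", y = y, X = X, K = Klist, M = M)
  }

  s2_tot <- sum(qr.resid(qr(X), y)^2) / (n - p)
  theta <- rep(s2_tot / M, M)
  free <- rep(TRUE, M)
  bound_tol <- 1e-8 * s2_tot
  steps <- character(0)
  ev <- reml_eval(st, theta)
  if (is.null(ev)) stop("V numerically singular at the starting values")
  converged <- FALSE
  it <- 0L
  while (it < control$maxit) {
    it <- it + 1L
    # free pinned components whose score turned positive
    unpin <- !free & ev$score > 0
    if (any(unpin)) {
      theta[unpin] <- 1e-4 * s2_tot
      free[unpin] <- TRUE
      ev <- reml_eval(st, theta)
    }
    idx <- which(free)
    step_kind <- "AI"
    prop <- theta
    sol <- tryCatch(solve(ev$AI[idx, idx, drop = FALSE], ev$score[idx]),
                    error = function(e) NULL)
    ev2 <- NULL
    if (!is.null(sol)) {
      # full AI step, then halved steps, each clamped to the boundary
      for (frac in c(1, 0.5, 0.25)) {
        cand <- theta
        cand[idx] <- pmax(theta[idx] + frac * sol, 0)
        if (cand[M] <= 0) next
        ev2 <- reml_eval(st, cand)
        if (!is.null(ev2) && ev2$logL >= ev$logL - 1e-10) {
          prop <- cand
          break
        }
        ev2 <- NULL
      }
    }
    if (is.null(ev2)) {
      # EM-REML fallback: guaranteed-direction, boundary-respecting
      step_kind <- "EM"
      prop <- theta
      em <- theta[idx] + theta[idx]^2 *
        (ev$yPKPy[idx] - ev$trPK[idx]) / q_levels[idx]
      em <- pmax(em, 0.05 * theta[idx])
      prop[idx] <- em
      ev2 <- reml_eval(st, prop)
      if (is.null(ev2)) {
        # halve toward the current point until feasible
        for (h in 1:30) {
          prop[idx] <- (prop[idx] + theta[idx]) / 2
          ev2 <- reml_eval(st, prop)
          if (!is.null(ev2)) break
        }
        if (is.null(ev2)) stop("V numerically singular; no feasible step")
      }
    }
    steps <- c(steps, step_kind)
    dlog <- abs(ev2$logL - ev$logL)
    dtheta <- max(abs(prop - theta) / pmax(pmax(prop, theta), 1e-4 * s2_tot))
    theta <- prop
    ev <- ev2
    # pin components collapsing onto the boundary with non-positive score
    pin <- free & seq_len(M) < M & theta < bound_tol & ev$score <= 0
    if (any(pin)) {
      theta[pin] <- 0
      free[pin] <- FALSE
      ev <- reml_eval(st, theta)
    }
    if (control$verbose)
      cat(sprintf("it %3d [%s] logL = %.8f  theta = %s\n", it, step_kind,
                  ev$logL, paste(signif(theta, 6), collapse = " ")))
    if (dlog < control$tol_logl * (1 + abs(ev$logL)) &&
        dtheta < control$tol_theta) {
      converged <- TRUE
      break
    }
  }

  term_names <- c(names(terms), "residual")
  idx <- which(free)
  ai_cov <- matrix(NA_real_, M, M, dimnames = list(term_names, term_names))
  se <- rep(NA_real_, M)
  ai_free_inv <- tryCatch(solve(ev$AI[idx, idx, drop = FALSE]),
                          error = function(e) NULL)
  if (!is.null(ai_free_inv)) {
    ai_cov[idx, idx] <- ai_free_inv
    se[idx] <- sqrt(pmax(diag(ai_free_inv), 0))
  }
  comp <- data.frame(term = term_names, variance = theta, se = se,
                     boundary = !free, row.names = NULL)

  beta <- stats::setNames(ev$beta, colnames(X))
  beta_cov <- ev$XtViX_inv
  dimnames(beta_cov) <- list(colnames(X), colnames(X))
  Py_orig <- if (st$kind == "diag") as.vector(st$U %*% ev$Py) else ev$Py

  fit <- list(spec = spec, components = comp, V_P = sum(theta),
              logLik = ev$logL, beta = beta,
              beta_cov = beta_cov,
              assign = bundle$assign, term_labels = bundle$term_labels,
              pruned = bundle$pruned, n_obs = n, n_fixed_rank = p,
              n_dropped = bundle$n_dropped,
              convergence = list(converged = converged, iterations = it,
                                 steps = steps,
                                 final_score_norm = sqrt(sum(ev$score[free]^2))),
              ai = ev$AI, ai_cov = ai_cov,
              internal = list(kind = st$kind, st = st, ev = ev,
                              Py = Py_orig),
              bundle = bundle, ybar = mean(y))
  class(fit) <- "reml_fit"
  if (!converged)
    warning("REML did not converge in ", control$maxit, " iterations")
  fit
}

#' @export
logLik.reml_fit <- function(object, ...) {
  structure(object$logLik, df = sum(!object$components$boundary),
            class = "logLik")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("Animal-model REML fit: n = %d, fixed rank = %d, logL = %.4f%s\n",
              x$n_obs, x$n_fixed_rank, x$logLik,
              if (x$convergence$converged) "" else "  [NOT CONVERGED]"))
  comp <- x$components
  comp$variance <- signif(comp$variance, 6)
  comp$se <- signif(comp$se, 4)
  print(comp, row.names = FALSE)
  cat(sprintf("V_P = %.6g\n", x$V_P))
  invisible(x)
}

#' Extract a variance component from a fit
#'
#' @param fit a [reml_fit()].
#' @param term term name (\code{"additive"}, \code{"residual"}, or an
#'   extra-random term name); unknown terms return 0 (absent from the
#'   model means the component is structurally zero).
#' @return the estimated variance.
#' @export
varcomp <- function(fit, term) {
  stopifnot(inherits(fit, "reml_fit"))
  i <- match(term, fit$components$term)
  if (is.na(i)) 0 else fit$components$variance[i]
}
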