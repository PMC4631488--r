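test_that("build_design assembles y, X and incidence maps", {
  ped <- pedigree(c("S", "D", paste0("O", 1:6)),
                  c(NA, NA, rep("S", 6)), c(NA, NA, rep("D", 6)))
  dat <- data.frame(animal = paste0("O", 1:6), y = rnorm(6))
  spec <- mm_spec("y", ~1, animal = "animal", pedigree = ped)
  b <- build_design(spec, dat)
  expect_equal(dim(b$X), c(6, 1))
  expect_true(all(b$X == 1))
  expect_equal(b$terms$additive$n_levels, 8)
  expect_equal(b$terms$additive$idx, 3:8)

  # repeated measures: a permanent-environment identity term maps two
  # records onto each of 3 animals
  dat2 <- data.frame(animal = rep(c("O1", "O2", "O3"), 2),
                     year = rep(1:2, each = 3), y = rnorm(6))
  spec2 <- mm_spec("y", ~1, animal = "animal", pedigree = ped,
                   extra_random = c(pe = "animal"))
  b2 <- build_design(spec2, dat2)
  expect_equal(b2$terms$pe$n_levels, 3)
  expect_equal(unname(table(b2$terms$pe$idx)), rep(2L, 3),
               ignore_attr = TRUE)
})

test_that("a 4-level factor nested in 2 years spans 8 estimable columns", {
  set.seed(1)
  dat <- expand.grid(year = factor(1:2), order = factor(1:4),
                     rep = 1:3)
  dat$y <- rnorm(nrow(dat))
  dat$g <- sample(c("a", "b"), nrow(dat), replace = TRUE)
  spec <- mm_spec("y", ~ year + year:order, extra_random = c(g = "g"))
  b <- build_design(spec, dat)
  # oracle: the cell-means space of the 2 x 4 grid has dimension 8
  expect_equal(ncol(b$X), qr(model.matrix(~ interaction(year, order),
                                          dat))$rank)
  expect_equal(ncol(b$X), 8)
})

test_that("design construction errors are specific", {
  ped <- pedigree(c("S", "D", "O1"), c(NA, NA, "S"), c(NA, NA, "D"))
  dat <- data.frame(animal = c("O1", "ghost"), y = c(1, 2), f = "one")
  spec <- mm_spec("y", ~1, animal = "animal", pedigree = ped)
  expect_error(build_design(spec, dat), "absent from the pedigree")
  dat$animal <- c("O1", "O1")
  spec2 <- mm_spec("y", ~f, animal = "animal", pedigree = ped)
  expect_error(build_design(spec2, dat), "single level")
  dat$y <- NA_real_
  expect_error(build_design(spec, dat), "no complete observations")
  expect_error(mm_spec("y", ~ 0 + f), "intercept")
})

test_that("pure-noise data pins the genetic variance at the boundary", {
  ds <- small_animal_data(V_A = 0, V_R = 25, seed = 5)
  spec <- mm_spec("value", ~1, animal = "animal", pedigree = ds$pedigree)
  fit <- reml_fit(spec, ds$phenotypes)
  comp <- fit$components
  expect_equal(comp$variance[comp$term == "additive"], 0)
  expect_true(comp$boundary[comp$term == "additive"])
  expect_equal(comp$variance[comp$term == "residual"],
               var(ds$phenotypes$value), tolerance = 0.15)
  # all breeding values are exactly zero at a zero additive variance
  expect_equal(unique(extract_breeding_values(fit)$ebv), 0)
})

test_that("balanced sire-model REML equals the closed-form ANOVA estimator", {
  for (seed in 1:5) {
    dat <- balanced_sire_data(s = 15, n = 10, v_s = 5, v_w = 20, seed = seed)
    ref <- anova_sire_estimate(dat)
    if (ref["sire"] <= 0) next
    fit <- reml_fit(sire_spec(), dat,
                    reml_control(tol_logl = 1e-12, tol_theta = 1e-9))
    expect_equal(varcomp(fit, "sire"), unname(ref["sire"]), tolerance = 1e-7)
    expect_equal(varcomp(fit, "residual"), unname(ref["residual"]),
                 tolerance = 1e-7)
  }
})

test_that("REML agrees with lme4 on an iid random-intercept model", {
  skip_if_not_installed("lme4")
  dat <- balanced_sire_data(s = 12, n = 7, seed = 3)
  # make it unbalanced so the check is not the ANOVA special case
  dat <- dat[-c(1, 2, 15), ]
  fit <- reml_fit(sire_spec(), dat,
                  reml_control(tol_logl = 1e-12, tol_theta = 1e-9))
  lf <- lme4::lmer(y ~ 1 + (1 | sire), dat, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(varcomp(fit, "sire"), vc$vcov[1], tolerance = 1e-4)
  expect_equal(varcomp(fit, "residual"), vc$vcov[2], tolerance = 1e-4)
  expect_equal(fit$logLik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
})

test_that("REML is invariant to row order and animal relabeling", {
  ds <- small_animal_data(seed = 8)
  spec <- mm_spec("value", ~1, animal = "animal", pedigree = ds$pedigree)
  fit <- reml_fit(spec, ds$phenotypes)
  # permute rows
  set.seed(1)
  perm <- sample(nrow(ds$phenotypes))
  fit_p <- reml_fit(spec, ds$phenotypes[perm, ])
  expect_equal(fit_p$components$variance, fit$components$variance,
               tolerance = 1e-6)
  expect_equal(fit_p$logLik, fit$logLik, tolerance = 1e-6)
  # relabel animals (prefix swap preserves structure, changes sort order)
  relab <- function(x) paste0("zz", x)
  ped2 <- ds$pedigree
  p2 <- pedigree(relab(ped2$animal),
                 ifelse(is.na(ped2$sire), NA, relab(ped2$sire)),
                 ifelse(is.na(ped2$dam), NA, relab(ped2$dam)))
  dat2 <- ds$phenotypes
  dat2$animal <- relab(dat2$animal)
  fit_r <- reml_fit(mm_spec("value", ~1, animal = "animal", pedigree = p2),
                    dat2)
  expect_equal(fit_r$components$variance, fit$components$variance,
               tolerance = 1e-6)
  expect_equal(fit_r$logLik, fit$logLik, tolerance = 1e-6)
})

test_that("converged components sit at a local REML maximum", {
  ds <- small_animal_data(V_A = 8, V_R = 20, seed = 2)
  phen <- ds$phenotypes
  spec <- mm_spec("value", ~1, animal = "animal", pedigree = ds$pedigree,
                  extra_random = c(family = "family"))
  fit <- reml_fit(spec, phen, reml_control(tol_logl = 1e-10))
  logl_at <- function(theta) {
    # re-evaluate the restricted likelihood at fixed components by a
    # one-iteration fit bootstrapped from the profile evaluator
    b <- build_design(spec, phen)
    K <- list(b$terms$additive$A[b$terms$additive$idx, b$terms$additive$idx],
              outer(b$terms$family$idx, b$terms$family$idx, "=="),
              diag(length(b$y)))
    n <- length(b$y)
    V <- theta[1] * K[[1]] + theta[2] * K[[2]] + theta[3] * K[[3]]
    ch <- chol(V)
    Vi <- chol2inv(ch)
    W <- Vi %*% b$X
    XtViX <- crossprod(b$X, W)
    Py <- Vi %*% b$y - W %*% solve(XtViX, crossprod(W, b$y))
    -0.5 * ((n - ncol(b$X)) * log(2 * pi) + 2 * sum(log(diag(ch))) +
              determinant(XtViX)$modulus[1] + sum(b$y * Py))
  }
  th <- fit$components$variance
  base <- logl_at(th)
  expect_equal(base, fit$logLik, tolerance = 1e-6)
  for (k in seq_along(th)) {
    for (eps in c(-0.05, 0.05)) {
      cand <- th
      cand[k] <- th[k] * (1 + eps)
      if (th[k] == 0) {
        if (eps < 0) next               # outward of the boundary
        cand[k] <- 0.05 * mean(th)      # inward perturbation only
      }
      expect_lte(logl_at(cand), base + 1e-6)
    }
  }
})

test_that("adding a random term never decreases the restricted likelihood", {
  ds <- small_animal_data(V_A = 6, V_R = 24, seed = 4)
  phen <- ds$phenotypes
  spec1 <- mm_spec("value", ~1, animal = "animal", pedigree = ds$pedigree)
  spec2 <- mm_spec("value", ~1, animal = "animal", pedigree = ds$pedigree,
                   extra_random = c(family = "family"))
  f1 <- reml_fit(spec1, phen)
  f2 <- reml_fit(spec2, phen)
  expect_gte(f2$logLik, f1$logLik - 1e-6)
})

test_that("the boundary LR test behaves at its edge cases", {
  ds <- small_animal_data(seed = 6)
  spec_full <- mm_spec("value", ~1, animal = "animal",
                       pedigree = ds$pedigree)
  fit <- reml_fit(spec_full, ds$phenotypes)
  expect_error(loglik_ratio_test(fit, fit), "exactly one random term")
  reduced <- reml_fit(mm_spec("value", ~1,
                              extra_random = c(family = "family")),
                      ds$phenotypes)
  expect_error(loglik_ratio_test(fit, reduced), "exactly one random term")
})

test_that("a zero likelihood gap gives the conventional p = 0.5", {
  ds <- small_animal_data(seed = 7)
  full <- reml_fit(mm_spec("value", ~1, animal = "animal",
                           pedigree = ds$pedigree,
                           extra_random = c(family = "family")),
                   ds$phenotypes)
  reduced <- full
  reduced$components <- reduced$components[
    reduced$components$term != "family", ]
  # same likelihood by construction
  lrt <- loglik_ratio_test(full, reduced)
  expect_equal(lrt$statistic, 0)
  expect_equal(lrt$p_value, 0.5)
  expect_equal(lrt$term, "family")
  lrt_plain <- loglik_ratio_test(full, reduced, mixture = FALSE)
  expect_equal(lrt_plain$p_value, 1)
})

test_that("Wald F reduces to the squared z for a single covariate", {
  set.seed(9)
  dat <- balanced_sire_data(s = 10, n = 8, seed = 9)
  dat$x <- rnorm(nrow(dat))
  dat$y <- dat$y + 0.3 * dat$x
  spec <- mm_spec("y", ~x, extra_random = c(sire = "sire"))
  fit <- reml_fit(spec, dat)
  w <- wald_f(fit, "x")
  z2 <- (fit$beta[["x"]] / sqrt(fit$beta_cov["x", "x"]))^2
  expect_equal(w$F, unname(z2), tolerance = 1e-8)
  expect_equal(w$ndf, 1)
  expect_equal(w$ddf, fit$n_obs - 2)
})

test_that("a large injected order effect is detected at p < 1e-6", {
  ds <- small_animal_data(V_A = 5, V_R = 10, seed = 10)
  phen <- ds$phenotypes
  phen$value <- phen$value + 25 * (phen$order - 1)   # effect >> noise
  spec <- mm_spec("value", ~ factor(order), animal = "animal",
                  pedigree = ds$pedigree)
  fit <- reml_fit(spec, phen)
  w <- wald_f(fit, "factor(order)")
  expect_equal(w$ndf, 3)
  expect_lt(w$p_value, 1e-6)
  expect_error(wald_f(fit, "nonexistent"), "not in the fixed part")
})
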