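test_that("identical seeds reproduce datasets byte-identically; distinct seeds differ", {
  a <- simulate_dataset(sim_config(seed = 101))
  b <- simulate_dataset(sim_config(seed = 101))
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth, b$truth)
  expect_identical(as.data.frame(a$pedigree), as.data.frame(b$pedigree))
  c <- simulate_dataset(sim_config(seed = 102))
  expect_false(identical(a$phenotypes$value, c$phenotypes$value))
  for (col in c("value", "age")) {
    expect_false(any(a$phenotypes[[col]][1:50] ==
                       c$phenotypes[[col]][1:50]))
  }
})

test_that("config validation rejects impossible designs", {
  expect_error(sim_config(offspring_range = c(0, 5)), "within \\[1, 50\\]")
  expect_error(sim_config(offspring_range = c(9, 5)), "increasing")
  expect_error(sim_config(components = list(
    intracellular = c(V_A = -1, V_C = 0, V_PE = 0, V_R = 1))),
    "non-negative")
  expect_error(sim_config(challenge_multiplier = 0), "positive")
  expect_error(sim_config(attrition = 0), "attrition")
})

test_that("the design yields the configured record counts and repeated measures", {
  cfg <- sim_config(seed = 55)
  ds <- simulate_dataset(cfg)
  phen <- ds$phenotypes[ds$phenotypes$fraction == "intracellular", ]
  n1 <- sum(phen$year == 1)
  n2 <- sum(phen$year == 2)
  expect_true(n1 >= 60 * 5 && n1 <= 60 * 10)
  expect_equal(n2, round(cfg$attrition * n1))
  # every phenotyped animal is in the pedigree with both parents known
  expect_true(all(phen$animal %in% ds$pedigree$animal))
  idx <- match(phen$animal, ds$pedigree$animal)
  expect_true(all(ds$pedigree$sire_idx[idx] > 0))
  expect_true(all(ds$pedigree$dam_idx[idx] > 0))
  # year-2 animals are a subset of year-1 animals (repeated measures)
  expect_true(all(phen$animal[phen$year == 2] %in%
                    phen$animal[phen$year == 1]))
})

test_that("degenerate generator: no genetic signal means h2 near zero", {
  cfg <- sim_config(n_sires = 10, n_dams_per_sire = 2,
                    offspring_range = c(8, 8),
                    components = list(
                      intracellular = c(V_A = 0, V_C = 0, V_PE = 0,
                                        V_R = 30)),
                    means = list(intracellular = c(20, 20)),
                    order_slope = 0, seed = 77)
  ds <- simulate_dataset(cfg)
  phen <- ds$phenotypes[ds$phenotypes$year == 1, ]
  expect_equal(var(phen$value), 30, tolerance = 0.25)
  fit <- reml_fit(mm_spec("value", ~1, animal = "animal",
                          pedigree = ds$pedigree), phen)
  expect_lt(heritability(fit)$h2, 0.1)
})

test_that("sib phenotypic covariances match the design's expectations", {
  # full-sib covariance ~ V_A/2 + V_C, paternal half-sib ~ V_A/4:
  # the identifiability backbone of the nested design
  V_A <- 12; V_C <- 4; V_R <- 24
  n_rep <- 250
  fs <- hs <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_sires = 6, n_dams_per_sire = 3,
                      offspring_range = c(4, 4),
                      components = list(
                        intracellular = c(V_A = V_A, V_C = V_C, V_PE = 0,
                                          V_R = V_R)),
                      means = list(intracellular = c(20, 20)),
                      order_slope = 0, attrition = 1, seed = 9000 + r)
    ds <- simulate_dataset(cfg)
    phen <- ds$phenotypes[ds$phenotypes$year == 1, ]
    idx <- match(phen$animal, ds$pedigree$animal)
    phen$sire <- ds$pedigree$sire[idx]
    phen$fam <- phen$family
    # mean cross-products of centred values within full-sib and half-sib
    # (different-dam) pairs; centred at the generator's true mean so the
    # cross-products are unbiased for the sib covariances
    y <- phen$value - 20
    fam_pairs <- hs_pairs <- 0
    fam_sum <- hs_sum <- 0
    split_fam <- split(seq_along(y), phen$fam)
    for (ii in split_fam) {
      cp <- tcrossprod(y[ii])
      fam_sum <- fam_sum + sum(cp[upper.tri(cp)])
      fam_pairs <- fam_pairs + choose(length(ii), 2)
    }
    split_sire <- split(seq_along(y), phen$sire)
    for (ii in split_sire) {
      cp <- tcrossprod(y[ii])
      tot <- sum(cp[upper.tri(cp)])
      # subtract the full-sib pairs within the sire group
      fams <- split(ii, phen$fam[ii])
      fs_in <- sum(vapply(fams, function(jj) {
        cpp <- tcrossprod(y[jj]); sum(cpp[upper.tri(cpp)])
      }, 0))
      fs_n <- sum(vapply(fams, function(jj) choose(length(jj), 2), 0))
      hs_sum <- hs_sum + tot - fs_in
      hs_pairs <- hs_pairs + choose(length(ii), 2) - fs_n
    }
    fs[r] <- fam_sum / fam_pairs
    hs[r] <- hs_sum / hs_pairs
  }
  mc_se_fs <- sd(fs) / sqrt(n_rep)
  mc_se_hs <- sd(hs) / sqrt(n_rep)
  expect_lt(abs(mean(fs) - (V_A / 2 + V_C)), 3 * mc_se_fs)
  expect_lt(abs(mean(hs) - V_A / 4), 3 * mc_se_hs)
})

test_that("stored truth reconstructs the phenotypes (slope one)", {
  cfg <- sim_config(n_sires = 12, n_dams_per_sire = 3,
                    offspring_range = c(6, 6),
                    components = list(
                      intracellular = c(V_A = 15, V_C = 5, V_PE = 5,
                                        V_R = 20)),
                    means = list(intracellular = c(20, 28)),
                    seed = 123)
  ds <- simulate_dataset(cfg)
  phen <- ds$phenotypes
  tr <- ds$truth[match(phen$animal, ds$truth$animal), ]
  genetic <- tr$bv + tr$family_effect + tr$pe
  # regress the phenotype on the stored genetic part, controlling the
  # fixed structure the generator added
  fitlm <- lm(phen$value ~ genetic + phen$age + factor(phen$order))
  expect_equal(unname(coef(fitlm)["genetic"]), 1, tolerance = 0.1)
})

test_that("challenge experiment has bounded groups and a calibrated null", {
  ch <- simulate_challenge_experiment(sim_config(seed = 8))
  sizes <- table(ch$group, ch$fraction)
  expect_true(all(sizes >= 6 & sizes <= 10))
  expect_setequal(levels(ch$group), c("not_injected", "SSW", "zymosan"))
  # multiplier 3: the challenge term is detected essentially always
  hits <- vapply(1:40, function(r) {
    ch <- simulate_challenge_experiment(sim_config(seed = 3000 + r))
    a <- pheno_anova(ch[ch$fraction == "intracellular", ], "hsp70", "group")
    a$table$p[1] < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  # multiplier 1: rejection collapses to the nominal rate
  null_p <- vapply(1:200, function(r) {
    ch <- simulate_challenge_experiment(
      sim_config(challenge_multiplier = 1, seed = 5000 + r))
    pheno_anova(ch[ch$fraction == "intracellular", ],
                "hsp70", "group")$table$p[1]
  }, 0)
  rate <- mean(null_p <= 0.05)
  expect_lt(abs(rate - 0.05), 1.96 * sqrt(0.05 * 0.95 / 200) + 0.02)
})

test_that("datasets write to commented CSV and the pedigree reads back", {
  ds <- simulate_dataset(sim_config(n_sires = 4, seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  expect_match(readLines(paths[1], n = 1), "^# seed 2$")
  ped <- read_pedigree(paths[1])
  expect_equal(nrow(ped), nrow(ds$pedigree))
  expect_setequal(founders(ped), founders(ds$pedigree))
})
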