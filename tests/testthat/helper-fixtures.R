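# Fixture builders shared across the suite. All randomness is driven by an
# explicit seed so every test is reproducible in isolation.

# Random multi-generation pedigree: founders plus animals whose parents are
# drawn (possibly unknown) from earlier animals. Guaranteed acyclic by
# construction.
random_pedigree <- function(n, n_founders = max(4L, n %/% 5L), seed = 1L) {
  set.seed(seed)
  id <- sprintf("A%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq.int(n_founders + 1L, n)) {
    pool <- seq_len(i - 1L)
    if (stats::runif(1) < 0.9) sire[i] <- id[sample(pool, 1)]
    if (stats::runif(1) < 0.9) dam[i] <- id[sample(pool, 1)]
  }
  pedigree(id, sire, dam)
}

# Balanced paternal half-sib style one-way layout for the sire model:
# s sires, n offspring each, V(sire) = v_s, V(within) = v_w.
balanced_sire_data <- function(s = 20, n = 15, v_s = 4, v_w = 20,
                               mu = 10, seed = 1L) {
  set.seed(seed)
  sire <- rep(sprintf("s%02d", seq_len(s)), each = n)
  u <- stats::rnorm(s, 0, sqrt(v_s))
  data.frame(y = mu + u[as.integer(factor(sire))] +
               stats::rnorm(s * n, 0, sqrt(v_w)),
             sire = sire)
}

sire_spec <- function() mm_spec("y", ~1, extra_random = c(sire = "sire"))

# Closed-form balanced one-way ANOVA estimator of the sire variance.
anova_sire_estimate <- function(dat) {
  n <- as.vector(table(dat$sire))[1]
  a <- stats::anova(stats::lm(y ~ sire, dat))
  c(sire = (a$`Mean Sq`[1] - a$`Mean Sq`[2]) / n,
    residual = a$`Mean Sq`[2])
}

# Small nested full-sib dataset with an additive animal effect, one record
# per animal, for animal-model unit tests.
small_animal_data <- function(n_sires = 6, n_dams = 2, n_off = 4,
                              V_A = 8, V_R = 20, mu = 10, seed = 1L) {
  cfg <- sim_config(n_sires = n_sires, n_dams_per_sire = n_dams,
                    offspring_range = c(n_off, n_off),
                    components = list(
                      intracellular = c(V_A = V_A, V_C = 0, V_PE = 0,
                                        V_R = V_R)),
                    means = list(intracellular = c(mu, mu)),
                    order_slope = 0, attrition = 1, seed = seed)
  ds <- simulate_dataset(cfg)
  ds$phenotypes <- ds$phenotypes[ds$phenotypes$year == 1, ]
  ds
}

# Printed per-age genetic estimates used as arithmetic inputs:
# mean, V_A, V_R, V_P per trait x age class.
table1_inputs <- function() {
  data.frame(
    row = c("intra_young", "intra_harvest", "extra_young", "extra_harvest"),
    mean = c(16.40, 32.27, 26.59, 30.87),
    V_A = c(4.72, 0.76, 18.61, 6.31),
    V_R = c(45.91, 92.29, 355.85, 84.14),
    V_P = c(50.62, 93.06, 374.47, 90.44))
}
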