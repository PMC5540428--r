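test_that("config validation rejects impossible variance shares and probabilities", {
  expect_error(sim_config(trait_params = list(t = c(a2 = 0.5, c2 = 0.2, e2 = 0.2))),
               "must equal 1")
  expect_error(sim_config(rG = 1.2), "\\[-1, 1\\]")
  expect_error(sim_config(p_extra_sib = 1.4), "probabilities")
  expect_error(sim_config(diagnosis_params = list(d = list(trait = 1, intercept = 0,
                                                           slope = 0, sigma2 = -1))),
               "nonnegative")
})

test_that("simulation is deterministic given the seed and structurally consistent", {
  cfg <- sim_config(n_mz_pairs = 30, n_dz_pairs = 40, p_extra_sib = 0.3,
                    n_singletons = 10,
                    item_bank = list(ad = default_item_bank(6, "ad")), seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  ped <- a$pedigree
  expect_false(anyDuplicated(ped$person_id) > 0)
  expect_true(all(a$responses$person_id == ped$person_id))
  # MZ co-twins share sex; twin pairs unique per family
  for (f in unique(ped$family_id[ped$zygosity == "MZ"])) {
    fam <- ped[ped$family_id == f & ped$role %in% c("twin1", "twin2"), ]
    expect_equal(length(unique(fam$sex)), 1)
  }
  x <- as.matrix(a$responses[, grep("^item_", names(a$responses), value = TRUE)])
  expect_true(all(x %in% 0:2))
})

test_that("a purely genetic trait makes MZ co-twins identical", {
  cfg <- sim_config(n_mz_pairs = 200, n_dz_pairs = 0, p_extra_sib = 0,
                    n_singletons = 0,
                    trait_params = list(t = c(a2 = 1, c2 = 0, e2 = 0)), seed = 3)
  co <- simulate_cohort(cfg)
  t1 <- co$truth$theta_t[co$pedigree$role == "twin1"]
  t2 <- co$truth$theta_t[co$pedigree$role == "twin2"]
  expect_equal(cor(t1, t2), 1, tolerance = 1e-12)
  expect_equal(t1, t2)
})

test_that("AE generation reproduces the closed-form twin correlations", {
  cfg <- sim_config(n_mz_pairs = 5000, n_dz_pairs = 5000, p_extra_sib = 0,
                    n_singletons = 0,
                    trait_params = list(t = c(a2 = 0.4, c2 = 0, e2 = 0.6)), seed = 7)
  co <- simulate_cohort(cfg)
  ped <- co$pedigree
  th <- co$truth$theta_t
  r <- sapply(c("MZ", "DZ"), function(z) {
    cor(th[ped$zygosity == z & ped$role == "twin1"],
        th[ped$zygosity == z & ped$role == "twin2"])
  })
  expect_lt(abs(r[["MZ"]] - 0.4), 0.03)
  expect_lt(abs(r[["DZ"]] - 0.2), 0.03)
  expect_lt(abs(var(th) - 1), 0.05)
  # twin-sibling sharing is 0.5 by design
  cfg2 <- sim_config(n_mz_pairs = 0, n_dz_pairs = 4000, p_extra_sib = 1,
                     n_singletons = 0,
                     trait_params = list(t = c(a2 = 1, c2 = 0, e2 = 0)), seed = 8)
  co2 <- simulate_cohort(cfg2)
  A1 <- co2$truth$A_t[co2$pedigree$role == "twin1"]
  As <- co2$truth$A_t[co2$pedigree$role == "sib"]
  expect_lt(abs(cor(A1, As) - 0.5), 0.04)
})

test_that("cross-trait genetic correlation matches the configured rG", {
  cfg <- sim_config(n_mz_pairs = 2500, n_dz_pairs = 2500, p_extra_sib = 0,
                    n_singletons = 0,
                    trait_params = list(t1 = c(a2 = 0.4, c2 = 0, e2 = 0.6),
                                        t2 = c(a2 = 0.5, c2 = 0, e2 = 0.5)),
                    rG = 0.87, rE = 0.44, seed = 11)
  co <- simulate_cohort(cfg)
  expect_lt(abs(cor(co$truth$A_t1, co$truth$A_t2) - 0.87), 0.03)
  expect_lt(abs(cor(co$truth$E_t1, co$truth$E_t2) - 0.44), 0.03)
})

test_that("graded-response items respect limits, asymptotes and ordering", {
  sp <- item_spec("x", a = 2, b = c(-0.5, 0.7), d = 1)
  S <- item_true_steps(sp, c(-50, 0, 50))
  expect_lt(abs(S[3, "S2"] - 1), 1e-10)   # logistic limit
  expect_lt(S[1, "S1"], 1e-10)
  lo <- item_spec("y", a = 2, b = c(0, 1), d = 0.4)
  Sl <- item_true_steps(lo, seq(-3, 3, length.out = 201))
  expect_lte(max(Sl[, "S1"]), 0.4)
  expect_true(all(Sl[, "S1"] >= Sl[, "S2"]))
  # dip produces an analytic decrease inside the central range
  dp <- item_spec("z", a = 2, b = c(-2, 1.2), dip = list(m = 0, s = 0.5, gamma = 0.3))
  g <- seq(-1.96, 1.96, length.out = 101)
  Sd <- item_true_steps(dp, g)[, "S1"]
  expect_lt(min(diff(Sd)), 0)
  expect_true(all(Sd >= item_true_steps(dp, g)[, "S2"]))
})

test_that("monotone items yield nondecreasing endorsement across trait deciles", {
  bank <- default_item_bank(8, "m")
  sim <- singleton_cohort(10000, bank, seed = 13)
  co <- sim$cohort
  th <- co$truth$theta_tr
  dec <- cut(th, quantile(th, 0:10 / 10), include.lowest = TRUE, labels = FALSE)
  x <- as.matrix(co$responses[, grep("^item_", names(co$responses), value = TRUE)])
  for (j in seq_len(ncol(x))) {
    p <- tapply(x[, j] >= 1, dec, mean)
    inv <- diff(p) < 0
    expect_lte(sum(inv), 1)
    if (any(inv)) expect_lte(max(-diff(p)[inv]), 0.02)
  }
})

test_that("retest administration has the configured trait reliability", {
  cfg1 <- sim_config(n_singletons = 5000, n_mz_pairs = 0, n_dz_pairs = 0,
                     trait_params = list(t = c(a2 = 0.3, c2 = 0, e2 = 0.7)),
                     retest_reliability = 1, seed = 17)
  co1 <- simulate_cohort(cfg1)
  r1 <- simulate_retest(co1, cfg1)
  expect_equal(unname(attr(r1, "theta_retest")[, 1]), co1$truth$theta_t)
  for (rho in c(0.47, 0)) {
    cfg <- sim_config(n_singletons = 5000, n_mz_pairs = 0, n_dz_pairs = 0,
                      trait_params = list(t = c(a2 = 0.3, c2 = 0, e2 = 0.7)),
                      retest_reliability = rho, seed = 17)
    co <- simulate_cohort(cfg)
    r2 <- simulate_retest(co, cfg)
    expect_lt(abs(cor(co$truth$theta_t, attr(r2, "theta_retest")[, 1]) - rho),
              0.03)
  }
})

test_that("diagnosis generator controls prevalence and slope", {
  cfg <- sim_config(n_singletons = 10000, n_mz_pairs = 0, n_dz_pairs = 0,
                    trait_params = list(t = c(a2 = 0.3, c2 = 0, e2 = 0.7)),
                    diagnosis_params = list(
                      flat = list(trait = 1, intercept = qlogis(0.16), slope = 0,
                                  sigma2 = 0),
                      mdd = list(trait = 1, intercept = qlogis(0.16),
                                 slope = log(1.39), sigma2 = 0)),
                    seed = 19)
  co <- simulate_cohort(cfg)
  dg <- simulate_diagnoses(co, cfg)
  expect_lt(abs(mean(dg$flat) - 0.16), 0.015)
  # ordinary ML logistic oracle recovers the generating odds ratio
  fit <- glm(dg$mdd ~ co$truth$theta_t, family = binomial())
  expect_lt(abs(exp(coef(fit)[[2]]) - 1.39), 0.05)
  # constant latent trait carries no association
  co$truth$theta_t <- rep(0, nrow(co$truth))
  dg0 <- simulate_diagnoses(co, cfg)
  z <- rnorm(nrow(co$truth))
  fit0 <- glm(dg0$mdd ~ z, family = binomial())
  expect_lt(abs(coef(fit0)[2]), 0.08)
})
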