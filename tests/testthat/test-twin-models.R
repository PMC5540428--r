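sim_scores <- function(seed, n_mz = 150, n_dz = 250, p_sib = 0.13, n_single = 30,
                       a2 = 0.4, two = FALSE, rG = 0.87, rE = 0.44) {
  tp <- if (two) list(t1 = c(a2 = a2, c2 = 0, e2 = 1 - a2),
                      t2 = c(a2 = 0.42, c2 = 0, e2 = 0.58))
  else list(t = c(a2 = a2, c2 = 0, e2 = 1 - a2))
  cfg <- sim_config(n_mz_pairs = n_mz, n_dz_pairs = n_dz, p_extra_sib = p_sib,
                    n_singletons = n_single, trait_params = tp,
                    rG = rG, rE = rE, seed = seed)
  co <- simulate_cohort(cfg)
  if (two) {
    sc <- cbind(co$truth$theta_t1, co$truth$theta_t2)
    rownames(sc) <- co$truth$person_id
    twin_data(co$pedigree, sc)
  } else {
    twin_data(co$pedigree, setNames(co$truth$theta_t, co$truth$person_id))
  }
}

test_that("the FIML likelihood equals direct multivariate-normal densities", {
  trio <- data.frame(person_id = c("a", "b", "c"), family_id = 1,
                     zygosity = "MZ", role = c("twin1", "twin2", "sib"),
                     sex = "F", y = c(0.3, -0.2, 1.1))
  a <- 0.6; e <- 0.7; mu <- 0.1
  S <- matrix(a^2 * 0.5, 3, 3)
  S[1, 2] <- S[2, 1] <- a^2
  diag(S) <- a^2 + e^2
  want <- oracle_mvn_logdens(trio$y, rep(mu, 3), S)
  got <- fiml_loglik(list(a = a, e = e, beta = mu), trio, "AE")
  expect_equal(got, want, tolerance = 1e-10)
  # singletons marginalize to univariate normals
  singles <- data.frame(person_id = letters[1:5], family_id = 1:5,
                        zygosity = "none", role = "singleton", sex = "M",
                        y = rnorm(5))
  got2 <- fiml_loglik(list(a = a, e = e, beta = 0), singles, "AE")
  expect_equal(got2, sum(dnorm(singles$y, 0, sqrt(a^2 + e^2), log = TRUE)),
               tolerance = 1e-10)
  # with no additive variance, zygosity is irrelevant
  dz <- trio; dz$zygosity <- "DZ"
  expect_equal(fiml_loglik(list(a = 0, c = 0.5, e = e, beta = mu), trio, "ACE"),
               fiml_loglik(list(a = 0, c = 0.5, e = e, beta = mu), dz, "ACE"),
               tolerance = 1e-12)
})

test_that("an E-only FIML fit equals the closed-form normal MLE", {
  set.seed(7)
  singles <- data.frame(person_id = sprintf("s%02d", 1:80), family_id = 1:80,
                        zygosity = "none", role = "singleton", sex = "F",
                        y = rnorm(80, 1.4, 1.7))
  f <- fit_univariate(singles, "E", ci = FALSE, n_starts = 2)
  expect_equal(unname(f$beta[1]), mean(singles$y), tolerance = 1e-5)
  expect_equal(unname(f$paths["e"]^2),
               mean((singles$y - mean(singles$y))^2), tolerance = 1e-4)
})

test_that("AE fits recover generating heritability and hit boundaries sensibly", {
  a2hat <- sapply(1:3, function(s)
    fit_univariate(sim_scores(200 + s, n_mz = 226, n_dz = 408, a2 = 0.42),
                   "AE", ci = FALSE)$proportions["a"])
  expect_lt(abs(mean(a2hat) - 0.42), 0.08)
  # perfect twin correlations drive the estimate to the boundary
  d <- sim_scores(7, n_mz = 400, n_dz = 400, p_sib = 0, n_single = 0, a2 = 1)
  f <- fit_univariate(d, "AE", ci = FALSE)
  expect_gt(f$proportions["a"], 0.95)
  expect_gt(f$twin_correlations["rMZ"], 0.99)
})

test_that("profile CIs bracket the estimate and nested LRTs are ordered", {
  d <- sim_scores(31, n_mz = 200, n_dz = 300, a2 = 0.4)
  f_ae <- fit_univariate(d, "AE", ci = TRUE)
  expect_lt(f_ae$ci$a[1], f_ae$proportions["a"])
  expect_gt(f_ae$ci$a[2], f_ae$proportions["a"])
  expect_true(f_ae$ci$a[1] >= 0 && f_ae$ci$a[2] <= 1)
  f_e <- fit_univariate(d, "E", ci = FALSE)
  expect_gte(f_e$minus2ll, f_ae$minus2ll)   # nesting
  lrt <- lrt_twin(f_ae, f_e)
  expect_equal(lrt$df, 1)
  expect_lt(lrt$p, 0.05)                    # strong generating signal
  expect_lt(lrt_twin(f_ae, f_e, mixture = TRUE)$p, lrt$p + 1e-15)
  f_ace <- fit_univariate(d, "ACE", ci = FALSE)
  expect_lte(f_ace$minus2ll, f_ae$minus2ll + 1e-4)
  expect_equal(f_ace$aic, f_ace$minus2ll + 2 * f_ace$n_par)
})

test_that("dropping A from pure-noise data is rarely significant", {
  hits <- sapply(1:25, function(s) {
    d <- sim_scores(400 + s, n_mz = 60, n_dz = 90, p_sib = 0, n_single = 0, a2 = 0)
    f1 <- fit_univariate(d, "AE", ci = FALSE, n_starts = 2)
    f0 <- fit_univariate(d, "E", ci = FALSE, n_starts = 2)
    lrt_twin(f1, f0)$p < 0.05
  })
  expect_lte(mean(hits), 0.10)
})

test_that("the omnibus homogeneity test respects nesting and detects inflation", {
  d <- sim_scores(41)
  om <- omnibus_homogeneity_test(d)
  expect_gte(om$minus2ll_constrained, om$minus2ll_saturated)
  expect_gt(om$df, 0)
  # doubled variance in MZ twins is picked up
  hits <- sapply(1:5, function(s) {
    d2 <- sim_scores(500 + s, n_mz = 250, n_dz = 350)
    infl <- d2$zygosity == "MZ" & d2$role == "twin1"
    d2$y[infl] <- d2$y[infl] * sqrt(2)
    suppressWarnings(omnibus_homogeneity_test(d2)$p) < 0.05
  })
  expect_gte(mean(hits), 0.8)
  # calibration under the null
  ps <- sapply(1:30, function(s) suppressWarnings(
    omnibus_homogeneity_test(sim_scores(600 + s,
      n_mz = 80, n_dz = 120, n_single = 20))$p))
  expect_lte(mean(ps < 0.05), 0.17)
  expect_gte(mean(ps < 0.5), 0.25)
})

test_that("sex-limitation check orders likelihoods and reacts to sex-specific a2", {
  d <- sim_scores(51)
  sl <- sex_limitation_check(d)
  expect_gte(sl$stat, -1e-6)   # equal-paths model can never fit better
  # construct sex-specific heritability by mixing two generated cohorts
  mk <- function(seed, a2) {
    dd <- sim_scores(seed, n_mz = 400, n_dz = 400, p_sib = 0, n_single = 0, a2 = a2)
    same_sex <- ave(dd$sex == "F", dd$family_id, FUN = function(v) length(unique(v)) == 1)
    dd[same_sex == 1, ]
  }
  dF <- mk(61, 0.6); dF <- dF[dF$sex == "F", ]
  dM <- mk(62, 0.2); dM <- dM[dM$sex == "M", ]
  dM$family_id <- dM$family_id + max(dF$family_id)
  sl2 <- sex_limitation_check(rbind(dF, dM))
  expect_lt(sl2$p, 0.05)
  expect_gt(sl2$paths_by_sex$F[1], sl2$paths_by_sex$M[1])
})

test_that("bivariate Cholesky fits recover structure and decompose exactly", {
  d <- sim_scores(71, n_mz = 214, n_dz = 386, two = TRUE)
  f <- fit_bivariate(d, "AE", tests = FALSE)
  # model-implied phenotypic correlation decomposes through the components
  recon <- f$rG * sqrt(f$a2[1] * f$a2[2]) + f$rE * sqrt(f$e2[1] * f$e2[2])
  expect_equal(f$r_phenotypic, recon, tolerance = 1e-6)
  expect_true(all(abs(c(f$rG, f$rE, f$r_phenotypic)) <= 1 + 1e-8))
  expect_equal(f$rG, 0.87, tolerance = 0.12)    # single-replicate sanity
  # a shared single genetic factor forces rG to 1
  cfg <- sim_config(n_mz_pairs = 200, n_dz_pairs = 300, p_extra_sib = 0,
                    n_singletons = 0,
                    trait_params = list(t1 = c(a2 = 0.5, c2 = 0, e2 = 0.5),
                                        t2 = c(a2 = 0.5, c2 = 0, e2 = 0.5)),
                    rG = 1, rE = 0, seed = 73)
  co <- simulate_cohort(cfg)
  sc <- cbind(co$truth$theta_t1, co$truth$theta_t2)
  rownames(sc) <- co$truth$person_id
  f2 <- fit_bivariate(twin_data(co$pedigree, sc), "AE", tests = TRUE)
  expect_gt(f2$rG, 0.9)
  expect_gt(f2$lrt$rG1, 0.05)    # rG = 1 not rejected
  expect_lt(f2$lrt$rG0, 0.01)    # rG = 0 strongly rejected
  # independent traits
  cfg0 <- sim_config(n_mz_pairs = 200, n_dz_pairs = 300, p_extra_sib = 0,
                     n_singletons = 0,
                     trait_params = list(t1 = c(a2 = 0.5, c2 = 0, e2 = 0.5),
                                         t2 = c(a2 = 0.5, c2 = 0, e2 = 0.5)),
                     rG = 0, rE = 0, seed = 79)
  co0 <- simulate_cohort(cfg0)
  sc0 <- cbind(co0$truth$theta_t1, co0$truth$theta_t2)
  rownames(sc0) <- co0$truth$person_id
  f0 <- fit_bivariate(twin_data(co0$pedigree, sc0), "AE", tests = TRUE)
  expect_lt(abs(f0$rG), 0.2)
  expect_gt(f0$lrt$rG0, 0.05)
})
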