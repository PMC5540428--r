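test_that("alpha equals its brute-force oracle and behaves at the extremes", {
  x <- matrix(c(0, 1, 2, 1,
                1, 2, 0, 0,
                2, 2, 1, 0), 4, 3,
              dimnames = list(NULL, paste0("item_", 1:3)))
  expect_equal(cronbach_alpha(x), oracle_alpha(x), tolerance = 1e-12)
  copies <- cbind(item_1 = x[, 1], item_2 = x[, 1], item_3 = x[, 1])
  expect_equal(cronbach_alpha(copies), 1, tolerance = 1e-12)
  set.seed(67)
  indep <- matrix(sample(0:2, 10000 * 6, replace = TRUE), 10000, 6,
                  dimnames = list(NULL, paste0("item_", 1:6)))
  expect_lt(abs(cronbach_alpha(indep)), 0.05)
  expect_error(cronbach_alpha(matrix(1, 5, 3)), "zero variance")
})

test_that("alpha of parallel items follows the Spearman-Brown prophecy", {
  set.seed(71)
  k <- 5; rho <- 0.3; n <- 10000
  f <- rnorm(n)
  x <- sapply(1:k, function(j) sqrt(rho) * f + sqrt(1 - rho) * rnorm(n))
  colnames(x) <- paste0("item_", 1:k)
  expect_equal(cronbach_alpha(x), k * rho / (1 + (k - 1) * rho), tolerance = 0.02)
})

test_that("scalability coefficients match exhaustive comonotone-coupling oracle", {
  x <- matrix(c(0, 0, 0,
                1, 0, 0,
                1, 1, 0,
                2, 1, 1,
                2, 2, 2), 5, 3, byrow = TRUE,
              dimnames = list(NULL, paste0("item_", 1:3)))
  # nested step pattern: a perfect Guttman scale
  rep_ <- loevinger_h(x)
  expect_true(all(abs(rep_$Hij[upper.tri(rep_$Hij)] - 1) < 1e-12))
  expect_equal(rep_$H, 1, tolerance = 1e-12)
  set.seed(73)
  y <- matrix(sample(0:2, 5 * 3, replace = TRUE), 5, 3,
              dimnames = list(NULL, paste0("item_", 1:3)))
  while (any(apply(y, 2, var) == 0))
    y <- matrix(sample(0:2, 5 * 3, replace = TRUE), 5, 3,
                dimnames = list(NULL, paste0("item_", 1:3)))
  got <- loevinger_h(y)
  want <- oracle_loevinger(y)
  expect_equal(unname(got$Hij[upper.tri(got$Hij)]),
               want$Hij[upper.tri(want$Hij)], tolerance = 1e-12)
  expect_equal(unname(got$Hi), want$Hi, tolerance = 1e-12)
  expect_equal(got$H, want$H, tolerance = 1e-12)
})

test_that("monotone item banks show no negative pairwise scalability", {
  sim <- singleton_cohort(5000, default_item_bank(10, "h"), seed = 79)
  rep_ <- loevinger_h(sim$cohort$responses)
  expect_equal(rep_$n_negative_Hij, 0)
  expect_true(all(rep_$Hij[upper.tri(rep_$Hij)] >= -1 &
                    rep_$Hij[upper.tri(rep_$Hij)] <= 1))
  # Mokken class agrees with the published cutoffs applied to min Hi
  expected_class <- if (rep_$min_Hi >= 0.5) "strong"
  else if (rep_$min_Hi >= 0.4) "medium"
  else if (rep_$min_Hi >= 0.3) "weak" else "none"
  expect_equal(rep_$mokken_class, expected_class)
})

test_that("zero-score mass of the calibrated generator brackets the field range", {
  sim <- singleton_cohort(4000, default_item_bank(14, "z"), seed = 83)
  p0 <- zero_score_proportion(sim$cohort$responses)
  expect_gte(unname(p0), 0.10)
  expect_lte(unname(p0), 0.30)
})

test_that("consistency ICC ignores shifts and matches the ANOVA oracle", {
  set.seed(89)
  y <- rnorm(20)
  expect_equal(icc_consistency(y, y + 5)$icc, 1, tolerance = 1e-12)
  t6 <- c(1.1, 2.3, 0.4, 3.2, 1.8, 2.7)
  r6 <- c(0.8, 2.9, 0.9, 2.8, 1.2, 3.1)
  expect_equal(icc_consistency(t6, r6)$icc, oracle_icc_c1(t6, r6), tolerance = 1e-12)
  a <- rnorm(5000); b <- rnorm(5000)
  expect_lt(abs(icc_consistency(a, b)$icc), 0.03)
  expect_error(icc_consistency(1:2, 2:3), "at least 3")
})

test_that("winsorisation clips exactly at the input moments", {
  set.seed(97)
  x <- rnorm(100)
  expect_identical(winsorise(x), x)   # nothing beyond 3 sd here
  v <- c(rnorm(200), 50)
  w <- winsorise(v)
  expect_equal(max(w), mean(v) + 3 * sd(v), tolerance = 1e-12)
  expect_equal(w[v <= mean(v) + 3 * sd(v) & v >= mean(v) - 3 * sd(v)],
               v[v <= mean(v) + 3 * sd(v) & v >= mean(v) - 3 * sd(v)])
  # brute-force clip oracle
  clip <- pmin(pmax(v, mean(v) - 3 * sd(v)), mean(v) + 3 * sd(v))
  expect_equal(w, clip, tolerance = 1e-15)
})

test_that("kinship sex test reduces to OLS for unrelated persons and finds effects", {
  set.seed(101)
  n <- 300
  ped <- data.frame(person_id = sprintf("p%03d", 1:n), family_id = 1:n,
                    zygosity = "none", role = "singleton",
                    sex = sample(c("F", "M"), n, TRUE), stringsAsFactors = FALSE)
  y <- rnorm(n) + 0.3 * (ped$sex == "F")
  got <- sex_difference_test(setNames(y, ped$person_id), ped)
  ols <- summary(lm(y ~ I(ped$sex == "F")))$coefficients
  expect_equal(got$estimate, ols[2, 1], tolerance = 1e-6)
  expect_equal(got$p, ols[2, 4], tolerance = 1e-6)
  # injected +0.5 sd sex effect in a related sample
  cfg <- sim_config(n_mz_pairs = 300, n_dz_pairs = 500, p_extra_sib = 0.13,
                    n_singletons = 50,
                    trait_params = list(t = c(a2 = 0.4, c2 = 0, e2 = 0.6)),
                    sex_effect = list(t = 0.5), seed = 103)
  co <- simulate_cohort(cfg)
  res <- sex_difference_test(setNames(co$truth$theta_obs_t, co$truth$person_id),
                             co$pedigree)
  expect_equal(res$estimate, 0.5, tolerance = 0.1)
  expect_lt(res$p, 1e-3)
})

test_that("the null distribution of the kinship sex test is calibrated", {
  ps <- sapply(1:120, function(s) {
    cfg <- sim_config(n_mz_pairs = 70, n_dz_pairs = 100, p_extra_sib = 0.15,
                      n_singletons = 30,
                      trait_params = list(t = c(a2 = 0.5, c2 = 0, e2 = 0.5)),
                      seed = 1000 + s)
    co <- simulate_cohort(cfg)
    sex_difference_test(setNames(co$truth$theta_t, co$truth$person_id),
                        co$pedigree)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(mean(ps < 0.05), 0.11)
})
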