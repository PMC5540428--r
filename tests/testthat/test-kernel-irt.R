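make_resp <- function(x, ids = sprintf("p%03d", seq_len(nrow(x)))) {
  out <- data.frame(person_id = ids, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(x))
}

test_that("rank-based trait assignment matches the normal-quantile oracle", {
  r1 <- make_resp(matrix(1L, 1, 3, dimnames = list(NULL, paste0("item_", 1:3))))
  expect_equal(rank_theta(r1)$theta, 0)
  x <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 2, 2, 2), 4, 3, byrow = TRUE,
              dimnames = list(NULL, paste0("item_", 1:3)))
  th <- rank_theta(make_resp(x))
  expect_equal(th$theta, qnorm(c(0.125, 0.375, 0.625, 0.875)), tolerance = 1e-10)
  expect_equal(round(th$theta, 4), c(-1.1503, -0.3186, 0.3186, 1.1503))
  # permuting rows leaves each person's assignment unchanged
  resp <- make_resp(matrix(sample(0:2, 60 * 4, replace = TRUE), 60, 4,
                           dimnames = list(NULL, paste0("item_", 1:4))))
  a <- rank_theta(resp, tie_seed = 9)
  b <- rank_theta(resp[sample(60), ], tie_seed = 9)
  expect_equal(a$theta[order(a$person_id)], b$theta[order(b$person_id)])
})

test_that("kernel curves obey probability algebra and degenerate limits", {
  sim <- singleton_cohort(400, default_item_bank(5, "k"), seed = 5)
  resp <- sim$cohort$responses
  resp$item_k06 <- 0L  # an item nobody endorses
  th <- rank_theta(resp)
  cu <- fit_item_curves(resp, th)
  for (it in names(cu$items)) {
    ci <- cu$items[[it]]
    expect_equal(unname(rowSums(ci$prob)), rep(1, length(cu$grid)), tolerance = 1e-9)
    expect_true(all(ci$S[, 1] >= ci$S[, 2] - 1e-12))
    expect_true(all(ci$S_lo >= 0 & ci$S_hi <= 1))
    expect_true(all(ci$S_lo <= ci$S + 1e-12 & ci$S <= ci$S_hi + 1e-12))
    # consistency of option curve and step functions at category 1
    expect_equal(unname(ci$S[, 1] - ci$S[, 2]), unname(ci$prob[, 2]), tolerance = 1e-12)
  }
  expect_true(all(cu$items$item_k06$S == 0))
  # flat-kernel limit: estimates equal overall sample proportions
  cu_flat <- fit_item_curves(resp, th, bandwidth = 1e6)
  props <- table(factor(resp$item_k01, 0:2)) / nrow(resp)
  expect_equal(unname(cu_flat$items$item_k01$prob[1, ]), unname(c(props)),
               tolerance = 1e-6)
})

test_that("kernel estimates converge to the generating curves", {
  target <- item_spec("t01", a = 2, b = c(-0.5, 0.7), d = 1)
  # informative co-items spanning the trait range, so the sum-score ranking
  # locates respondents well where the target item is steep
  b1 <- seq(-1.8, 1.8, length.out = 13)
  co_items <- lapply(1:13, function(j)
    item_spec(sprintf("f%02d", j), a = c(1.5, 2, 2.5)[(j - 1) %% 3 + 1],
              b = c(b1[j], b1[j] + 1.1)))
  bank <- c(list(target), co_items)
  errs <- sapply(c(500, 2000, 5000), function(n) {
    sim <- singleton_cohort(n, bank, seed = 23)
    resp <- sim$cohort$responses
    th <- rank_theta(resp)
    cu <- fit_item_curves(resp, th)
    keep <- abs(cu$grid) <= 2
    tr <- item_true_steps(target, cu$grid)
    max(abs(cu$items$item_t01$S[keep, ] - tr[keep, ]))
  })
  expect_lt(errs[2], 0.08)
  expect_lt(errs[3], errs[1])
})

test_that("ML scoring hits the boundary, matches its oracle and orders persons", {
  sim <- singleton_cohort(2000, default_item_bank(14, "s"), seed = 29)
  resp <- sim$cohort$responses
  th <- rank_theta(resp)
  cu <- fit_item_curves(resp, th)
  cols <- names(cu$items)
  zero <- resp[1, ]
  zero[cols] <- 0L
  expect_equal(unname(ml_score(zero, cu)), -3)
  sc <- ml_score(resp, cu)
  truth <- sim$cohort$truth$theta_tr[match(resp$person_id, sim$cohort$truth$person_id)]
  expect_gt(cor(sc, truth, method = "spearman", use = "complete.obs"), 0.85)
  ssum <- rowSums(resp[, cols])
  expect_gt(cor(sc, ssum, method = "spearman"), 0.95)
  # exhaustive grid-search oracle agrees exactly, including with missing items
  sub <- resp[1:40, ]
  sub$item_s03[1:10] <- NA
  got <- ml_score(sub, cu)
  want <- vapply(seq_len(nrow(sub)), function(i) oracle_grid_ml(sub[i, ], cu, cols),
                 numeric(1))
  expect_identical(unname(got), want)
  # a person missing every item gets NA
  allna <- sub[1, ]; allna[cols] <- NA
  expect_true(is.na(ml_score(allna, cu)))
})

test_that("left asymptote of monotone banks is essentially zero", {
  sim <- singleton_cohort(2000, default_item_bank(10, "z"), seed = 31)
  resp <- sim$cohort$responses
  cu <- fit_item_curves(resp, rank_theta(resp))
  for (it in names(cu$items)) expect_lt(cu$items[[it]]$S[1, 1], 0.05)
})

test_that("expected-score PCA orders items by difficulty and discrimination", {
  grid <- default_grid()
  bs <- analytic_curve_set(list(
    item_spec("b1", a = 1.5, b = c(-1, 0.2)),
    item_spec("b2", a = 1.5, b = c(0, 1.2)),
    item_spec("b3", a = 1.5, b = c(1, 2.2))), grid)
  dd <- difficulty_discrimination(bs)
  expect_equal(order(dd$difficulty, decreasing = TRUE), 1:3)  # easiest first
  # crossed difficulty x discrimination bank: PC1 separates difficulty,
  # PC2 separates discrimination within each difficulty level
  mixed <- analytic_curve_set(list(
    item_spec("e_lo", a = 0.9, b = c(-1, 0.2)),
    item_spec("e_hi", a = 2.4, b = c(-1, 0.2)),
    item_spec("m_lo", a = 0.9, b = c(0, 1.2)),
    item_spec("m_hi", a = 2.4, b = c(0, 1.2)),
    item_spec("h_lo", a = 0.9, b = c(1, 2.2)),
    item_spec("h_hi", a = 2.4, b = c(1, 2.2))), grid)
  dm <- difficulty_discrimination(mixed)
  hi <- grepl("hi", dm$item)
  expect_gt(min(dm$discrimination[hi]), max(dm$discrimination[!hi]))
  twin <- analytic_curve_set(list(
    item_spec("c1", a = 1.5, b = c(0, 1)),
    item_spec("c2", a = 1.5, b = c(0, 1)),
    item_spec("c3", a = 0.9, b = c(0.5, 1.5))), grid)
  dt <- difficulty_discrimination(twin)
  expect_equal(dt$difficulty[1], dt$difficulty[2], tolerance = 1e-10)
  expect_equal(dt$discrimination[1], dt$discrimination[2], tolerance = 1e-10)
  expect_error(difficulty_discrimination(analytic_curve_set(list(item_spec("o", a = 1)))),
               "at least 3")
})
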