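# Independent oracles used across the suite. Each is a deliberately naive
# implementation (explicit loops, direct formulas) kept separate from the
# package's code paths.

# Cronbach's alpha from the raw formula, spreadsheet style
oracle_alpha <- function(x) {
  k <- ncol(x)
  item_vars <- numeric(k)
  for (j in 1:k) item_vars[j] <- var(x[, j])
  tot <- rowSums(x)
  k / (k - 1) * (1 - sum(item_vars) / var(tot))
}

# Loevinger coefficients by explicit enumeration of the comonotone coupling
oracle_loevinger <- function(x) {
  k <- ncol(x)
  cv <- cvm <- matrix(NA_real_, k, k)
  n <- nrow(x)
  for (i in 1:k) for (j in 1:k) {
    cv[i, j] <- sum((x[, i] - mean(x[, i])) * (x[, j] - mean(x[, j]))) / (n - 1)
    xi <- sort(x[, i]); xj <- sort(x[, j])   # comonotone coupling
    cvm[i, j] <- sum((xi - mean(xi)) * (xj - mean(xj))) / (n - 1)
  }
  Hij <- cv / cvm
  Hi <- numeric(k)
  for (i in 1:k) Hi[i] <- sum(cv[i, -i]) / sum(cvm[i, -i])
  num <- 0; den <- 0
  for (i in 1:(k - 1)) for (j in (i + 1):k) { num <- num + cv[i, j]; den <- den + cvm[i, j] }
  list(Hij = Hij, Hi = Hi, H = num / den)
}

# ICC(C,1) from explicitly written two-way ANOVA mean squares
oracle_icc_c1 <- function(y1, y2) {
  y <- cbind(y1, y2); n <- nrow(y); k <- 2
  grand <- mean(y)
  ssr <- k * sum((rowMeans(y) - grand)^2)
  ssc <- n * sum((colMeans(y) - grand)^2)
  sst <- sum((y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

# density-weighted RMS distance between two step functions, independent loop
oracle_dif_rms <- function(sa, sb, grid) {
  num <- 0; den <- 0
  for (q in seq_along(grid)) {
    w <- dnorm(grid[q])
    num <- num + w * (sa[q] - sb[q])^2
    den <- den + w
  }
  sqrt(num / den)
}

# rule-based relatedness oracle for flat twin/sib pedigrees
oracle_relatedness <- function(ped) {
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$person_id, ped$person_id))
  for (i in 1:n) for (j in 1:n) {
    if (i == j) K[i, j] <- 1
    else if (ped$family_id[i] == ped$family_id[j]) {
      both_twins <- ped$role[i] %in% c("twin1", "twin2") &&
        ped$role[j] %in% c("twin1", "twin2")
      K[i, j] <- if (both_twins && ped$zygosity[i] == "MZ") 1 else 0.5
    }
  }
  K
}

# multivariate normal log density, direct formula
oracle_mvn_logdens <- function(y, mu, S) {
  k <- length(y)
  r <- y - mu
  as.numeric(-0.5 * (k * log(2 * pi) + determinant(S, logarithm = TRUE)$modulus +
                       t(r) %*% solve(S) %*% r))
}

# exhaustive grid-search ML scorer, independent of ml_score internals
oracle_grid_ml <- function(x_row, curves, cols, floor = 1e-6) {
  best_q <- 1; best_ll <- -Inf
  for (q in seq_along(curves$grid)) {
    ll <- 0; seen <- FALSE
    for (it in cols) {
      xij <- x_row[[it]]
      if (!is.na(xij)) {
        ll <- ll + log(max(curves$items[[it]]$prob[q, xij + 1], floor))
        seen <- TRUE
      }
    }
    if (seen && ll > best_ll) { best_ll <- ll; best_q <- q }
  }
  curves$grid[best_q]
}

# wrap analytic generating curves in an item_curve_set-shaped object
analytic_curve_set <- function(specs, grid = default_grid(), band = 0.01) {
  items <- list()
  for (sp in specs) {
    S <- item_true_steps(sp, grid)
    p <- cbind(p0 = 1 - S[, 1], p1 = S[, 1] - S[, 2], p2 = S[, 2])
    items[[paste0("item_", sp$item_id)]] <- list(
      prob = p, S = S,
      S_lo = pmax(S - band, 0), S_hi = pmin(S + band, 1),
      n_eff = rep(1e6, length(grid)),
      expected = p[, 2] + 2 * p[, 3],
      counts = c(1, 1, 1))
  }
  structure(list(grid = grid, bandwidth = NA, n = NA, items = items),
            class = "item_curve_set")
}

# quick singleton-only cohort (independent persons) for IRT tests
singleton_cohort <- function(n, bank, seed, trait = "tr",
                             sex_effect = NULL) {
  cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 0, p_extra_sib = 0,
                    n_singletons = n,
                    trait_params = setNames(list(c(a2 = 0.3, c2 = 0, e2 = 0.7)), trait),
                    item_bank = setNames(list(bank), trait),
                    sex_effect = sex_effect, seed = seed)
  list(cohort = simulate_cohort(cfg), config = cfg)
}
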