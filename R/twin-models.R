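#' Assemble per-person twin-model data from a pedigree and scores
#'
#' @param pedigree pedigree data frame
#' @param scores named numeric vector or data frame column(s) aligned to
#'   `pedigree$person_id`; a matrix/data frame with two columns yields a
#'   bivariate data set (`y1`, `y2`)
#' @return data frame ready for [fit_univariate()] / [fit_bivariate()]
#' @export
twin_data <- function(pedigree, scores) {
  d <- pedigree
  if (is.null(dim(scores))) {
    if (!is.null(names(scores))) scores <- scores[match(d$person_id, names(scores))]
    d$y <- as.numeric(scores)
  } else {
    s <- as.matrix(scores)
    if (!is.null(rownames(s))) s <- s[match(d$person_id, rownames(s)), , drop = FALSE]
    d$y1 <- s[, 1]; d$y2 <- s[, 2]
  }
  d
}

dominance_block <- function(fam) {
  k <- nrow(fam)
  m <- matrix(0.25, k, k, dimnames = list(fam$person_id, fam$person_id))
  diag(m) <- 1
  mz <- which(fam$zygosity == "MZ" & fam$role %in% c("twin1", "twin2"))
  if (length(mz) == 2) m[mz[1], mz[2]] <- m[mz[2], mz[1]] <- 1
  m
}

# Group families sharing an identical covariance-structure pattern so the
# likelihood reduces to a handful of dense solves. `extra_key` lets callers
# stratify further (e.g. by member sexes for sex-limitation models).
family_groups <- function(data, extra_key = NULL) {
  fam_rows <- split(seq_len(nrow(data)), data$family_id)
  keys <- character(length(fam_rows))
  Ks <- Ds <- vector("list", length(fam_rows))
  for (i in seq_along(fam_rows)) {
    ix <- fam_rows[[i]]
    fam <- data[ix, , drop = FALSE]
    Ks[[i]] <- relatedness_block(fam)
    Ds[[i]] <- dominance_block(fam)
    keys[i] <- paste(length(ix), paste(round(Ks[[i]], 3), collapse = ","),
                     paste(round(Ds[[i]], 3), collapse = ","),
                     if (!is.null(extra_key)) paste(extra_key[ix], collapse = ","),
                     sep = "|")
  }
  out <- list()
  for (key in unique(keys)) {
    sel <- which(keys == key)
    out[[key]] <- list(rows = do.call(rbind, fam_rows[sel]),
                       K = Ks[[sel[1]]], D = Ds[[sel[1]]],
                       n_fam = length(sel), k = ncol(Ks[[sel[1]]]))
  }
  out
}

# Sum of family-wise MVN log densities with common per-group covariance.
grouped_mvn_loglik <- function(groups, resid, sigma_fun) {
  ll <- 0
  for (g in groups) {
    S <- sigma_fun(g)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    R <- matrix(resid[t(g$rows)], ncol = g$k, byrow = TRUE)
    Z <- R %*% backsolve(ch, diag(g$k))
    ll <- ll - 0.5 * (g$n_fam * (g$k * log(2 * pi) + 2 * sum(log(diag(ch)))) +
                        sum(Z^2))
  }
  ll
}

model_components <- function(model) {
  switch(model,
         ACE = c("a", "c", "e"), ADE = c("a", "d", "e"), AE = c("a", "e"),
         CE = c("c", "e"), E = "e",
         stop_config("unknown model '%s'", model))
}

uni_sigma_fun <- function(vA, vC, vD, vE) {
  function(g) {
    vA * g$K + vC * matrix(1, g$k, g$k) + vD * g$D + vE * diag(g$k)
  }
}

#' Full-information univariate twin-model log-likelihood
#'
#' Sum over families of the multivariate-normal log density of the observed
#' members, with mean `X beta` and covariance built from the variance
#' components: every pair's covariance is `k_A a^2 + c^2` (ACE) or
#' `k_A a^2 + k_D d^2` (ADE), where the additive coefficient `k_A` is 1 for
#' MZ co-twins and 0.5 for other sib pairs, and the dominance coefficient
#' `k_D` is 1 for MZ co-twins and 0.25 otherwise. Missing members are
#' marginalized by dropping their rows. Exposed for direct evaluation
#' against density oracles.
#'
#' @param params list with paths `a`, `c`, `d`, `e` (unused ones 0) and
#'   `beta` (fixed-effect vector matching `cbind(1, covariates)`)
#' @param data twin data frame with `y`
#' @param model one of `"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"E"`
#' @param covariates character vector of covariate column names
#' @return log-likelihood (scalar; `-Inf` for a non-PD covariance)
#' @export
fiml_loglik <- function(params, data, model = "ACE", covariates = character()) {
  prep <- prep_uni(data, covariates)
  beta <- params$beta %||% rep(0, ncol(prep$X))
  resid <- prep$y - drop(prep$X %*% beta)
  grouped_mvn_loglik(prep$groups,
                     resid,
                     uni_sigma_fun((params$a %||% 0)^2, (params$c %||% 0)^2,
                                   (params$d %||% 0)^2, (params$e %||% 0)^2))
}

prep_uni <- function(data, covariates) {
  data <- data[!is.na(data$y), , drop = FALSE]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, covariates, drop = FALSE]))
  storage.mode(X) <- "double"
  list(data = data, y = data$y, X = X, groups = family_groups(data))
}

uni_nll_factory <- function(prep, comps) {
  np <- length(comps)
  function(par) {
    paths <- setNames(par[seq_len(np)], comps)
    beta <- par[-seq_len(np)]
    resid <- prep$y - drop(prep$X %*% beta)
    v <- function(p) if (p %in% comps) paths[[p]]^2 else 0
    -grouped_mvn_loglik(prep$groups, resid,
                        uni_sigma_fun(v("a"), v("c"), v("d"), v("e")))
  }
}

optim_multistart <- function(nll, init, n_starts, seed = 1L, jitter = 0.3) {
  best <- NULL
  last_err <- "none"
  with_seed(as.integer(seed), {
    for (s in seq_len(n_starts)) {
      st <- if (s == 1) init else init * exp(rnorm(length(init), 0, jitter)) +
        rnorm(length(init), 0, 0.05)
      fit <- tryCatch(optim(st, nll, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-10)),
                      error = function(e) { last_err <<- conditionMessage(e); NULL })
      if (!is.null(fit) && is.finite(fit$value) &&
          (is.null(best) || fit$value < best$value)) best <- fit
    }
  })
  if (is.null(best))
    stop_config("twin-model optimization failed in all starts (last error: %s)",
                last_err)
  best
}

#' Fit a univariate twin variance-component model by FIML
#'
#' Optimizes unbounded path coefficients (variances are their squares, so
#' non-negativity is automatic; signs resolve to non-negative paths by
#' convention) with seeded multi-starts, returns standardized variance
#' proportions, optional profile-likelihood 95% CIs on the proportions, and
#' fit statistics.
#'
#' @param data twin data frame (`family_id`, `zygosity`, `role`, `y`,
#'   covariate columns)
#' @param model `"ACE"`, `"ADE"`, `"AE"`, `"CE"`, or `"E"`
#' @param covariates covariate column names entering the mean
#' @param n_starts seeded multi-starts
#' @param ci compute profile CIs for the standardized proportions?
#' @param seed multi-start seed
#' @return object of class `twin_fit`: `model`, `paths`, `proportions`,
#'   `ci` (when requested), `beta`, `minus2ll`, `aic`, `n_par`,
#'   `n_families`, `twin_correlations` (rMZ, rDZ from complete pairs)
#' @export
fit_univariate <- function(data, model = "AE", covariates = character(),
                           n_starts = 5, ci = TRUE, seed = 1L) {
  prep <- prep_uni(data, covariates)
  comps <- model_components(model)
  vy <- var(prep$y)
  init_paths <- sqrt(vy / length(comps)) * rep(1, length(comps))
  init_beta <- c(mean(prep$y), rep(0, ncol(prep$X) - 1))
  nll <- uni_nll_factory(prep, comps)
  best <- optim_multistart(nll, c(init_paths, init_beta), n_starts, seed)
  np <- length(comps)
  paths <- abs(setNames(best$par[seq_len(np)], comps))
  beta <- setNames(best$par[-seq_len(np)], colnames(prep$X))
  vars <- paths^2
  props <- vars / sum(vars)
  n_par <- length(best$par)
  out <- list(model = model, paths = paths, proportions = props,
              beta = beta, minus2ll = 2 * best$value,
              aic = 2 * best$value + 2 * n_par, n_par = n_par,
              n_families = length(unique(prep$data$family_id)),
              n_persons = nrow(prep$data),
              twin_correlations = twin_pair_correlations(prep$data, beta, prep$X))
  if (ci) out$ci <- profile_ci_uni(prep, model, best, comps)
  class(out) <- "twin_fit"
  out
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("%s model: -2lnL = %.2f, AIC = %.2f (%d families)\n",
              x$model, x$minus2ll, x$aic, x$n_families))
  print(round(x$proportions, 3))
  if (!is.null(x$ci)) {
    for (nm in names(x$ci))
      cat(sprintf("  %s2 = %.2f [%.2f, %.2f]\n", nm, x$proportions[nm],
                  x$ci[[nm]][1], x$ci[[nm]][2]))
  }
  invisible(x)
}

twin_pair_correlations <- function(data, beta, X) {
  resid <- data$y - drop(X %*% beta)
  out <- c(rMZ = NA_real_, rDZ = NA_real_)
  for (z in c("MZ", "DZ")) {
    t1 <- data[data$zygosity == z & data$role == "twin1", c("family_id", "y")]
    t2 <- data[data$zygosity == z & data$role == "twin2", c("family_id", "y")]
    r1 <- resid[data$zygosity == z & data$role == "twin1"]
    r2 <- resid[data$zygosity == z & data$role == "twin2"]
    m <- match(t1$family_id, t2$family_id)
    ok <- !is.na(m)
    if (sum(ok) > 2) out[paste0("r", z)] <- cor(r1[ok], r2[m[ok]])
  }
  out
}

# Profile-likelihood CI on the standardized proportion of each component:
# the model is reparameterized with the target proportion fixed, total
# variance (and, for 3-component models, the split of the remainder) free.
profile_ci_uni <- function(prep, model, best, comps, level = 0.95) {
  if (length(comps) < 2) return(NULL)
  crit <- qchisq(level, 1)
  nbeta <- ncol(prep$X)
  nll_at <- function(comp, p) {
    others <- setdiff(comps, comp)
    obj <- function(par) {
      logT <- par[1]
      Tot <- exp(logT)
      if (length(others) == 1) {
        vars <- setNames(c(p * Tot, (1 - p) * Tot), c(comp, others))
        beta <- par[-1]
      } else {
        q <- plogis(par[2])
        vars <- setNames(c(p * Tot, q * (1 - p) * Tot, (1 - q) * (1 - p) * Tot),
                         c(comp, others))
        beta <- par[-(1:2)]
      }
      paths <- setNames(numeric(length(comps)), comps)
      paths[names(vars)] <- sqrt(vars)
      resid <- prep$y - drop(prep$X %*% beta)
      v <- function(pp) if (pp %in% comps) paths[[pp]]^2 else 0
      -grouped_mvn_loglik(prep$groups, resid,
                          uni_sigma_fun(v("a"), v("c"), v("d"), v("e")))
    }
    np0 <- length(comps)
    vars_hat <- best$par[seq_len(np0)]^2
    init <- c(log(sum(vars_hat)),
              if (length(others) == 2) 0,
              best$par[-seq_len(np0)])
    opt <- tryCatch(optim(init, obj, method = "BFGS",
                          control = list(maxit = 300)),
                    error = function(e) list(value = Inf))
    opt$value
  }
  out <- list()
  vars_hat <- best$par[seq_len(length(comps))]^2
  props_hat <- vars_hat / sum(vars_hat)
  for (comp in comps) {
    p_hat <- props_hat[match(comp, comps)]
    dev <- function(p) 2 * (nll_at(comp, p) - best$value) - crit
    lo <- if (p_hat < 1e-4 || dev(1e-4) < 0) 0 else
      tryCatch(uniroot(dev, c(1e-4, p_hat), tol = 1e-4)$root,
               error = function(e) NA_real_)
    hi <- if (p_hat > 1 - 1e-4 || dev(1 - 1e-4) < 0) 1 else
      tryCatch(uniroot(dev, c(p_hat, 1 - 1e-4), tol = 1e-4)$root,
               error = function(e) NA_real_)
    out[[comp]] <- c(lo, hi)
  }
  out
}

#' Likelihood-ratio test between two nested twin fits
#'
#' Uses the naive chi-square reference with df equal to the parameter-count
#' difference; `mixture = TRUE` applies the 50:50 point-mass mixture
#' correction appropriate when the constrained parameter sits on a boundary
#' (df = 1 only).
#'
#' @param full,reduced `twin_fit` objects (reduced nested in full)
#' @param mixture use the boundary mixture reference?
#' @return list: `stat`, `df`, `p`
#' @export
lrt_twin <- function(full, reduced, mixture = FALSE) {
  stat <- reduced$minus2ll - full$minus2ll
  df <- full$n_par - reduced$n_par
  p <- pchisq(max(stat, 0), df, lower.tail = FALSE)
  if (mixture && df == 1) p <- p / 2
  list(stat = stat, df = df, p = p)
}

#' Omnibus homogeneity test of means and variances
#'
#' Compares a saturated model with group-specific means and variances for
#' every zygosity-by-role cell (within-family covariances free per pair
#' type in both models) against a model equating all means and all
#' variances. A significant result indicates sampling heterogeneity or
#' outliers that would bias variance-component estimates. The df is the
#' parameter-count difference of the fitted parameterization.
#'
#' @param data twin data frame with `y`
#' @return list: `stat`, `df`, `p`, `minus2ll_saturated`,
#'   `minus2ll_constrained`
#' @export
omnibus_homogeneity_test <- function(data) {
  data <- data[!is.na(data$y), , drop = FALSE]
  cell <- factor(paste(data$zygosity, data$role, sep = "."))
  if (nlevels(cell) < 2) stop_config("homogeneity test needs >= 2 groups")
  small <- table(cell) < 5
  if (any(small)) {
    warning("cells with <5 observations collapsed: ",
            paste(names(which(small)), collapse = ", "))
    lv <- levels(cell)
    lv[lv %in% names(which(small))] <- "other"
    cell <- factor(lv[as.integer(cell)])
  }
  ci <- as.integer(cell)
  groups <- family_groups(data, extra_key = ci)
  pair_kind <- function(K, fam) {
    # 1 = MZ co-twin pair, 2 = any 0.5-related pair
    ifelse(K == 1, 1L, 2L)
  }
  fit_hom <- function(saturated) {
    nc <- if (saturated) nlevels(cell) else 1L
    # params: nc means, nc log-sds, 2 atanh-correlations (MZ pair, 0.5 pair)
    nll <- function(par) {
      mu <- par[seq_len(nc)]
      sdv <- exp(par[nc + seq_len(nc)])
      rho <- tanh(par[2 * nc + 1:2])
      mu_i <- if (saturated) mu[ci] else rep(mu, nrow(data))
      sd_i <- if (saturated) sdv[ci] else rep(sdv, nrow(data))
      resid <- data$y - mu_i
      ll <- 0
      for (g in groups) {
        rows1 <- g$rows[1, ]
        kind <- ifelse(g$K == 1, 1L, 2L)
        sg <- sd_i[rows1]
        S <- outer(sg, sg) * matrix(rho[kind], g$k, g$k)
        diag(S) <- sg^2
        ch <- tryCatch(chol(S), error = function(e) NULL)
        if (is.null(ch)) return(Inf)
        R <- matrix(resid[t(g$rows)], ncol = g$k, byrow = TRUE)
        # standardized residuals: sds vary by family only through cells,
        # identical within a group by construction of the grouping key
        Z <- R %*% backsolve(ch, diag(g$k))
        ll <- ll - 0.5 * (g$n_fam * (g$k * log(2 * pi) + 2 * sum(log(diag(ch)))) +
                            sum(Z^2))
      }
      -ll
    }
    init <- c(rep(mean(data$y), nc), rep(log(sd(data$y)), nc), 0.3, 0.2)
    opt <- optim(init, nll, method = "BFGS", control = list(maxit = 500))
    list(value = opt$value, n_par = length(init))
  }
  sat <- fit_hom(TRUE)
  con <- fit_hom(FALSE)
  stat <- 2 * (con$value - sat$value)
  df <- sat$n_par - con$n_par
  list(stat = stat, df = df, p = pchisq(max(stat, 0), df, lower.tail = FALSE),
       minus2ll_saturated = 2 * sat$value, minus2ll_constrained = 2 * con$value)
}

#' Sex-limitation check for an AE model
#'
#' Likelihood-ratio test of sex-specific A and E paths (opposite-sex pairs
#' covary through `0.5 a_F a_M`) against equal paths across sexes; means
#' are sex-specific in both models.
#'
#' @param data twin data frame with `y` and `sex`
#' @return list: `stat`, `df`, `p`, `paths_by_sex`, plus a `limited` note
#'   when not all five zygosity-by-sex groups are present
#' @export
sex_limitation_check <- function(data) {
  data <- data[!is.na(data$y), , drop = FALSE]
  si <- ifelse(data$sex == "F", 1L, 2L)
  groups <- family_groups(data, extra_key = si)
  have <- unique(paste(data$zygosity, data$sex))
  limited <- length(have) < 5
  nll_fun <- function(sex_specific) {
    function(par) {
      if (sex_specific) { aF <- par[1]; aM <- par[2]; eF <- par[3]; eM <- par[4]
      } else { aF <- aM <- par[1]; eF <- eM <- par[2] }
      mu <- tail(par, 2)
      a_i <- ifelse(si == 1L, aF, aM)
      e_i <- ifelse(si == 1L, eF, eM)
      resid <- data$y - mu[si]
      ll <- 0
      for (g in groups) {
        rows1 <- g$rows[1, ]
        av <- a_i[rows1]; ev <- e_i[rows1]
        S <- g$K * outer(av, av)
        diag(S) <- av^2 + ev^2
        ch <- tryCatch(chol(S), error = function(e) NULL)
        if (is.null(ch)) return(Inf)
        R <- matrix(resid[t(g$rows)], ncol = g$k, byrow = TRUE)
        Z <- R %*% backsolve(ch, diag(g$k))
        ll <- ll - 0.5 * (g$n_fam * (g$k * log(2 * pi) + 2 * sum(log(diag(ch)))) +
                            sum(Z^2))
      }
      -ll
    }
  }
  sdv <- sd(data$y)
  init_free <- c(rep(sdv * 0.6, 2), rep(sdv * 0.8, 2),
                 mean(data$y[si == 1L]), mean(data$y[si == 2L]))
  init_eq <- c(sdv * 0.6, sdv * 0.8,
               mean(data$y[si == 1L]), mean(data$y[si == 2L]))
  free <- optim(init_free, nll_fun(TRUE), method = "BFGS", control = list(maxit = 500))
  eq <- optim(init_eq, nll_fun(FALSE), method = "BFGS", control = list(maxit = 500))
  stat <- 2 * (eq$value - free$value)
  list(stat = stat, df = 2, p = pchisq(max(stat, 0), 2, lower.tail = FALSE),
       paths_by_sex = list(F = abs(free$par[c(1, 3)]), M = abs(free$par[c(2, 4)])),
       limited = limited)
}

# ---- bivariate Cholesky -------------------------------------------------

chol_from_par <- function(p3) {
  L <- matrix(0, 2, 2)
  L[1, 1] <- p3[1]; L[2, 1] <- p3[2]; L[2, 2] <- p3[3]
  L
}

prep_bi <- function(data, covariates) {
  keep <- !(is.na(data$y1) & is.na(data$y2))
  data <- data[keep, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1, as.matrix(data[, covariates, drop = FALSE]))
  storage.mode(X) <- "double"
  # observation pattern per person: which of the two traits are present
  pat <- paste0(as.integer(!is.na(data$y1)), as.integer(!is.na(data$y2)))
  groups <- family_groups(data, extra_key = pat)
  list(data = data, X = X, groups = groups)
}

bi_nll_factory <- function(prep, model, fixed = list()) {
  data <- prep$data
  X <- prep$X
  p <- ncol(X)
  has_c <- model == "ACE"
  nll <- function(par) {
    i <- 0
    take <- function(n) { v <- par[i + seq_len(n)]; i <<- i + n; v }
    aP <- c(if (is.null(fixed$a11)) take(1) else fixed$a11,
            if (is.null(fixed$a21)) take(1) else fixed$a21,
            if (is.null(fixed$a22)) take(1) else fixed$a22)
    cP <- if (has_c) take(3) else c(0, 0, 0)
    eP <- c(take(2), if (is.null(fixed$e22)) take(1) else fixed$e22)
    B <- matrix(take(2 * p), p, 2)
    La <- chol_from_par(aP); Lc <- chol_from_par(cP); Le <- chol_from_par(eP)
    Sa <- tcrossprod(La); Sc <- tcrossprod(Lc); Se <- tcrossprod(Le)
    mu <- X %*% B                       # n x 2
    r1 <- data$y1 - mu[, 1]; r2 <- data$y2 - mu[, 2]
    ll <- 0
    for (g in prep$groups) {
      k <- g$k
      J <- matrix(1, k, k)
      S <- kronecker(g$K, Sa) + kronecker(J, Sc) + kronecker(diag(k), Se)
      # tiny ridge keeps boundary-constrained refits (rank-deficient
      # component matrices, e.g. rE = 1) finitely evaluable
      diag(S) <- diag(S) + 1e-8
      rows1 <- g$rows[1, ]
      obs_mask <- as.vector(rbind(!is.na(data$y1[rows1]), !is.na(data$y2[rows1])))
      # person-major stacking: (p1 t1, p1 t2, p2 t1, ...)
      S <- S[obs_mask, obs_mask, drop = FALSE]
      ch <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(ch)) return(Inf)
      Rfull <- matrix(rbind(r1[t(g$rows)], r2[t(g$rows)]), nrow = g$n_fam,
                      byrow = TRUE)
      R <- Rfull[, obs_mask, drop = FALSE]
      Z <- R %*% backsolve(ch, diag(sum(obs_mask)))
      ll <- ll - 0.5 * (g$n_fam * (sum(obs_mask) * log(2 * pi) +
                                     2 * sum(log(diag(ch)))) + sum(Z^2))
    }
    -ll
  }
  n_free <- 3 - sum(c("a11", "a21", "a22") %in% names(fixed)) +
    (if (has_c) 3 else 0) + 3 - ("e22" %in% names(fixed)) + 2 * p
  attr(nll, "n_free") <- n_free
  nll
}

#' Fit a bivariate Cholesky twin model by FIML
#'
#' Each variance component (A, E, and C for ACE) is parameterized by a
#' lower-triangular 2x2 Cholesky factor; the genetic correlation is
#' \eqn{r_G = \Sigma_A[1,2] / \sqrt{\Sigma_A[1,1]\,\Sigma_A[2,2]}} and
#' analogously for the other components. Likelihood-ratio tests of
#' `rG = 0` (cross path a21 = 0), `rG = 1` (trait-specific genetic path
#' a22 = 0) and `rE = 1` (e22 = 0) are computed from constrained refits.
#'
#' @param data twin data frame with `y1`, `y2`
#' @param model `"AE"` or `"ACE"`
#' @param covariates covariate column names (enter both trait means)
#' @param n_starts seeded multi-starts
#' @param seed multi-start seed
#' @param tests compute the constrained-refit LRTs?
#' @return object of class `bivariate_fit`: per-trait standardized
#'   components, `rG`, `rC` (ACE), `rE`, `r_phenotypic`, component
#'   covariance matrices, `beta`, `minus2ll`, `aic`, LRT p-values
#' @export
fit_bivariate <- function(data, model = "AE", covariates = character(),
                          n_starts = 5, seed = 1L, tests = TRUE) {
  prep <- prep_bi(data, covariates)
  p <- ncol(prep$X)
  nll <- bi_nll_factory(prep, model)
  v1 <- var(prep$data$y1, na.rm = TRUE); v2 <- var(prep$data$y2, na.rm = TRUE)
  r12 <- cor(prep$data$y1, prep$data$y2, use = "complete.obs")
  init <- c(sqrt(v1 * 0.4), r12 * sqrt(v2 * 0.4), sqrt(v2 * 0.4 * (1 - r12^2)),
            if (model == "ACE") c(0.1, 0.05, 0.1),
            sqrt(v1 * 0.6), r12 * sqrt(v2 * 0.6), sqrt(v2 * 0.6 * (1 - r12^2)),
            rbind(c(mean(prep$data$y1, na.rm = TRUE), mean(prep$data$y2, na.rm = TRUE)),
                  matrix(0, p - 1, 2)))
  best <- optim_multistart(nll, init, n_starts, seed)
  i <- 0; take <- function(n) { v <- best$par[i + seq_len(n)]; i <<- i + n; v }
  Sa <- tcrossprod(chol_from_par(take(3)))
  Sc <- if (model == "ACE") tcrossprod(chol_from_par(take(3))) else matrix(0, 2, 2)
  Se <- tcrossprod(chol_from_par(take(3)))
  B <- matrix(take(2 * p), p, 2, dimnames = list(colnames(prep$X), c("y1", "y2")))
  tot <- diag(Sa) + diag(Sc) + diag(Se)
  comp_cor <- function(S) if (any(diag(S) <= 0)) NA_real_ else
    S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  cov12 <- Sa[1, 2] + Sc[1, 2] + Se[1, 2]
  out <- list(model = model,
              Sigma_A = Sa, Sigma_C = Sc, Sigma_E = Se, beta = B,
              a2 = diag(Sa) / tot, c2 = diag(Sc) / tot, e2 = diag(Se) / tot,
              rG = comp_cor(Sa), rC = if (model == "ACE") comp_cor(Sc) else NA_real_,
              rE = comp_cor(Se),
              r_phenotypic = cov12 / sqrt(prod(tot)),
              minus2ll = 2 * best$value,
              aic = 2 * best$value + 2 * attr(nll, "n_free"),
              n_par = attr(nll, "n_free"),
              n_families = length(unique(prep$data$family_id)))
  if (tests) {
    refit <- function(fixed) {
      nll0 <- bi_nll_factory(prep, model, fixed = fixed)
      drop_idx <- c(if (!is.null(fixed$a21)) 2, if (!is.null(fixed$a22)) 3,
                    if (!is.null(fixed$e22)) (if (model == "ACE") 9 else 6))
      init0 <- init[-drop_idx]
      opt0 <- optim_multistart(nll0, init0, max(2, n_starts - 2), seed)
      2 * opt0$value
    }
    lrtp <- function(m2ll0) pchisq(max(m2ll0 - out$minus2ll, 0), 1,
                                   lower.tail = FALSE)
    out$lrt <- list(rG0 = lrtp(refit(list(a21 = 0))),
                    rG1 = lrtp(refit(list(a22 = 0))),
                    rE1 = lrtp(refit(list(e22 = 0))))
  }
  class(out) <- "bivariate_fit"
  out
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat(sprintf("bivariate %s Cholesky: rG = %.2f, rE = %.2f, r_phen = %.2f\n",
              x$model, x$rG, x$rE, x$r_phenotypic))
  cat(sprintf("  a2 = (%.2f, %.2f), e2 = (%.2f, %.2f); -2lnL = %.2f\n",
              x$a2[1], x$a2[2], x$e2[1], x$e2[2], x$minus2ll))
  invisible(x)
}
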