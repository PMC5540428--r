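# Blockwise generalized-least-squares pieces for V = diag(1/w) + sigma2 * K,
# K block-diagonal by family. Returns the Gaussian ML loglik of z, the GLS
# fixed effects and their covariance, and the random-effect BLUP.
gls_kinship <- function(z, X, w, sigma2, blocks, Kb, want_u = FALSE) {
  p <- ncol(X)
  XtVX <- matrix(0, p, p); XtVz <- numeric(p); ztVz <- 0; logdet <- 0
  u <- if (want_u) numeric(length(z)) else NULL
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    k <- length(idx)
    V <- sigma2 * Kb[[b]]
    diag(V) <- diag(V) + 1 / w[idx]
    if (k == 1) {
      vi <- 1 / V[1, 1]
      logdet <- logdet + log(V[1, 1])
      xb <- X[idx, , drop = FALSE]
      XtVX <- XtVX + crossprod(xb) * vi
      XtVz <- XtVz + t(xb) %*% (z[idx] * vi)
      ztVz <- ztVz + z[idx]^2 * vi
    } else {
      ch <- chol(V)
      logdet <- logdet + 2 * sum(log(diag(ch)))
      Xb <- backsolve(ch, X[idx, , drop = FALSE], transpose = TRUE)
      zb <- backsolve(ch, z[idx], transpose = TRUE)
      XtVX <- XtVX + crossprod(Xb)
      XtVz <- XtVz + crossprod(Xb, zb)
      ztVz <- ztVz + sum(zb^2)
    }
  }
  beta <- drop(solve(XtVX + diag(1e-10, p), XtVz))
  rss <- ztVz - 2 * sum(beta * XtVz) + drop(t(beta) %*% XtVX %*% beta)
  ll <- -0.5 * (logdet + rss + length(z) * log(2 * pi))
  if (want_u) {
    r <- z - drop(X %*% beta)
    for (b in seq_along(blocks)) {
      idx <- blocks[[b]]
      V <- sigma2 * Kb[[b]]
      diag(V) <- diag(V) + 1 / w[idx]
      u[idx] <- sigma2 * drop(Kb[[b]] %*% solve(V, r[idx]))
    }
  }
  list(beta = beta, vcov = solve(XtVX + diag(1e-10, p)), loglik = ll, u = u)
}

#' Kinship-aware logistic mixed model by penalized quasi-likelihood
#'
#' Fits `logit P(y=1) = X beta + u` with `u ~ N(0, sigma_g^2 K)`, `K` the
#' pedigree's additive relatedness, by iterating the standard working
#' linearization: at each cycle the logit is linearized around the current
#' fit, the variance component is re-estimated by maximizing the Gaussian
#' likelihood of the working response, and the fixed and random effects are
#' updated from the mixed-model equations. Inference on the score
#' coefficient is a Wald t-test with model-based covariance and
#' `df = n - rank(X)`. With `sigma_g^2` shrinking to zero this reduces to
#' ordinary logistic regression (iteratively reweighted least squares).
#'
#' @param outcome 0/1 vector, aligned to `pedigree` rows
#' @param score numeric predictor of interest (per-person scale score)
#' @param covariates optional data frame / matrix of covariates (numeric or
#'   character/factor columns; characters are expanded to dummies)
#' @param pedigree pedigree data frame providing the family blocks
#' @param max_cycles maximum PQL cycles
#' @param tol convergence tolerance on the coefficients
#' @return object of class `assoc_result`: `or`, `ci`, `p`, `beta` table,
#'   `sigma2_g`, `n`, `converged`, `separation`
#' @export
pql_logistic_mixed <- function(outcome, score, covariates = NULL, pedigree,
                               max_cycles = 100, tol = 1e-6) {
  stopifnot(all(outcome %in% 0:1))
  y <- as.numeric(outcome)
  X <- cbind(`(Intercept)` = 1, score = score)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates, stringsAsFactors = TRUE)
    mm <- stats::model.matrix(~ ., data = cv)[, -1, drop = FALSE]
    # drop constant dummies (e.g. single-level factors after subsetting)
    keep <- apply(mm, 2, function(v) var(v) > 0)
    X <- cbind(X, mm[, keep, drop = FALSE])
  }
  X <- as.matrix(X)
  blocks <- split(seq_along(y), pedigree$family_id)
  Kb <- lapply(blocks, function(idx)
    relatedness_block(pedigree[idx, , drop = FALSE]))
  # start from ordinary logistic regression
  beta <- tryCatch(stats::glm.fit(X, y, family = binomial())$coefficients,
                   error = function(e) rep(0, ncol(X)))
  beta[is.na(beta)] <- 0
  u <- numeric(length(y))
  sigma2 <- 0.1
  converged <- FALSE
  for (cycle in seq_len(max_cycles)) {
    eta <- drop(X %*% beta) + u
    mu <- pmin(pmax(plogis(eta), 1e-8), 1 - 1e-8)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    opt <- optimize(function(ls) -gls_kinship(z, X, w, exp(ls), blocks, Kb)$loglik,
                    interval = c(-10, 2.5))
    cand_s <- c(1e-8, exp(opt$minimum))
    lls <- vapply(cand_s, function(s) gls_kinship(z, X, w, s, blocks, Kb)$loglik, 0)
    sigma2 <- cand_s[which.max(lls)]
    g <- gls_kinship(z, X, w, sigma2, blocks, Kb, want_u = TRUE)
    delta <- max(abs(g$beta - beta))
    beta <- g$beta
    u <- g$u
    if (delta < tol) { converged <- TRUE; break }
  }
  se <- sqrt(diag(g$vcov))
  df <- length(y) - qr(X)$rank
  tval <- beta / se
  pvals <- 2 * pt(-abs(tval), df)
  bs <- beta[["score"]]
  ses <- se[which(colnames(X) == "score")]
  crit <- qt(0.975, df)
  structure(list(
    or = exp(bs), ci = exp(bs + c(-1, 1) * crit * ses), p = pvals[["score"]],
    beta = data.frame(term = colnames(X), estimate = beta, se = se,
                      t = tval, p = pvals, row.names = NULL),
    sigma2_g = sigma2, n = length(y), df = df,
    converged = converged, separation = abs(bs) > 15),
    class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("OR = %.3f [%.3f, %.3f], p = %.3g (n = %d, sigma2_g = %.3f%s)\n",
              x$or, x$ci[1], x$ci[2], x$p, x$n, x$sigma2_g,
              if (!x$converged) ", NOT CONVERGED" else ""))
  invisible(x)
}

#' Effective number of independent tests from score correlations
#'
#' Li-Ji estimator: with eigenvalues \eqn{\lambda_i} of the
#' pairwise-complete correlation matrix of the scores,
#' \eqn{n_p = \sum_i \left(1[\lambda_i \ge 1] + (\lambda_i -
#' \lfloor\lambda_i\rfloor)\right)}. The Nyholt variant
#' \eqn{1 + (M-1)(1 - \mathrm{var}(\lambda)/M)} is available as an option.
#'
#' @param score_matrix numeric matrix, one column per score (e.g. scale x
#'   age bin), at least 3 rows
#' @param method `"liji"` or `"nyholt"`
#' @return effective number of tests
#' @export
effective_tests <- function(score_matrix, method = c("liji", "nyholt")) {
  method <- match.arg(method)
  m <- as.matrix(score_matrix)
  if (ncol(m) < 2 || nrow(m) < 3) stop_config("need >= 2 scores and >= 3 observations")
  sds <- apply(m, 2, sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0)) stop_config("constant score column")
  R <- cor(m, use = "pairwise.complete.obs")
  if (anyNA(R)) stop_config("correlation matrix has missing entries")
  lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  # guard the floor() against eigenvalues an ulp below an integer
  lam <- round(pmax(lam, 0), 10)
  if (method == "liji") sum((lam >= 1) + (lam - floor(lam)))
  else 1 + (ncol(m) - 1) * (1 - var(lam) / ncol(m))
}

#' Bonferroni threshold with an effective number of tests
#'
#' @param np effective number of independent scores (>= 1)
#' @param n_outcomes number of outcomes tested (>= 1)
#' @param alpha family-wise error rate
#' @return `alpha / (np * n_outcomes)`
#' @export
bonferroni_threshold <- function(np, n_outcomes, alpha = 0.05) {
  if (np < 1 || n_outcomes < 1) stop_config("np and n_outcomes must be >= 1")
  alpha / (np * n_outcomes)
}
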