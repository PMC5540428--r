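#' Cronbach's alpha
#'
#' Internal consistency \eqn{\alpha = \frac{k}{k-1}\left(1 - \sum_j
#' \mathrm{var}(X_j)/\mathrm{var}(\sum_j X_j)\right)} computed on complete
#' cases of the scale items.
#'
#' @param responses response data frame (or plain numeric matrix of items)
#' @param scale optional scale definition
#' @return alpha (scalar)
#' @export
cronbach_alpha <- function(responses, scale = NULL) {
  x <- extract_items(responses, scale)
  x <- x[complete.cases(x), , drop = FALSE]
  if (ncol(x) < 2 || nrow(x) < 2)
    stop_config("alpha needs at least 2 items and 2 complete respondents")
  vt <- var(rowSums(x))
  if (vt == 0) stop_config("total score has zero variance; alpha undefined")
  k <- ncol(x)
  k / (k - 1) * (1 - sum(apply(x, 2, var)) / vt)
}

extract_items <- function(responses, scale = NULL) {
  if (is.matrix(responses)) return(responses)
  cols <- if (is.null(scale)) item_cols(responses) else scale_item_cols(scale)
  as.matrix(responses[, cols, drop = FALSE])
}

#' Polytomous Loevinger scalability coefficients and Mokken classification
#'
#' The pairwise coefficient is \eqn{H_{ij} =
#' \mathrm{Cov}(X_i, X_j)/\mathrm{Cov}_{\max}(X_i, X_j)}, where the maximum
#' covariance is attained by the comonotone coupling of the two observed
#' marginals (both samples sorted in the same order — the Frechet upper
#' bound). Item and scale coefficients are ratio aggregates:
#' \eqn{H_i = \sum_{j \ne i} \mathrm{Cov}_{ij} / \sum_{j \ne i}
#' \mathrm{Cov}_{\max,ij}} and analogously over all pairs for \eqn{H}.
#' Mokken classes use the conventional cutoffs on \eqn{\min_i H_i}: weak
#' (0.3), medium (0.4), strong (0.5), requiring all \eqn{H_{ij} > 0}.
#'
#' @param responses response data frame or item matrix
#' @param scale optional scale definition
#' @return list: `alpha`, `Hij` matrix, `Hi`, `H`, `n_negative_Hij`,
#'   `min_Hi`, `items_Hi_below_0.3`, `mokken_class`
#' @export
loevinger_h <- function(responses, scale = NULL) {
  x <- extract_items(responses, scale)
  x <- x[complete.cases(x), , drop = FALSE]
  k <- ncol(x)
  if (k < 2) stop_config("scalability needs at least 2 items")
  const <- apply(x, 2, function(v) var(v) == 0)
  if (any(const)) {
    warning("constant items excluded from scalability: ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
    k <- ncol(x)
    if (k < 2) stop_config("fewer than 2 non-degenerate items remain")
  }
  cv <- cov(x)
  cvmax <- matrix(NA_real_, k, k, dimnames = dimnames(cv))
  for (i in seq_len(k)) for (j in seq_len(k))
    cvmax[i, j] <- cov(sort(x[, i]), sort(x[, j]))
  Hij <- cv / cvmax
  diag(Hij) <- NA
  Hi <- vapply(seq_len(k), function(i)
    sum(cv[i, -i]) / sum(cvmax[i, -i]), numeric(1))
  names(Hi) <- colnames(x)
  tot_num <- sum(cv[upper.tri(cv)])
  tot_den <- sum(cvmax[upper.tri(cvmax)])
  H <- tot_num / tot_den
  min_hi <- min(Hi)
  all_pos <- all(Hij[upper.tri(Hij)] > 0)
  cls <- if (!all_pos || min_hi < 0.3) "none"
         else if (min_hi < 0.4) "weak"
         else if (min_hi < 0.5) "medium" else "strong"
  list(alpha = cronbach_alpha(x), Hij = Hij, Hi = Hi, H = H,
       n_negative_Hij = sum(Hij[upper.tri(Hij)] < 0),
       min_Hi = min_hi,
       items_Hi_below_0.3 = names(Hi)[Hi < 0.3],
       mokken_class = cls)
}

#' Two-way consistency intraclass correlation
#'
#' ICC(C,1) from a two-way ANOVA without interaction with k = 2 occasions:
#' \eqn{(MS_R - MS_E)/(MS_R + (k-1) MS_E)}. Consistency ICC ignores
#' systematic occasion shifts (adding a constant to the retest leaves it at
#' 1). The 95% CI uses the F-distribution method.
#'
#' @param test,retest paired numeric vectors
#' @return list: `icc`, `ci` (length-2), `n`
#' @export
icc_consistency <- function(test, retest) {
  ok <- complete.cases(test, retest)
  y1 <- test[ok]; y2 <- retest[ok]
  n <- length(y1)
  if (n < 3) stop_config("ICC needs at least 3 paired observations")
  k <- 2
  y <- cbind(y1, y2)
  grand <- mean(y)
  ms_r <- k * var(rowMeans(y))                         # between-subjects
  ms_c <- n * sum((colMeans(y) - grand)^2) / (k - 1)   # between-occasions
  sse <- sum((y - outer(rowMeans(y), rep(1, k)) -
                outer(rep(1, n), colMeans(y)) + grand)^2)
  ms_e <- sse / ((n - 1) * (k - 1))
  icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  f <- ms_r / ms_e
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  fl <- f / qf(0.975, df1, df2)
  fu <- f * qf(0.975, df2, df1)
  ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  list(icc = icc, ci = ci, n = n)
}

#' Winsorise a score vector
#'
#' Clips values to `mean +/- z * sd`, with moments taken from the input
#' vector. Clipping changes the moments, so a second application is a no-op
#' only if nothing was clipped the first time.
#'
#' @param scores numeric vector (length >= 2)
#' @param z number of standard deviations
#' @return clipped vector
#' @export
winsorise <- function(scores, z = 3) {
  if (length(scores) < 2) stop_config("winsorisation needs at least 2 values")
  m <- mean(scores, na.rm = TRUE)
  s <- sd(scores, na.rm = TRUE)
  pmin(pmax(scores, m - z * s), m + z * s)
}

#' Proportion of zero sum scores
#'
#' Share of complete respondents whose scale sum score is 0 (the floor of a
#' symptom screener), reported overall or per wave.
#'
#' @param responses response data frame
#' @param scale optional scale definition
#' @param by optional grouping column (e.g. `"wave"`)
#' @return named numeric vector of proportions
#' @export
zero_score_proportion <- function(responses, scale = NULL, by = NULL) {
  x <- extract_items(responses, scale)
  ok <- complete.cases(x)
  z <- rowSums(x[ok, , drop = FALSE]) == 0
  if (is.null(by)) return(c(all = mean(z)))
  g <- responses[[by]][ok]
  tapply(z, g, mean)
}

# Gaussian mixed model y = X b + g + e, g ~ N(0, sg2 K), e ~ N(0, se2 I),
# with K block-diagonal by family. Profile ML over gamma = sg2/se2.
kinship_lmm <- function(y, X, ped, gamma_max = 50) {
  fam <- ped$family_id
  blocks <- split(seq_along(y), fam)
  kb <- lapply(blocks, function(idx) relatedness_block(ped[idx, , drop = FALSE]))
  n <- length(y)
  fit_gamma <- function(gamma) {
    logdet <- 0
    XtVX <- matrix(0, ncol(X), ncol(X)); XtVy <- numeric(ncol(X)); ytVy <- 0
    for (b in seq_along(blocks)) {
      idx <- blocks[[b]]
      V <- diag(length(idx)) + gamma * kb[[b]]
      if (length(idx) == 1) {
        Vi <- 1 / V[1, 1]; logdet <- logdet + log(V[1, 1])
        XtVX <- XtVX + crossprod(X[idx, , drop = FALSE]) * Vi
        XtVy <- XtVy + t(X[idx, , drop = FALSE]) %*% (y[idx] * Vi)
        ytVy <- ytVy + y[idx]^2 * Vi
      } else {
        ch <- chol(V)
        logdet <- logdet + 2 * sum(log(diag(ch)))
        Xb <- backsolve(ch, X[idx, , drop = FALSE], transpose = TRUE)
        yb <- backsolve(ch, y[idx], transpose = TRUE)
        XtVX <- XtVX + crossprod(Xb)
        XtVy <- XtVy + crossprod(Xb, yb)
        ytVy <- ytVy + sum(yb^2)
      }
    }
    beta <- solve(XtVX + diag(1e-8, ncol(X)), XtVy)
    rss <- ytVy - 2 * sum(beta * XtVy) + as.numeric(t(beta) %*% XtVX %*% beta)
    se2 <- as.numeric(rss) / n
    ll <- -0.5 * (n * log(2 * pi * se2) + logdet + n)
    list(ll = ll, beta = beta, se2 = se2, XtVX = XtVX)
  }
  opt <- optimize(function(lg) -fit_gamma(exp(lg))$ll, interval = c(-12, log(gamma_max)))
  cand <- list(c(gamma = 0, nll = -fit_gamma(0)$ll),
               c(gamma = exp(opt$minimum), nll = opt$objective))
  best <- cand[[which.min(vapply(cand, `[[`, 0, "nll"))]]
  f <- fit_gamma(best["gamma"])
  # df-adjusted residual variance for Wald inference (reduces to the OLS
  # t-test when the optimal gamma is irrelevant, e.g. identity relatedness)
  vb <- (f$se2 * n / (n - ncol(X))) * solve(f$XtVX + diag(1e-8, ncol(X)))
  list(beta = drop(f$beta), vcov = vb, gamma = unname(best["gamma"]),
       sigma2_e = f$se2, sigma2_g = unname(best["gamma"]) * f$se2,
       loglik = f$ll, df = n - qr(X)$rank)
}

#' Test a sex difference in scale scores accounting for relatedness
#'
#' Linear mixed model `score ~ sex + g` with a genetic random effect
#' `g ~ N(0, sigma_g^2 K)` built from the pedigree's additive relatedness;
#' Wald t-test on the sex coefficient. With an identity relatedness
#' structure this reduces to the ordinary least-squares t-test.
#'
#' @param scores numeric vector aligned with `pedigree` rows (or named by
#'   person id)
#' @param pedigree pedigree data frame (person_id, family_id, zygosity,
#'   role, sex)
#' @return list: `estimate` (female - male difference), `se`, `t`, `df`,
#'   `p`, `sigma2_g`, `sigma2_e`
#' @export
sex_difference_test <- function(scores, pedigree) {
  if (!is.null(names(scores)))
    scores <- scores[match(pedigree$person_id, names(scores))]
  ok <- !is.na(scores)
  ped <- pedigree[ok, , drop = FALSE]
  y <- scores[ok]
  if (length(unique(ped$sex)) < 2) stop_config("both sexes must be present")
  X <- cbind(1, ped$sex == "F")
  fit <- kinship_lmm(y, X, ped)
  est <- fit$beta[2]
  se <- sqrt(fit$vcov[2, 2])
  tval <- est / se
  list(estimate = unname(est), se = unname(se), t = unname(tval), df = fit$df,
       p = 2 * pt(-abs(tval), fit$df),
       sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e)
}
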