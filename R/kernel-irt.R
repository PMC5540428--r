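#' Default latent-trait evaluation grid
#'
#' 51 equally spaced points on \[-3, 3\]. The endpoints are chosen so that a
#' respondent endorsing nothing is mapped to the boundary score -3 by
#' [ml_score()].
#'
#' @param grid_min,grid_max,grid_n grid extent and size
#' @return numeric vector
#' @export
default_grid <- function(grid_min = -3, grid_max = 3, grid_n = 51) {
  seq(grid_min, grid_max, length.out = grid_n)
}

#' Assign latent-trait values from sum-score ranks
#'
#' Respondents with complete responses on the scale items are ranked by sum
#' score; ties are broken by a seeded uniform jitter keyed on `person_id`
#' (so the assignment is invariant to row order); rank `r` of `N` maps to
#' \eqn{\theta = \Phi^{-1}((r - 0.5)/N)}.
#'
#' @param responses response data frame with `person_id` and `item_<id>`
#'   columns
#' @param scale a scale definition (see [scale_definition()]); `NULL` uses
#'   all item columns
#' @param tie_seed integer seed for tie-breaking
#' @return data frame `person_id`, `sum_score`, `theta`, ordered as the
#'   complete-case rows of `responses`
#' @export
rank_theta <- function(responses, scale = NULL, tie_seed = 1L) {
  cols <- if (is.null(scale)) item_cols(responses) else scale_item_cols(scale)
  missing_cols <- setdiff(cols, names(responses))
  if (length(missing_cols))
    stop_config("scale items not present in responses: %s",
                paste(missing_cols, collapse = ", "))
  x <- as.matrix(responses[, cols, drop = FALSE])
  keep <- complete.cases(x)
  ids <- responses$person_id[keep]
  s <- rowSums(x[keep, , drop = FALSE])
  n <- length(s)
  if (n < 1) stop_config("no complete respondents on the scale")
  if (length(unique(s)) == 1L && n > 1L)
    warning("all respondents have identical sum scores; ordering is pure tie-break")
  # jitter drawn in person_id order so the result does not depend on row order
  ord <- order(ids)
  u <- numeric(n)
  u[ord] <- with_seed(as.integer(tie_seed), runif(n))
  r <- rank(s + u * 0.5)  # jitter < spacing of integer sums, breaks ties only
  data.frame(person_id = ids, sum_score = s,
             theta = qnorm((r - 0.5) / n), stringsAsFactors = FALSE)
}

#' Kernel-smoothed option curves and item response step functions
#'
#' For each item and category k, the option characteristic curve at grid
#' point \eqn{\theta_q} is the Nadaraya-Watson estimate
#' \eqn{\hat p_{jk}(\theta_q) = \sum_i K((\theta_q-\theta_i)/h)\,1[x_{ij}=k]
#' / \sum_i K((\theta_q-\theta_i)/h)} with a Gaussian kernel. Step functions
#' are cumulative sums over the upper categories; pointwise 95% bands use a
#' kernel-weighted binomial approximation with effective sample size
#' \eqn{n_\mathrm{eff} = (\sum w)^2 / \sum w^2}. Missing responses are
#' excluded item-wise.
#'
#' @param responses response data frame
#' @param theta a [rank_theta()] assignment (or any data frame with
#'   `person_id`, `theta`)
#' @param scale optional scale definition restricting the items
#' @param grid strictly increasing evaluation grid
#' @param bandwidth kernel bandwidth; `NULL` uses the kernel-IRT default
#'   \eqn{1.1\,N^{-1/5}}
#' @return an object of class `item_curve_set`: grid, bandwidth, and per
#'   item the option probabilities, step functions `S1 >= S2` with bands,
#'   effective n, expected score and observed category counts
#' @export
fit_item_curves <- function(responses, theta, scale = NULL, grid = default_grid(),
                            bandwidth = NULL) {
  stopifnot(all(diff(grid) > 0))
  cols <- if (is.null(scale)) item_cols(responses) else scale_item_cols(scale)
  idx <- match(theta$person_id, responses$person_id)
  if (anyNA(idx)) stop_config("theta assignment contains unknown person ids")
  x <- as.matrix(responses[idx, cols, drop = FALSE])
  th <- theta$theta
  n <- length(th)
  h <- bandwidth %||% (1.1 * n^(-1/5))
  if (h <= 0) stop_config("bandwidth must be positive")
  W <- dnorm(outer(grid, th, "-") / h)      # Q x N
  items <- list()
  for (j in seq_along(cols)) {
    obs <- !is.na(x[, j])
    Wj <- W[, obs, drop = FALSE]
    tot <- rowSums(Wj)
    if (any(tot <= 0)) stop_config("zero kernel weight at a grid point")
    counts <- tabulate(x[obs, j] + 1L, nbins = 3L)
    p <- sapply(0:2, function(k) rowSums(Wj[, x[obs, j] == k, drop = FALSE]) / tot)
    colnames(p) <- c("p0", "p1", "p2")
    n_eff <- tot^2 / rowSums(Wj^2)
    S <- cbind(S1 = p[, 2] + p[, 3], S2 = p[, 3])
    half <- 1.96 * sqrt(pmax(S * (1 - S), 0) / n_eff)
    items[[cols[j]]] <- list(
      prob = p, S = S,
      S_lo = pmax(S - half, 0), S_hi = pmin(S + half, 1),
      n_eff = n_eff, expected = p[, 2] + 2 * p[, 3],
      counts = counts)
  }
  structure(list(grid = grid, bandwidth = h, n = n, items = items),
            class = "item_curve_set")
}

#' @export
print.item_curve_set <- function(x, ...) {
  cat(sprintf("item_curve_set: %d items, %d grid points on [%.2f, %.2f], h = %.3f, N = %d\n",
              length(x$items), length(x$grid), min(x$grid), max(x$grid),
              x$bandwidth, x$n))
  invisible(x)
}

#' Serialize fitted curves to a long-format data frame
#'
#' One row per item x step function x grid point, suitable for CSV export.
#'
#' @param curves an `item_curve_set`
#' @return data frame with columns item, step, grid_point, estimate, lo, hi,
#'   n_eff
#' @export
curves_to_long <- function(curves) {
  do.call(rbind, lapply(names(curves$items), function(it) {
    ci <- curves$items[[it]]
    do.call(rbind, lapply(1:2, function(s)
      data.frame(item = it, step = s, grid_point = curves$grid,
                 estimate = ci$S[, s], lo = ci$S_lo[, s], hi = ci$S_hi[, s],
                 n_eff = ci$n_eff, stringsAsFactors = FALSE)))
  }))
}

#' Maximum-likelihood latent-trait scores from fitted curves
#'
#' For each respondent the score is the grid point maximizing
#' \eqn{\sum_j \log \max(\hat p_{j,x_{ij}}(\theta_q), \epsilon)} over the
#' observed items, with a probability floor \eqn{\epsilon = 10^{-6}} guarding
#' against smoothing zeros; ties resolve to the lowest tied grid point.
#' Respondents missing every scale item receive `NA`.
#'
#' @param responses response data frame
#' @param curves an `item_curve_set` fitted on the same items
#' @param scale optional scale definition restricting the items
#' @param floor probability floor
#' @return named numeric vector of scores (names are person ids)
#' @export
ml_score <- function(responses, curves, scale = NULL, floor = 1e-6) {
  cols <- if (is.null(scale)) names(curves$items) else scale_item_cols(scale)
  cols <- intersect(cols, names(curves$items))
  if (!length(cols)) stop_config("no scale items present in the curve set")
  x <- as.matrix(responses[, cols, drop = FALSE])
  Q <- length(curves$grid)
  # log p for each item, category, grid point
  logp <- lapply(cols, function(it) log(pmax(curves$items[[it]]$prob, floor)))
  out <- rep(NA_real_, nrow(x))
  for (i in seq_len(nrow(x))) {
    ll <- numeric(Q)
    any_obs <- FALSE
    for (j in seq_along(cols)) {
      xij <- x[i, j]
      if (!is.na(xij)) {
        ll <- ll + logp[[j]][, xij + 1L]
        any_obs <- TRUE
      }
    }
    if (any_obs) out[i] <- curves$grid[which.max(ll)]
  }
  names(out) <- responses$person_id
  out
}

#' Item difficulty and discrimination from expected-score PCA
#'
#' Principal component analysis (centered, unscaled) of the items-by-grid
#' matrix of expected item scores. The first component is oriented so that
#' higher values mean easier items (positive correlation with the item's
#' mean expected score); the second so that higher values mean more
#' discriminant items (positive correlation with the total variation of the
#' expected-score curve).
#'
#' @param curves an `item_curve_set` with at least 3 items
#' @return data frame: item, difficulty (PC1), discrimination (PC2),
#'   mean_expected, total_variation
#' @export
difficulty_discrimination <- function(curves) {
  if (length(curves$items) < 3) stop_config("expected-score PCA needs at least 3 items")
  E <- t(vapply(curves$items, function(ci) ci$expected, numeric(length(curves$grid))))
  pc <- prcomp(E, center = TRUE, scale. = FALSE)
  sc <- pc$x[, 1:2, drop = FALSE]
  m <- rowMeans(E)
  tv <- apply(E, 1, function(e) sum(abs(diff(e))))
  orient <- function(v, target) {
    s <- sign(sum((v - mean(v)) * (target - mean(target))))
    if (is.na(s) || s == 0) 1 else s
  }
  data.frame(item = rownames(E),
             difficulty = sc[, 1] * orient(sc[, 1], m),
             discrimination = sc[, 2] * orient(sc[, 2], tv),
             mean_expected = m, total_variation = tv,
             row.names = NULL, stringsAsFactors = FALSE)
}
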