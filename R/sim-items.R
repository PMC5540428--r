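#' Specify a graded-response item
#'
#' Items are polytomous with three ordered categories (0, 1, 2) and are
#' generated from two logistic step functions
#' \eqn{S_x(\theta) = d \cdot \sigma(a(\theta - b_x))}, the probabilities of
#' responding at least 1 and at least 2. The upper asymptote `d < 1` produces
#' low-endorsement items whose step functions never approach 1; an optional
#' Gaussian "dip" subtracted from the first step function produces a
#' controlled violation of monotonicity; `dif_shift` moves the thresholds for
#' a named group, producing differential item functioning.
#'
#' @param item_id identifier (used as the `item_<id>` response column name)
#' @param a discrimination, positive
#' @param b numeric length-2, thresholds for the two step functions, `b[1] < b[2]`
#' @param d upper asymptote in (0, 1]
#' @param dif_shift optional named numeric vector: group label -> additive
#'   threshold shift applied to both thresholds for members of that group
#' @param dip optional list(m, s, gamma): center, width and depth of a
#'   Gaussian bump subtracted from the first step function
#' @return an object of class `item_spec`
#' @export
item_spec <- function(item_id, a = 1.5, b = c(-0.5, 0.8), d = 1,
                      dif_shift = NULL, dip = NULL) {
  if (a <= 0) stop_config("discrimination must be positive (item %s)", item_id)
  if (length(b) != 2 || b[1] >= b[2])
    stop_config("thresholds must satisfy b1 < b2 (item %s)", item_id)
  if (d <= 0 || d > 1) stop_config("upper asymptote must lie in (0,1] (item %s)", item_id)
  if (!is.null(dip)) {
    dip <- as.list(dip)
    stopifnot(all(c("m", "s", "gamma") %in% names(dip)))
    if (dip$s <= 0 || dip$gamma < 0) stop_config("dip needs s > 0, gamma >= 0")
  }
  structure(list(item_id = as.character(item_id), a = a, b = b, d = d,
                 dif_shift = dif_shift, dip = dip),
            class = "item_spec")
}

#' Analytic step functions of a generating item
#'
#' Evaluates the true cumulative response probabilities
#' \eqn{P(X \ge 1 | \theta)} and \eqn{P(X \ge 2 | \theta)} of an
#' [item_spec()], including asymptote, group threshold shift and dip, with
#' the ordering \eqn{S_1 \ge S_2} enforced by clipping (the dip is subtracted
#' from \eqn{S_1} only and may not push it below \eqn{S_2}).
#'
#' @param spec an [item_spec()]
#' @param theta numeric vector of latent-trait values
#' @param group optional character vector (same length as `theta`) of group
#'   labels, matched against `spec$dif_shift`
#' @return matrix with columns `S1`, `S2`
#' @export
item_true_steps <- function(spec, theta, group = NULL) {
  shift <- rep(0, length(theta))
  if (!is.null(spec$dif_shift)) {
    if (is.null(group))
      stop_config("item %s has a dif_shift but no group labels were given", spec$item_id)
    hit <- match(group, names(spec$dif_shift))
    shift <- ifelse(is.na(hit), 0, spec$dif_shift[hit])
  }
  s1 <- spec$d * plogis(spec$a * (theta - (spec$b[1] + shift)))
  s2 <- spec$d * plogis(spec$a * (theta - (spec$b[2] + shift)))
  if (!is.null(spec$dip))
    s1 <- s1 - spec$dip$gamma * exp(-(theta - spec$dip$m)^2 / (2 * spec$dip$s^2))
  s1 <- pmin(pmax(s1, s2), 1)
  s2 <- pmin(pmax(s2, 0), 1)
  cbind(S1 = s1, S2 = s2)
}

#' Draw polytomous responses from graded-response items
#'
#' Category probabilities follow the graded-response construction
#' `P(X = 2) = S2`, `P(X = 1) = S1 - S2`, `P(X = 0) = 1 - S1`.
#'
#' @param theta numeric vector of latent-trait values (finite)
#' @param item_bank list of [item_spec()]
#' @param group_labels optional group labels for DIF-shifted items
#' @param seed integer seed for the category draws
#' @return integer matrix persons x items with values in \{0, 1, 2\}; columns
#'   named `item_<id>`
#' @export
simulate_items <- function(theta, item_bank, group_labels = NULL, seed = 1L) {
  stopifnot(all(is.finite(theta)))
  n <- length(theta)
  out <- matrix(0L, n, length(item_bank))
  colnames(out) <- paste0("item_", vapply(item_bank, `[[`, "", "item_id"))
  with_seed(seed, {
    for (j in seq_along(item_bank)) {
      s <- item_true_steps(item_bank[[j]], theta, group_labels)
      u <- runif(n)
      out[, j] <- (u < s[, "S1"]) + (u < s[, "S2"])
    }
  })
  out
}

#' Default calibrated item bank
#'
#' A bank of well-behaved graded-response items spanning a range of
#' difficulties and discriminations. The threshold spread is calibrated so
#' that, for a 14-item scale on a standard-normal trait, roughly one fifth of
#' respondents endorse nothing (sum score 0), matching the zero-score mass a
#' population mental-health screener typically shows.
#'
#' @param n_items number of items
#' @param prefix item-id prefix
#' @return list of [item_spec()]
#' @export
default_item_bank <- function(n_items = 14, prefix = "ad") {
  j <- seq_len(n_items)
  b1 <- seq(0.4, 1.8, length.out = n_items)  # mostly hard items: analytic
                                             # zero-score mass ~0.20 at k=14
  # discriminations 1.2-1.8, raised for the hardest items so every clean
  # item's first step function clearly approaches 1 at the top of the
  # trait range (ceiling >= 0.97 at theta = 3)
  a <- pmax(1.2 + 0.3 * ((j - 1) %% 3), 3.5 / (3 - b1))
  b2 <- b1 + 1.2
  lapply(j, function(k)
    item_spec(sprintf("%s%02d", prefix, k), a = a[k], b = c(b1[k], b2[k]), d = 1))
}

#' Item bank containing deliberate pathologies
#'
#' Starts from [default_item_bank()] and replaces chosen items with
#' non-monotone (dip), low-endorsement (asymptote), empty-top-category and
#' sex-DIF items, mirroring the failure modes an item-screening protocol must
#' detect.
#'
#' @param n_items bank size
#' @param prefix item-id prefix
#' @param dip_items,low_endorse_items,empty_cat_items,dif_items integer
#'   positions of the pathological items
#' @param dif_shift threshold shift applied to group `"F"` for `dif_items`
#' @return list of [item_spec()]
#' @export
pathological_item_bank <- function(n_items = 15, prefix = "cf",
                                   dip_items = c(6, 10, 12),
                                   low_endorse_items = c(13, 14),
                                   empty_cat_items = 15,
                                   dif_items = integer(0), dif_shift = 1.0) {
  bank <- default_item_bank(n_items, prefix)
  for (k in dip_items)  # easy discriminating items with the bump centered
                        # where the scale is informative, so the decrease
                        # survives rank noise and kernel smoothing
    bank[[k]] <- item_spec(bank[[k]]$item_id, a = 2, b = c(-1.2, 1.8),
                           dip = list(m = 1, s = 0.6, gamma = 0.6))
  for (k in low_endorse_items)  # low ceiling reached early, so the plateau
                                # below 1 is well estimated at the grid top
    bank[[k]] <- item_spec(bank[[k]]$item_id, a = bank[[k]]$a, b = c(0.3, 1.5),
                           d = 0.25)
  for (k in empty_cat_items)
    bank[[k]] <- item_spec(bank[[k]]$item_id, a = bank[[k]]$a, b = c(2.5, 15), d = 1)
  for (k in dif_items)
    bank[[k]] <- item_spec(bank[[k]]$item_id, a = bank[[k]]$a, b = bank[[k]]$b,
                           dif_shift = c(F = dif_shift))
  bank
}
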