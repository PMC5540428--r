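#' Root-mean-square differential item functioning statistic
#'
#' Distance between two groups' item response step functions on a common
#' grid, weighted by the standard-normal latent density:
#' \deqn{\mathrm{DIF} = \sqrt{\sum_q \phi(\theta_q)\,(S_A(\theta_q) -
#' S_B(\theta_q))^2 / \sum_q \phi(\theta_q)}.}
#' Symmetric in the two groups. A mean-absolute-difference variant is
#' available via `metric = "mad"`.
#'
#' @param curves_a,curves_b `item_curve_set`s fitted on the same grid
#' @param item item column name
#' @param step step function index (1 or 2)
#' @param metric `"rms"` (default) or `"mad"`
#' @return a single value in \[0, 1\]
#' @export
dif_statistic <- function(curves_a, curves_b, item, step = 1, metric = c("rms", "mad")) {
  metric <- match.arg(metric)
  if (!isTRUE(all.equal(curves_a$grid, curves_b$grid)))
    stop_config("curve sets must share the same grid")
  sa <- curves_a$items[[item]]$S[, step]
  sb <- curves_b$items[[item]]$S[, step]
  if (is.null(sa) || is.null(sb)) stop_config("item %s missing from a curve set", item)
  w <- dnorm(curves_a$grid)
  if (metric == "rms") sqrt(sum(w * (sa - sb)^2) / sum(w))
  else sum(w * abs(sa - sb)) / sum(w)
}

band_disjoint_mass <- function(curves_a, curves_b, item, step) {
  ga <- curves_a$items[[item]]
  gb <- curves_b$items[[item]]
  disjoint <- ga$S_lo[, step] > gb$S_hi[, step] | gb$S_lo[, step] > ga$S_hi[, step]
  if (!any(disjoint)) return(0)
  w <- dnorm(curves_a$grid)
  w <- w / sum(w)
  r <- rle(disjoint)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  max(vapply(which(r$values), function(k) sum(w[starts[k]:ends[k]]), 0))
}

#' Decide exclusion of an item for differential item functioning
#'
#' An item is excluded when its aggregate DIF exceeds `threshold` *and* the
#' two groups' 95% confidence bands are disjoint over a contiguous grid
#' region carrying at least `mass` of the standard-normal latent density.
#'
#' @param result one row of a [compare_groups()] result (or a list with
#'   `item_dif` and `significant`)
#' @param threshold DIF exclusion threshold
#' @return logical: exclude the item?
#' @export
flag_item_dif <- function(result, threshold = 0.25) {
  isTRUE(result$item_dif > threshold && result$significant)
}

#' Per-item DIF between two groups on a common latent metric
#'
#' Pools both groups for a single sum-score ranking (so groups are compared
#' at equal proficiency), fits kernel curves per group, and reports per-step
#' and aggregate DIF with the confidence-band significance rule. The
#' aggregate `item_dif` is the maximum over the two step functions.
#'
#' @param responses response data frame containing `group_column`
#' @param scale scale definition
#' @param group_column name of a two-level grouping column (e.g. sex, wave)
#' @param grid,bandwidth,tie_seed passed to the kernel fit
#' @param threshold DIF exclusion threshold
#' @param mass minimum latent mass of a contiguous band-disjoint region for
#'   significance
#' @return list with `table` (item, dif_step1, dif_step2, item_dif,
#'   significant, excluded), `median_dif`, `group_sizes`, and the per-group
#'   curve sets
#' @export
compare_groups <- function(responses, scale, group_column, grid = default_grid(),
                           bandwidth = NULL, tie_seed = 1L, threshold = 0.25,
                           mass = 0.10) {
  g <- responses[[group_column]]
  if (is.null(g)) stop_config("grouping column '%s' not found", group_column)
  lev <- unique(stats::na.omit(g))
  if (length(lev) != 2)
    stop_config("grouping column '%s' must have exactly 2 levels (found %d)",
                group_column, length(lev))
  lev <- sort(as.character(lev))
  theta <- rank_theta(responses, scale, tie_seed = tie_seed)
  sizes <- setNames(integer(2), lev)
  curves <- list()
  for (l in lev) {
    sub <- responses[!is.na(g) & g == l, , drop = FALSE]
    th_sub <- theta[theta$person_id %in% sub$person_id, , drop = FALSE]
    sizes[l] <- nrow(th_sub)
    if (sizes[l] < 30)
      warning(sprintf("group '%s' has %d respondents; curves may be unstable",
                      l, sizes[l]))
    curves[[l]] <- fit_item_curves(sub, th_sub, scale, grid, bandwidth)
  }
  cols <- scale_item_cols(scale)
  tab <- do.call(rbind, lapply(cols, function(it) {
    d1 <- dif_statistic(curves[[1]], curves[[2]], it, 1)
    d2 <- dif_statistic(curves[[1]], curves[[2]], it, 2)
    idif <- max(d1, d2)
    step_max <- which.max(c(d1, d2))
    sig <- band_disjoint_mass(curves[[1]], curves[[2]], it, step_max) >= mass
    data.frame(item = it, dif_step1 = d1, dif_step2 = d2, item_dif = idif,
               significant = sig, stringsAsFactors = FALSE)
  }))
  tab$excluded <- vapply(seq_len(nrow(tab)), function(i)
    flag_item_dif(tab[i, ], threshold), logical(1))
  list(table = tab, median_dif = median(tab$item_dif), group_sizes = sizes,
       curves = curves)
}
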