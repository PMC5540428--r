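#' Define a scale as a named set of items
#'
#' @param name scale name
#' @param items vector of item identifiers (without the `item_` prefix)
#' @param provenance optional named list item -> provenance string
#'   (`"original"`, `"added"`, or `"excluded:<reason>"`); defaults to
#'   `"original"` for every active item
#' @return an object of class `scale_definition`
#' @export
scale_definition <- function(name, items, provenance = NULL) {
  items <- as.character(items)
  if (anyDuplicated(items)) stop_config("duplicate items in scale '%s'", name)
  if (is.null(provenance))
    provenance <- setNames(as.list(rep("original", length(items))), items)
  excluded <- names(provenance)[startsWith(unlist(provenance), "excluded")]
  if (length(intersect(items, excluded)))
    stop_config("excluded items may not remain in the active set")
  structure(list(name = name, items = items, provenance = provenance,
                 max_category = 2L), class = "scale_definition")
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("scale '%s': %d active items (%s)\n", x$name, length(x$items),
              paste(x$items, collapse = ", ")))
  invisible(x)
}

#' Check monotonicity of an item's step functions
#'
#' Flags `non_monotone` when a step function decreases by more than `delta`
#' over a run of at least two consecutive decreasing grid steps lying within
#' the central 95% of the latent density (\[-1.96, 1.96\]), and the decrease
#' is unambiguous given the pointwise confidence bands (the run's starting
#' estimate exceeds the end's upper band limit). Decreases confined to the
#' extreme tails are reported in the evidence but not flagged, since they
#' affect almost no respondents.
#'
#' @param curves an `item_curve_set`
#' @param item item column name
#' @param delta minimum flagged decrease
#' @param central central latent range inside which decreases count
#' @return list: `item`, `flags` (character subset of `"non_monotone"`),
#'   `evidence` (data frame of decreasing runs: step, from, to, drop,
#'   central)
#' @export
check_monotonicity <- function(curves, item, delta = 0.05,
                               central = c(-1.96, 1.96)) {
  ci <- curves$items[[item]]
  if (is.null(ci)) stop_config("item %s not in curve set", item)
  ev <- NULL
  flagged <- FALSE
  for (s in 1:2) {
    y <- ci$S[, s]
    dec <- diff(y) < 0
    r <- rle(dec)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    lo <- ci$S_lo[, s]; hi <- ci$S_hi[, s]
    for (k in which(r$values & r$lengths >= 2)) {
      i0 <- starts[k]; i1 <- ends[k] + 1L
      drop <- y[i0] - y[i1]
      # only the part of the decrease inside the central range counts
      # towards the flag; tail-confined decreases are reported only
      cen <- which(curves$grid >= central[1] & curves$grid <= central[2])
      j0 <- max(i0, min(cen)); j1 <- min(i1, max(cen))
      drop_central <- if (j0 < j1) y[j0] - y[j1] else 0
      # the decrease must also be unambiguous given the pointwise bands:
      # the run's starting estimate must sit above the end's upper
      # confidence limit, so kernel-noise wiggles within the bands never
      # count
      significant <- j0 < j1 && y[j0] > hi[j1]
      if (drop > delta) {
        hit <- drop_central > delta && significant
        ev <- rbind(ev, data.frame(step = s, from = curves$grid[i0],
                                   to = curves$grid[i1], drop = drop,
                                   drop_central = drop_central,
                                   central = hit))
        if (hit) flagged <- TRUE
      }
    }
  }
  list(item = item, flags = if (flagged) "non_monotone" else character(0),
       evidence = ev)
}

#' Check endorsement of an item
#'
#' Flags `low_endorsement` when the upper 95% band of the first step
#' function fails to reach 0.95 anywhere over the top of the latent grid
#' (`theta >= 2.5`; the curve's ceiling is visibly below 1), and
#' `empty_category` when a response category was never observed. Taking the
#' best band over the whole top region, rather than the single endpoint,
#' keeps the check stable where the effective sample thins out.
#'
#' @param curves an `item_curve_set`
#' @param item item column name
#' @param top latent value above which the ceiling is assessed
#' @return list: `item`, `flags`, `evidence`
#' @export
check_endorsement <- function(curves, item, top = 2.5) {
  ci <- curves$items[[item]]
  if (is.null(ci)) stop_config("item %s not in curve set", item)
  flags <- character(0)
  sel <- curves$grid >= min(top, max(curves$grid))
  top_hi <- max(ci$S_hi[sel, 1])
  if (top_hi < 0.95) flags <- c(flags, "low_endorsement")
  if (any(ci$counts == 0)) flags <- c(flags, "empty_category")
  list(item = item, flags = flags,
       evidence = data.frame(top_upper_band = top_hi,
                             n_cat0 = ci$counts[1], n_cat1 = ci$counts[2],
                             n_cat2 = ci$counts[3]))
}

# Monotonicity is checked on curves fitted against the full-scale sum-score
# ranking (smoother; a genuine dip survives the ranking). The endorsement
# (ceiling) check instead ranks by the REST score, the scale sum excluding
# the item itself: ranking by the full sum conditions an item on itself --
# respondents at the extreme top of the sum distribution have, by
# construction, endorsed nearly everything, which drags the top of every
# step function towards 1 and masks genuine ceilings.
screen_items <- function(responses, scale, grid, bandwidth, tie_seed) {
  theta <- rank_theta(responses, scale, tie_seed = tie_seed)
  curves <- fit_item_curves(responses, theta, scale, grid, bandwidth)
  flags <- lapply(scale$items, function(id) {
    it <- paste0("item_", id)
    rest_items <- setdiff(scale$items, id)
    cu_rest <- if (length(rest_items) >= 2) {
      rest <- scale_definition(scale$name, rest_items)
      th_r <- rank_theta(responses, rest, tie_seed = tie_seed)
      fit_item_curves(responses, th_r, scale_definition("one", id), grid, bandwidth)
    } else curves
    m <- check_monotonicity(curves, it)
    e <- check_endorsement(cu_rest, it)
    list(item = it, flags = c(m$flags, e$flags),
         evidence = list(monotonicity = m$evidence, endorsement = e$evidence))
  })
  names(flags) <- scale_item_cols(scale)
  list(curves = curves, flags = flags)
}

strip_prefix <- function(x) sub("^item_", "", x)

#' Iterative scale refinement
#'
#' Implements the screening protocol: fit kernel curves on the current
#' scale, exclude (in one batch) all items flagged non-monotone,
#' low-endorsement or empty-category, refit, and repeat until no item is
#' flagged. Then each candidate item is tested singly for admission: it is
#' admitted when, added to the refined scale, it raises no flag and its
#' discrimination (total variation of its expected-score curve) exceeds the
#' lower quartile of the scale items'
#' discriminations. Batch exclusion (rather than one-at-a-time) is used
#' because flags can be artifacts of poorly correlated co-items distorting
#' the latent ranking.
#'
#' @param responses response data frame
#' @param initial_scale starting [scale_definition()]
#' @param candidate_items character vector of candidate item ids (disjoint
#'   from the scale)
#' @param forbidden_items item ids that may never be admitted (e.g. items
#'   belonging to another scale, to avoid artificially inflating
#'   between-scale correlations)
#' @param min_items abort threshold: stochastic ordering by the sum score
#'   needs more than 5 items
#' @param admission_quantile quantile of scale discriminations a candidate
#'   must exceed
#' @param grid,bandwidth,tie_seed kernel-fit controls
#' @return list: `scale` (refined definition), `report` (iteration log with
#'   every flag and decision)
#' @export
refine_scale <- function(responses, initial_scale, candidate_items = character(0),
                         forbidden_items = character(0), min_items = 6,
                         admission_quantile = 0.25, grid = default_grid(),
                         bandwidth = NULL, tie_seed = 1L) {
  candidate_items <- as.character(candidate_items)
  if (length(intersect(candidate_items, initial_scale$items)))
    stop_config("candidate items must be disjoint from the initial scale")
  scale <- initial_scale
  prov <- scale$provenance
  log <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    sc <- screen_items(responses, scale, grid, bandwidth, tie_seed)
    bad <- names(sc$flags)[vapply(sc$flags, function(f) length(f$flags) > 0, logical(1))]
    log[[length(log) + 1L]] <- list(iteration = iter, action = "screen",
                                    excluded = strip_prefix(bad),
                                    flags = sc$flags[bad])
    if (!length(bad)) break
    for (b in bad)
      prov[[strip_prefix(b)]] <- paste0("excluded:",
                                        paste(sc$flags[[b]]$flags, collapse = "+"))
    keep <- setdiff(scale$items, strip_prefix(bad))
    if (length(keep) < min_items)
      stop_config("scale '%s' shrank below %d items during refinement", scale$name, min_items)
    scale <- scale_definition(scale$name, keep,
                              provenance = prov[c(keep, setdiff(names(prov), keep))])
  }
  # candidate admission, each tested singly against the refined scale; the
  # discrimination measure is the total variation of the expected-score
  # curve (its climb over the trait range), which is stable where the PC2
  # coordinate can be dominated by curve-shape contrasts
  base_curves <- sc$curves
  dd <- difficulty_discrimination(base_curves)
  cut <- quantile(dd$total_variation, admission_quantile)
  admitted <- character(0)
  for (cand in candidate_items) {
    if (cand %in% forbidden_items) {
      log[[length(log) + 1L]] <- list(action = "candidate", item = cand,
                                      decision = "refused: belongs to another scale")
      next
    }
    trial <- scale_definition(scale$name, c(scale$items, cand))
    sc_t <- screen_items(responses, trial, grid, bandwidth, tie_seed)
    fl <- sc_t$flags[[paste0("item_", cand)]]$flags
    dd_t <- difficulty_discrimination(sc_t$curves)
    disc <- dd_t$total_variation[dd_t$item == paste0("item_", cand)]
    ok <- length(fl) == 0 && disc > cut
    log[[length(log) + 1L]] <- list(action = "candidate", item = cand,
                                    flags = fl, discrimination = disc,
                                    threshold = unname(cut),
                                    decision = if (ok) "admitted" else "rejected")
    if (ok) admitted <- c(admitted, cand)
  }
  if (length(admitted)) {
    for (a in admitted) prov[[a]] <- "added"
    scale <- scale_definition(scale$name, c(scale$items, admitted),
                              provenance = prov)
  } else {
    scale$provenance <- prov
  }
  list(scale = scale, report = log)
}

#' Screen a refined scale for differential item functioning
#'
#' Applies [compare_groups()] + [flag_item_dif()] for each grouping column
#' (two-level comparisons; for a multi-level column such as wave, each
#' non-reference level is compared with the reference level, the study-design
#' benchmark wave) and removes excluded items.
#'
#' @param responses response data frame
#' @param scale refined [scale_definition()]
#' @param group_columns grouping columns to screen (e.g. `c("sex", "wave")`)
#' @param reference optional named list column -> reference level for
#'   multi-level columns (default: last level in sort order)
#' @param threshold,mass,grid,bandwidth,tie_seed passed through
#' @return list: `scale` (with DIF exclusions recorded), `report` (one
#'   comparison table per group contrast)
#' @export
dif_screen <- function(responses, scale, group_columns = c("sex", "wave"),
                       reference = NULL, threshold = 0.25, mass = 0.10,
                       grid = default_grid(), bandwidth = NULL, tie_seed = 1L) {
  prov <- scale$provenance
  report <- list()
  for (gc in group_columns) {
    g <- responses[[gc]]
    lev <- sort(unique(as.character(stats::na.omit(g))))
    if (length(lev) < 2) next
    contrasts <- if (length(lev) == 2) list(lev) else {
      ref <- reference[[gc]] %||% lev[length(lev)]
      lapply(setdiff(lev, ref), function(l) c(l, ref))
    }
    for (ct in contrasts) {
      sub <- responses[as.character(g) %in% ct, , drop = FALSE]
      cg <- compare_groups(sub, scale, gc, grid, bandwidth, tie_seed,
                           threshold, mass)
      key <- paste(gc, paste(ct, collapse = "_vs_"), sep = ":")
      report[[key]] <- cg$table
      out <- strip_prefix(cg$table$item[cg$table$excluded])
      for (o in out)
        prov[[o]] <- sprintf("excluded:dif_%s(%.2f)", key,
                             cg$table$item_dif[cg$table$item == paste0("item_", o)])
      keep <- setdiff(scale$items, out)
      scale <- scale_definition(scale$name, keep,
                                provenance = prov[c(keep, setdiff(names(prov), keep))])
    }
  }
  list(scale = scale, report = report)
}

#' Published SPHERE-21 scale definitions
#'
#' Returns the anxiety-depression (14 items) and chronic fatigue (10 items)
#' scales of the 21-item SPHERE questionnaire, as shipped in
#' `inst/extdata/sphere21_scales.json`. Three items (3 "Poor memory",
#' 30 "Poor concentration", 32 "Feeling lost for words") belong to both
#' scales. Two anxiety-depression item numbers not stated in running text
#' are reconstructed from the instrument's published composition and marked
#' as such in the fixture file.
#'
#' @return list of two [scale_definition()]s: `anxiety_depression`,
#'   `chronic_fatigue`
#' @export
sphere21_definition <- function() {
  path <- system.file("extdata", "sphere21_scales.json", package = "twinirt")
  raw <- jsonlite::read_json(path)
  lapply(raw, function(sc)
    scale_definition(sc$name, unlist(sc$items),
                     provenance = sc$provenance))
}
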