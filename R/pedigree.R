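#' Additive relatedness block for one family
#'
#' Expected additive-genetic relatedness (twice the kinship coefficient)
#' among the children of one family: 1 on the diagonal and between MZ
#' co-twins, 0.5 for every other within-family pair (DZ co-twins,
#' twin-sibling, sib-sib).
#'
#' @param fam pedigree rows of a single family
#' @return symmetric matrix with person ids as dimnames
#' @export
relatedness_block <- function(fam) {
  k <- nrow(fam)
  m <- matrix(0.5, k, k, dimnames = list(fam$person_id, fam$person_id))
  diag(m) <- 1
  mz <- which(fam$zygosity == "MZ" & fam$role %in% c("twin1", "twin2"))
  if (length(mz) == 2) m[mz[1], mz[2]] <- m[mz[2], mz[1]] <- 1
  m
}

#' Additive relatedness matrix of a pedigree
#'
#' Block-diagonal by family; sparse (persons unrelated across families).
#'
#' @param pedigree pedigree data frame (`person_id`, `family_id`,
#'   `zygosity`, `role`)
#' @return a symmetric sparse `Matrix` with person ids as dimnames
#' @export
relatedness_matrix <- function(pedigree) {
  if (anyDuplicated(pedigree$person_id))
    stop_config("duplicate person ids in pedigree")
  blocks <- lapply(split(pedigree, pedigree$family_id), relatedness_block)
  K <- Matrix::bdiag(blocks)
  ids <- unlist(lapply(blocks, rownames), use.names = FALSE)
  dimnames(K) <- list(ids, ids)
  K[pedigree$person_id, pedigree$person_id]
}

#' Demographic-matched familial pruning
#'
#' Draws one person per family, `n_iter` times with a seeded stream, and
#' returns the draw whose demographics best match the full sample:
#' \deqn{d = |\Delta \bar{age}|/sd_{full} + |var_{sub}/var_{full} - 1| +
#' |\Delta f_{female}|.}
#'
#' @param responses data frame with `person_id`, `age`, `sex` (one row per
#'   person)
#' @param pedigree pedigree data frame
#' @param n_iter number of seeded random draws
#' @param seed integer seed
#' @return list: `person_id` (selected subset), `objective`, `audit`
#'   (objective value of every draw)
#' @export
prune_unrelated <- function(responses, pedigree, n_iter = 1000, seed = 1L) {
  ped <- pedigree[pedigree$person_id %in% responses$person_id, , drop = FALSE]
  demo <- responses[match(ped$person_id, responses$person_id), , drop = FALSE]
  fam_idx <- split(seq_len(nrow(ped)), ped$family_id)
  mu <- mean(demo$age); v <- var(demo$age); sdev <- sd(demo$age)
  if (sdev == 0) sdev <- 1
  pf <- mean(demo$sex == "F")
  obj <- function(idx) {
    a <- demo$age[idx]
    abs(mean(a) - mu) / sdev +
      abs((if (length(a) > 1) var(a) else 0) / max(v, 1e-12) - 1) +
      abs(mean(demo$sex[idx] == "F") - pf)
  }
  audit <- numeric(n_iter)
  best <- NULL; best_d <- Inf
  with_seed(as.integer(seed), {
    for (it in seq_len(n_iter)) {
      idx <- vapply(fam_idx, function(ix)
        if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)], integer(1))
      d <- obj(idx)
      audit[it] <- d
      if (d < best_d) { best_d <- d; best <- idx }
    }
  })
  list(person_id = ped$person_id[best], objective = best_d, audit = audit)
}

#' Cross-wave selection of unrelated observations
#'
#' For a two-wave comparison, selects one person per family across both
#' waves and assigns each selected person to one wave, preferring the wave
#' that currently has fewer participants when a person was assessed in
#' both. The familial pruning and assignment are iterated `n_iter` times,
#' keeping the iteration with the most similar wave sizes.
#'
#' @param responses data frame with `person_id`, `wave` (one row per person
#'   per wave)
#' @param pedigree pedigree data frame
#' @param n_iter iterations
#' @param seed integer seed
#' @return list: per-wave person-id vectors (disjoint persons), `imbalance`
#' @export
cross_wave_select <- function(responses, pedigree, n_iter = 100, seed = 1L) {
  waves <- sort(unique(responses$wave))
  if (length(waves) != 2) stop_config("cross-wave selection expects exactly 2 waves")
  ped <- pedigree[pedigree$person_id %in% responses$person_id, , drop = FALSE]
  fam_members <- split(ped$person_id, ped$family_id)
  wave_of <- split(responses$wave, responses$person_id)
  best <- NULL; best_imb <- Inf
  with_seed(as.integer(seed), {
    for (it in seq_len(n_iter)) {
      sel <- vapply(fam_members, function(ids)
        if (length(ids) == 1) ids else ids[sample.int(length(ids), 1)], character(1))
      sel <- sel[sample.int(length(sel))]  # random processing order
      na <- 0L; nb <- 0L
      assign_a <- character(0); assign_b <- character(0)
      for (p in sel) {
        w <- wave_of[[p]]
        pick <- if (length(w) == 1) w else if (na <= nb) waves[1] else waves[2]
        if (pick == waves[1]) { assign_a <- c(assign_a, p); na <- na + 1L }
        else { assign_b <- c(assign_b, p); nb <- nb + 1L }
      }
      imb <- abs(na - nb)
      if (imb < best_imb) {
        best_imb <- imb
        best <- setNames(list(assign_a, assign_b), waves)
      }
    }
  })
  c(best, list(imbalance = best_imb))
}

#' Assign observations to age bins
#'
#' Half-open, left-closed bins \[9,13), \[13,15), \[15,17), \[17,28\].
#' Observations outside \[9,28\] are dropped with a warning; when a person
#' has several observations in one bin, one is kept by a seeded random
#' choice.
#'
#' @param responses data frame with `person_id`, `age` (one row per
#'   observation)
#' @param seed integer seed for duplicate resolution
#' @return `responses` with an `age_bin` column, one row per person per bin
#' @export
assign_age_bins <- function(responses, seed = 1L) {
  breaks <- c(9, 13, 15, 17, 28)
  labels <- c("9-12", "13-14", "15-16", "17-28")
  out_of_range <- responses$age < 9 | responses$age > 28
  if (any(out_of_range)) {
    warning(sum(out_of_range), " observation(s) outside ages [9, 28] dropped")
    responses <- responses[!out_of_range, , drop = FALSE]
  }
  bin <- cut(responses$age, breaks, labels = labels, right = FALSE,
             include.lowest = TRUE)
  responses$age_bin <- as.character(bin)
  key <- paste(responses$person_id, responses$age_bin)
  keep <- with_seed(as.integer(seed), {
    ord <- sample.int(nrow(responses))
    ord[!duplicated(key[ord])]
  })
  responses[sort(keep), , drop = FALSE]
}

#' Restrict families to at most three children
#'
#' Keeps the twin pair plus one seeded-random extra sibling; other siblings
#' are dropped. (MZ trios, were they present, would reduce to a random
#' pair.)
#'
#' @param pedigree pedigree data frame
#' @param max_children maximum family size
#' @param seed integer seed
#' @return restricted pedigree
#' @export
restrict_family_size <- function(pedigree, max_children = 3, seed = 1L) {
  keep <- with_seed(as.integer(seed), {
    unlist(lapply(split(seq_len(nrow(pedigree)), pedigree$family_id), function(ix) {
      if (length(ix) <= max_children) return(ix)
      fam <- pedigree[ix, , drop = FALSE]
      tw <- ix[fam$role %in% c("twin1", "twin2")]
      sib <- setdiff(ix, tw)
      n_extra <- max_children - length(tw)
      c(tw, if (n_extra > 0 && length(sib)) sib[sample.int(length(sib), min(n_extra, length(sib)))])
    }))
  })
  pedigree[sort(keep), , drop = FALSE]
}
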