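#' Replication experiments
#'
#' Seeded simulation studies that exercise the whole pipeline at the design
#' points of the study the package models: the 8-12-year twin-cohort
#' composition (226 MZ pairs, 408 DZ pairs, extra siblings, singletons),
#' heritabilities around 0.41-0.42, genetic/environmental cross-trait
#' correlations 0.87/0.44, a 52-pair retest design at consistency 0.47, and
#' a diagnosis odds ratio of 1.39 per latent-trait unit at ~16% prevalence.
#' Each function returns the per-replicate estimates so means and spreads
#' can be inspected.
#'
#' @name experiments
NULL

#' @describeIn experiments ML latent-trait score of an all-lowest respondent
#'   after a kernel IRT fit on a well-behaved cohort (`n` persons, 14
#'   items); the boundary of the default grid by construction of the rank
#'   mapping.
#' @param n cohort size
#' @param seed integer seed
#' @export
experiment_boundary_score <- function(n = 1000, seed = 1L) {
  bank <- default_item_bank(14, "ad")
  cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 0, p_extra_sib = 0,
                    n_singletons = n,
                    trait_params = list(ad = c(a2 = 0.41, c2 = 0, e2 = 0.59)),
                    item_bank = list(ad = bank), seed = seed)
  co <- simulate_cohort(cfg)
  resp <- co$responses
  theta <- rank_theta(resp, tie_seed = seed)
  curves <- fit_item_curves(resp, theta)
  zero <- resp[1, ]
  zero[grep("^item_", names(zero))] <- 0L
  unname(ml_score(zero, curves))
}

#' @describeIn experiments univariate AE heritability recovery at the
#'   8-12-year design (one fitted standardized A proportion per replicate).
#' @param n_rep replicates
#' @param a2 generating additive-genetic share
#' @export
experiment_heritability_recovery <- function(n_rep = 20, a2 = 0.41, seed = 1L) {
  vapply(seq_len(n_rep), function(r) {
    cfg <- sim_config(n_mz_pairs = 226, n_dz_pairs = 408,
                      p_extra_sib = 84 / 634, n_singletons = 28,
                      trait_params = list(t = c(a2 = a2, c2 = 0, e2 = 1 - a2)),
                      seed = substream_seed(seed, paste0("h2_", r)))
    co <- simulate_cohort(cfg)
    d <- twin_data(co$pedigree, setNames(co$truth$theta_t, co$truth$person_id))
    unname(fit_univariate(d, "AE", ci = FALSE, n_starts = 3)$proportions["a"])
  }, numeric(1))
}

#' @describeIn experiments bivariate Cholesky recovery of the genetic and
#'   environmental correlations at the 9-12-year design (600 twin+sibling
#'   families; returns a data frame with `rG` and `rE` per replicate).
#' @param rG,rE generating component correlations
#' @param a2_1,a2_2 per-trait additive shares
#' @export
experiment_bivariate_recovery <- function(n_rep = 20, rG = 0.87, rE = 0.44,
                                          a2_1 = 0.41, a2_2 = 0.42, seed = 1L) {
  out <- t(vapply(seq_len(n_rep), function(r) {
    cfg <- sim_config(n_mz_pairs = 214, n_dz_pairs = 386, p_extra_sib = 0.13,
                      n_singletons = 0,
                      trait_params = list(t1 = c(a2 = a2_1, c2 = 0, e2 = 1 - a2_1),
                                          t2 = c(a2 = a2_2, c2 = 0, e2 = 1 - a2_2)),
                      rG = rG, rE = rE,
                      seed = substream_seed(seed, paste0("biv_", r)))
    co <- simulate_cohort(cfg)
    sc <- cbind(co$truth$theta_t1, co$truth$theta_t2)
    rownames(sc) <- co$truth$person_id
    f <- fit_bivariate(twin_data(co$pedigree, sc), "AE", tests = FALSE,
                       n_starts = 3)
    c(rG = f$rG, rE = f$rE)
  }, c(rG = 0, rE = 0)))
  as.data.frame(out)
}

#' @describeIn experiments two-way consistency ICC recovery for a 52-pair
#'   retest design at a given true consistency (one ICC per replicate).
#' @param icc true pairwise consistency
#' @param n_pairs retest sample size
#' @export
experiment_icc_recovery <- function(n_rep = 200, icc = 0.47, n_pairs = 52,
                                    seed = 1L) {
  vapply(seq_len(n_rep), function(r) {
    with_seed(substream_seed(seed, paste0("icc_", r)), {
      t1 <- rnorm(n_pairs)
      t2 <- icc * t1 + sqrt(1 - icc^2) * rnorm(n_pairs)
      icc_consistency(t1, t2)$icc
    })
  }, numeric(1))
}

#' @describeIn experiments odds-ratio recovery of the kinship-aware
#'   quasi-likelihood logistic model at the 15-16-year design (~2000
#'   persons, ~16% prevalence, sex/age covariates; one fitted OR per
#'   replicate).
#' @param or generating per-unit odds ratio
#' @param sigma2 polygenic variance of the generating random effect
#' @export
experiment_or_recovery <- function(n_rep = 20, or = 1.39, sigma2 = 0.3,
                                   seed = 1L) {
  vapply(seq_len(n_rep), function(r) {
    cfg <- sim_config(n_mz_pairs = 300, n_dz_pairs = 500, p_extra_sib = 0.13,
                      n_singletons = 180,
                      trait_params = list(t = c(a2 = 0.29, c2 = 0, e2 = 0.71)),
                      diagnosis_params = list(
                        mdd = list(trait = 1, intercept = qlogis(0.163),
                                   slope = log(or), sigma2 = sigma2)),
                      age_mean = 16, age_sd = 0.4,
                      seed = substream_seed(seed, paste0("or_", r)))
    co <- simulate_cohort(cfg)
    dg <- simulate_diagnoses(co, cfg)
    cov <- data.frame(sex = co$pedigree$sex, age_sphere = co$pedigree$age,
                      age_cidi = dg$age_interview)
    pql_logistic_mixed(dg$mdd, co$truth$theta_t, cov, co$pedigree)$or
  }, numeric(1))
}

#' @describeIn experiments false-positive rate of the DIF exclusion rule on
#'   null comparisons (no generating group difference; returns the fraction
#'   of item-comparisons excluded).
#' @export
experiment_dif_null_fpr <- function(n_rep = 50, seed = 1L) {
  sc <- scale_definition("d", sprintf("d%02d", 1:10))
  hits <- vapply(seq_len(n_rep), function(r) {
    cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 0, p_extra_sib = 0,
                      n_singletons = 2000,
                      trait_params = list(d = c(a2 = 0.3, c2 = 0, e2 = 0.7)),
                      item_bank = list(d = default_item_bank(10, "d")),
                      seed = substream_seed(seed, paste0("difnull_", r)))
    co <- simulate_cohort(cfg)
    cg <- compare_groups(co$responses, sc, "sex")
    sum(cg$table$excluded)
  }, numeric(1))
  sum(hits) / (n_rep * 10)
}

#' @describeIn experiments refinement-protocol operating characteristics on
#'   replicate cohorts containing six pathological and nine clean items plus
#'   two good candidates; returns per-replicate logicals for "all
#'   pathological excluded" and "all clean retained".
#' @param n cohort size per replicate
#' @export
experiment_refinement_success <- function(n_rep = 20, n = 1200, seed = 1L) {
  bank <- pathological_item_bank(15, "cf")
  cand <- list(item_spec("cd01", a = 2.0, b = c(0.3, 1.5)),
               item_spec("cd02", a = 1.8, b = c(0.8, 2.0)))
  patho <- sprintf("cf%02d", c(6, 10, 12, 13, 14, 15))
  clean <- setdiff(sprintf("cf%02d", 1:15), patho)
  out <- t(vapply(seq_len(n_rep), function(r) {
    cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 0, p_extra_sib = 0,
                      n_singletons = n,
                      trait_params = list(cf = c(a2 = 0.42, c2 = 0, e2 = 0.58)),
                      item_bank = list(cf = c(bank, cand)),
                      seed = substream_seed(seed, paste0("refine_", r)))
    co <- simulate_cohort(cfg)
    init <- scale_definition("cf", sprintf("cf%02d", 1:15))
    rs <- tryCatch(refine_scale(co$responses, init,
                                candidate_items = c("cd01", "cd02")),
                   error = function(e) NULL)
    if (is.null(rs)) return(c(pathological_out = FALSE, clean_in = FALSE))
    c(pathological_out = !any(patho %in% rs$scale$items),
      clean_in = all(clean %in% rs$scale$items))
  }, c(pathological_out = FALSE, clean_in = FALSE)))
  as.data.frame(out)
}

#' @describeIn experiments type-I error of the kinship-aware logistic model
#'   at nominal 0.05 under a null slope with family structure (returns the
#'   rejection rate).
#' @export
experiment_pql_type1 <- function(n_rep = 200, seed = 1L) {
  hits <- vapply(seq_len(n_rep), function(r) {
    cfg <- sim_config(n_mz_pairs = 60, n_dz_pairs = 90, p_extra_sib = 0.1,
                      n_singletons = 20,
                      trait_params = list(t = c(a2 = 0.4, c2 = 0, e2 = 0.6)),
                      diagnosis_params = list(
                        d = list(trait = 1, intercept = qlogis(0.2), slope = 0,
                                 sigma2 = 0.3)),
                      seed = substream_seed(seed, paste0("t1_", r)))
    co <- simulate_cohort(cfg)
    dg <- simulate_diagnoses(co, cfg)
    cov <- data.frame(sex = co$pedigree$sex, age_sphere = co$pedigree$age)
    pql_logistic_mixed(dg$d, co$truth$theta_t, cov, co$pedigree)$p < 0.05
  }, logical(1))
  mean(hits)
}
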