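#' Configuration for a synthetic twin-family cohort
#'
#' Defines the family composition (MZ/DZ twin pairs, optional third sibling,
#' singletons), the variance decomposition of one or two latent traits into
#' additive-genetic (A), common-environment (C) and unique-environment (E)
#' shares, the cross-trait correlations of each component, the item banks
#' that turn latent traits into polytomous questionnaire responses, covariate
#' effects, retest reliability, and the generating model for binary
#' diagnoses.
#'
#' @param n_mz_pairs,n_dz_pairs numbers of monozygotic / dizygotic twin pairs
#' @param p_extra_sib probability that a twin family includes a third sibling
#' @param n_singletons number of single-child families
#' @param trait_params named list of numeric vectors `c(a2, c2, e2)` summing
#'   to 1 (one or two traits)
#' @param rG,rC,rE cross-trait correlations of the A, C and E components
#'   (ignored with a single trait)
#' @param item_bank named list (same names as `trait_params`) of item banks,
#'   each a list of [item_spec()]; may be `NULL` for score-only simulations
#' @param sex_effect,age_effect named per-trait additive shifts on the latent
#'   trait (female indicator; years from the cohort mean age)
#' @param retest_reliability correlation of the latent trait across the two
#'   administrations, in \[0, 1\]
#' @param diagnosis_params named list of outcomes, each
#'   `list(trait, intercept, slope, sigma2)`: logit-scale intercept,
#'   per-unit-trait log-odds slope, and polygenic variance of the
#'   kinship-structured random effect
#' @param age_mean,age_sd mean and SD of the family base age (years)
#' @param mcar_rate optional missing-completely-at-random masking rate for
#'   item responses
#' @param seed master integer seed; every stage derives its own sub-stream
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_mz_pairs = 226, n_dz_pairs = 408, p_extra_sib = 0.13,
                       n_singletons = 28,
                       trait_params = list(ad = c(a2 = 0.41, c2 = 0, e2 = 0.59)),
                       rG = 0.87, rC = 0, rE = 0.44,
                       item_bank = NULL,
                       sex_effect = NULL, age_effect = NULL,
                       retest_reliability = 0.47,
                       diagnosis_params = list(
                         mdd = list(trait = 1, intercept = qlogis(0.166),
                                    slope = log(1.39), sigma2 = 0.3)),
                       age_mean = 12, age_sd = 0.5, mcar_rate = 0, seed = 1L) {
  cfg <- list(n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
              p_extra_sib = p_extra_sib, n_singletons = n_singletons,
              trait_params = trait_params, rG = rG, rC = rC, rE = rE,
              item_bank = item_bank, sex_effect = sex_effect,
              age_effect = age_effect, retest_reliability = retest_reliability,
              diagnosis_params = diagnosis_params, age_mean = age_mean,
              age_sd = age_sd, mcar_rate = mcar_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (nm in names(cfg$trait_params)) {
    v <- cfg$trait_params[[nm]]
    if (length(v) != 3 || any(v < 0) || abs(sum(v) - 1) > 1e-12)
      stop_config("trait '%s': a2 + c2 + e2 must equal 1 with nonnegative shares", nm)
  }
  for (r in c(cfg$rG, cfg$rC, cfg$rE))
    if (abs(r) > 1) stop_config("component correlations must lie in [-1, 1]")
  probs <- c(cfg$p_extra_sib, cfg$retest_reliability, cfg$mcar_rate)
  if (any(probs < 0 | probs > 1)) stop_config("probabilities must lie in [0, 1]")
  for (nm in names(cfg$diagnosis_params)) {
    dp <- cfg$diagnosis_params[[nm]]
    if (!is.null(dp$sigma2) && dp$sigma2 < 0)
      stop_config("diagnosis '%s': polygenic variance must be nonnegative", nm)
  }
  invisible(cfg)
}

# Family skeleton: one row per person, with zygosity/role/sex/age.
build_pedigree <- function(cfg) {
  fams <- list()
  fid <- 0L
  add_fam <- function(zyg, with_sib) {
    fid <<- fid + 1L
    roles <- c("twin1", "twin2", if (with_sib) "sib")
    data.frame(family_id = fid, role = roles, zygosity = zyg,
               stringsAsFactors = FALSE)
  }
  n_tw <- cfg$n_mz_pairs + cfg$n_dz_pairs
  sib_draw <- runif(n_tw) < cfg$p_extra_sib
  for (i in seq_len(cfg$n_mz_pairs)) fams[[length(fams) + 1L]] <- add_fam("MZ", sib_draw[i])
  for (i in seq_len(cfg$n_dz_pairs))
    fams[[length(fams) + 1L]] <- add_fam("DZ", sib_draw[cfg$n_mz_pairs + i])
  for (i in seq_len(cfg$n_singletons)) {
    fid <- fid + 1L
    fams[[length(fams) + 1L]] <- data.frame(family_id = fid, role = "singleton",
                                            zygosity = "none", stringsAsFactors = FALSE)
  }
  ped <- do.call(rbind, fams)
  n <- nrow(ped)
  # sexes: MZ co-twins identical, everyone else independent
  sex <- sample(c("F", "M"), n, replace = TRUE)
  mz1 <- ped$zygosity == "MZ" & ped$role == "twin1"
  mz2 <- ped$zygosity == "MZ" & ped$role == "twin2"
  sex[mz2] <- sex[mz1][match(ped$family_id[mz2], ped$family_id[mz1])]
  ped$sex <- sex
  # ages: twins share the family base age, the extra sibling is 2-4 years off
  base <- rnorm(max(ped$family_id), cfg$age_mean, cfg$age_sd)
  age <- base[ped$family_id]
  is_sib <- ped$role == "sib"
  age[is_sib] <- age[is_sib] + sample(c(-4, -3, -2, 2, 3, 4), sum(is_sib), replace = TRUE)
  ped$age <- round(age, 2)
  ped$person_id <- sprintf("p%05d", seq_len(n))
  ped[, c("person_id", "family_id", "zygosity", "role", "sex", "age")]
}

rbivnorm <- function(n, r) {
  z1 <- rnorm(n)
  z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * rnorm(n)
  cbind(z1, z2)
}

# A/C/E component draws for up to two traits with cross-trait correlations.
# A is built from a shared mid-parental stream plus an individual segregation
# stream so that MZ co-twins are identical and every other sib pair
# (DZ twins, twin-sibling, sib-sib) correlates 0.5.
draw_components <- function(ped, cfg) {
  k <- length(cfg$trait_params)
  n <- nrow(ped)
  nf <- max(ped$family_id)
  draw <- function(m, r) if (k == 2) rbivnorm(m, r) else matrix(rnorm(m), m, 1)
  a_fam <- draw(nf, cfg$rG)
  c_fam <- draw(nf, cfg$rC)
  seg <- draw(n, cfg$rG)   # per-person segregation; MZ twin2 copies twin1
  mz1 <- ped$zygosity == "MZ" & ped$role == "twin1"
  mz2 <- ped$zygosity == "MZ" & ped$role == "twin2"
  seg[mz2, ] <- seg[mz1, , drop = FALSE][match(ped$family_id[mz2], ped$family_id[mz1]), ]
  A <- sqrt(0.5) * a_fam[ped$family_id, , drop = FALSE] + sqrt(0.5) * seg
  C <- c_fam[ped$family_id, , drop = FALSE]
  E <- draw(n, cfg$rE)
  theta <- matrix(NA_real_, n, k)
  for (t in seq_len(k)) {
    v <- cfg$trait_params[[t]]
    theta[, t] <- sqrt(v[1]) * A[, t] + sqrt(v[2]) * C[, t] + sqrt(v[3]) * E[, t]
  }
  tn <- names(cfg$trait_params)
  colnames(theta) <- tn
  colnames(A) <- colnames(C) <- colnames(E) <- if (k == 2) tn else tn[1]
  list(theta = theta, A = A[, seq_len(k), drop = FALSE],
       C = C[, seq_len(k), drop = FALSE], E = E[, seq_len(k), drop = FALSE])
}

shifted_theta <- function(theta, ped, cfg) {
  out <- theta
  for (t in colnames(theta)) {
    s <- cfg$sex_effect[[t]] %||% 0
    a <- cfg$age_effect[[t]] %||% 0
    out[, t] <- theta[, t] + s * (ped$sex == "F") + a * (ped$age - cfg$age_mean)
  }
  out
}

#' Simulate a twin-family questionnaire cohort
#'
#' Generates the pedigree, the latent A/C/E trait structure and (when item
#' banks are supplied) item-level polytomous responses for one
#' administration. Latent traits are standardized (mean 0, variance 1 in
#' expectation) before sex and age shifts are applied. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()]
#' @return list with elements `responses` (one row per person: demographics,
#'   `wave`, item columns), `pedigree`, and `truth` (latent traits and
#'   component draws per person)
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  ped <- with_seed(substream_seed(config$seed, "structure"), build_pedigree(config))
  comp <- with_seed(substream_seed(config$seed, "components"),
                    draw_components(ped, config))
  th <- shifted_theta(comp$theta, ped, config)
  resp <- ped
  resp$wave <- "W1"
  if (!is.null(config$item_bank)) {
    for (t in names(config$item_bank)) {
      x <- simulate_items(th[, t], config$item_bank[[t]], group_labels = ped$sex,
                          seed = substream_seed(config$seed, paste0("items_", t)))
      resp <- cbind(resp, as.data.frame(x))
    }
    if (config$mcar_rate > 0) {
      ic <- item_cols(resp)
      with_seed(substream_seed(config$seed, "mcar"), {
        for (cc in ic) {
          miss <- runif(nrow(resp)) < config$mcar_rate
          resp[[cc]][miss] <- NA_integer_
        }
      })
    }
  }
  truth <- data.frame(person_id = ped$person_id, family_id = ped$family_id,
                      stringsAsFactors = FALSE)
  for (t in colnames(comp$theta)) {
    truth[[paste0("theta_", t)]] <- comp$theta[, t]
    truth[[paste0("theta_obs_", t)]] <- th[, t]
    truth[[paste0("A_", t)]] <- comp$A[, t]
    truth[[paste0("C_", t)]] <- comp$C[, t]
    truth[[paste0("E_", t)]] <- comp$E[, t]
  }
  list(responses = resp, pedigree = ped, truth = truth)
}

#' Simulate a retest administration
#'
#' The second-administration latent trait is
#' \eqn{\theta' = \rho\,\theta + \sqrt{1-\rho^2}\,\epsilon} with fresh noise
#' \eqn{\epsilon}, so that `retest_reliability` is the test-retest
#' correlation of the trait; items are regenerated from \eqn{\theta'}.
#'
#' @param cohort result of [simulate_cohort()]
#' @param config the same [sim_config()]
#' @return a response data frame with `wave = "W2"`, plus attribute
#'   `theta_retest` (matrix of second-administration traits)
#' @export
simulate_retest <- function(cohort, config) {
  rho <- config$retest_reliability
  ped <- cohort$pedigree
  tn <- names(config$trait_params)
  th1 <- as.matrix(cohort$truth[paste0("theta_", tn)])
  colnames(th1) <- tn
  eps <- with_seed(substream_seed(config$seed, "retest"),
                   matrix(rnorm(length(th1)), nrow(th1), ncol(th1)))
  th2 <- rho * th1 + sqrt(max(0, 1 - rho^2)) * eps
  th2s <- shifted_theta(th2, ped, config)
  resp <- ped
  resp$wave <- "W2"
  if (!is.null(config$item_bank)) {
    for (t in names(config$item_bank)) {
      x <- simulate_items(th2s[, t], config$item_bank[[t]], group_labels = ped$sex,
                          seed = substream_seed(config$seed, paste0("retest_items_", t)))
      resp <- cbind(resp, as.data.frame(x))
    }
  }
  attr(resp, "theta_retest") <- th2
  resp
}

#' Simulate binary diagnoses with a kinship-structured random effect
#'
#' Outcomes follow `logit p_i = intercept + slope * theta_i + u_i` with
#' `u ~ N(0, sigma2 * K)` where `K` is the additive relatedness matrix of
#' the pedigree. Marginal prevalence is controlled by the intercept.
#'
#' @param cohort result of [simulate_cohort()]
#' @param config a [sim_config()] whose `diagnosis_params` define outcomes
#' @return data frame: `person_id`, `age_interview`, one 0/1 column per
#'   outcome
#' @export
simulate_diagnoses <- function(cohort, config) {
  ped <- cohort$pedigree
  tn <- names(config$trait_params)
  out <- data.frame(person_id = ped$person_id, stringsAsFactors = FALSE)
  with_seed(substream_seed(config$seed, "diagnoses"), {
    out$age_interview <- round(ped$age + 8 + rnorm(nrow(ped), 0, 1.5), 1)
    for (nm in names(config$diagnosis_params)) {
      dp <- config$diagnosis_params[[nm]]
      trait <- if (is.numeric(dp$trait)) tn[dp$trait] else dp$trait
      th <- cohort$truth[[paste0("theta_", trait)]]
      u <- numeric(nrow(ped))
      if ((dp$sigma2 %||% 0) > 0) {
        for (f in unique(ped$family_id)) {
          idx <- which(ped$family_id == f)
          kb <- relatedness_block(ped[idx, , drop = FALSE])
          L <- chol(dp$sigma2 * kb + diag(1e-10, length(idx)))
          u[idx] <- as.numeric(t(L) %*% rnorm(length(idx)))
        }
      }
      p <- plogis(dp$intercept + dp$slope * th + u)
      out[[nm]] <- rbinom(nrow(ped), 1, p)
    }
  })
  out
}

#' Write a simulated cohort to plain-text files
#'
#' Emits `responses.csv`, `pedigree.csv`, `truth.csv`, optionally
#' `diagnoses.csv`, and the configuration as `config.yaml` (item banks
#' flattened to their parameters).
#'
#' @param cohort result of [simulate_cohort()]
#' @param config the [sim_config()] used
#' @param dir output directory (created if needed)
#' @param diagnoses optional result of [simulate_diagnoses()]
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, config, dir, diagnoses = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$responses, file.path(dir, "responses.csv"), row.names = FALSE)
  utils::write.csv(cohort$pedigree, file.path(dir, "pedigree.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  if (!is.null(diagnoses))
    utils::write.csv(diagnoses, file.path(dir, "diagnoses.csv"), row.names = FALSE)
  cfg <- unclass(config)
  cfg$item_bank <- lapply(cfg$item_bank, function(bank)
    lapply(bank, function(s) list(item_id = s$item_id, a = s$a, b = s$b, d = s$d,
                                  dif_shift = as.list(s$dif_shift), dip = s$dip)))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
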