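#' @keywords internal
"_PACKAGE"

#' @importFrom stats qnorm dnorm pnorm plogis qlogis rnorm runif rbinom cor
#'   cov var sd median quantile optim optimize uniroot prcomp qf pchisq
#'   qchisq complete.cases binomial glm.fit model.matrix na.omit pt qt
#'   setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Each simulation stage draws from its own seeded stream so that stages can
#' be re-run independently without perturbing one another. The sub-seed is a
#' deterministic function of the master seed and a stage label, kept within
#' the 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed master integer seed
#' @param stage character stage label
#' @return an integer seed
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483587L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

item_cols <- function(responses) {
  grep("^item_", names(responses), value = TRUE)
}

scale_item_cols <- function(scale) {
  paste0("item_", scale$items)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
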