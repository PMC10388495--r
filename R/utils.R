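#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm qnorm pt qt pchisq rnorm runif sd quantile
#'   approx lm coef setNames complete.cases median
#' @importFrom utils head tail modifyList
NULL

# Run `code` under a local RNG stream started at `seed`, restoring the
# caller's RNG state afterwards. Every stochastic operation in the package
# funnels through this so that a user-level seed gives exact reproducibility
# without clobbering the global stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive k child seeds from a master seed; used to give each trait (and the
# truth layer) an independent substream so adding one never perturbs another.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

z_crit <- function(alpha = 0.05) qnorm(1 - alpha / 2)

# floored at the smallest normalized double: extreme z-scores underflow
# 2*pnorm(-|z|) to exactly 0, which the p in (0,1] invariant forbids
two_sided_p_norm <- function(z)
  pmax(pmin(1, 2 * pnorm(-abs(z))), .Machine$double.xmin)
two_sided_p_t <- function(t, df)
  pmax(pmin(1, 2 * pt(-abs(t), df = df)), .Machine$double.xmin)

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
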