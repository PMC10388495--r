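# Product-of-coefficients mediation decomposition on MR estimates:
# indirect = Beta(XZ) * Beta(ZY); proportion R = indirect/total * 100%;
# direct = total - indirect.

#' Mediation decomposition of a total causal effect
#'
#' Given the total effect of exposure on outcome `Beta(XY)` (univariable
#' random-effects IVW), the exposure-on-mediator effect `Beta(XZ)`
#' (univariable IVW), and the mediator-on-outcome effect adjusted for the
#' exposure `Beta(ZY)` (the multivariable-IVW coefficient), computes the
#' indirect effect `Beta(XZ) * Beta(ZY)`, the direct effect
#' `Beta(XY) - indirect`, and the proportion mediated
#' `R = indirect / Beta(XY) * 100%`. The decomposition
#' `direct + indirect = total` holds at machine precision by construction.
#'
#' Uncertainty: the indirect-effect SE uses the product delta method,
#' `sqrt(Bxz^2 se_zy^2 + Bzy^2 se_xz^2)`; the proportion CI uses the ratio
#' delta method treating total and indirect as independent. A warning flag
#' is set when the indirect and total effects have opposite signs, in which
#' case R is not interpretable as a percentage of the effect.
#'
#' @param total total effect `Beta(XY)` (nonzero).
#' @param exposure_mediator effect `Beta(XZ)`.
#' @param mediator_outcome_adjusted effect `Beta(ZY)`.
#' @param ses optional numeric vector of the three SEs, in the same order
#'   `c(total, exposure_mediator, mediator_outcome_adjusted)`; all >= 0.
#' @return object of class `mediation_result`.
#' @export
#' @examples
#' mediate(log(0.703), log(2.103), -0.277)
mediate <- function(total, exposure_mediator, mediator_outcome_adjusted,
                    ses = c(0, 0, 0)) {
  assert_that(length(total) == 1 && total != 0, "total effect must be a nonzero scalar")
  assert_that(length(ses) == 3 && all(ses >= 0), "ses must be three values >= 0")
  bxz <- exposure_mediator
  bzy <- mediator_outcome_adjusted
  indirect <- bxz * bzy
  direct <- total - indirect
  # re-assemble the total from its parts so direct + indirect == total holds
  # bit-exactly (floating point does not guarantee (a-b)+b == a); differs
  # from the input by at most one ulp
  total <- direct + indirect
  proportion <- 100 * indirect / total
  indirect_se <- sqrt(bxz^2 * ses[3]^2 + bzy^2 * ses[2]^2)
  # ratio delta method on R = 100 * I / T (independence approximation)
  prop_se <- if (indirect == 0) 100 * indirect_se / abs(total) else
    abs(proportion) * sqrt((indirect_se / indirect)^2 + (ses[1] / total)^2)
  crit <- qnorm(0.975)
  structure(list(total = total, exposure_mediator = bxz,
                 mediator_outcome_adjusted = bzy,
                 indirect = indirect, direct = direct, proportion = proportion,
                 indirect_se = indirect_se, proportion_se = prop_se,
                 proportion_ci = c(proportion - crit * prop_se,
                                   proportion + crit * prop_se),
                 opposite_signs = sign(indirect) * sign(total) < 0),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(paste0("<mediation_result>\n  total     Beta(XY) = %.3f\n",
                     "  indirect  Beta(XZ)*Beta(ZY) = %.3f\n",
                     "  direct    Beta(XY) - indirect = %.3f\n",
                     "  proportion mediated R = %.2f%%\n"),
              x$total, x$indirect, x$direct, x$proportion))
  if (x$opposite_signs)
    cat("  warning: indirect and total effects have opposite signs;\n",
        "  R is not interpretable as a percentage of the effect\n")
  invisible(x)
}
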