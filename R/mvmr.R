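# Multivariable MR: joint instrument assembly across K exposures, MV-IVW
# and MV-Egger with their heterogeneity and pleiotropy checks.

#' Construct multivariable MR input
#'
#' @param snp_ids length-J SNP ids.
#' @param exposure_betas,exposure_ses J x K matrices (K >= 2 exposures),
#'   columns named by exposure.
#' @param Gamma,se_Gamma outcome betas and SEs aligned to the same effect
#'   alleles.
#' @return object of class `mvmr_input`.
#' @export
mvmr_input <- function(snp_ids, exposure_betas, exposure_ses, Gamma, se_Gamma) {
  exposure_betas <- as.matrix(exposure_betas)
  exposure_ses <- as.matrix(exposure_ses)
  J <- length(snp_ids); K <- ncol(exposure_betas)
  assert_that(K >= 2, "mvmr_input requires K >= 2 exposures")
  assert_that(J > K, "mvmr_input requires more instruments than exposures (J > K)")
  assert_that(nrow(exposure_betas) == J && all(dim(exposure_ses) == c(J, K)) &&
              length(Gamma) == J && length(se_Gamma) == J,
              "mvmr_input dimensions disagree")
  assert_that(all(exposure_ses > 0) && all(se_Gamma > 0), "all SEs must be > 0")
  structure(list(snp_ids = as.character(snp_ids),
                 exposure_betas = exposure_betas, exposure_ses = exposure_ses,
                 Gamma = as.numeric(Gamma), se_Gamma = as.numeric(se_Gamma)),
            class = "mvmr_input")
}

#' Assemble a multivariable MR input from per-trait summary datasets
#'
#' Takes the union of each exposure's significant SNPs (per-exposure p-value
#' selection with relaxation), jointly clumps the union (clump rank = each
#' SNP's best p-value across exposures), and aligns every dataset to the
#' first exposure's effect allele with the same allele-matching rules as
#' [harmonize()]. SNPs missing from any dataset, irreconcilable, or
#' intermediate-frequency palindromic are dropped with logged reasons.
#'
#' @param exposure_sets list of K >= 2 `summary_dataset`s.
#' @param outcome a `summary_dataset`.
#' @param ld optional [ld_matrix()] for joint clumping.
#' @param p_threshold,relaxed_p_threshold,min_instruments,clump_r2,clump_window_kb,palindrome_band
#'   selection parameters as in the univariable pipeline.
#' @return an [mvmr_input()]; attribute `log` records per-stage drops.
#' @export
build_mvmr_input <- function(exposure_sets, outcome, ld = NULL,
                             p_threshold = 5e-8, relaxed_p_threshold = 5e-6,
                             min_instruments = 3, clump_r2 = 0.001,
                             clump_window_kb = 10000, palindrome_band = 0.08) {
  K <- length(exposure_sets)
  assert_that(K >= 2, "build_mvmr_input requires K >= 2 exposures")
  selected <- lapply(exposure_sets, select_by_pvalue, threshold = p_threshold,
                     relaxed_threshold = relaxed_p_threshold,
                     min_instruments = min_instruments)
  union_ids <- unique(unlist(lapply(selected, function(d) d$data$snp)))
  ref <- exposure_sets[[1]]
  # clump on the union: take each SNP's row from the first exposure that
  # carries it, with p = best p across exposures
  best_p <- rep(1, length(union_ids)); names(best_p) <- union_ids
  rows <- NULL
  for (d in exposure_sets) {
    hit <- d$data[d$data$snp %in% union_ids, ]
    bp <- pmin(best_p[hit$snp], hit$p)
    best_p[hit$snp] <- bp
    if (is.null(rows)) rows <- hit
    else rows <- rbind(rows, hit[!(hit$snp %in% rows$snp), ])
  }
  rows <- rows[match(union_ids[union_ids %in% rows$snp], rows$snp), ]
  rows$p <- best_p[rows$snp]
  union_ds <- summary_dataset(rows, "mvmr_union", ref$trait_type)
  clumped <- ld_clump(union_ds, ld = ld, r2_max = clump_r2,
                      window_kb = clump_window_kb)
  ids <- clumped$data$snp

  drop_log <- character(0)
  all_sets <- c(exposure_sets, list(outcome))
  present <- Reduce(intersect, lapply(all_sets, function(d) d$data$snp), ids)
  if (length(present) < length(ids))
    drop_log <- c(drop_log, sprintf("%d SNP(s) missing from one or more datasets",
                                    length(ids) - length(present)))
  # align exposures 2..K and the outcome to exposure 1's effect allele by
  # harmonizing each against the first exposure restricted to `present`
  ref_sub <- summary_dataset(ref$data[match(present, ref$data$snp), ],
                             ref$trait_name, ref$trait_type)
  aligned <- lapply(all_sets[-1], function(d) {
    harmonize(ref_sub, d, palindrome_band = palindrome_band)
  })
  keep_ids <- Reduce(intersect, lapply(aligned, function(h) h$snp_ids), present)
  if (length(keep_ids) < length(present))
    drop_log <- c(drop_log, sprintf("%d SNP(s) removed during cross-dataset harmonization",
                                    length(present) - length(keep_ids)))
  J <- length(keep_ids)
  assert_that(J > K, sprintf("only %d instruments for %d exposures after assembly", J, K))
  eb <- matrix(NA_real_, J, K); es <- matrix(NA_real_, J, K)
  ref_rows <- match(keep_ids, ref$data$snp)
  eb[, 1] <- ref$data$beta[ref_rows]; es[, 1] <- ref$data$se[ref_rows]
  for (k in 2:K) {
    hk <- aligned[[k - 1]]
    m <- match(keep_ids, hk$snp_ids)
    eb[, k] <- hk$Gamma[m]; es[, k] <- hk$se_Gamma[m]
  }
  ho <- aligned[[K]]  # outcome vs exposure 1
  m <- match(keep_ids, ho$snp_ids)
  nm <- vapply(exposure_sets, function(d) d$trait_name, "")
  colnames(eb) <- nm; colnames(es) <- nm
  out <- mvmr_input(keep_ids, eb, es, ho$Gamma[m], ho$se_Gamma[m])
  attr(out, "log") <- drop_log
  out
}

mvmr_fit <- function(input, intercept = FALSE) {
  X <- input$exposure_betas
  Gamma <- input$Gamma
  J <- nrow(X); K <- ncol(X)
  if (intercept) {
    # orient all SNPs so the first exposure's beta is non-negative
    s <- sign(X[, 1]); s[s == 0] <- 1
    X <- X * s
    Gamma <- Gamma * s
    X <- cbind(`(intercept)` = 1, X)
  }
  w <- 1 / input$se_Gamma^2
  A <- crossprod(X, w * X)
  if (qr(A)$rank < ncol(X)) stop("collinear exposures", call. = FALSE)
  bhat <- drop(solve(A, crossprod(X, w * Gamma)))
  resid <- Gamma - drop(X %*% bhat)
  q <- sum(w * resid^2)
  df <- J - ncol(X)
  assert_that(df >= 1, sprintf("J = %d leaves no residual degrees of freedom", J))
  scale <- max(1, sqrt(q / df))
  ses <- sqrt(diag(solve(A))) * scale
  list(coef = bhat, se = ses, q = q, df = df, scale = scale)
}

mvmr_result_table <- function(fit, method, exposures, use_t = FALSE) {
  idx <- match(exposures, names(fit$coef))
  beta <- fit$coef[idx]; se <- fit$se[idx]
  crit <- if (use_t) qt(0.975, fit$df) else qnorm(0.975)
  p <- if (use_t) two_sided_p_t(beta / se, fit$df) else two_sided_p_norm(beta / se)
  data.frame(exposure = exposures, method = method, beta = unname(beta),
             se = unname(se), ci_low = unname(beta - crit * se),
             ci_high = unname(beta + crit * se), pvalue = unname(p),
             stringsAsFactors = FALSE)
}

#' Multivariable IVW
#'
#' Weighted least squares of outcome betas on the J x K exposure-beta matrix
#' with no intercept, weights `1/se_Gamma^2`; each coefficient is that
#' exposure's direct effect on the outcome conditional on the others.
#' Multiplicative overdispersion floored at 1; normal-based inference.
#'
#' @param input an `mvmr_input` with J > K.
#' @return list of class `mvmr_result`: per-exposure `table`, heterogeneity
#'   `q/df/p`.
#' @export
mv_ivw <- function(input) {
  fit <- mvmr_fit(input, intercept = FALSE)
  tab <- mvmr_result_table(fit, "mv_ivw", colnames(input$exposure_betas))
  structure(list(method = "mv_ivw", table = tab, q = fit$q, df = fit$df,
                 q_pvalue = pchisq(fit$q, fit$df, lower.tail = FALSE)),
            class = "mvmr_result")
}

#' Multivariable MR-Egger
#'
#' As [mv_ivw()] but with a free intercept after orienting every SNP so the
#' first exposure's beta is non-negative; the intercept estimates average
#' directional pleiotropy in the multivariable model. t(J-K-1) inference.
#'
#' @param input an `mvmr_input` with J > K + 1.
#' @return list of class `mvmr_result` including `intercept`,
#'   `intercept_se`, `intercept_p`.
#' @export
mv_egger <- function(input) {
  K <- ncol(input$exposure_betas)
  assert_that(nrow(input$exposure_betas) > K + 1,
              "mv_egger requires J > K + 1 instruments")
  fit <- mvmr_fit(input, intercept = TRUE)
  tab <- mvmr_result_table(fit, "mv_egger", colnames(input$exposure_betas),
                           use_t = TRUE)
  i_est <- fit$coef[["(intercept)"]]
  i_se <- fit$se[[1]]
  structure(list(method = "mv_egger", table = tab, q = fit$q, df = fit$df,
                 q_pvalue = pchisq(fit$q, fit$df, lower.tail = FALSE),
                 intercept = i_est, intercept_se = i_se,
                 intercept_p = two_sided_p_t(i_est / i_se, fit$df)),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("<mvmr_result> %s (Q = %.2f on %d df, p = %.3g)\n",
              x$method, x$q, x$df, x$q_pvalue))
  print(x$table)
  invisible(x)
}
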