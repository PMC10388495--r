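# Heterogeneity, pleiotropy, outlier and influence diagnostics:
# Cochran's Q (IVW and Egger forms), the Egger intercept test, MR-PRESSO
# (global / outlier / distortion), leave-one-out, and plot-ready tables.

#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (Gamma_j - fitted_j)^2` with `w_j = 1/se_Gamma_j^2`,
#' fitted values from the fixed-effect IVW line through the origin
#' (`df = J-1`) or the Egger line with intercept (`df = J-2`); the p-value
#' is the upper tail of chi-square(df). `Q p < 0.05` is the conventional
#' heterogeneity call that switches the primary IVW model to random effects.
#'
#' @param h a `harmonized_set`.
#' @param method `"ivw"` (J >= 2) or `"egger"` (J >= 3).
#' @return object of class `heterogeneity_result`: `method, q, df, pvalue`.
#' @export
cochran_q <- function(h, method = c("ivw", "egger")) {
  method <- match.arg(method)
  J <- length(h$gamma)
  w <- 1 / h$se_Gamma^2
  if (method == "ivw") {
    if (J < 2) stop("cochran_q(ivw) requires J >= 2", call. = FALSE)
    beta <- ivw_point(h)
    q <- sum(w * (h$Gamma - beta * h$gamma)^2)
    df <- J - 1
  } else {
    if (J < 3) stop("cochran_q(egger) requires J >= 3", call. = FALSE)
    q <- mr_egger(h)$extras$q
    df <- J - 2
  }
  structure(list(method = method, q = q, df = df,
                 pvalue = pchisq(q, df, lower.tail = FALSE)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("<heterogeneity> %s: Q = %.3f on %d df, p = %.3g\n",
              x$method, x$q, x$df, x$pvalue))
  invisible(x)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' A statistically significant Egger intercept indicates average directional
#' (horizontal) pleiotropy across the instruments. Two-sided t(J-2)
#' inference on the intercept of [mr_egger()].
#'
#' @param h a `harmonized_set` with J >= 3.
#' @return list of class `pleiotropy_result` with `egger_intercept`,
#'   `intercept_se`, `intercept_p`.
#' @export
egger_intercept_test <- function(h) {
  e <- mr_egger(h)
  structure(list(egger_intercept = e$extras$intercept,
                 intercept_se = e$extras$intercept_se,
                 intercept_p = e$extras$intercept_p),
            class = "pleiotropy_result")
}

# Leave-one-out fixed-effect IVW estimates for all j in O(J) via sums.
loo_ivw_points <- function(gamma, Gamma, w) {
  sxy <- sum(w * gamma * Gamma)
  sxx <- sum(w * gamma^2)
  (sxy - w * gamma * Gamma) / (sxx - w * gamma^2)
}

#' MR-PRESSO: global pleiotropy test, outlier detection, distortion test
#'
#' Simulation-based residual-sum-of-squares test. For each SNP the
#' leave-one-out IVW estimate gives a residual
#' `r_j = Gamma_j - b_(-j) * gamma_j`; the observed statistic is
#' `RSS = sum_j w_j r_j^2`. Its null distribution is built by simulating
#' `n_sim` datasets with `Gamma_j* ~ N(b_(-j) gamma_j, se_Gamma_j)` and
#' `gamma_j* ~ N(gamma_j, se_gamma_j)` and recomputing RSS the same way.
#' Global p = `(1 + #[RSS_sim >= RSS_obs]) / (n_sim + 1)`. Per-SNP outlier
#' p-values rank each observed weighted squared residual in its own
#' simulated distribution and are Bonferroni-corrected over J; flagged SNPs
#' (corrected p < `outlier_alpha`) are removed from the returned corrected
#' set. When outliers are found, a distortion p-value compares the
#' estimate shift after their removal against the shift under random
#' removal of the same number of SNPs.
#'
#' @param h a `harmonized_set` with J >= 4.
#' @param n_sim simulated datasets (>= 100; default 1000).
#' @param seed integer seed.
#' @param outlier_alpha level for the Bonferroni-corrected outlier call.
#' @return list of class `presso_result`: `rss_obs`, `global_p`,
#'   `outliers` (data.frame snp/raw_p/corrected_p/flag), `distortion_p`
#'   (NA when no outliers), and `corrected` (a `harmonized_set`).
#' @export
mr_presso <- function(h, n_sim = 1000, seed, outlier_alpha = 0.05) {
  J <- length(h$gamma)
  if (J < 4) stop("mr_presso requires J >= 4 instruments", call. = FALSE)
  assert_that(n_sim >= 100, "mr_presso requires n_sim >= 100")
  w <- 1 / h$se_Gamma^2
  b_loo <- loo_ivw_points(h$gamma, h$Gamma, w)
  r_obs <- h$Gamma - b_loo * h$gamma
  wr2_obs <- w * r_obs^2
  rss_obs <- sum(wr2_obs)

  res <- with_seed(seed, {
    Gs <- matrix(rnorm(J * n_sim, mean = b_loo * h$gamma, sd = h$se_Gamma), J, n_sim)
    gs <- matrix(rnorm(J * n_sim, mean = h$gamma, sd = h$se_gamma), J, n_sim)
    sxy <- colSums(w * gs * Gs)
    sxx <- colSums(w * gs^2)
    b_loo_sim <- (rep(sxy, each = J) - w * gs * Gs) / (rep(sxx, each = J) - w * gs^2)
    wr2_sim <- w * (Gs - b_loo_sim * gs)^2  # J x n_sim
    list(rss_sim = colSums(wr2_sim), wr2_sim = wr2_sim)
  })
  global_p <- (1 + sum(res$rss_sim >= rss_obs)) / (n_sim + 1)
  raw_p <- (1 + rowSums(res$wr2_sim >= wr2_obs)) / (n_sim + 1)
  corrected_p <- pmin(1, raw_p * J)
  flag <- corrected_p < outlier_alpha
  outliers <- data.frame(snp = h$snp_ids, raw_p = raw_p,
                         corrected_p = corrected_p, flag = flag,
                         stringsAsFactors = FALSE)

  distortion_p <- NA_real_
  corrected <- h
  if (all(flag)) {
    warning("mr_presso: every instrument flagged as an outlier; returning the input set uncorrected",
            call. = FALSE)
  } else if (any(flag)) {
    corrected <- subset_harmonized(h, !flag)
    b_all <- ivw_point(h)
    b_corr <- ivw_point(corrected)
    d_obs <- b_corr - b_all
    k <- sum(flag)
    d_null <- with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(i) {
        drop <- sample.int(J, k)
        ivw_point(subset_harmonized(h, -drop)) - b_all
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
  }
  structure(list(rss_obs = rss_obs, global_p = global_p, outliers = outliers,
                 distortion_p = distortion_p, corrected = corrected,
                 n_sim = n_sim, outlier_alpha = outlier_alpha),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<mr_presso> RSS = %.3f, global p = %.4g, %d outlier(s)",
              x$rss_obs, x$global_p, sum(x$outliers$flag)))
  if (!is.na(x$distortion_p)) cat(sprintf(", distortion p = %.3g", x$distortion_p))
  cat("\n")
  invisible(x)
}

#' Leave-one-out influence analysis
#'
#' Random-effects IVW recomputed J times, each time excluding one SNP, plus
#' the all-SNP estimate. The result is judged stable when every
#' leave-one-out confidence interval still covers the full estimate (the
#' "error line does not change much" criterion read off leave-one-out
#' forest plots).
#'
#' @param h a `harmonized_set` with J >= 3.
#' @return list of class `loo_result`: `table` (J+1 rows: excluded snp,
#'   beta, se, ci_low, ci_high) and `stable` flag.
#' @export
leave_one_out <- function(h) {
  J <- length(h$gamma)
  if (J < 3) stop("leave_one_out requires J >= 3", call. = FALSE)
  rows <- lapply(seq_len(J), function(j) {
    r <- mr_ivw(subset_harmonized(h, -j), "random")
    data.frame(excluded = h$snp_ids[j], beta = r$beta, se = r$se,
               ci_low = r$ci_low, ci_high = r$ci_high, stringsAsFactors = FALSE)
  })
  full <- mr_ivw(h, "random")
  tab <- rbind(do.call(rbind, rows),
               data.frame(excluded = "(none)", beta = full$beta, se = full$se,
                          ci_low = full$ci_low, ci_high = full$ci_high,
                          stringsAsFactors = FALSE))
  loo <- tab[tab$excluded != "(none)", ]
  stable <- all(loo$ci_low <= full$beta & full$beta <= loo$ci_high)
  structure(list(table = tab, stable = stable, full = full), class = "loo_result")
}

#' Plot-ready tables for scatter, forest and funnel displays
#'
#' Emits the numbers the standard MR figures are drawn from: a scatter
#' table (exposure vs outcome betas with error bars and one fitted line per
#' method), a forest table (per-SNP Wald ratios plus the combined IVW row),
#' and a funnel table (per-SNP ratio vs precision with the IVW center
#' line). Rendering is left to the caller.
#'
#' @param h a `harmonized_set`.
#' @param results named list of `mr_result`s (e.g. from [mr_all()]).
#' @return list with data.frames `scatter`, `lines`, `forest`, `funnel`.
#' @export
plot_data <- function(h, results) {
  assert_that(length(results) > 0, "plot_data: empty result collection")
  wr <- wald_ratios(h)
  scatter <- data.frame(snp = h$snp_ids, gamma = h$gamma, se_gamma = h$se_gamma,
                        Gamma = h$Gamma, se_Gamma = h$se_Gamma,
                        stringsAsFactors = FALSE)
  lines <- do.call(rbind, lapply(results, function(r) {
    data.frame(method = r$method, slope = r$beta,
               intercept = r$extras$intercept %||% 0, stringsAsFactors = FALSE)
  }))
  ivw_idx <- which(vapply(results, function(r) r$method, "")
                   %in% c("ivw_re", "ivw_fe"))
  # center/combined rows use IVW when present, else the first result
  ivw <- results[[if (length(ivw_idx)) ivw_idx[1] else 1L]]
  forest <- rbind(data.frame(snp = wr$snp, beta = wr$beta, se = wr$se,
                             combined = FALSE, stringsAsFactors = FALSE),
                  data.frame(snp = "All (IVW)", beta = ivw$beta, se = ivw$se,
                             combined = TRUE, stringsAsFactors = FALSE))
  funnel <- data.frame(snp = wr$snp, beta = wr$beta, precision = 1 / wr$se,
                       center = ivw$beta, stringsAsFactors = FALSE)
  list(scatter = scatter, lines = lines, forest = forest, funnel = funnel)
}
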