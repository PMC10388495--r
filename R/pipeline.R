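# Config-driven orchestration of the full workflow: forward two-sample MR,
# multivariable MR, mediation, and reverse-direction MR, with a per-stage
# filter ledger (instrument counts and removal reasons) in the run report.

#' Pipeline configuration
#'
#' @param exposure,mediator,outcome `summary_dataset`s or file paths
#'   (mediator optional unless mvmr/mediation modes requested).
#' @param ld an `ld_matrix`, a file path, or `NULL` (distance-only clumping).
#' @param column_map used when datasets are given as paths.
#' @param modes subset of `c("forward","mvmr","mediation","reverse")` or
#'   `"all"`.
#' @param p_threshold,relaxed_p_threshold,min_instruments,clump_r2,clump_window_kb,palindrome_band,freq_source,weak_f_cutoff
#'   instrument-selection knobs (defaults: 5e-8, 5e-6, 3, 0.001, 10000,
#'   0.08, "exposure", 10).
#' @param remove_weak drop instruments with F below `weak_f_cutoff`
#'   (default TRUE; set FALSE to only flag them).
#' @param methods,n_boot,phi estimator settings (see [mr_all()]).
#' @param n_sim,outlier_alpha,run_presso MR-PRESSO settings.
#' @param alpha two-sided significance level for report language.
#' @param seed master seed for every stochastic step (mandatory).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(exposure, outcome, mediator = NULL, ld = NULL,
                            column_map = default_column_map(),
                            modes = "all",
                            p_threshold = 5e-8, relaxed_p_threshold = 5e-6,
                            min_instruments = 3, clump_r2 = 0.001,
                            clump_window_kb = 10000, palindrome_band = 0.08,
                            freq_source = "exposure", weak_f_cutoff = 10,
                            remove_weak = TRUE,
                            methods = c("ivw_re", "egger", "weighted_median",
                                        "simple_mode", "weighted_mode"),
                            n_boot = 5000, phi = 1,
                            n_sim = 1000, outlier_alpha = 0.05,
                            run_presso = TRUE, alpha = 0.05, seed) {
  assert_that(!missing(seed), "pipeline_config requires a seed")
  if (identical(modes, "all")) modes <- c("forward", "mvmr", "mediation", "reverse")
  bad_modes <- setdiff(modes, c("forward", "mvmr", "mediation", "reverse"))
  assert_that(length(bad_modes) == 0,
              paste0("unknown mode(s): ", paste(bad_modes, collapse = ", ")))
  if (any(c("mvmr", "mediation") %in% modes))
    assert_that(!is.null(mediator), "mvmr/mediation modes require a mediator dataset")
  cfg <- as.list(environment())
  cfg$bad_modes <- NULL
  structure(cfg, class = "pipeline_config")
}

load_dataset <- function(x, column_map, trait_type = "quantitative") {
  if (inherits(x, "summary_dataset")) return(x)
  read_summary(x, column_map = column_map, trait_type = trait_type)
}

# One univariable exposure -> outcome analysis with the full filter chain.
analyse_pair <- function(exposure, outcome, cfg, label, log_fun) {
  sel <- select_by_pvalue(exposure, cfg$p_threshold, cfg$relaxed_p_threshold,
                          cfg$min_instruments)
  if (attr(sel, "relaxed"))
    log_fun(sprintf("[%s] relaxed threshold %g used (strict %g yielded < %d instruments)",
                    label, cfg$relaxed_p_threshold, cfg$p_threshold, cfg$min_instruments))
  clumped <- ld_clump(sel, ld = cfg$ld, r2_max = cfg$clump_r2,
                      window_kb = cfg$clump_window_kb)
  h <- harmonize(clumped, outcome, palindrome_band = cfg$palindrome_band,
                 freq_source = cfg$freq_source)
  n_harm <- length(h$snp_ids)
  removed <- h$provenance[startsWith(h$provenance$action, "removed"), ]
  if (nrow(removed))
    log_fun(sprintf("[%s] harmonization removed %d SNP(s): %s", label, nrow(removed),
                    paste(unique(removed$action), collapse = ", ")))
  presso <- NULL
  if (isTRUE(cfg$run_presso) && length(h$snp_ids) >= 4) {
    presso <- mr_presso(h, n_sim = cfg$n_sim, seed = cfg$seed,
                        outlier_alpha = cfg$outlier_alpha)
    n_removed <- length(h$snp_ids) - length(presso$corrected$snp_ids)
    if (n_removed > 0)
      log_fun(sprintf("[%s] MR-PRESSO removed %d outlier SNP(s)", label, n_removed))
    else if (any(presso$outliers$flag))
      log_fun(sprintf("[%s] MR-PRESSO flagged every instrument; none removed", label))
    h <- presso$corrected
  } else if (isTRUE(cfg$run_presso)) {
    log_fun(sprintf("[%s] MR-PRESSO skipped (J = %d < 4)", label, length(h$snp_ids)))
  }
  n_presso <- length(h$snp_ids)
  fstats <- f_statistics(h, cfg$weak_f_cutoff)
  if (isTRUE(cfg$remove_weak) && all(fstats$weak_flags)) {
    log_fun(sprintf("[%s] all instruments weak (F < %g); none removed", label,
                    cfg$weak_f_cutoff))
  } else if (isTRUE(cfg$remove_weak) && any(fstats$weak_flags)) {
    log_fun(sprintf("[%s] removed %d weak instrument(s) (F < %g)", label,
                    sum(fstats$weak_flags), cfg$weak_f_cutoff))
    h <- subset_harmonized(h, !fstats$weak_flags)
    fstats <- f_statistics(h, cfg$weak_f_cutoff)
  }
  J <- length(h$snp_ids)
  counts <- data.frame(analysis = label,
                       selected = n_snps(sel), clumped = n_snps(clumped),
                       harmonized = n_harm, after_presso = n_presso,
                       after_weak = J, stringsAsFactors = FALSE)
  results <- if (J >= 2) mr_all(h, n_boot = cfg$n_boot, phi = cfg$phi,
                                seed = cfg$seed, methods = cfg$methods)
             else list()
  if (J == 1) {
    wr <- wald_ratios(h)
    results$wald_ratio <- new_mr_result("wald_ratio", wr$beta, wr$se,
                                        two_sided_p_norm(wr$beta / wr$se), 1L)
    log_fun(sprintf("[%s] single instrument: Wald ratio reported, IVW refused", label))
  }
  sens <- list()
  if (J >= 2) sens$q_ivw <- cochran_q(h, "ivw")
  if (J >= 3) {
    sens$q_egger <- cochran_q(h, "egger")
    sens$egger_intercept <- egger_intercept_test(h)
    sens$loo <- leave_one_out(h)
  }
  if (!is.null(presso)) sens$presso <- presso
  if (!is.null(sens$q_ivw)) {
    het <- sens$q_ivw$pvalue < cfg$alpha
    log_fun(sprintf("[%s] heterogeneity Q p = %.3g -> %s IVW is primary", label,
                    sens$q_ivw$pvalue,
                    if (het) "random-effects" else "fixed-effects-equivalent random-effects"))
  }
  plots <- if (length(results)) plot_data(h, results) else NULL
  list(label = label, counts = counts, harmonized = h, f_stats = fstats,
       results = results, sensitivity = sens, plots = plots,
       threshold_used = attr(sel, "threshold_used"),
       relaxed = attr(sel, "relaxed"))
}

#' Run the full analysis pipeline
#'
#' Executes, per requested mode: instrument selection -> LD clumping ->
#' harmonization -> MR-PRESSO outlier removal -> weak-instrument filter ->
#' the requested estimators -> the sensitivity suite; then multivariable MR
#' over exposure + mediator, mediation combining the univariable total
#' effect with the MVMR-adjusted mediator effect, and the reverse-direction
#' analysis (outcome as exposure, threshold relaxation active). Every stage
#' is logged with counts and removal reasons; a reverse-stage failure is
#' recorded without invalidating forward results.
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_report` with elements `forward`,
#'   `exposure_mediator`, `mvmr`, `mediation`, `reverse`, `counts`, `log`,
#'   `fingerprint`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  log_fun <- function(msg) log_lines <<- c(log_lines, msg)
  exposure <- load_dataset(config$exposure, config$column_map)
  outcome <- load_dataset(config$outcome, config$column_map, "binary")
  mediator <- if (!is.null(config$mediator))
    load_dataset(config$mediator, config$column_map, "binary") else NULL
  if (is.character(config$ld)) config$ld <- read_ld_matrix(config$ld)

  report <- list(forward = NULL, exposure_mediator = NULL, mvmr = NULL,
                 mediation = NULL, reverse = NULL)
  counts <- NULL

  if (any(c("forward", "mediation") %in% config$modes)) {
    report$forward <- analyse_pair(exposure, outcome, config,
                                   paste(exposure$trait_name, "->", outcome$trait_name),
                                   log_fun)
    counts <- rbind(counts, report$forward$counts)
  }
  if ("mediation" %in% config$modes) {
    report$exposure_mediator <- analyse_pair(exposure, mediator, config,
                                             paste(exposure$trait_name, "->", mediator$trait_name),
                                             log_fun)
    counts <- rbind(counts, report$exposure_mediator$counts)
  }
  if (any(c("mvmr", "mediation") %in% config$modes)) {
    mv_in <- build_mvmr_input(list(exposure, mediator), outcome, ld = config$ld,
                              p_threshold = config$p_threshold,
                              relaxed_p_threshold = config$relaxed_p_threshold,
                              min_instruments = config$min_instruments,
                              clump_r2 = config$clump_r2,
                              clump_window_kb = config$clump_window_kb,
                              palindrome_band = config$palindrome_band)
    for (line in attr(mv_in, "log")) log_fun(paste0("[mvmr] ", line))
    log_fun(sprintf("[mvmr] %d instruments assembled for %d exposures",
                    length(mv_in$snp_ids), ncol(mv_in$exposure_betas)))
    report$mvmr <- list(input = mv_in, mv_ivw = mv_ivw(mv_in),
                        mv_egger = mv_egger(mv_in))
  }
  if ("mediation" %in% config$modes) {
    total_res <- report$forward$results$ivw_re
    xz_res <- report$exposure_mediator$results$ivw_re
    assert_that(!is.null(total_res) && !is.null(xz_res),
                "mediation requires IVW results from the forward and exposure->mediator stages")
    mvt <- report$mvmr$mv_ivw$table
    zrow <- mvt[mvt$exposure == mediator$trait_name, ]
    assert_that(nrow(zrow) == 1, "mediator effect not found in MVMR output")
    report$mediation <- mediate(total_res$beta, xz_res$beta, zrow$beta,
                                ses = c(total_res$se, xz_res$se, zrow$se))
    log_fun(sprintf("[mediation] proportion mediated = %.2f%%",
                    report$mediation$proportion))
  }
  if ("reverse" %in% config$modes) {
    report$reverse <- tryCatch({
      rev <- analyse_pair(outcome, exposure, config,
                          paste(outcome$trait_name, "->", exposure$trait_name),
                          log_fun)
      counts <- rbind(counts, rev$counts)
      rev
    }, error = function(e) {
      log_fun(sprintf("[reverse] failed: %s (forward results unaffected)",
                      conditionMessage(e)))
      structure(list(error = conditionMessage(e)), class = "failed_stage")
    })
  }
  structure(list(forward = report$forward,
                 exposure_mediator = report$exposure_mediator,
                 mvmr = report$mvmr, mediation = report$mediation,
                 reverse = report$reverse, counts = counts, log = log_lines,
                 alpha = config$alpha,
                 fingerprint = list(package = "mrmediate",
                                    version = as.character(utils::packageVersion("mrmediate")),
                                    seed = config$seed, modes = config$modes)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  if (!is.null(x$counts)) { cat("instrument filter chain:\n"); print(x$counts) }
  for (blk in c("forward", "exposure_mediator")) {
    if (is.null(x[[blk]])) next
    cat(sprintf("\n%s [%s]:\n", blk, x[[blk]]$label))
    for (r in x[[blk]]$results) print(r)
  }
  if (!is.null(x$mvmr)) { cat("\nmvmr:\n"); print(x$mvmr$mv_ivw); print(x$mvmr$mv_egger) }
  if (!is.null(x$mediation)) { cat("\n"); print(x$mediation) }
  if (inherits(x$reverse, "failed_stage"))
    cat(sprintf("\nreverse: FAILED (%s)\n", x$reverse$error))
  else if (!is.null(x$reverse)) {
    cat(sprintf("\nreverse [%s]:\n", x$reverse$label))
    for (r in x$reverse$results) print(r)
  }
  invisible(x)
}

#' Method-concordance table for a pipeline run
#'
#' Per estimator: estimate, CI, p, whether its sign agrees with IVW, and
#' whether it is significant at `alpha`. Divergence between methods (e.g.
#' Egger vs IVW under directional pleiotropy) is recorded, not suppressed.
#'
#' @param report a `run_report`, or a named list of `mr_result`s (>= 2).
#' @param alpha significance level (default: the report's, else 0.05).
#' @return data.frame, one row per method.
#' @export
compare_methods <- function(report, alpha = NULL) {
  results <- if (inherits(report, "run_report")) {
    alpha <- alpha %||% report$alpha
    report$forward$results
  } else report
  alpha <- alpha %||% 0.05
  if (length(results) < 2) stop("nothing to compare: fewer than 2 methods run", call. = FALSE)
  tab <- do.call(rbind, lapply(results, as.data.frame))
  ivw_idx <- which(tab$method %in% c("ivw_re", "ivw_fe"))[1]
  assert_that(!is.na(ivw_idx), "compare_methods needs an IVW result as reference")
  tab$sign_agrees_ivw <- sign(tab$beta) == sign(tab$beta[ivw_idx])
  tab$significant <- tab$pvalue < alpha
  rownames(tab) <- NULL
  tab
}
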