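# Instrument selection: p-value thresholding with relaxation, greedy LD
# clumping, allele harmonization, and F-statistic strength assessment.

#' Construct a harmonized exposure/outcome instrument set
#'
#' The container every estimator consumes: J instruments with exposure betas
#' `gamma` (standard errors `se_gamma`) and outcome betas `Gamma`
#' (`se_Gamma`) aligned to a common effect allele per SNP.
#'
#' @param snp_ids,gamma,se_gamma,Gamma,se_Gamma equal-length vectors; all SEs
#'   strictly positive.
#' @param eaf aligned effect-allele frequency (NA permitted).
#' @param provenance data.frame audit trail of harmonization actions.
#' @return object of class `harmonized_set`.
#' @export
harmonized_set <- function(snp_ids, gamma, se_gamma, Gamma, se_Gamma,
                           eaf = rep(NA_real_, length(snp_ids)),
                           provenance = NULL) {
  J <- length(snp_ids)
  assert_that(J >= 1, "harmonized set must contain at least one SNP")
  assert_that(all(lengths(list(gamma, se_gamma, Gamma, se_Gamma, eaf)) == J),
              "harmonized set arrays must have equal length")
  assert_that(all(se_gamma > 0) && all(se_Gamma > 0),
              "all standard errors must be > 0")
  structure(list(snp_ids = as.character(snp_ids),
                 gamma = as.numeric(gamma), se_gamma = as.numeric(se_gamma),
                 Gamma = as.numeric(Gamma), se_Gamma = as.numeric(se_Gamma),
                 eaf = as.numeric(eaf), provenance = provenance),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> J = %d instruments\n", length(x$snp_ids)))
  invisible(x)
}

#' Subset a harmonized set by index
#' @param h a `harmonized_set`.
#' @param idx integer or logical index of instruments to keep.
#' @return a `harmonized_set`.
#' @export
subset_harmonized <- function(h, idx) {
  harmonized_set(h$snp_ids[idx], h$gamma[idx], h$se_gamma[idx],
                 h$Gamma[idx], h$se_Gamma[idx], h$eaf[idx],
                 provenance = h$provenance)
}

#' Select instruments by p-value with threshold relaxation
#'
#' Keeps rows with `p < threshold`. If fewer than `min_instruments` survive,
#' re-selects at `relaxed_threshold` (the fallback used when a trait, e.g. a
#' small-case-count disease GWAS, lacks genome-wide-significant hits); the
#' threshold actually used and whether relaxation happened are recorded as
#' attributes `threshold_used` and `relaxed`.
#'
#' @param dataset a `summary_dataset`.
#' @param threshold strict significance level (default genome-wide 5e-8).
#' @param relaxed_threshold fallback level (default 5e-6).
#' @param min_instruments minimum count below which relaxation triggers.
#' @return filtered `summary_dataset` with selection attributes.
#' @export
select_by_pvalue <- function(dataset, threshold = 5e-8,
                             relaxed_threshold = 5e-6, min_instruments = 3) {
  assert_that(threshold > 0 && threshold <= relaxed_threshold && relaxed_threshold < 1,
              "need 0 < threshold <= relaxed_threshold < 1")
  strict <- dataset$data$p < threshold
  relaxed <- FALSE
  keep <- strict
  if (sum(strict) < min_instruments) {
    keep <- dataset$data$p < relaxed_threshold
    relaxed <- TRUE
  }
  if (sum(keep) == 0)
    stop(sprintf("no instruments for '%s' even at relaxed threshold %g",
                 dataset$trait_name, relaxed_threshold), call. = FALSE)
  out <- summary_dataset(dataset$data[keep, , drop = FALSE],
                         dataset$trait_name, dataset$trait_type)
  attr(out, "threshold_used") <- if (relaxed) relaxed_threshold else threshold
  attr(out, "relaxed") <- relaxed
  out
}

#' Greedy LD clumping of a summary dataset
#'
#' Sorts SNPs by ascending p-value (ties by p then id for determinism),
#' accepts the best remaining SNP, and discards any other SNP that is BOTH in
#' LD with an accepted SNP (`r2 >= r2_max`) AND within `window_kb` of it on
#' the same chromosome; both conditions must hold, mirroring the joint
#' `r2 < 0.001` / `kb > 10,000` convention. Without an LD matrix the fallback
#' is distance-only clumping, with a warning.
#'
#' @param dataset a `summary_dataset`.
#' @param ld an [ld_matrix()] covering every SNP in `dataset`, or `NULL`.
#' @param r2_max LD threshold (default 0.001).
#' @param window_kb physical window in kilobases (default 10000).
#' @return clumped `summary_dataset` (subset of the input, input order kept).
#' @export
ld_clump <- function(dataset, ld = NULL, r2_max = 0.001, window_kb = 10000) {
  df <- dataset$data
  if (!is.null(ld)) {
    missing_ld <- setdiff(df$snp, ld$snp_ids)
    assert_that(length(missing_ld) == 0,
                paste0("SNP(s) missing from LD matrix: ",
                       paste(head(missing_ld, 5), collapse = ", ")))
  } else if (nrow(df) > 1) {
    warning("ld_clump: no LD matrix supplied, falling back to distance-only clumping",
            call. = FALSE)
  }
  ord <- order(df$p, df$snp)
  accepted <- integer(0)
  for (i in ord) {
    if (length(accepted)) {
      same_chr <- df$chr[accepted] == df$chr[i]
      near <- same_chr & abs(df$pos[accepted] - df$pos[i]) <= window_kb * 1000
      linked <- if (!is.null(ld)) {
        ld$r2[df$snp[accepted], df$snp[i]] >= r2_max
      } else rep(TRUE, length(accepted))
      if (any(near & linked)) next
    }
    accepted <- c(accepted, i)
  }
  keep <- sort(accepted)  # preserve input order
  summary_dataset(df[keep, , drop = FALSE], dataset$trait_name, dataset$trait_type)
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) COMPLEMENT[ea] == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect allele per shared SNP:
#' exact allele matches are kept; swapped effect/other alleles flip the sign
#' of the outcome beta (and reflect its frequency); strand-complement matches
#' are complemented first. Palindromic SNPs (A/T or C/G) cannot be resolved
#' from alleles alone: those whose governing allele frequency lies within
#' `palindrome_band` of 0.5 (or is missing) are removed; the remainder are
#' aligned by frequency concordance (exposure and outcome frequencies on
#' opposite sides of 0.5 imply a strand flip, i.e. a sign flip).
#' Irreconcilable allele pairs are removed. Every action is logged in the
#' returned set's `provenance`.
#'
#' @param exposure,outcome `summary_dataset`s sharing SNP ids.
#' @param palindrome_band half-width of the intermediate-frequency exclusion
#'   zone around 0.5 (default 0.08, i.e. eaf in `[0.42, 0.58]` removed).
#' @param freq_source which study's frequency governs palindrome decisions.
#' @return a [harmonized_set()] in exposure order.
#' @export
harmonize <- function(exposure, outcome, palindrome_band = 0.08,
                      freq_source = c("exposure", "outcome")) {
  freq_source <- match.arg(freq_source)
  shared <- intersect(exposure$data$snp, outcome$data$snp)
  assert_that(length(shared) > 0, "no shared SNPs between exposure and outcome")
  ex <- exposure$data[match(shared, exposure$data$snp), ]
  ou <- outcome$data[match(shared, outcome$data$snp), ]
  # keep exposure file order
  ord <- order(match(shared, exposure$data$snp))
  ex <- ex[ord, ]; ou <- ou[ord, ]

  J <- nrow(ex)
  action <- character(J)
  Gamma <- ou$beta
  out_eaf <- ou$eaf
  for (j in seq_len(J)) {
    ea_x <- ex$ea[j]; oa_x <- ex$oa[j]
    ea_y <- ou$ea[j]; oa_y <- ou$oa[j]
    pal <- is_palindromic(ea_x, oa_x)
    if (pal) {
      gov <- if (freq_source == "exposure") ex$eaf[j] else ou$eaf[j]
      if (is.na(gov)) { action[j] <- "removed_palindrome_no_eaf"; next }
      if (abs(gov - 0.5) <= palindrome_band) {
        action[j] <- "removed_palindrome_intermediate"; next
      }
      # alleles alone cannot distinguish swap from strand flip; use frequency
      same_orientation <- (ea_y == ea_x && oa_y == oa_x)
      swapped <- (ea_y == oa_x && oa_y == ea_x)
      if (!same_orientation && !swapped) { action[j] <- "removed_mismatch"; next }
      eaf_y <- if (same_orientation) ou$eaf[j] else 1 - ou$eaf[j]
      if (!is.na(eaf_y) && ((ex$eaf[j] < 0.5) != (eaf_y < 0.5))) {
        # opposite frequency sides -> reported on the other strand: flip
        Gamma[j] <- -Gamma[j]
        out_eaf[j] <- 1 - eaf_y
        action[j] <- "palindrome_freq_flipped"
      } else {
        if (swapped) Gamma[j] <- -Gamma[j]
        out_eaf[j] <- eaf_y
        action[j] <- "kept_palindrome"
      }
      next
    }
    if (ea_y == ea_x && oa_y == oa_x) {
      action[j] <- "kept"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      Gamma[j] <- -Gamma[j]
      out_eaf[j] <- 1 - ou$eaf[j]
      action[j] <- "flipped"
    } else if (COMPLEMENT[ea_y] == ea_x && COMPLEMENT[oa_y] == oa_x) {
      action[j] <- "strand_corrected"
    } else if (COMPLEMENT[ea_y] == oa_x && COMPLEMENT[oa_y] == ea_x) {
      Gamma[j] <- -Gamma[j]
      out_eaf[j] <- 1 - ou$eaf[j]
      action[j] <- "strand_corrected_flipped"
    } else {
      action[j] <- "removed_mismatch"
    }
  }
  provenance <- data.frame(snp = ex$snp, action = action, stringsAsFactors = FALSE)
  keep <- !startsWith(action, "removed")
  assert_that(any(keep), "no SNPs survived harmonization")
  eaf_aligned <- ex$eaf[keep]  # exposure-frame frequency of the common effect allele
  harmonized_set(ex$snp[keep], ex$beta[keep], ex$se[keep],
                 Gamma[keep], ou$se[keep], eaf_aligned, provenance = provenance)
}

#' Per-instrument F statistics
#'
#' Instrument strength as `F = (gamma/se_gamma)^2`; `F < cutoff`
#' (conventionally 10) marks a weak instrument. This operation only flags —
#' whether weak instruments are removed is pipeline policy.
#'
#' @param h a `harmonized_set`.
#' @param weak_f_cutoff weak-instrument threshold (default 10).
#' @return object of class `instrument_stats`: `f_stat`, `mean_f`, `weak_flags`.
#' @export
f_statistics <- function(h, weak_f_cutoff = 10) {
  f <- (h$gamma / h$se_gamma)^2
  structure(list(f_stat = f, mean_f = mean(f), weak_flags = f < weak_f_cutoff,
                 cutoff = weak_f_cutoff),
            class = "instrument_stats")
}

#' @export
print.instrument_stats <- function(x, ...) {
  cat(sprintf("<instrument_stats> mean F = %.1f; %d/%d weak (F < %g)\n",
              x$mean_f, sum(x$weak_flags), length(x$f_stat), x$cutoff))
  invisible(x)
}
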