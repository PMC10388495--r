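# Reading, validating and writing GWAS summary statistics and LD matrices.
# All formats are plain delimited text; column naming is mapped explicitly
# because silent mis-mapping is the dominant failure mode with summary data.

CANONICAL_COLS <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "p", "n")

#' Default column mapping for summary-statistics tables
#'
#' Maps the canonical internal names to the column names expected in the
#' input file. Override any entry to adapt to another dialect, e.g.
#' `default_column_map(snp = "rsid", p = "pval")`.
#'
#' @param ... named overrides, one per canonical column
#'   (`snp, chr, pos, ea, oa, eaf, beta, se, p, n`).
#' @return named character vector mapping canonical -> file column names.
#' @export
#' @examples
#' default_column_map(p = "pval", n = "samplesize")
default_column_map <- function(...) {
  map <- setNames(CANONICAL_COLS, CANONICAL_COLS)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), CANONICAL_COLS)
    assert_that(length(bad) == 0,
                paste0("unknown column-map keys: ", paste(bad, collapse = ", ")))
    map[names(over)] <- unlist(over)
  }
  map
}

#' Construct a summary dataset
#'
#' A `summary_dataset` is a named collection of per-SNP GWAS associations for
#' one trait: one row per SNP with identifier, chromosome, position, effect
#' and other allele, effect-allele frequency, beta, standard error, p-value
#' and sample size. For binary traits `beta` is on the log-odds scale.
#'
#' @param data data.frame with canonical columns
#'   `snp, chr, pos, ea, oa, eaf, beta, se, p, n` (`eaf` and `n` may be `NA`).
#' @param trait_name label for the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param validate check invariants (se > 0, eaf in (0,1), allele codes,
#'   unique SNP ids).
#' @return object of class `summary_dataset`.
#' @export
summary_dataset <- function(data, trait_name, trait_type = c("quantitative", "binary"),
                            validate = TRUE) {
  trait_type <- match.arg(trait_type)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CANONICAL_COLS, names(data))
  assert_that(length(missing_cols) == 0,
              paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")))
  data <- data[CANONICAL_COLS]
  data$snp <- as.character(data$snp)
  data$chr <- as.character(data$chr)
  data$ea <- toupper(as.character(data$ea))
  data$oa <- toupper(as.character(data$oa))
  for (col in c("pos", "eaf", "beta", "se", "p", "n"))
    data[[col]] <- as.numeric(data[[col]])
  if (validate) {
    assert_that(nrow(data) > 0, "summary dataset is empty")
    assert_that(!anyDuplicated(data$snp), "duplicate snp ids in summary dataset")
    assert_that(all(data$se > 0), "all standard errors must be > 0")
    ok_eaf <- is.na(data$eaf) | (data$eaf > 0 & data$eaf < 1)
    assert_that(all(ok_eaf), "eaf must lie in (0,1) when present")
    assert_that(all(data$ea %in% c("A", "C", "G", "T")) &&
                all(data$oa %in% c("A", "C", "G", "T")),
                "alleles must be one of A/C/G/T")
    assert_that(all(data$ea != data$oa), "effect and other allele must differ")
    assert_that(all(data$p > 0 & data$p <= 1), "p-values must lie in (0,1]")
  }
  structure(list(trait_name = trait_name, trait_type = trait_type, data = data),
            class = "summary_dataset")
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> %s (%s): %d SNPs\n",
              x$trait_name, x$trait_type, nrow(x$data)))
  print(head(x$data, 5))
  invisible(x)
}

#' Number of SNPs in a summary dataset
#' @param x a `summary_dataset`.
#' @return integer SNP count.
#' @export
n_snps <- function(x) nrow(x$data)

#' Read GWAS summary statistics from a delimited file
#'
#' Tab- or comma-delimited text with a header row. Columns are located via
#' `column_map`; alleles are upper-cased; rows with unparseable or invalid
#' `beta`/`se`/`p`/alleles are dropped with a message reporting the count.
#' A consistency check compares the stated p-value with `2*pnorm(-|beta/se|)`
#' and warns (never fails — published summaries are rounded) when the worst
#' discrepancy exceeds `p_tolerance`.
#'
#' @param path file path.
#' @param column_map from [default_column_map()]; `eaf` and `n` columns are
#'   optional in the file, all others mandatory.
#' @param trait_name label (defaults to the file name).
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param p_tolerance absolute tolerance for the p/Z consistency warning.
#' @return a [summary_dataset()].
#' @export
read_summary <- function(path, column_map = default_column_map(),
                         trait_name = basename(path),
                         trait_type = c("quantitative", "binary"),
                         p_tolerance = 0.01) {
  trait_type <- match.arg(trait_type)
  assert_that(file.exists(path), paste0("file not found: ", path))
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           colClasses = list(character = unname(column_map[c("snp", "chr", "ea", "oa")])))
  assert_that(nrow(raw) > 0, paste0("empty summary-statistics file: ", path))
  optional <- c("eaf", "n")
  for (key in CANONICAL_COLS) {
    file_col <- column_map[[key]]
    if (!file_col %in% names(raw)) {
      if (key %in% optional) { raw[[file_col]] <- NA_real_ }
      else stop(sprintf("missing mandatory column '%s' (mapped from '%s') in %s",
                        file_col, key, path), call. = FALSE)
    }
  }
  df <- setNames(raw[unname(column_map)], names(column_map))
  df$beta <- suppressWarnings(as.numeric(df$beta))
  df$se <- suppressWarnings(as.numeric(df$se))
  df$p <- suppressWarnings(as.numeric(df$p))
  df$ea <- toupper(as.character(df$ea))
  df$oa <- toupper(as.character(df$oa))
  bad <- !is.finite(df$beta) | !is.finite(df$se) | df$se <= 0 |
    !is.finite(df$p) | df$p <= 0 | df$p > 1 |
    !(df$ea %in% c("A", "C", "G", "T")) | !(df$oa %in% c("A", "C", "G", "T")) |
    df$ea == df$oa
  if (any(bad)) {
    message(sprintf("read_summary: dropped %d invalid row(s) from %s", sum(bad), path))
    df <- df[!bad, , drop = FALSE]
  }
  assert_that(nrow(df) > 0, paste0("no valid rows after validation: ", path))
  implied <- two_sided_p_norm(df$beta / df$se)
  disc <- abs(df$p - implied)
  if (any(disc > p_tolerance, na.rm = TRUE))
    warning(sprintf("%d p-value(s) inconsistent with beta/se beyond %g (max discrepancy %.3g)",
                    sum(disc > p_tolerance, na.rm = TRUE), p_tolerance, max(disc, na.rm = TRUE)),
            call. = FALSE)
  summary_dataset(df, trait_name = trait_name, trait_type = trait_type)
}

#' Write a summary dataset to a delimited file
#' @param dataset a `summary_dataset`.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_summary <- function(dataset, path) {
  data.table::fwrite(dataset$data, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Construct an LD matrix object
#'
#' @param r2 square symmetric matrix of squared correlations in `[0,1]` with
#'   unit diagonal; dimnames give the SNP ids.
#' @param snp_ids SNP ids (defaults to `rownames(r2)`).
#' @param positions optional named base-pair positions for window checks.
#' @return object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, snp_ids = rownames(r2), positions = NULL) {
  r2 <- as.matrix(r2)
  assert_that(nrow(r2) == ncol(r2), "LD matrix must be square")
  assert_that(!is.null(snp_ids) && length(snp_ids) == nrow(r2),
              "LD matrix needs one SNP id per row")
  asym <- max(abs(r2 - t(r2)))
  assert_that(asym <= 1e-6,
              sprintf("LD matrix asymmetric beyond tolerance (max |r2 - t(r2)| = %.3g)", asym))
  r2 <- (r2 + t(r2)) / 2
  assert_that(all(r2 >= 0 & r2 <= 1), "LD r2 entries must lie in [0,1]")
  assert_that(all(abs(diag(r2) - 1) <= 1e-12), "LD matrix diagonal must be 1")
  diag(r2) <- 1
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r2 = r2, positions = positions),
            class = "ld_matrix")
}

#' Read a labeled square LD (r-squared) matrix
#'
#' First column = SNP ids, remaining columns numeric; header carries the same
#' ids. Asymmetries up to 1e-6 are symmetrized by averaging, anything larger
#' is an error, as are entries outside `[0,1]`.
#'
#' @param path file path.
#' @return an [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE)
  assert_that(nrow(raw) > 0, paste0("empty LD matrix file: ", path))
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  assert_that(nrow(m) == ncol(m), "LD matrix file is not square")
  ld_matrix(m, snp_ids = ids)
}

#' Write an LD matrix
#' @param ld an `ld_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- data.frame(snp = ld$snp_ids, ld$r2, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Format an odds ratio with its 95\% confidence interval
#' @param or,lo,hi odds ratio and CI bounds.
#' @param digits decimal places.
#' @return character, e.g. `"0.703 (0.508, 0.973)"`.
#' @export
format_or <- function(or, lo, hi, digits = 3) {
  sprintf("%.*f (%.*f, %.*f)", digits, or, digits, lo, digits, hi)
}

#' Write MR results as a delimited table plus a structured JSON dump
#'
#' The tabular file renders the odds ratio column as `OR (low, high)` the way
#' result figures print it; the JSON dump preserves full precision for
#' round-tripping.
#'
#' @param results a data.frame of results (e.g. from [mr_all()] or
#'   [as.data.frame.mr_result()]), or a list of `mr_result`s.
#' @param path output path for the table; the JSON dump goes to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "mr_result")) results <- list(results)
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, inherits, TRUE, "mr_result")))
    results <- do.call(rbind, lapply(results, as.data.frame))
  results <- as.data.frame(results)
  assert_that(nrow(results) > 0, "write_results: empty result collection")
  out <- results
  if (all(c("or", "or_low", "or_high") %in% names(out)))
    out$or_95ci <- format_or(out$or, out$or_low, out$or_high)
  ok <- tryCatch({
    data.table::fwrite(out, path, sep = "\t", quote = FALSE)
    jsonlite::write_json(results, paste0(path, ".json"), digits = NA, dataframe = "rows")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop(sprintf("cannot write results to '%s': %s", path,
                                conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#' @param path path given to `write_results` (reads the JSON dump).
#' @return data.frame of results at full precision.
#' @export
read_results <- function(path) {
  as.data.frame(jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE))
}
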