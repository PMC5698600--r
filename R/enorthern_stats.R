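#' Classifier configuration for tissue-preference calls
#'
#' Holds the thresholds of the twofold rule used to call mammary-preferential
#' expression: a gene is called UP when its mammary TPM exceeds its skin TPM
#' and its relative expression coefficient is at least `up_threshold`; DOWN
#' when mammary TPM is below skin TPM and the coefficient is at most
#' `down_threshold`. Thresholds are compared on unrounded coefficients;
#' `decimals` only controls reporting precision.
#'
#' @param up_threshold Upregulation threshold on the relative expression
#'   coefficient; must exceed 1 (default 2).
#' @param down_threshold Downregulation threshold; must lie in (0, 1)
#'   (default 0.5).
#' @param decimals Decimal places used when reporting derived statistics
#'   (default 3).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(up_threshold = 2, down_threshold = 0.5, decimals = 3) {
  if (!is.numeric(up_threshold) || length(up_threshold) != 1 || up_threshold <= 1) {
    stop_enorthern("up_threshold must be a single number > 1", "enorthern_validation_error")
  }
  if (!is.numeric(down_threshold) || length(down_threshold) != 1 ||
      down_threshold <= 0 || down_threshold >= 1) {
    stop_enorthern("down_threshold must lie in (0, 1)", "enorthern_validation_error")
  }
  if (!is.numeric(decimals) || length(decimals) != 1 || decimals < 0 ||
      decimals != trunc(decimals)) {
    stop_enorthern("decimals must be a non-negative integer", "enorthern_validation_error")
  }
  structure(
    list(up_threshold = up_threshold, down_threshold = down_threshold,
         decimals = as.integer(decimals)),
    class = "classifier_config"
  )
}

#' Percent mammary transcript abundance
#'
#' For each gene, its mammary TPM as a percentage of the summed mammary TPM
#' over the whole panel. The denominator deliberately includes genes with
#' incomplete tissue profiles: abundance is a property of the mammary column
#' alone, and excluded genes still contribute transcripts to it.
#'
#' @param table A [study_table()].
#' @return A named numeric vector (percent, unrounded) in table order.
#' @examples
#' tab <- read_study_table(enorthern_example("table2.tsv"))
#' round_half_up(percent_abundance(tab)[["SCD5"]])
#' @export
percent_abundance <- function(table) {
  total <- sum(table$tpm_ma)
  if (total <= 0) {
    stop_enorthern("all mammary TPMs are zero: percent abundance undefined",
                   "enorthern_validation_error")
  }
  setNames(100 * table$tpm_ma / total, table$gene)
}

#' Mammary-to-skin TPM ratio
#'
#' `tpm_ma / tpm_s`, defined only when both TPMs are positive; `NA`
#' otherwise (rendered as an em-dash in output tables, following the
#' reporting convention of electronic-Northern studies).
#'
#' @param tpm_ma,tpm_s Non-negative numeric vectors (recycled).
#' @return Numeric vector with `NA` where the ratio is undefined.
#' @examples
#' ratio_ma_s(398, 29)
#' @export
ratio_ma_s <- function(tpm_ma, tpm_s) {
  ifelse(tpm_ma > 0 & tpm_s > 0, tpm_ma / tpm_s, NA_real_)
}

#' Relative expression coefficient
#'
#' The ratio of mammary transcript abundance to the geometric mean of
#' skin and muscle abundance:
#' \deqn{E_r = \mathrm{TPM}_{ma} / \sqrt{\mathrm{TPM}_s \cdot \mathrm{TPM}_{mu}}}
#' Defined whenever both reference TPMs are positive; a zero mammary TPM
#' yields a coefficient of 0, while a zero in either reference tissue makes
#' the coefficient undefined (`NA`).
#'
#' @param tpm_ma,tpm_s,tpm_mu Non-negative numeric vectors (recycled).
#' @return Numeric vector with `NA` where the coefficient is undefined.
#' @examples
#' relative_expression(755, 29, 69)
#' @export
relative_expression <- function(tpm_ma, tpm_s, tpm_mu) {
  # double arithmetic: integer TPMs can overflow in the product
  ifelse(tpm_s > 0 & tpm_mu > 0,
         as.numeric(tpm_ma) / sqrt(as.numeric(tpm_s) * as.numeric(tpm_mu)),
         NA_real_)
}

#' Classify tissue-preferential expression
#'
#' Applies the twofold rule: genes missing expression in any of the three
#' tissues (any TPM equal to 0, an incomplete profile) are `EXCLUDED`;
#' otherwise `UP` if `tpm_ma > tpm_s` and the relative expression
#' coefficient is at least the up threshold, `DOWN` if `tpm_ma < tpm_s` and
#' the coefficient is at most the down threshold, else `NOT_DIFFERENTIAL`.
#' The four statuses partition the genes; comparisons use unrounded
#' coefficients.
#'
#' @param tpm_ma,tpm_s,tpm_mu Non-negative numeric vectors (recycled).
#' @param config A [classifier_config()].
#' @return Character vector of statuses.
#' @examples
#' classify(755, 29, 69)   # UP
#' classify(10, 177, 34)   # DOWN
#' classify(593, 29, 0)    # EXCLUDED
#' @export
classify <- function(tpm_ma, tpm_s, tpm_mu, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  e_r <- relative_expression(tpm_ma, tpm_s, tpm_mu)
  complete <- tpm_ma > 0 & tpm_s > 0 & tpm_mu > 0
  status <- rep("NOT_DIFFERENTIAL", length(e_r))
  status[complete & tpm_ma > tpm_s & e_r >= config$up_threshold] <- "UP"
  status[complete & tpm_ma < tpm_s & e_r <= config$down_threshold] <- "DOWN"
  status[!complete] <- "EXCLUDED"
  status
}

#' Adult-stage expression preference
#'
#' Compares stage-specific TPMs: `TRUE` when the adult TPM strictly exceeds
#' `min_fold` times the young TPM, `FALSE` otherwise (a tie is not a
#' preference), `NA` when either stage TPM is missing. The default
#' `min_fold = 1` imposes no fold threshold beyond strict inequality.
#'
#' @param tpm_adult,tpm_young Non-negative numeric vectors, possibly `NA`.
#' @param min_fold Minimum adult/young fold for a preference call (default 1).
#' @return Logical vector with `NA` where a stage TPM is missing.
#' @export
stage_preference <- function(tpm_adult, tpm_young, min_fold = 1) {
  if (!is.numeric(min_fold) || length(min_fold) != 1 || min_fold <= 0) {
    stop_enorthern("min_fold must be a single positive number", "enorthern_validation_error")
  }
  ifelse(is.na(tpm_adult) | is.na(tpm_young), NA,
         tpm_adult > min_fold * tpm_young)
}

#' Run the full electronic-Northern analysis
#'
#' Combines percent abundance, the mammary/skin ratio, the relative
#' expression coefficient, the tissue-preference classification and (when
#' stage TPMs are present) the adult-stage comparison into one result row
#' per gene, preserving input order. Derived numeric columns are rounded to
#' `config$decimals` for reporting; classification decisions are made on
#' unrounded values.
#'
#' @param table A [study_table()].
#' @param config A [classifier_config()].
#' @return A tibble with columns `gene`, `bioprocess`, `tpm_ma`, `tpm_s`,
#'   `tpm_mu`, `pct_abundance`, `ratio_ma_s`, `e_r`, `complete`, `status`
#'   and, if stage TPMs were supplied, `adult_preferential`.
#' @examples
#' tab <- read_study_table(enorthern_example("table2.tsv"))
#' res <- run_enorthern(tab)
#' table(res$status)
#' @export
run_enorthern <- function(table, config = classifier_config()) {
  stopifnot(inherits(table, "study_table"), inherits(config, "classifier_config"))
  d <- config$decimals
  res <- tibble::tibble(
    gene = table$gene,
    bioprocess = table$bioprocess,
    tpm_ma = table$tpm_ma,
    tpm_s = table$tpm_s,
    tpm_mu = table$tpm_mu,
    pct_abundance = round_half_up(unname(percent_abundance(table)), d),
    ratio_ma_s = round_half_up(ratio_ma_s(table$tpm_ma, table$tpm_s), d),
    e_r = round_half_up(relative_expression(table$tpm_ma, table$tpm_s, table$tpm_mu), d),
    complete = table$tpm_ma > 0 & table$tpm_s > 0 & table$tpm_mu > 0,
    status = classify(table$tpm_ma, table$tpm_s, table$tpm_mu, config)
  )
  if (all(c("tpm_adult", "tpm_young") %in% names(table))) {
    res$adult_preferential <- stage_preference(table$tpm_adult, table$tpm_young)
  }
  res
}
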