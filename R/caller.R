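# Calling C-to-U editing sites from pileup columns.

#' Filter configuration for editing-site calling
#'
#' The four site filters applied to every candidate position, and the
#' sequencing error rate used by the binomial error-probability model.
#' All threshold comparisons are inclusive (`>=`).
#'
#' @param min_coverage Minimum total read coverage at the site (default 10).
#' @param min_count Minimum number of edited (T) reads (default 3).
#' @param min_frequency_percent Minimum editing frequency in percent
#'   (default 10).
#' @param min_probability Minimum probability that the T reads are not
#'   explainable by sequencing error alone (default 0.95); see
#'   [error_model_probability()].
#' @param sequencing_error_rate Assumed per-base substitution error rate
#'   (default 0.001).
#' @return A validated list of class `filter_config`.
#' @export
filter_config <- function(min_coverage = 10,
                          min_count = 3,
                          min_frequency_percent = 10,
                          min_probability = 0.95,
                          sequencing_error_rate = 0.001) {
  stopifnot(
    min_coverage >= 0, min_count >= 0, min_frequency_percent >= 0,
    min_probability >= 0, min_probability <= 1,
    sequencing_error_rate >= 0, sequencing_error_rate <= 1
  )
  structure(
    list(
      min_coverage = min_coverage,
      min_count = min_count,
      min_frequency_percent = min_frequency_percent,
      min_probability = min_probability,
      sequencing_error_rate = sequencing_error_rate
    ),
    class = "filter_config"
  )
}

#' Per-site editing statistics from pileup columns
#'
#' For C-reference positions, the edited count is the number of T reads and
#' the frequency (the editing-extent estimate) is `100 * T / coverage` over
#' the full A+C+G+T coverage.
#'
#' @param pileup Pileup tibble ([build_pileup()]); only rows with `ref == "C"`
#'   are evaluated.
#' @return Tibble with `gene_id`, `cds_pos`, `ref_base`, `edited_count`,
#'   `coverage`, `frequency_percent` (`NA` where coverage is 0: the site is
#'   not evaluable).
#' @export
site_statistics <- function(pileup) {
  pileup %>%
    filter(.data$ref == "C") %>%
    mutate(
      ref_base = "C",
      edited_count = .data$T,
      frequency_percent = if_else(.data$coverage > 0,
                                  100 * .data$T / .data$coverage,
                                  NA_real_)
    ) %>%
    select("gene_id", "cds_pos", "ref_base", "edited_count", "coverage",
           "frequency_percent")
}

#' Probability that observed edited reads exceed sequencing error
#'
#' Under an error-only null model the number of T reads at a C position is
#' Binomial(`coverage`, `q`) with `q = error_rate / 3` (errors substitute to
#' each alternative base with equal probability). The probability reported
#' is the complement of the upper binomial tail,
#' `1 - P[X >= edited_count]`, so values near 1 mean the observed count is
#' not explainable by error. With `edited_count = 0` the tail is 1 and the
#' probability 0.
#'
#' @param edited_count,coverage Integer vectors, `0 <= edited_count <= coverage`.
#' @param error_rate Per-base sequencing error rate.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
error_model_probability <- function(edited_count, coverage, error_rate = 0.001) {
  stopifnot(all(edited_count >= 0), all(edited_count <= coverage))
  q <- error_rate / 3
  # P[X >= k] = 1 - P[X <= k - 1]
  tail <- pbinom(edited_count - 1, size = coverage, prob = q,
                 lower.tail = FALSE)
  1 - tail
}

#' Call C-to-U editing sites
#'
#' Evaluates every C-reference position with at least one T read against the
#' four filters of `config`: coverage, edited count, frequency, and the
#' error-model probability. All comparisons are inclusive.
#'
#' @param pileup Pileup tibble from [build_pileup()].
#' @param config A [filter_config()].
#' @return Tibble of candidate sites: `gene_id`, `cds_pos`, `ref_base`,
#'   `edited_count`, `coverage`, `frequency_percent`, `probability`,
#'   `passed`, and `filter_failures` (comma-separated names of failed
#'   filters, `""` when passed).
#' @export
call_editing_sites <- function(pileup, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  stats <- site_statistics(pileup) %>%
    filter(.data$edited_count >= 1L, .data$coverage > 0L)
  if (nrow(stats) == 0L) {
    return(mutate(stats, probability = numeric(0), passed = logical(0),
                  filter_failures = character(0)))
  }
  stats %>%
    mutate(
      probability = error_model_probability(
        .data$edited_count, .data$coverage, config$sequencing_error_rate
      ),
      fail_coverage = .data$coverage < config$min_coverage,
      fail_count = .data$edited_count < config$min_count,
      fail_frequency = .data$frequency_percent < config$min_frequency_percent,
      fail_probability = .data$probability < config$min_probability,
      passed = !(.data$fail_coverage | .data$fail_count |
                   .data$fail_frequency | .data$fail_probability),
      filter_failures = paste0(
        if_else(.data$fail_coverage, "coverage,", ""),
        if_else(.data$fail_count, "count,", ""),
        if_else(.data$fail_frequency, "frequency,", ""),
        if_else(.data$fail_probability, "probability,", "")
      ) %>% sub(",$", "", .)
    ) %>%
    select(-dplyr::starts_with("fail_"))
}
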