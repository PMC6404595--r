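# Flagging genes contaminated by reads from diverged homologs.
#
# Genes whose mapped reads carry variant positions other than C-to-T are
# suspect: true C-to-U editing can only produce C-reference/T-read signals
# on sense-strand CDS references, so other substitution classes passing the
# same filters indicate unspecifically mapped transcripts of a nuclear
# paralog (dual transcription).

#' Per-gene mismatch profile and paralog flag
#'
#' Tests every reference position for every alternative base with the same
#' coverage/count/frequency/probability filters used for editing calls,
#' then tallies passing C-to-T variants separately from all other
#' substitution classes. G-to-A variants count as non-C-to-T: on
#' sense-strand references genuine editing cannot appear as G-to-A.
#'
#' @param pileup Pileup tibble from [build_pileup()].
#' @param config A [filter_config()].
#' @param flag_threshold Minimum number of passing non-C-to-T variants that
#'   flags a gene (default 1).
#' @return A tibble with one row per gene: `gene_id`, `n_ct_variants`,
#'   `n_non_ct_variants`, `flagged`. The per-variant detail is attached as
#'   attribute `"variants"`.
#' @export
mismatch_profile <- function(pileup, config = filter_config(),
                             flag_threshold = 1L) {
  stopifnot(inherits(config, "filter_config"))
  long <- pileup %>%
    tidyr::pivot_longer(cols = c("A", "C", "G", "T"),
                        names_to = "alt", values_to = "alt_count") %>%
    filter(.data$alt != .data$ref, .data$alt_count >= 1L, .data$coverage > 0L) %>%
    mutate(
      frequency_percent = 100 * .data$alt_count / .data$coverage,
      probability = error_model_probability(
        .data$alt_count, .data$coverage, config$sequencing_error_rate
      ),
      passed = .data$coverage >= config$min_coverage &
        .data$alt_count >= config$min_count &
        .data$frequency_percent >= config$min_frequency_percent &
        .data$probability >= config$min_probability,
      is_ct = .data$ref == "C" & .data$alt == "T"
    )

  profile <- pileup %>%
    distinct(.data$gene_id) %>%
    left_join(
      long %>%
        group_by(.data$gene_id) %>%
        summarise(
          n_ct_variants = sum(.data$passed & .data$is_ct),
          n_non_ct_variants = sum(.data$passed & !.data$is_ct),
          .groups = "drop"
        ),
      by = "gene_id"
    ) %>%
    mutate(
      n_ct_variants = dplyr::coalesce(.data$n_ct_variants, 0L),
      n_non_ct_variants = dplyr::coalesce(.data$n_non_ct_variants, 0L),
      flagged = .data$n_non_ct_variants >= flag_threshold
    )
  attr(profile, "variants") <- filter(long, .data$passed)
  profile
}

#' Exclude sites on paralog-flagged genes
#'
#' Removes called sites located on genes whose mismatch profile is flagged,
#' reproducing the validation step in which genes with non-C-to-T
#' polymorphisms among their mapped reads are discarded wholesale.
#'
#' @param sites Tibble of called sites ([call_editing_sites()] output).
#' @param profiles Per-gene profiles from [mismatch_profile()].
#' @return The sites of unflagged genes; the excluded rows are attached as
#'   attribute `"excluded"`.
#' @export
apply_validation <- function(sites, profiles) {
  flagged <- profiles$gene_id[profiles$flagged]
  excluded <- filter(sites, .data$gene_id %in% flagged)
  kept <- filter(sites, !.data$gene_id %in% flagged)
  if (nrow(excluded)) {
    message("excluded ", nrow(excluded), " site(s) on ", length(flagged),
            " flagged gene(s): ", paste(flagged, collapse = ", "))
  }
  if (nrow(kept) == 0L && nrow(sites) > 0L) {
    warning("all genes with sites were flagged; no validated sites remain")
  }
  attr(kept, "excluded") <- excluded
  kept
}
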