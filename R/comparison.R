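# Cross-sample / cross-species comparison of editing sites.

#' Union table of editing sites across samples
#'
#' Builds the union of validated, passing sites over all samples, keyed by
#' `(gene_id, cds_pos)`, and fills per-sample coverage and frequency from
#' each sample's pileup even where the site was not called in that sample.
#'
#' @param site_lists Named list of per-sample site tibbles (validated calls;
#'   only rows with `passed == TRUE` enter the union).
#' @param pileups Named list of per-sample pileup tibbles, same names as
#'   `site_lists`, all built against the same gene set.
#' @return A wide tibble keyed by `gene_id`, `cds_pos`, with per-sample
#'   columns `coverage_<sample>`, `frequency_<sample>`, `called_<sample>`.
#' @export
build_union <- function(site_lists, pileups) {
  stopifnot(length(site_lists) >= 1L, !is.null(names(site_lists)),
            identical(sort(names(site_lists)), sort(names(pileups))))
  samples <- names(site_lists)

  passing <- purrr::map(site_lists, function(s) {
    if ("passed" %in% names(s)) s <- filter(s, .data$passed)
    select(s, "gene_id", "cds_pos")
  })
  union_keys <- bind_rows(passing) %>%
    distinct(.data$gene_id, .data$cds_pos) %>%
    arrange(.data$gene_id, .data$cds_pos)
  if (nrow(union_keys) == 0L) {
    warning("no passing sites in any sample")
  }

  ref_check <- purrr::map(pileups, function(p) {
    semi_join(p, union_keys, by = c("gene_id", "cds_pos"))$ref
  })
  if (length(unique(ref_check)) > 1L) {
    stop("samples were not called against the same references")
  }

  out <- union_keys
  for (smp in samples) {
    cov <- pileups[[smp]] %>%
      semi_join(union_keys, by = c("gene_id", "cds_pos")) %>%
      mutate(frequency = if_else(.data$coverage > 0,
                                 100 * .data$T / .data$coverage, NA_real_)) %>%
      select("gene_id", "cds_pos", "coverage", "frequency")
    called <- passing[[smp]] %>% mutate(called = TRUE)
    out <- out %>%
      left_join(cov, by = c("gene_id", "cds_pos")) %>%
      left_join(called, by = c("gene_id", "cds_pos")) %>%
      mutate(
        coverage = dplyr::coalesce(.data$coverage, 0L),
        called = dplyr::coalesce(.data$called, FALSE)
      ) %>%
      rename(
        !!paste0("coverage_", smp) := "coverage",
        !!paste0("frequency_", smp) := "frequency",
        !!paste0("called_", smp) := "called"
      )
  }
  out
}

#' Apply the coverage gate and conservation classification
#'
#' A site is *comparable* when its coverage is at least `coverage_gate` in
#' every sample (sites under-covered in any sample cannot be compared
#' fairly), and *conserved* when it is comparable and called in every
#' sample.
#'
#' @param union_table Output of [build_union()].
#' @param coverage_gate Minimum per-sample coverage (default 10 reads).
#' @return `union_table` with logical columns `comparable` and `conserved`
#'   appended.
#' @export
classify_comparable <- function(union_table, coverage_gate = 10) {
  cov_cols <- grep("^coverage_", names(union_table), value = TRUE)
  called_cols <- grep("^called_", names(union_table), value = TRUE)
  stopifnot(length(cov_cols) >= 1L)
  cov <- as.matrix(union_table[cov_cols])
  called <- as.matrix(union_table[called_cols])
  union_table %>%
    mutate(
      comparable = apply(cov >= coverage_gate, 1L, all),
      conserved = .data$comparable & apply(called, 1L, all)
    )
}

#' Totals of a classified comparison table
#'
#' @param classified Output of [classify_comparable()].
#' @return One-row tibble `n_union`, `n_comparable`, `n_conserved`
#'   (always `n_conserved <= n_comparable <= n_union`).
#' @export
comparison_totals <- function(classified) {
  stopifnot(all(c("comparable", "conserved") %in% names(classified)))
  tibble(
    n_union = nrow(classified),
    n_comparable = sum(classified$comparable),
    n_conserved = sum(classified$conserved)
  )
}

#' Per-gene site counts and densities
#'
#' Counts union editing sites per gene and reports the density in sites per
#' kb of annotated CDS length, rounded to one decimal.
#'
#' @param sites Tibble with `gene_id`, `cds_pos` (union table or site list).
#' @param gene_set The reference gene set (provides CDS lengths).
#' @return Tibble `gene_id`, `n_sites`, `cds_length_bp`, `density_sites_per_kb`
#'   with one row per gene (zeros for genes without sites).
#' @export
gene_summaries <- function(sites, gene_set) {
  stopifnot(inherits(gene_set, "gene_set"))
  counts <- sites %>%
    distinct(.data$gene_id, .data$cds_pos) %>%
    count(.data$gene_id, name = "n_sites")
  gene_set$genes %>%
    select("gene_id", cds_length_bp = "length") %>%
    left_join(counts, by = "gene_id") %>%
    mutate(
      n_sites = dplyr::coalesce(.data$n_sites, 0L),
      density_sites_per_kb = round(.data$n_sites / (.data$cds_length_bp / 1000), 1)
    ) %>%
    select("gene_id", "n_sites", "cds_length_bp", "density_sites_per_kb")
}
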