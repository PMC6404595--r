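# End-to-end orchestration: pileup -> call -> annotate -> validate ->
# compare -> SNP fates -> plot-data export, with a run manifest.

#' Per-gene plot tracks of editing extent and coverage
#'
#' One row per CDS position: the coverage trace (clipped at 100 reads for
#' display, as in the classic editing-site plots; raw coverage preserved)
#' and a red-bar height equal to the editing extent in percent at passing
#' sites, `NA` elsewhere. Every bar corresponds to exactly one passing site.
#'
#' @param sites Called sites ([call_editing_sites()]); only `passed` rows
#'   produce bars.
#' @param pileup Pileup tibble for the same sample.
#' @return Tibble `gene_id`, `cds_pos`, `coverage`, `coverage_display`,
#'   `extent_percent`.
#' @export
export_plot_data <- function(sites, pileup) {
  passing <- sites
  if ("passed" %in% names(passing)) passing <- filter(passing, .data$passed)
  bars <- select(passing, "gene_id", "cds_pos",
                 extent_percent = "frequency_percent")
  pileup %>%
    select("gene_id", "cds_pos", "coverage") %>%
    left_join(bars, by = c("gene_id", "cds_pos")) %>%
    mutate(coverage_display = pmin(.data$coverage, 100L)) %>%
    select("gene_id", "cds_pos", "coverage", "coverage_display",
           "extent_percent")
}

#' Plot an editing track for one gene
#'
#' Red bars give the editing extent (percent) at passing sites; the blue
#' line traces coverage, clipped at 100 for display.
#'
#' @param track Tibble from [export_plot_data()].
#' @param gene Gene id to plot (defaults to the first in the track).
#' @return A ggplot object.
#' @export
plot_editing_track <- function(track, gene = track$gene_id[1]) {
  d <- filter(track, .data$gene_id == gene)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cds_pos)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$coverage_display),
                       colour = "steelblue") +
    ggplot2::geom_col(
      data = filter(d, !is.na(.data$extent_percent)),
      ggplot2::aes(y = .data$extent_percent),
      fill = "firebrick", width = 1
    ) +
    ggplot2::labs(
      x = "CDS position (bp)",
      y = "editing extent (%) / coverage (reads, clipped at 100)",
      title = gene
    ) +
    ggplot2::theme_minimal()
}

#' Run the full editing-detection pipeline
#'
#' Loads (or accepts) the reference gene set, builds a pileup per sample,
#' calls editing sites, annotates consequences, flags paralog-contaminated
#' genes and excludes their sites, builds the cross-sample comparison with
#' the coverage gate, summarises per-gene counts and densities, intersects
#' genomic SNPs with editing sites when a second species' CDS set is given,
#' exports plot tracks, and writes all tables plus a manifest to `out_dir`.
#'
#' @param reference CDS FASTA path or a [load_gene_set()] object (species A).
#' @param samples Named character vector of SAM/BAM paths, one per sample.
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing files.
#' @param annotations Optional gene coordinates (see [load_gene_set()]).
#' @param reference_b Optional second species' CDS FASTA or gene set for
#'   SNP intersection.
#' @param filter A [filter_config()].
#' @param coverage_gate Comparison coverage gate (default 10 reads).
#' @return An object of class `edit_run`: a list with `gene_set`, `pileups`,
#'   `sites` (per-sample called+annotated), `profiles`, `validated`,
#'   `comparison` (classified union table), `totals`, `gene_summaries`,
#'   `codon_distribution`, `snps`, `fates`, `tracks`, `manifest`.
#' @export
run_pipeline <- function(reference, samples, out_dir = NULL,
                         annotations = NULL, reference_b = NULL,
                         filter = filter_config(), coverage_gate = 10) {
  stopifnot(length(samples) >= 1L, !is.null(names(samples)))
  # fail on missing inputs before any computation
  paths <- c(
    if (is.character(reference)) reference,
    unname(samples),
    if (is.character(annotations)) annotations,
    if (is.character(reference_b)) reference_b
  )
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("input file(s) not found: ",
                            paste(missing, collapse = ", "))

  gene_set <- if (inherits(reference, "gene_set")) reference
    else load_gene_set(reference, annotations)
  gene_set_b <- if (is.null(reference_b)) NULL
    else if (inherits(reference_b, "gene_set")) reference_b
    else load_gene_set(reference_b)

  pileups <- purrr::map(samples, build_pileup, gene_set = gene_set)
  sites <- purrr::map(pileups, function(p) {
    call_editing_sites(p, filter) %>% annotate_sites(gene_set)
  })
  profiles <- purrr::map(pileups, mismatch_profile, config = filter)
  validated <- purrr::map2(sites, profiles, apply_validation)

  comparison <- build_union(validated, pileups) %>%
    classify_comparable(coverage_gate)
  totals <- comparison_totals(comparison)
  summaries <- gene_summaries(comparison, gene_set)
  codon_dist <- codon_position_distribution(
    bind_rows(purrr::map(validated, function(s) filter(s, .data$passed)))
  )

  snps <- NULL
  fates <- NULL
  if (!is.null(gene_set_b)) {
    snps <- pairwise_cds_snps(gene_set, gene_set_b)
    pooled <- bind_rows(purrr::map(validated, function(s) filter(s, .data$passed))) %>%
      distinct(.data$gene_id, .data$cds_pos)
    fates <- classify_site_fate(snps, pooled, gene_set)
  }

  tracks <- purrr::map2(validated, pileups, export_plot_data)

  manifest <- c(
    sprintf("mitoedit_version: %s",
            as.character(utils::packageVersion("mitoedit"))),
    sprintf("n_samples: %d", length(samples)),
    sprintf("sample_%s: %s (md5 %s)", names(samples), unname(samples),
            unname(tools::md5sum(unname(samples)))),
    sprintf("min_coverage: %g", filter$min_coverage),
    sprintf("min_count: %g", filter$min_count),
    sprintf("min_frequency_percent: %g", filter$min_frequency_percent),
    sprintf("min_probability: %g", filter$min_probability),
    sprintf("sequencing_error_rate: %g", filter$sequencing_error_rate),
    sprintf("coverage_gate: %g", coverage_gate)
  )

  run <- structure(
    list(
      gene_set = gene_set, pileups = pileups, sites = sites,
      profiles = profiles, validated = validated, comparison = comparison,
      totals = totals, gene_summaries = summaries,
      codon_distribution = codon_dist, snps = snps, fates = fates,
      tracks = tracks, manifest = manifest
    ),
    class = "edit_run"
  )

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) readr::write_tsv(x, file.path(out_dir, name))
  for (smp in names(run$sites)) {
    w(run$sites[[smp]], paste0("sites_", smp, ".tsv"))
    w(run$profiles[[smp]], paste0("profiles_", smp, ".tsv"))
    w(run$tracks[[smp]], paste0("track_", smp, ".tsv"))
  }
  w(run$comparison, "comparison.tsv")
  w(run$gene_summaries, "gene_summaries.tsv")
  w(run$codon_distribution, "codon_position_distribution.tsv")
  if (!is.null(run$snps)) w(run$snps, "snps.tsv")
  if (!is.null(run$fates)) w(run$fates, "site_fates.tsv")
  jsonlite::write_json(as.list(run$totals), file.path(out_dir, "totals.json"),
                       auto_unbox = TRUE)
  writeLines(run$manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' @export
print.edit_run <- function(x, ...) {
  cat("<edit_run> ", length(x$pileups), " sample(s), ",
      nrow(x$gene_set$genes), " genes\n", sep = "")
  cat("  union sites: ", x$totals$n_union,
      "; comparable: ", x$totals$n_comparable,
      "; conserved: ", x$totals$n_conserved, "\n", sep = "")
  invisible(x)
}

#' Tidy the per-site results of a pipeline run
#'
#' @param x An `edit_run` object.
#' @param ... Unused.
#' @return The classified cross-sample comparison table (one row per union
#'   editing site).
#' @method tidy edit_run
#' @export
tidy.edit_run <- function(x, ...) x$comparison

#' One-row summary of a pipeline run
#'
#' @param x An `edit_run` object.
#' @param ... Unused.
#' @return One-row tibble: `n_genes`, `n_samples`, `n_union`,
#'   `n_comparable`, `n_conserved`, `n_flagged_genes`.
#' @method glance edit_run
#' @export
glance.edit_run <- function(x, ...) {
  tibble(
    n_genes = nrow(x$gene_set$genes),
    n_samples = length(x$pileups),
    n_union = x$totals$n_union,
    n_comparable = x$totals$n_comparable,
    n_conserved = x$totals$n_conserved,
    n_flagged_genes = length(unique(unlist(
      purrr::map(x$profiles, function(p) p$gene_id[p$flagged])
    )))
  )
}

#' Plot a gene's editing track from a pipeline run
#'
#' @param object An `edit_run` object.
#' @param gene Gene id; defaults to the gene with most sites.
#' @param sample Sample name; defaults to the first sample.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot edit_run
#' @export
autoplot.edit_run <- function(object, gene = NULL,
                              sample = names(object$tracks)[1], ...) {
  if (is.null(gene)) {
    gene <- object$gene_summaries$gene_id[
      which.max(object$gene_summaries$n_sites)
    ]
  }
  plot_editing_track(object$tracks[[sample]], gene)
}
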