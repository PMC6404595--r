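# Per-position base counts from read alignments.

#' Build a per-position base pileup for every gene
#'
#' Counts aligned A/C/G/T bases at every CDS position of every gene. Aligned
#' `N` bases, positions under deletions or insertions, and soft-clipped
#' bases are not counted. Every CDS position appears in the output, with
#' zero counts where no read aligns.
#'
#' @param alignments Path to a SAM or BAM file whose reference names are the
#'   gene ids of `gene_set` (alignments in CDS coordinates).
#' @param gene_set A [load_gene_set()] / [simulate_references()] gene set.
#' @param min_base_quality,min_mapq Optional quality thresholds; both default
#'   to 0 (no filtering), matching a pipeline that applies none.
#' @return A tibble with one row per gene per CDS position:
#'   `gene_id`, `cds_pos`, `ref`, `A`, `C`, `G`, `T`, `coverage`
#'   (`coverage = A + C + G + T`), ordered by gene and position.
#' @export
build_pileup <- function(alignments, gene_set,
                         min_base_quality = 0L, min_mapq = 0L) {
  stopifnot(inherits(gene_set, "gene_set"))
  if (!file.exists(alignments)) stop("alignment file not found: ", alignments)

  bam <- alignments
  if (grepl("\\.sam$", alignments, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(alignments, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  } else if (!file.exists(paste0(bam, ".bai"))) {
    Rsamtools::indexBam(bam)
  }

  # reads mapped to references absent from the gene set are skipped
  idx <- Rsamtools::idxstatsBam(bam)
  unknown <- idx[!(as.character(idx$seqnames) %in% gene_set$genes$gene_id) &
                   idx$mapped > 0, ]
  if (nrow(unknown)) {
    warning(sum(unknown$mapped), " read(s) on unknown reference(s) skipped: ",
            paste(unknown$seqnames, collapse = ", "))
  }

  pp <- Rsamtools::PileupParam(
    max_depth = 1000000L,
    min_base_quality = as.integer(min_base_quality),
    min_mapq = as.integer(min_mapq),
    min_nucleotide_depth = 1L,
    distinguish_strands = FALSE,
    distinguish_nucleotides = TRUE,
    ignore_query_Ns = TRUE,
    include_deletions = FALSE,
    include_insertions = FALSE
  )
  res <- Rsamtools::pileup(bam, pileupParam = pp)
  res <- as_tibble(res) %>%
    mutate(
      gene_id = as.character(.data$seqnames),
      nucleotide = as.character(.data$nucleotide)
    ) %>%
    filter(.data$nucleotide %in% c("A", "C", "G", "T"),
           .data$gene_id %in% gene_set$genes$gene_id) %>%
    select("gene_id", cds_pos = "pos", "nucleotide", "count") %>%
    tidyr::pivot_wider(names_from = "nucleotide", values_from = "count",
                       values_fill = 0L)

  grid <- purrr::pmap(
    list(gene_set$genes$gene_id, gene_set$genes$cds_sequence,
         gene_set$genes$length),
    function(id, s, L) {
      tibble(gene_id = id, cds_pos = seq_len(L),
             ref = strsplit(s, "", fixed = TRUE)[[1]])
    }
  ) %>% bind_rows()

  out <- left_join(grid, res, by = c("gene_id", "cds_pos"))
  for (b in c("A", "C", "G", "T")) {
    if (!b %in% names(out)) out[[b]] <- 0L
    out[[b]][is.na(out[[b]])] <- 0L
  }
  out %>%
    mutate(coverage = .data$A + .data$C + .data$G + .data$T) %>%
    select("gene_id", "cds_pos", "ref", "A", "C", "G", "T", "coverage") %>%
    arrange(match(.data$gene_id, gene_set$genes$gene_id), .data$cds_pos)
}

#' Mean read coverage per gene
#'
#' Arithmetic mean of per-position coverage over all CDS positions of each
#' gene, the quantity used to judge whether a CDS is deep enough for
#' editing-site detection at all.
#'
#' @param pileup A pileup tibble from [build_pileup()].
#' @return A tibble with `gene_id` and `mean_coverage`.
#' @export
mean_coverage <- function(pileup) {
  stopifnot(nrow(pileup) >= 1L)
  pileup %>%
    group_by(.data$gene_id) %>%
    summarise(mean_coverage = mean(.data$coverage), .groups = "drop")
}
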