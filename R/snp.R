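# Genomic C/T polymorphisms at editing sites: loss and mimicry.

#' Position-wise SNPs between homologous CDS sets
#'
#' Compares the CDS of two individuals/species position by position over
#' shared gene ids (collinear, equal-length CDS assumed; genes of unequal
#' length are skipped with a warning).
#'
#' @param gene_set_a,gene_set_b Gene sets from [load_gene_set()].
#' @return Tibble of SNPs: `gene_id`, `cds_pos`, `base_a`, `base_b`,
#'   `involves_c` (TRUE when either allele is C — the only SNPs that can
#'   create or destroy an editing site).
#' @export
pairwise_cds_snps <- function(gene_set_a, gene_set_b) {
  stopifnot(inherits(gene_set_a, "gene_set"), inherits(gene_set_b, "gene_set"))
  shared <- intersect(gene_set_a$genes$gene_id, gene_set_b$genes$gene_id)
  if (length(shared) == 0L) stop("no shared gene ids between the two sets")

  purrr::map(shared, function(g) {
    sa <- gene_sequence(gene_set_a, g)
    sb <- gene_sequence(gene_set_b, g)
    if (nchar(sa) != nchar(sb)) {
      warning("gene ", g, " skipped: unequal CDS lengths (",
              nchar(sa), " vs ", nchar(sb), ")")
      return(NULL)
    }
    a <- strsplit(sa, "", fixed = TRUE)[[1]]
    b <- strsplit(sb, "", fixed = TRUE)[[1]]
    diff <- which(a != b)
    if (!length(diff)) return(NULL)
    tibble(gene_id = g, cds_pos = diff, base_a = a[diff], base_b = b[diff])
  }) %>%
    bind_rows() %>%
    (function(x) {
      if (nrow(x) == 0L) {
        tibble(gene_id = character(), cds_pos = integer(),
               base_a = character(), base_b = character(),
               involves_c = logical())
      } else {
        mutate(x, involves_c = .data$base_a == "C" | .data$base_b == "C")
      }
    })()
}

#' Classify how genomic SNPs interact with editing sites
#'
#' A C(A)-to-T(B) SNP at a position called as an editing site in species A
#' means the edited state is hard-coded in species B's genome: the editing
#' site is lost by thymidine substitution, and the substitution has the same
#' codon consequence as full editing. A C-to-T SNP at a position *not*
#' called is flagged as potential editing mimicry — mapping B's reads to A's
#' reference would fake an editing signal there. All other SNPs are
#' unaffected.
#'
#' @param snps Tibble from [pairwise_cds_snps()].
#' @param editing_sites Called sites on species A ([call_editing_sites()]
#'   output; only `passed` rows count as called).
#' @param gene_set_a Species A gene set (for codon consequences).
#' @param table Codon table, default [mt_codon_table()].
#' @return One row per SNP: the SNP columns plus `category`
#'   (`lost_by_thymidine_substitution`, `potential_mimicry`, `unaffected`)
#'   and, for lost sites, consequence columns from [annotate_sites()].
#' @export
classify_site_fate <- function(snps, editing_sites, gene_set_a,
                               table = mt_codon_table()) {
  called <- editing_sites
  if ("passed" %in% names(called)) called <- filter(called, .data$passed)
  called_keys <- distinct(called, .data$gene_id, .data$cds_pos) %>%
    mutate(is_called = TRUE)

  out <- snps %>%
    left_join(called_keys, by = c("gene_id", "cds_pos")) %>%
    mutate(
      is_called = dplyr::coalesce(.data$is_called, FALSE),
      ct_ab = .data$base_a == "C" & .data$base_b == "T",
      category = dplyr::case_when(
        .data$ct_ab & .data$is_called ~ "lost_by_thymidine_substitution",
        .data$ct_ab ~ "potential_mimicry",
        TRUE ~ "unaffected"
      )
    ) %>%
    select(-"is_called")

  lost <- filter(out, .data$category == "lost_by_thymidine_substitution")
  cons_cols <- c("codon_position", "ref_codon", "edited_codon", "ref_aa",
                 "edited_aa", "synonymous", "creates_stop", "removes_stop")
  if (nrow(lost)) {
    cons <- annotate_sites(select(lost, "gene_id", "cds_pos"), gene_set_a, table)
    out <- left_join(out, cons, by = c("gene_id", "cds_pos"))
  } else {
    for (cc in cons_cols) out[[cc]] <- NA
  }
  if (any(out$category == "potential_mimicry")) {
    warning(sum(out$category == "potential_mimicry"),
            " C-to-T SNP(s) at uncalled positions could mimic editing if ",
            "species B reads are mapped to species A references")
  }
  select(out, -"ct_ab")
}
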