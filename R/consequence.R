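# Codon and amino-acid consequences of editing events.

#' Annotate sites with codon and amino-acid consequences
#'
#' For each site, locates the containing codon, applies the C-to-T exchange
#' at the site's codon offset, and translates both codons with the plant
#' mitochondrial table (so `TGA` and `CGG` read as Trp). Stop gain/loss is
#' judged against the same table. A site whose codon is truncated by the end
#' of the sequence keeps its `codon_position` but gets no amino-acid fields.
#'
#' @param sites Tibble with at least `gene_id` and `cds_pos` (e.g. the
#'   output of [call_editing_sites()]); the referenced base must be C.
#' @param gene_set The gene set the sites were called on.
#' @param table Codon table, default [mt_codon_table()].
#' @return The input with appended columns `codon_position`, `ref_codon`,
#'   `edited_codon`, `ref_aa`, `edited_aa`, `synonymous`, `creates_stop`,
#'   `removes_stop`.
#' @export
annotate_sites <- function(sites, gene_set, table = mt_codon_table()) {
  stopifnot(inherits(gene_set, "gene_set"))
  if (nrow(sites) == 0L) {
    return(mutate(sites, codon_position = integer(0), ref_codon = character(0),
                  edited_codon = character(0), ref_aa = character(0),
                  edited_aa = character(0), synonymous = logical(0),
                  creates_stop = logical(0), removes_stop = logical(0)))
  }
  seqs <- setNames(gene_set$genes$cds_sequence, gene_set$genes$gene_id)
  lens <- setNames(gene_set$genes$length, gene_set$genes$gene_id)
  if (any(!sites$gene_id %in% names(seqs))) {
    stop("site(s) on genes absent from the gene set")
  }

  s <- unname(seqs[sites$gene_id])
  len <- unname(lens[sites$gene_id])
  pos <- as.integer(sites$cds_pos)
  if (any(pos < 1L | pos > len)) stop("site position outside its CDS")

  ref_at <- substring(s, pos, pos)
  if (any(ref_at != "C")) {
    stop("reference base is not C at: ",
         paste(sites$gene_id[ref_at != "C"], pos[ref_at != "C"],
               sep = ":", collapse = ", "))
  }

  offset <- codon_position(pos)
  codon_start <- pos - offset + 1L
  complete <- codon_start + 2L <= len

  ref_codon <- ifelse(complete, substring(s, codon_start, codon_start + 2L),
                      NA_character_)
  edited_codon <- ref_codon
  has <- !is.na(edited_codon)
  substring(edited_codon[has], offset[has], offset[has]) <- rep("T", sum(has))

  ref_aa <- ifelse(has, translate_codon(ifelse(has, ref_codon, "NNN"), table),
                   NA_character_)
  edited_aa <- ifelse(has, translate_codon(ifelse(has, edited_codon, "NNN"), table),
                      NA_character_)

  sites %>%
    mutate(
      codon_position = offset,
      ref_codon = ref_codon,
      edited_codon = edited_codon,
      ref_aa = ref_aa,
      edited_aa = edited_aa,
      synonymous = if_else(.data$ref_aa == "X" | .data$edited_aa == "X",
                           NA, .data$ref_aa == .data$edited_aa),
      creates_stop = .data$ref_aa != "Ter" & .data$edited_aa == "Ter",
      removes_stop = .data$ref_aa == "Ter" & .data$edited_aa != "Ter"
    )
}

#' Distribution of editing sites over codon positions
#'
#' @param changes Tibble with a `codon_position` column, e.g. from
#'   [annotate_sites()].
#' @return A tibble with one row per codon position 1-3: `codon_position`,
#'   `n`, `percent` (integer, rounded half-up so that published-style
#'   percentages like 33/53/14 are reproduced), and `fraction` (raw).
#' @export
codon_position_distribution <- function(changes) {
  n <- vapply(1:3, function(p) sum(changes$codon_position == p, na.rm = TRUE),
              integer(1))
  total <- sum(n)
  frac <- if (total > 0) n / total else rep(0, 3)
  tibble(
    codon_position = 1:3,
    n = n,
    percent = as.integer(floor(100 * frac + 0.5)),
    fraction = frac
  )
}
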