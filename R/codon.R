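# Codon arithmetic and translation under the plant mitochondrial code.

AA_THREE_LETTER <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)

#' Plant mitochondrial codon table
#'
#' The standard genetic code with the exceptions applied that govern plant
#' mitochondrial translation of edited transcripts: `TGA` (RNA `UGA`) and
#' `CGG` (RNA `CGG`) both encode tryptophan. Codons are given in the DNA
#' alphabet; amino acids as three-letter symbols with `"Ter"` for stop.
#'
#' @param exceptions Named character vector of codon -> amino-acid overrides
#'   applied on top of the standard code. Default `c(TGA = "Trp", CGG = "Trp")`.
#' @return A named character vector of length 64 mapping each codon to a
#'   three-letter amino-acid symbol.
#' @examples
#' tab <- mt_codon_table()
#' tab[["TGA"]] # "Trp", not "Ter"
#' @export
mt_codon_table <- function(exceptions = c(TGA = "Trp", CGG = "Trp")) {
  tab <- unname(AA_THREE_LETTER[Biostrings::GENETIC_CODE])
  names(tab) <- names(Biostrings::GENETIC_CODE)
  if (length(exceptions)) {
    bad <- setdiff(names(exceptions), names(tab))
    if (length(bad)) {
      stop("unknown codon(s) in exceptions: ", paste(bad, collapse = ", "))
    }
    tab[names(exceptions)] <- exceptions
  }
  tab
}

#' Codon position of a CDS position
#'
#' Maps a 1-based position within a coding sequence to its offset within the
#' codon: `pos mod 3 = 1` is codon position 1, `pos mod 3 = 2` is position 2,
#' and `pos mod 3 = 0` is position 3.
#'
#' @param cds_pos Integer vector of 1-based CDS positions.
#' @return Integer vector with values in `{1, 2, 3}`.
#' @examples
#' codon_position(146) # 2
#' @export
codon_position <- function(cds_pos) {
  if (any(is.na(cds_pos)) || any(cds_pos < 1) || any(cds_pos != round(cds_pos))) {
    stop("cds_pos must be positive integers (1-based)")
  }
  m <- as.integer(cds_pos %% 3)
  ifelse(m == 0L, 3L, m)
}

#' Codon containing a CDS position
#'
#' @param cds_sequence A single CDS string (sense strand, DNA alphabet).
#' @param cds_pos Integer vector of 1-based positions within the sequence.
#' @return A tibble with columns `codon` (the 3-mer) and `offset`
#'   (codon position of `cds_pos`, in `{1, 2, 3}`).
#' @examples
#' codon_at("ATGTCC", 6) # codon "TCC", offset 3
#' @export
codon_at <- function(cds_sequence, cds_pos) {
  stopifnot(is.character(cds_sequence), length(cds_sequence) == 1L)
  len <- nchar(cds_sequence)
  if (any(cds_pos < 1) || any(cds_pos > len)) {
    stop("cds_pos outside the sequence (length ", len, ")")
  }
  start <- 3L * ((as.integer(cds_pos) - 1L) %/% 3L) + 1L
  if (any(start + 2L > len)) {
    stop("codon truncated by the end of the sequence")
  }
  tibble(
    codon = substr(rep(cds_sequence, length(start)), start, start + 2L),
    offset = codon_position(cds_pos)
  )
}

#' Translate a codon
#'
#' Translates DNA codons with [mt_codon_table()] semantics: the exceptions
#' override the standard code, and any codon containing a base outside
#' A/C/G/T translates to the unknown symbol `"X"`.
#'
#' @param codon Character vector of 3-mers (DNA alphabet).
#' @param table Codon table as returned by [mt_codon_table()].
#' @return Character vector of three-letter amino-acid symbols
#'   (`"Ter"` for stop, `"X"` for untranslatable codons).
#' @examples
#' translate_codon(c("TCC", "TTC", "TGA"))
#' @export
translate_codon <- function(codon, table = mt_codon_table()) {
  codon <- toupper(codon)
  if (any(nchar(codon) != 3L)) stop("codons must be 3-mers")
  aa <- unname(table[codon])
  aa[is.na(aa)] <- "X"
  aa
}

#' Overlap length between two 1-based inclusive intervals
#'
#' Returns `max(0, min(end) - max(start))` — the boundary-difference
#' convention used when screening annotated CDS pairs for overlaps, under
#' which the cox3/sdh4 coordinates (246,064-246,861 and 246,789-247,184)
#' give 72 bp.
#'
#' @param a,b Numeric vectors of length 2, `(start, end)` with `end >= start`.
#' @return A single non-negative integer.
#' @examples
#' interval_overlap(c(246064, 246861), c(246789, 247184)) # 72
#' @export
interval_overlap <- function(a, b) {
  stopifnot(length(a) == 2L, length(b) == 2L, a[2] >= a[1], b[2] >= b[1])
  max(0L, as.integer(min(a[2], b[2]) - max(a[1], b[1])))
}
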