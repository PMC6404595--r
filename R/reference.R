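# Loading and validating CDS references and gene annotations.

#' Load a set of CDS reference genes
#'
#' Reads sense-strand CDS sequences from a FASTA file and, optionally, gene
#' coordinates from a GFF3 file or a tabular annotation. Pairwise overlaps
#' between coordinate-bearing genes are computed with [interval_overlap()]
#' so that downstream site calls in shared regions can be interpreted
#' per gene.
#'
#' @param cds_fasta Path to a FASTA file of CDS sequences (one record per
#'   gene; the first whitespace-delimited token of each header is the
#'   gene id), or a named character vector of sequences.
#' @param annotations Optional gene coordinates: a path to a GFF3 file
#'   (`.gff`/`.gff3`; CDS features, 1-based inclusive), a path to a
#'   tab-separated file with columns `gene_id`, `start`, `end`, `strand`,
#'   or a data frame with those columns. Gene ids must match FASTA ids.
#' @param pseudogenes Character vector of gene ids to flag as potential
#'   pseudogenes (e.g. CDS lacking a confirmed start codon).
#' @return An object of class `gene_set`: a list with
#'   \describe{
#'     \item{genes}{tibble with `gene_id`, `cds_sequence`, `length`,
#'       `genome_start`, `genome_end`, `strand`, `pseudogene_flag`,
#'       `multiple_of_3`}
#'     \item{overlaps}{tibble of overlapping coordinate pairs
#'       (`gene_id_a`, `gene_id_b`, `overlap_bp`), `overlap_bp > 0` only}
#'   }
#' @details CDS whose length is not a multiple of 3 are accepted (they may
#'   be pseudogene candidates annotated from an unconfirmed start) but are
#'   reported via a message and flagged in `multiple_of_3`. Duplicate
#'   record ids and empty FASTA files are hard errors. `N` and other IUPAC
#'   ambiguity letters are permitted; codons containing them translate
#'   to `"X"`.
#' @export
load_gene_set <- function(cds_fasta, annotations = NULL, pseudogenes = character()) {
  if (is.character(cds_fasta) && length(cds_fasta) == 1L && file.exists(cds_fasta)) {
    seqs <- Biostrings::readDNAStringSet(cds_fasta)
    ids <- sub("\\s.*$", "", names(seqs))
    seqs <- as.character(seqs)
  } else if (is.character(cds_fasta) && !is.null(names(cds_fasta))) {
    ids <- names(cds_fasta)
    seqs <- unname(cds_fasta)
  } else {
    stop("cds_fasta must be a FASTA path or a named character vector")
  }
  if (length(seqs) == 0L) stop("no sequences found in ", cds_fasta)
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(seqs)
  ok <- grepl("^[ACGTRYSWKMBDHVN]*$", seqs)
  if (!all(ok)) stop("non-IUPAC DNA letters in record(s): ",
                     paste(ids[!ok], collapse = ", "))
  if (any(nchar(seqs) < 3L)) stop("CDS shorter than one codon: ",
                                  paste(ids[nchar(seqs) < 3L], collapse = ", "))

  genes <- tibble(
    gene_id = unname(ids),
    cds_sequence = unname(seqs),
    length = nchar(seqs),
    genome_start = NA_integer_,
    genome_end = NA_integer_,
    strand = NA_character_,
    pseudogene_flag = ids %in% pseudogenes,
    multiple_of_3 = nchar(seqs) %% 3L == 0L
  )

  if (!all(genes$multiple_of_3)) {
    message("CDS length not a multiple of 3 (read in frame from position 1): ",
            paste(genes$gene_id[!genes$multiple_of_3], collapse = ", "))
  }

  if (!is.null(annotations)) {
    ann <- read_annotations(annotations)
    unknown <- setdiff(ann$gene_id, genes$gene_id)
    if (length(unknown)) {
      stop("annotation gene id(s) not in FASTA: ", paste(unknown, collapse = ", "))
    }
    if (any(ann$end < ann$start)) stop("annotation with end < start")
    idx <- match(ann$gene_id, genes$gene_id)
    genes$genome_start[idx] <- as.integer(ann$start)
    genes$genome_end[idx] <- as.integer(ann$end)
    genes$strand[idx] <- as.character(ann$strand)
  }

  structure(list(genes = genes, overlaps = compute_overlaps(genes)),
            class = "gene_set")
}

read_annotations <- function(annotations) {
  if (is.data.frame(annotations)) {
    ann <- as_tibble(annotations)
  } else if (is.character(annotations) && length(annotations) == 1L) {
    if (grepl("\\.gff3?$", annotations, ignore.case = TRUE)) {
      if (!requireNamespace("rtracklayer", quietly = TRUE)) {
        stop("reading GFF3 requires the rtracklayer package")
      }
      gr <- rtracklayer::import(annotations)
      gr <- gr[as.character(gr$type) %in% c("CDS", "gene", "pseudogene")]
      md <- S4Vectors::mcols(gr)
      id <- if ("gene_id" %in% names(md)) md$gene_id
        else if ("Name" %in% names(md)) md$Name
        else md$ID
      ann <- tibble(
        gene_id = as.character(id),
        start = GenomicRanges::start(gr),
        end = GenomicRanges::end(gr),
        strand = as.character(GenomicRanges::strand(gr))
      )
      ann <- distinct(ann, .data$gene_id, .keep_all = TRUE)
    } else {
      ann <- readr::read_tsv(annotations, show_col_types = FALSE,
                             col_names = c("gene_id", "start", "end", "strand"))
      # tolerate a header row
      if (identical(ann$gene_id[1], "gene_id")) ann <- ann[-1, ]
      ann <- mutate(ann, start = as.integer(.data$start), end = as.integer(.data$end))
    }
  } else {
    stop("annotations must be a file path or a data frame")
  }
  required <- c("gene_id", "start", "end", "strand")
  if (!all(required %in% names(ann))) {
    stop("annotations need columns: ", paste(required, collapse = ", "))
  }
  ann[required]
}

compute_overlaps <- function(genes) {
  coords <- filter(genes, !is.na(.data$genome_start), !is.na(.data$genome_end))
  out <- tibble(gene_id_a = character(), gene_id_b = character(),
                overlap_bp = integer())
  n <- nrow(coords)
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ov <- interval_overlap(
        c(coords$genome_start[i], coords$genome_end[i]),
        c(coords$genome_start[j], coords$genome_end[j])
      )
      if (ov > 0L) {
        out <- bind_rows(out, tibble(gene_id_a = coords$gene_id[i],
                                     gene_id_b = coords$gene_id[j],
                                     overlap_bp = ov))
      }
    }
  }
  out
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", nrow(x$genes), " genes, ",
      nrow(x$overlaps), " overlapping pair(s)\n", sep = "")
  print(x$genes, ...)
  invisible(x)
}

# internal: fetch one gene's sequence
gene_sequence <- function(gene_set, gene_id) {
  i <- match(gene_id, gene_set$genes$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene_id)
  gene_set$genes$cds_sequence[i]
}
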