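# Small in-code fixtures shared across tests.

# gene set from named sequences, no file IO
make_gene_set <- function(...) load_gene_set(c(...))

# write a minimal SAM: reads is a data.frame with gene_id, pos, seq and
# optionally cigar (defaults to full-length match)
write_test_sam <- function(gene_set, reads, path = tempfile(fileext = ".sam")) {
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", gene_set$genes$gene_id, gene_set$genes$length)
  )
  cigar <- if ("cigar" %in% names(reads)) reads$cigar
    else paste0(nchar(reads$seq), "M")
  body <- sprintf(
    "r%04d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
    seq_len(nrow(reads)), reads$gene_id, reads$pos, cigar, reads$seq,
    strrep("I", nchar(reads$seq))
  )
  writeLines(c(header, body), path)
  path
}

# pileup row constructor for unit tests that bypass alignment files
pileup_row <- function(gene_id, cds_pos, ref, A = 0L, C = 0L, G = 0L, T = 0L) {
  tibble::tibble(gene_id = gene_id, cds_pos = as.integer(cds_pos), ref = ref,
                 A = as.integer(A), C = as.integer(C), G = as.integer(G),
                 T = as.integer(T), coverage = as.integer(A + C + G + T))
}

# independent brute-force enumeration of the binomial upper tail,
# kept free of pbinom so it can serve as an oracle
brute_force_probability <- function(count, coverage, error_rate) {
  q <- error_rate / 3
  ks <- seq(count, coverage)
  tail <- sum(choose(coverage, ks) * q^ks * (1 - q)^(coverage - ks))
  1 - tail
}

# count T reads and total reads covering one position straight from SAM text,
# independent of build_pileup (simple full-match reads only)
count_base_from_sam <- function(sam_path, gene, pos) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  hits <- vapply(f, function(x) {
    x[3] == gene && as.integer(x[4]) <= pos &&
      as.integer(x[4]) + nchar(x[10]) - 1L >= pos
  }, logical(1))
  f <- f[hits]
  bases <- vapply(f, function(x) {
    substr(x[10], pos - as.integer(x[4]) + 1L, pos - as.integer(x[4]) + 1L)
  }, character(1))
  c(t = sum(bases == "T"), n = length(bases))
}
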