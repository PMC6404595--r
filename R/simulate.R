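# Synthetic references and aligned reads with known editing structure.
#
# The simulator emits alignments directly in CDS coordinates (the analysis
# consumes transcript-space mappings), so SAM records use each CDS as its
# reference sequence, all on the forward strand.

#' Configuration for the editing-site simulator
#'
#' Defines the reference layout, the per-site editing truth, and the read
#' model used by [simulate_references()] and [simulate_reads()].
#'
#' @param n_genes Number of CDS-like genes.
#' @param gene_length_range Length range in bp; lengths are rounded to a
#'   multiple of 3.
#' @param editing_sites_per_gene Number of edited C positions per gene.
#' @param true_extent_range Range of true editing extents, drawn uniformly;
#'   editing extents observed in plant mitochondria span roughly 0.1 to 1.
#' @param depth_per_gene Target mean read depth, a scalar or one value per gene.
#' @param read_length Read length in bp (>= 20).
#' @param sequencing_error_rate Per-base substitution error probability;
#'   errors substitute uniformly among the three alternative bases.
#' @param dna_contamination_fraction Fraction of reads drawn from the
#'   genomic template, which never show editing and so dilute the observed
#'   extent toward `true_extent * (1 - fraction)`.
#' @param paralog_settings Optional list
#'   `list(target_gene_ids=, divergence_proportion=, read_fraction=)`
#'   describing diverged nuclear-paralog transcripts whose reads map
#'   unspecifically onto the target genes.
#' @param species_b_snps Genomic differences carried by a second species:
#'   either a data frame with columns `gene_id`, `cds_pos`, `ref_base`,
#'   `alt_base`, or a per-base substitution rate (numeric scalar), or `NULL`.
#' @param seed Integer seed; all simulator output is deterministic given it.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 4,
                              gene_length_range = c(300, 600),
                              editing_sites_per_gene = 5,
                              true_extent_range = c(0.1, 1),
                              depth_per_gene = 50,
                              read_length = 100,
                              sequencing_error_rate = 0.001,
                              dna_contamination_fraction = 0,
                              paralog_settings = NULL,
                              species_b_snps = NULL,
                              seed = 1L) {
  stopifnot(
    n_genes >= 1,
    length(gene_length_range) == 2L,
    gene_length_range[1] >= 21,
    gene_length_range[2] >= gene_length_range[1],
    editing_sites_per_gene >= 0,
    all(true_extent_range >= 0), all(true_extent_range <= 1),
    all(depth_per_gene >= 0),
    length(depth_per_gene) %in% c(1L, n_genes),
    read_length >= 20,
    sequencing_error_rate >= 0, sequencing_error_rate <= 1,
    dna_contamination_fraction >= 0, dna_contamination_fraction < 1,
    seed == round(seed)
  )
  if (!is.null(paralog_settings)) {
    stopifnot(
      is.list(paralog_settings),
      all(c("target_gene_ids", "divergence_proportion", "read_fraction") %in%
            names(paralog_settings)),
      paralog_settings$divergence_proportion >= 0,
      paralog_settings$divergence_proportion <= 1,
      paralog_settings$read_fraction >= 0,
      paralog_settings$read_fraction <= 1
    )
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      gene_length_range = gene_length_range,
      editing_sites_per_gene = editing_sites_per_gene,
      true_extent_range = true_extent_range,
      depth_per_gene = depth_per_gene,
      read_length = as.integer(read_length),
      sequencing_error_rate = sequencing_error_rate,
      dna_contamination_fraction = dna_contamination_fraction,
      paralog_settings = paralog_settings,
      species_b_snps = species_b_snps,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate CDS references for two species plus an editing truth table
#'
#' Generates `n_genes` random CDS sequences (species A), places editing
#' sites on C positions with true extents drawn from the configured range,
#' and derives species B from A by applying the configured genomic SNPs.
#' When a paralog is configured, a diverged copy of each target gene is
#' generated and stored for [simulate_reads()].
#'
#' @param config A [simulation_config()] object.
#' @return A list of class `sim_refs` with elements `gene_set_a`,
#'   `gene_set_b` ([load_gene_set()] objects), `truth` (tibble `gene_id`,
#'   `cds_pos`, `true_extent`, `ref_base`), `snps` (tibble `gene_id`,
#'   `cds_pos`, `ref_base`, `alt_base`) and `paralog_seqs` (named list).
#' @export
simulate_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)

  len_choices <- seq(config$gene_length_range[1], config$gene_length_range[2])
  lens <- len_choices[sample.int(length(len_choices), config$n_genes,
                                 replace = TRUE)]
  lens <- pmax(3L * (lens %/% 3L), 21L)
  ids <- sprintf("gene%02d", seq_len(config$n_genes))

  seqs <- vapply(lens, function(L) {
    body <- sample(c("A", "C", "G", "T"), L - 6L, replace = TRUE)
    paste0("ATG", paste(body, collapse = ""), "TAA")
  }, character(1))
  names(seqs) <- ids

  truth <- purrr::map2(ids, seqs, function(id, s) {
    cpos <- which(strsplit(s, "", fixed = TRUE)[[1]] == "C")
    k <- min(config$editing_sites_per_gene, length(cpos))
    if (k < config$editing_sites_per_gene) {
      warning("gene ", id, ": only ", k, " C positions available for editing sites")
    }
    if (k == 0L) return(NULL)
    pos <- sort(cpos[sample.int(length(cpos), k)])
    tibble(
      gene_id = id, cds_pos = pos,
      true_extent = runif(k, config$true_extent_range[1], config$true_extent_range[2]),
      ref_base = "C"
    )
  }) %>% bind_rows()
  if (nrow(truth) == 0L) {
    truth <- tibble(gene_id = character(), cds_pos = integer(),
                    true_extent = numeric(), ref_base = character())
  }

  # species B: apply SNPs on top of A
  snps <- config$species_b_snps
  if (is.null(snps)) {
    snps <- tibble(gene_id = character(), cds_pos = integer(),
                   ref_base = character(), alt_base = character())
  } else if (is.numeric(snps) && length(snps) == 1L) {
    rate <- snps
    snps <- purrr::map2(ids, seqs, function(id, s) {
      hit <- which(runif(nchar(s)) < rate)
      if (!length(hit)) return(NULL)
      ref <- substring(s, hit, hit)
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                    character(1))
      tibble(gene_id = id, cds_pos = hit, ref_base = unname(ref), alt_base = alt)
    }) %>% bind_rows()
  } else {
    snps <- as_tibble(snps)
    stopifnot(all(c("gene_id", "cds_pos", "ref_base", "alt_base") %in% names(snps)))
  }

  if (nrow(snps)) {
    for (i in seq_len(nrow(snps))) {
      g <- snps$gene_id[i]
      if (!g %in% ids) stop("SNP on unknown gene: ", g)
      p <- snps$cds_pos[i]
      if (substring(seqs[[g]], p, p) != snps$ref_base[i]) {
        # place the requested reference base in species A so the pair is valid
        substr(seqs[[g]], p, p) <- snps$ref_base[i]
      }
    }
  }
  seqs_b <- seqs
  if (nrow(snps)) {
    for (i in seq_len(nrow(snps))) {
      substr(seqs_b[[snps$gene_id[i]]], snps$cds_pos[i], snps$cds_pos[i]) <-
        snps$alt_base[i]
    }
  }

  if (nrow(truth)) {
    base_now <- substring(seqs[truth$gene_id], truth$cds_pos, truth$cds_pos)
    if (any(base_now != "C")) {
      warning("dropping editing site(s) displaced by a configured SNP")
      truth <- truth[base_now == "C", ]
    }
  }

  paralog_seqs <- list()
  ps <- config$paralog_settings
  if (!is.null(ps)) {
    for (g in ps$target_gene_ids) {
      if (!g %in% ids) stop("paralog target not among genes: ", g)
      s <- strsplit(seqs[[g]], "", fixed = TRUE)[[1]]
      hit <- which(runif(length(s)) < ps$divergence_proportion)
      for (p in hit) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
      paralog_seqs[[g]] <- paste(s, collapse = "")
    }
  }

  structure(
    list(
      gene_set_a = load_gene_set(seqs),
      gene_set_b = load_gene_set(seqs_b),
      truth = truth,
      snps = snps,
      paralog_seqs = paralog_seqs
    ),
    class = "sim_refs"
  )
}

#' Simulate aligned RNA-seq reads over a gene set
#'
#' Draws reads uniformly over start positions. At every true editing site a
#' transcript read shows T with probability `true_extent` (before error);
#' genomic-DNA contamination reads always show the genomic base; paralog
#' reads are copied from the diverged duplicate and recorded against the
#' target gene; sequencing errors substitute uniformly among the three
#' alternative bases. Alignments are written as SAM against CDS coordinates.
#'
#' @param gene_set Reference genes (species A) as from [simulate_references()].
#' @param truth Truth table tibble (`gene_id`, `cds_pos`, `true_extent`).
#' @param config A [simulation_config()].
#' @param sam_path Output SAM path (plain text).
#' @param paralog_seqs Named list of diverged paralog sequences
#'   (as produced by [simulate_references()]), or empty.
#' @return Invisibly, a list with `sam_path`, `n_reads`, and `expected`
#'   (tibble of per-site expected observed extents,
#'   `true_extent * (1 - dna_contamination_fraction)` for non-paralog reads).
#' @export
simulate_reads <- function(gene_set, truth, config,
                           sam_path = tempfile(fileext = ".sam"),
                           paralog_seqs = list()) {
  stopifnot(inherits(gene_set, "gene_set"), inherits(config, "sim_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed + 1L)

  genes <- gene_set$genes
  depth <- rep(config$depth_per_gene, length.out = nrow(genes))
  rl <- config$read_length
  bases <- c("A", "C", "G", "T")

  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", genes$gene_id, genes$length)
  )
  records <- character(0)
  n_total <- 0L

  for (gi in seq_len(nrow(genes))) {
    g <- genes$gene_id[gi]
    L <- genes$length[gi]
    this_rl <- min(rl, L)
    n_starts <- L - this_rl + 1L
    n_reads <- as.integer(round(depth[gi] * n_starts / this_rl))
    if (n_reads == 0L) next
    n_total <- n_total + n_reads

    starts <- sample.int(n_starts, n_reads, replace = TRUE)
    reads <- substring(genes$cds_sequence[gi], starts, starts + this_rl - 1L)

    is_contam <- runif(n_reads) < config$dna_contamination_fraction
    is_paralog <- rep(FALSE, n_reads)
    if (g %in% names(paralog_seqs)) {
      frac <- config$paralog_settings$read_fraction
      is_paralog <- runif(n_reads) < frac
      if (any(is_paralog)) {
        reads[is_paralog] <- substring(paralog_seqs[[g]], starts[is_paralog],
                                       starts[is_paralog] + this_rl - 1L)
      }
    }

    gt <- filter(truth, .data$gene_id == g)
    if (nrow(gt)) {
      editable <- !is_contam & !is_paralog
      for (si in seq_len(nrow(gt))) {
        p <- gt$cds_pos[si]
        off <- p - starts + 1L
        covers <- off >= 1L & off <= this_rl & editable
        idx <- which(covers)
        if (!length(idx)) next
        edited <- idx[runif(length(idx)) < gt$true_extent[si]]
        if (length(edited)) {
          tmp <- reads[edited]
          substring(tmp, off[edited], off[edited]) <- rep("T", length(edited))
          reads[edited] <- tmp
        }
      }
    }

    if (config$sequencing_error_rate > 0) {
      n_err <- rbinom(n_reads, this_rl, config$sequencing_error_rate)
      for (ri in which(n_err > 0L)) {
        pos <- sample.int(this_rl, n_err[ri])
        for (p in pos) {
          cur <- substr(reads[ri], p, p)
          substr(reads[ri], p, p) <- sample(setdiff(bases, cur), 1L)
        }
      }
    }

    qual <- strrep("I", this_rl)
    records <- c(records, sprintf(
      "%s_r%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
      g, seq_len(n_reads), g, starts, this_rl, reads, qual
    ))
  }

  if (n_total == 0L) warning("zero depth everywhere: empty read set")
  writeLines(c(header, records), sam_path)

  expected <- mutate(
    truth,
    expected_extent = .data$true_extent * (1 - config$dna_contamination_fraction)
  )
  invisible(list(sam_path = sam_path, n_reads = n_total, expected = expected))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
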