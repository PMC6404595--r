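test_that("full-length error-free reads give uniform columns on the reference", {
  gene <- strrep("ACGT", 25)
  gs <- make_gene_set(g1 = gene)
  reads <- data.frame(gene_id = "g1", pos = 1L, seq = gene)[rep(1, 10), ]
  sam <- write_test_sam(gs, reads)
  p <- build_pileup(sam, gs)
  expect_equal(nrow(p), 100L)
  expect_true(all(p$coverage == 10L))
  expect_equal(p$cds_pos, 1:100)
  # all counts sit on the reference base
  ref_count <- mapply(function(b, i) p[[b]][i], p$ref, seq_len(nrow(p)))
  expect_true(all(ref_count == 10L))
  # count conservation: counted bases equal aligned bases
  expect_equal(sum(p$coverage), 10L * 100L)
})

test_that("an empty alignment yields all-zero columns", {
  gs <- make_gene_set(g1 = "ATGAAATAA")
  sam <- write_test_sam(gs, data.frame(gene_id = character(), pos = integer(),
                                       seq = character()))
  p <- build_pileup(sam, gs)
  expect_equal(nrow(p), 9L)
  expect_true(all(p$coverage == 0L))
})

test_that("soft clips, deletions and N bases are not counted", {
  gs <- make_gene_set(g1 = "ACGTACGTACGTACGTACGT")  # 20 bp
  reads <- data.frame(
    gene_id = "g1",
    pos = c(11L, 1L, 1L),
    seq = c("AAAAACGTACGTACG",    # 5S10M: first 5 bases clipped, aligns 11-20
            "ACGTACGTAC",         # 4M2D4M over ref 1-10: ref 5-6 deleted
            "NCGTACGTAC"),        # 10M with an N at ref position 1
    cigar = c("5S10M", "4M2D4M", "10M")
  )
  # adjust: the 4M2D4M read has 8 query bases
  reads$seq[2] <- "ACGTCGTA"
  sam <- write_test_sam(gs, reads)
  p <- build_pileup(sam, gs)

  expect_equal(p$coverage[1], 1L)   # N of read 3 not counted; read 2 counts
  expect_equal(p$coverage[2], 2L)   # both reads spanning position 2 count
  expect_equal(p$coverage[5], 1L)   # ref 5-6 deleted in read 2
  expect_equal(p$coverage[6], 1L)
  expect_equal(p$coverage[7], 2L)
  expect_equal(p$coverage[10], 2L)
  expect_equal(p$coverage[11], 1L)  # clipped read aligns only from 11 on
  expect_true(all(p$coverage[12:20] == 1L))
  # conservation: 10 aligned bases (read 1) + 8 (read 2) + 9 non-N (read 3)
  expect_equal(sum(p$coverage), 27L)
})

test_that("reads on references absent from the gene set are skipped with a warning", {
  gs_two <- make_gene_set(g1 = "ATGAAATAA", g2 = "ATGCCCTAA")
  reads <- data.frame(gene_id = c("g1", "g2"), pos = 1L,
                      seq = c("ATGAAATAA", "ATGCCCTAA"))
  sam <- write_test_sam(gs_two, reads)
  gs_one <- make_gene_set(g1 = "ATGAAATAA")
  expect_warning(p <- build_pileup(sam, gs_one), "unknown reference")
  expect_setequal(unique(p$gene_id), "g1")
  expect_equal(sum(p$coverage), 9L)
})

test_that("simulated editing extent is recovered in the pileup column", {
  cfg <- simulation_config(
    n_genes = 1, gene_length_range = c(300, 300), editing_sites_per_gene = 0,
    depth_per_gene = 1000, read_length = 100, sequencing_error_rate = 0,
    seed = 31
  )
  refs <- simulate_references(cfg)
  gene <- refs$gene_set_a$genes
  pos <- which(strsplit(gene$cds_sequence, "")[[1]] == "C")[8]
  truth <- tibble::tibble(gene_id = gene$gene_id, cds_pos = pos,
                          true_extent = 0.4, ref_base = "C")
  rd <- simulate_reads(refs$gene_set_a, truth, cfg)
  p <- build_pileup(rd$sam_path, refs$gene_set_a)
  col <- p[p$cds_pos == pos, ]
  phat <- col$T / col$coverage
  expect_lt(abs(phat - 0.4), 3 * sqrt(0.4 * 0.6 / col$coverage))
})

test_that("mean coverage is the arithmetic mean over all CDS positions", {
  p <- dplyr::bind_rows(
    pileup_row("g1", 1, "A", A = 10),
    pileup_row("g1", 2, "C", C = 10),
    pileup_row("g1", 3, "G", G = 10)
  )
  expect_equal(mean_coverage(p)$mean_coverage, 10)

  p2 <- dplyr::bind_rows(
    pileup_row("g1", 1, "A"),
    pileup_row("g1", 2, "C", C = 20)
  )
  expect_equal(mean_coverage(p2)$mean_coverage, 10)

  # uniform read placement: interior mean near the target depth
  cfg <- simulation_config(
    n_genes = 1, gene_length_range = c(600, 600), editing_sites_per_gene = 0,
    depth_per_gene = 50, read_length = 50, sequencing_error_rate = 0, seed = 8
  )
  refs <- simulate_references(cfg)
  rd <- simulate_reads(refs$gene_set_a, refs$truth, cfg)
  p3 <- build_pileup(rd$sam_path, refs$gene_set_a)
  interior <- p3[p3$cds_pos >= 50 & p3$cds_pos <= 551, ]
  expect_lt(abs(mean(interior$coverage) - 50) / 50, 0.1)
})
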