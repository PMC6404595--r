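test_that("references are deterministic given the seed", {
  cfg <- simulation_config(n_genes = 2, seed = 11)
  r1 <- simulate_references(cfg)
  r2 <- simulate_references(cfg)
  expect_identical(r1$gene_set_a$genes, r2$gene_set_a$genes)
  expect_identical(r1$truth, r2$truth)

  s1 <- tempfile(fileext = ".sam"); s2 <- tempfile(fileext = ".sam")
  simulate_reads(r1$gene_set_a, r1$truth, cfg, sam_path = s1)
  simulate_reads(r2$gene_set_a, r2$truth, cfg, sam_path = s2)
  expect_identical(readLines(s1), readLines(s2))
})

test_that("species B carries exactly the configured SNPs", {
  snp <- data.frame(gene_id = "gene01", cds_pos = 146,
                    ref_base = "C", alt_base = "T")
  cfg <- simulation_config(n_genes = 2, species_b_snps = snp, seed = 3)
  refs <- simulate_references(cfg)
  a <- refs$gene_set_a$genes$cds_sequence[1]
  b <- refs$gene_set_b$genes$cds_sequence[1]
  expect_equal(substr(a, 146, 146), "C")
  expect_equal(substr(b, 146, 146), "T")
  # no other difference anywhere
  expect_equal(substr(a, 1, 145), substr(b, 1, 145))
  expect_equal(substr(a, 147, nchar(a)), substr(b, 147, nchar(b)))
  expect_identical(refs$gene_set_a$genes$cds_sequence[2],
                   refs$gene_set_b$genes$cds_sequence[2])

  # without SNPs the two species are identical
  refs0 <- simulate_references(simulation_config(n_genes = 1, seed = 3))
  expect_identical(refs0$gene_set_a$genes, refs0$gene_set_b$genes)
})

test_that("every editing site sits on a C in species A", {
  refs <- simulate_references(simulation_config(n_genes = 4, seed = 5))
  base <- substring(
    refs$gene_set_a$genes$cds_sequence[
      match(refs$truth$gene_id, refs$gene_set_a$genes$gene_id)],
    refs$truth$cds_pos, refs$truth$cds_pos
  )
  expect_true(all(base == "C"))
  expect_true(all(refs$truth$true_extent >= 0 & refs$truth$true_extent <= 1))
})

test_that("observed T fraction follows the binomial sampling model", {
  cfg <- simulation_config(
    n_genes = 1, gene_length_range = c(300, 300), editing_sites_per_gene = 0,
    depth_per_gene = 10000, read_length = 100, sequencing_error_rate = 0,
    seed = 21
  )
  refs <- simulate_references(cfg)
  gene <- refs$gene_set_a$genes
  pos <- which(strsplit(gene$cds_sequence, "")[[1]] == "C")[10]
  truth <- tibble::tibble(gene_id = gene$gene_id, cds_pos = pos,
                          true_extent = 0.4, ref_base = "C")

  rd <- simulate_reads(refs$gene_set_a, truth, cfg)
  cnt <- count_base_from_sam(rd$sam_path, gene$gene_id, pos)
  phat <- cnt[["t"]] / cnt[["n"]]
  sd3 <- 3 * sqrt(0.4 * 0.6 / cnt[["n"]])
  expect_lt(abs(phat - 0.4), sd3)
})

test_that("genomic contamination dilutes the observed extent", {
  cfg <- simulation_config(
    n_genes = 1, gene_length_range = c(300, 300), editing_sites_per_gene = 0,
    depth_per_gene = 10000, read_length = 100, sequencing_error_rate = 0,
    dna_contamination_fraction = 0.2, seed = 22
  )
  refs <- simulate_references(cfg)
  gene <- refs$gene_set_a$genes
  pos <- which(strsplit(gene$cds_sequence, "")[[1]] == "C")[10]
  truth <- tibble::tibble(gene_id = gene$gene_id, cds_pos = pos,
                          true_extent = 0.5, ref_base = "C")

  rd <- simulate_reads(refs$gene_set_a, truth, cfg)
  expect_equal(rd$expected$expected_extent, 0.4)
  cnt <- count_base_from_sam(rd$sam_path, gene$gene_id, pos)
  phat <- cnt[["t"]] / cnt[["n"]]
  sd3 <- 3 * sqrt(0.4 * 0.6 / cnt[["n"]])
  expect_lt(abs(phat - 0.4), sd3)
})

test_that("full editing without error or contamination shows T on every read", {
  cfg <- simulation_config(
    n_genes = 1, gene_length_range = c(150, 150), editing_sites_per_gene = 0,
    depth_per_gene = 50, read_length = 50, sequencing_error_rate = 0, seed = 9
  )
  refs <- simulate_references(cfg)
  gene <- refs$gene_set_a$genes
  pos <- which(strsplit(gene$cds_sequence, "")[[1]] == "C")[5]
  truth <- tibble::tibble(gene_id = gene$gene_id, cds_pos = pos,
                          true_extent = 1, ref_base = "C")
  rd <- simulate_reads(refs$gene_set_a, truth, cfg)
  cnt <- count_base_from_sam(rd$sam_path, gene$gene_id, pos)
  expect_equal(cnt[["t"]], cnt[["n"]])
  expect_gt(cnt[["n"]], 0)
})

test_that("zero depth yields an empty read set with a warning", {
  cfg <- simulation_config(n_genes = 1, depth_per_gene = 0, seed = 2)
  refs <- simulate_references(cfg)
  expect_warning(
    rd <- simulate_reads(refs$gene_set_a, refs$truth, cfg),
    "empty read set"
  )
  expect_equal(rd$n_reads, 0L)
})
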