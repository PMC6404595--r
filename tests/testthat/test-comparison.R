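# hand-built sites/pileups for the set-algebra cases
toy_sites <- function(pos, gene = "g1") {
  tibble::tibble(gene_id = gene, cds_pos = as.integer(pos), passed = TRUE)
}
toy_pileup <- function(gene_seq, cov, gene = "g1") {
  n <- nchar(gene_seq)
  tibble::tibble(
    gene_id = gene, cds_pos = seq_len(n),
    ref = strsplit(gene_seq, "")[[1]],
    A = 0L, C = as.integer(cov), G = 0L, T = 0L,
    coverage = as.integer(cov)
  )
}

test_that("identical site lists across samples are fully conserved", {
  seq <- strrep("C", 30)
  sites <- toy_sites(c(2, 5, 9, 14, 20))
  pils <- list(s1 = toy_pileup(seq, 50), s2 = toy_pileup(seq, 50))
  u <- build_union(list(s1 = sites, s2 = sites), pils)
  cls <- classify_comparable(u)
  tot <- comparison_totals(cls)
  expect_equal(tot$n_union, 5L)
  expect_equal(tot$n_comparable, 5L)
  expect_equal(tot$n_conserved, 5L)
})

test_that("union and conserved sets follow set algebra", {
  seq <- strrep("C", 30)
  pils <- list(a = toy_pileup(seq, 40), b = toy_pileup(seq, 40))
  u <- build_union(list(a = toy_sites(c(1, 2)), b = toy_sites(c(2, 3))), pils)
  cls <- classify_comparable(u)
  expect_equal(nrow(cls), 3L)
  expect_equal(cls$cds_pos[cls$conserved], 2L)
  # order of samples does not change the union
  u2 <- build_union(list(b = toy_sites(c(2, 3)), a = toy_sites(c(1, 2))), pils)
  expect_equal(dplyr::arrange(u2, cds_pos)$cds_pos, u$cds_pos)
})

test_that("a site under-covered in any sample is not comparable", {
  seq <- strrep("C", 10)
  pils <- list(s1 = toy_pileup(seq, 12), s2 = toy_pileup(seq, 9),
               s3 = toy_pileup(seq, 50), s4 = toy_pileup(seq, 40))
  sites <- toy_sites(5)
  u <- build_union(list(s1 = sites, s2 = sites, s3 = sites, s4 = sites), pils)
  cls <- classify_comparable(u, coverage_gate = 10)
  expect_false(cls$comparable)
  expect_false(cls$conserved)
})

test_that("conserved sites recover the shared truth in a 4-sample simulation", {
  cfg <- simulation_config(
    n_genes = 3, gene_length_range = c(360, 360), editing_sites_per_gene = 6,
    true_extent_range = c(0.3, 0.9), depth_per_gene = 120, read_length = 90,
    sequencing_error_rate = 0.001, seed = 61
  )
  refs <- simulate_references(cfg)
  # interior sites only: uniform placement thins coverage at CDS ends
  truth <- refs$truth[refs$truth$cds_pos >= 90 & refs$truth$cds_pos <= 271, ]

  samples <- list()
  pils <- list()
  for (i in 1:4) {
    cfg_i <- simulation_config(
      n_genes = 3, gene_length_range = c(360, 360), editing_sites_per_gene = 6,
      depth_per_gene = 120, read_length = 90, sequencing_error_rate = 0.001,
      seed = 61 + i
    )
    rd <- simulate_reads(refs$gene_set_a, refs$truth, cfg_i)
    p <- build_pileup(rd$sam_path, refs$gene_set_a)
    pils[[paste0("s", i)]] <- p
    samples[[paste0("s", i)]] <- call_editing_sites(p)
  }
  u <- build_union(samples, pils)
  cls <- classify_comparable(u)
  tot <- comparison_totals(cls)
  expect_lte(tot$n_conserved, tot$n_comparable)
  expect_lte(tot$n_comparable, tot$n_union)

  conserved <- cls[cls$conserved, c("gene_id", "cds_pos")]
  expect_true(all(
    paste(truth$gene_id, truth$cds_pos) %in%
      paste(conserved$gene_id, conserved$cds_pos)
  ))
  # conserved equals the intersection of called sets within the gated set
  called_cols <- grep("^called_", names(cls), value = TRUE)
  inter <- cls$comparable & Reduce(`&`, lapply(called_cols, function(cc) cls[[cc]]))
  expect_equal(cls$conserved, inter)
})

test_that("gene summaries report counts and densities per kb of CDS", {
  expect_message(
    gs <- make_gene_set(rpl16 = strrep("C", 417), other = strrep("A", 300)),
    NA
  )
  sites <- toy_sites(c(108, 110, 214, 383, 389), gene = "rpl16")
  s <- gene_summaries(sites, gs)
  expect_equal(s$n_sites[s$gene_id == "rpl16"], 5L)
  expect_equal(s$density_sites_per_kb[s$gene_id == "rpl16"], 12)
  expect_equal(s$n_sites[s$gene_id == "other"], 0L)
  expect_equal(s$density_sites_per_kb[s$gene_id == "other"], 0)
})

test_that("mismatched references across samples are a hard error", {
  pils <- list(a = toy_pileup(strrep("C", 10), 20),
               b = toy_pileup(strrep("G", 10), 20))
  sites <- toy_sites(5)
  expect_error(build_union(list(a = sites, b = sites), pils),
               "same references")
})
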