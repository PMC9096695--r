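test_that("size filter applies the >= 50 kb convention at the boundary", {
  calls <- dplyr::bind_rows(
    toy_call("A", start = 0, end = 49999),
    toy_call("B", start = 0, end = 50000)
  )
  kept <- filter_cnvs(calls, min_size_bp = 5e4)
  expect_equal(kept$sample_id, "B")
})

test_that("size filter matches a brute-force filter on a mixed fixture", {
  set.seed(7)
  lens <- c(sample(1000:49999, 7), sample(50000:200000, 13))
  calls <- toy_call(sample_id = sprintf("S%02d", 1:20), start = 0,
                    end = lens)
  kept <- filter_cnvs(calls, min_size_bp = 5e4)
  expect_equal(nrow(kept), sum(lens >= 5e4))
  expect_setequal(kept$sample_id, calls$sample_id[calls$end - calls$start >= 5e4])
})

test_that("chrX is dropped by default and kept on request; chrY/chrM always dropped; QC failures dropped", {
  calls <- dplyr::bind_rows(
    toy_call("A", chrom = "chr1", end = 60000),
    toy_call("B", chrom = "chrX", end = 60000),
    toy_call("C", chrom = "chrY", end = 60000),
    toy_call("D", chrom = "chrM", end = 60000),
    toy_call("E", chrom = "chr2", end = 60000)
  )
  calls$qc_pass[5] <- FALSE
  expect_equal(filter_cnvs(calls)$sample_id, "A")
  expect_setequal(filter_cnvs(calls, include_chrX = TRUE)$sample_id,
                  c("A", "B"))
})

test_that("malformed coordinates raise a validation error naming the record", {
  calls <- toy_call("BADSAMPLE", start = 500, end = 500)
  expect_error(filter_cnvs(calls), "BADSAMPLE",
               class = "cnvrisk_validation_error")
})

test_that("gene containment handles empty, coextensive, and oracle cases", {
  genes <- toy_genes()
  # intergenic CNV
  expect_equal(nrow(genes_in_cnv(list(chrom = "chr1", start = 1000, end = 1500),
                                 genes)), 0)
  # exactly coextensive with one gene
  hit <- genes_in_cnv(list(chrom = "chr1", start = 100, end = 300), genes)
  expect_equal(hit$gene_id, "G1")
  # unknown chromosome
  expect_equal(nrow(genes_in_cnv(list(chrom = "chr9", start = 0, end = 1e6),
                                 genes)), 0)
  # partially overlapped gene only counts under the any-overlap rule
  part <- list(chrom = "chr1", start = 200, end = 1000)
  expect_equal(genes_in_cnv(part, genes)$gene_id, "G2")
  expect_setequal(genes_in_cnv(part, genes, rule = "any")$gene_id,
                  c("G1", "G2"))
})

test_that("per-CNV gene lists match the all-pairs containment oracle on a random fixture", {
  fx <- random_fixture(n_genes = 1000, n_cnvs = 200)
  for (i in seq_len(nrow(fx$calls))) {
    cnv <- fx$calls[i, ]
    expect_identical(genes_in_cnv(cnv, fx$genes)$gene_id,
                     bf_genes_in_cnv(cnv, fx$genes)$gene_id)
  }
})

test_that("single-gene deletion arithmetic is exact and duplication channel stays zero", {
  genes <- tibble::tibble(gene_id = "G1", chrom = "chr1", start = 100L,
                          end = 300L, pHI = 0.8, pTS = 0.4, pLI = 0.9,
                          LOEUF = 0.5)
  prof <- score_samples(toy_call("S1", start = 0, end = 1000), genes)
  expect_equal(prof$del_sum_pHI, 0.8)
  expect_equal(prof$del_sum_pLI, 0.9)
  expect_equal(prof$del_sum_invLOEUF, 2.0)
  expect_equal(prof$del_n_genes, 1)
  expect_equal(prof$del_total_size, 1000)
  expect_true(all(as.matrix(prof[grep("^dup_", names(prof))]) == 0))
})

test_that("samples with no calls receive an all-zero profile and stay in the cohort", {
  genes <- toy_genes()
  prof <- score_samples(toy_call("S1", end = 1000), genes,
                        samples = c("S1", "S2", "S3"))
  expect_equal(nrow(prof), 3)
  z <- prof[prof$sample_id == "S2", -1]
  expect_true(all(as.matrix(z) == 0))
})

test_that("full profiles equal the brute-force oracle on a mixed random fixture", {
  fx <- random_fixture(n_genes = 1000, n_cnvs = 300, seed = 11)
  samples <- sort(unique(fx$calls$sample_id))
  prof <- score_samples(fx$calls, fx$genes, samples = samples)
  bf <- bf_profile(fx$calls, fx$genes, samples)
  expect_equal(as.data.frame(prof[names(bf)]), as.data.frame(bf),
               tolerance = 1e-12)
})

test_that("duplicate records are dropped with a warning", {
  calls <- dplyr::bind_rows(toy_call("S1"), toy_call("S1"))
  expect_warning(prof <- score_samples(calls, toy_genes()), "duplicate")
  expect_equal(prof$del_total_size, 1000)
})

test_that("overlapping same-state calls are merged before scoring", {
  genes <- toy_genes()
  calls <- dplyr::bind_rows(
    toy_call("S1", start = 0, end = 600),
    toy_call("S1", start = 400, end = 1000)
  )
  prof <- score_samples(calls, genes)
  expect_equal(prof$del_total_size, 1000)  # union, not 1200
  expect_equal(prof$del_n_genes, 2)        # G1 and G2 once each
})

test_that("profiles are additive over disjoint call sets (pre-transform)", {
  genes <- toy_genes()
  a <- toy_call("S1", start = 0, end = 1000)
  b <- toy_call("S1", chrom = "chr2", start = 0, end = 1000)
  pa <- score_samples(a, genes)
  pb <- score_samples(b, genes)
  pab <- score_samples(dplyr::bind_rows(a, b), genes)
  for (col in setdiff(names(pab), "sample_id")) {
    expect_equal(pab[[col]], pa[[col]] + pb[[col]], info = col)
  }
})

test_that("adding a genic deletion never decreases deletion sums; channels are separated", {
  genes <- toy_genes()
  base <- dplyr::bind_rows(
    toy_call("S1", start = 0, end = 1000),
    toy_call("S1", chrom = "chr2", start = 50, end = 500, type = "duplication")
  )
  more <- dplyr::bind_rows(base, toy_call("S1", start = 1900, end = 2600))
  p0 <- score_samples(base, genes)
  p1 <- score_samples(more, genes)
  del_cols <- grep("^del_", names(p0), value = TRUE)
  expect_true(all(p1[del_cols] >= p0[del_cols]))
  # perturbing the duplication channel leaves deletion fields unchanged
  perturbed <- base
  perturbed$start[perturbed$type == "duplication"] <- 60
  p2 <- score_samples(perturbed, genes)
  expect_equal(p2[del_cols], p0[del_cols])
})

test_that("transforms preserve zero, match the closed form, and preserve rank order", {
  prof <- score_samples(toy_call("S1")[0, ], toy_genes(), samples = "S1")
  tr <- transform_scores(prof)
  expect_equal(tr$del_log_pLI, 0)
  expect_equal(tr$del_pHI_gt0, 0)

  prof$del_sum_pLI <- exp(1) - 1
  expect_equal(transform_scores(prof)$del_log_pLI, 1)

  set.seed(3)
  p <- score_samples(toy_call("S1")[0, ], toy_genes(),
                     samples = sprintf("S%03d", 1:100))
  p$del_sum_invLOEUF <- rexp(100, 0.5)
  p$del_sum_pHI <- rexp(100)
  tr <- transform_scores(p)
  expect_equal(order(tr$del_log_invLOEUF), order(p$del_sum_invLOEUF))
  expect_equal(as.numeric(p$del_sum_pHI > 0), tr$del_pHI_gt0)
})

test_that("pathogenic exclusion follows the reciprocal-overlap rule", {
  regions <- tibble::tibble(chrom = "chr1", start = 0L, end = 100000L,
                            type = "deletion")
  # identical call -> excluded
  same <- toy_call("S1", start = 0, end = 100000)
  res <- exclude_pathogenic(same, regions)
  expect_equal(res$excluded_samples, "S1")
  expect_equal(nrow(res$calls), 0)

  # overlap fractions 0.3 and 0.6 against threshold 0.5: only 0.6 excluded
  partial <- dplyr::bind_rows(
    toy_call("LOW", start = 70000, end = 170000),   # overlap 30k / 100k = 0.3
    toy_call("HIGH", start = 40000, end = 140000)   # overlap 60k / 100k = 0.6
  )
  res2 <- exclude_pathogenic(partial, regions, reciprocal_overlap = 0.5)
  expect_equal(res2$excluded_samples, "HIGH")
  expect_equal(res2$calls$sample_id, "LOW")

  # copy-state must match
  dup <- toy_call("S9", start = 0, end = 100000, type = "duplication")
  expect_equal(exclude_pathogenic(dup, regions)$excluded_samples, character())

  # empty region list: warning + identity
  expect_warning(res3 <- exclude_pathogenic(same, regions[0, ]), "Empty")
  expect_equal(res3$calls, same)
})
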