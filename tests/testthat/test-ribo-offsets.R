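# frame fractions, metagene offset inference and A-site assignment

simple_cds <- function() {
  data.frame(gene = "g1", cds_start = 100L, cds_end = 400L,
             stringsAsFactors = FALSE)
}

test_that("frame fractions follow the 5'-end position definition", {
  cds <- simple_cds()
  # all 5' ends on codon starts: frame0 = 1
  r <- data.frame(gene = "g1", pos5 = 100L + 3L * (0:99), length = 28L)
  ff <- frame_fractions(r, cds)
  expect_equal(ff$frame0, 1)
  expect_equal(ff$frame1 + ff$frame2, 0)
  # uniform 5' ends: about a third in each frame
  set.seed(1)
  r <- data.frame(gene = "g1", pos5 = sample(100:399, 9000, replace = TRUE),
                  length = 28L)
  ff <- frame_fractions(r, cds)
  expect_true(all(abs(c(ff$frame0, ff$frame1, ff$frame2) - 1 / 3) < 0.02))
  expect_error(frame_fractions(data.frame(gene = "g1", pos5 = 5L,
                                          length = 28L), cds),
               "no reads")
})

test_that("frame fidelity is recovered as the frame-0 fraction", {
  # offset 12 is a multiple of 3, so true-frame 5' ends sit on frame 0
  cfg <- sim_config(n_genes = 30, n_onco = 5, n_tsg = 5,
                    offset_by_length = c("28" = 12L), frame_fidelity = 0.9,
                    reads_per_length = 10000, seed = 3)
  set.seed(cfg$seed)
  genes <- simulate_genes(cfg)
  reads <- simulate_rpf_reads(cfg, genes$cds)
  ff <- frame_fractions(reads, genes$cds)
  se <- sqrt(0.9 * 0.1 / ff$n)
  expect_lt(abs(ff$frame0 - 0.9), 4 * se)
})

test_that("metagene peak position gives the P-site offset, ties to smaller", {
  cds <- simple_cds()
  peak <- function(rel, n) {
    data.frame(gene = "g1", pos5 = 100L + rel, length = 28L)[rep(1, n), ]
  }
  # single clean peak 12 nt upstream of the start codon
  off <- infer_psite_offsets(peak(-12L, 300), cds, min_reads = 100)
  expect_equal(off$offset, 12L)
  expect_true(off$qc_pass)
  # two equal peaks at 12 and 13: the smaller offset wins
  off <- infer_psite_offsets(rbind(peak(-12L, 200), peak(-13L, 200)), cds,
                             min_reads = 100)
  expect_equal(off$offset, 12L)
  # too few reads: flagged; all lengths failing is an error
  expect_error(infer_psite_offsets(peak(-12L, 50), cds, min_reads = 100),
               "calibration failed")
})

test_that("programmed per-length offsets are recovered exactly", {
  cfg <- sim_config(n_genes = 60, n_onco = 15, n_tsg = 15,
                    offset_by_length = c("28" = 12L, "29" = 12L,
                                         "30" = 13L, "31" = 13L),
                    frame_fidelity = 0.9, reads_per_length = 2000, seed = 13)
  set.seed(cfg$seed)
  genes <- simulate_genes(cfg)
  reads <- simulate_rpf_reads(cfg, genes$cds)
  off <- infer_psite_offsets(reads, genes$cds)
  expect_identical(off$offset[match(28:31, off$length)],
                   c(12L, 12L, 13L, 13L))
  expect_true(all(off$qc_pass))
  expect_true(all(off$qc_warn == ""))
})

test_that("A-site interval arithmetic matches the offset definition", {
  offs <- data.frame(length = c(28L, 31L), offset = c(12L, 13L),
                     qc_pass = c(TRUE, TRUE))
  iv <- asite_interval(c(100L, 0L, 200L), c(28L, 28L, 31L), offs)
  expect_equal(iv$start, c(115L, 15L, 216L))
  expect_equal(iv$end, c(118L, 18L, 219L))
  # unknown or flagged lengths give NA
  offs$qc_pass[2] <- FALSE
  iv <- asite_interval(c(200L, 10L), c(31L, 30L), offs)
  expect_true(all(is.na(iv$start)))
})

test_that("A-site counting respects the interval rule and read labels", {
  seqs <- c(g1 = strrep("A", 300))
  offs <- data.frame(length = 28L, offset = 12L, qc_pass = TRUE)
  sites <- data.frame(gene = "g1", pos = 115L)
  mk <- function(pos5, n, allele) {
    data.frame(gene = "g1", pos5 = pos5, length = 28L, sample = "p01",
               condition = "tumor", site_pos = 115L, allele = allele,
               stringsAsFactors = FALSE)[rep(1, n), ]
  }
  # A-site [115,118) when pos5 = 100; P-site covers 115 when pos5 = 102
  reads <- rbind(mk(100L, 10L, "A"), mk(100L, 5L, "G"), mk(102L, 4L, "G"))
  res <- asite_site_counts(reads, offs, sites, seqs)
  expect_equal(res$counts$A, 10L)
  expect_equal(res$counts$G, 5L)   # P-site-only reads contribute nothing
  # out-of-bounds and flagged lengths are skipped and counted
  reads2 <- rbind(mk(100L, 2L, "A"),
                  data.frame(gene = "g1", pos5 = 290L, length = 28L,
                             sample = "p01", condition = "tumor",
                             site_pos = NA_integer_,
                             allele = NA_character_),
                  data.frame(gene = "g1", pos5 = 100L, length = 30L,
                             sample = "p01", condition = "tumor",
                             site_pos = NA_integer_,
                             allele = NA_character_))
  res2 <- asite_site_counts(reads2, offs, sites, seqs)
  expect_equal(unname(res2$skipped), c(1L, 1L))
  expect_equal(res2$counts$A, 2L)
})

test_that("each retained read covers exactly three A-site positions", {
  cfg <- sim_config(n_genes = 20, n_onco = 5, n_tsg = 5,
                    reads_per_length = 300, seed = 23)
  ds <- generate_dataset(cfg)
  off <- infer_psite_offsets(ds$reads, ds$cds, min_reads = 100)
  # query every position of every transcript: total counted bases must be
  # exactly 3x the number of retained in-bounds reads
  sites <- do.call(rbind, lapply(seq_len(nrow(ds$cds)), function(i) {
    data.frame(gene = ds$cds$gene[i], pos = seq_len(ds$cds$tx_len[i]) - 1L)
  }))
  res <- asite_site_counts(ds$reads, off, sites, ds$seqs)
  n_used <- nrow(ds$reads) - sum(res$skipped)
  expect_equal(sum(res$counts[, c("A", "C", "G", "T")]), 3L * n_used)
})
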