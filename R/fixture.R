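# A tiny deterministic dataset with exact, hand-specified counts. Used in
# documentation and unit tests; no sampling is involved.
#
# Three genes (g1 oncogene, g2 TSG, g3 other), six synonymous variants at
# third codon positions. Sites s1 and s2 pass the strict tumor-specific
# filter; the other four each violate one (or two) of its five criteria:
#   s3  normal RNA coverage 4          (fails criterion 1 and the loose tier)
#   s4  derived read in normal A-site  (fails criterion 2)
#   s5  tumor derived allele count 2   (fails criteria 3 and 4)
#   s6  present in the known-SNP panel (fails criterion 5)

#' Worked example dataset
#'
#' Returns a hand-specified 3-gene, 6-variant tumor/normal dataset with
#' exact counts and known expected outcomes at every pipeline stage,
#' including designed RPF reads whose A-site counting reproduces the
#' site-count table, and gene-level counts with round-number RPKM and TE
#' values (with library sizes of 1e6: TE normal = 0.5/2/1, TE tumor =
#' 1/1/1 for g1/g2/g3).
#'
#' @return a `synoribo_dataset` with an extra `offsets` element (the
#'   designed P-site offset table, all fixture reads are 28 nt with
#'   offset 12) and `lib_sizes` (the library sizes of the worked TE
#'   example).
#' @examples
#' fx <- worked_fixture()
#' v <- polarize_sites(fx$site_counts)
#' sum(strict_filter(v, fx$panel))  # the 2 designed strict-pass sites
#' @export
worked_fixture <- function() {
  utr5 <- strrep("AC", 15)
  utr3 <- strrep("GT", 15)
  make_cds <- function(n_codons, special) {
    codons <- c("ATG", rep("GAC", n_codons - 2L), "TAA")
    for (idx in names(special)) codons[as.integer(idx) + 1L] <- special[[idx]]
    paste(codons, collapse = "")
  }
  seqs <- c(
    g1 = paste0(utr5, make_cds(200, list("10" = "TTT", "40" = "AAA")), utr3),
    g2 = paste0(utr5, make_cds(100, list("20" = "TTT", "50" = "GGG")), utr3),
    g3 = paste0(utr5, make_cds(100, list("30" = "CCC", "60" = "GCA")), utr3)
  )
  cds <- data.frame(
    gene = c("g1", "g2", "g3"),
    tx_len = c(660L, 360L, 360L),
    cds_start = 30L, cds_end = c(630L, 330L, 330L),
    cds_len = c(600L, 300L, 300L),
    stringsAsFactors = FALSE
  )

  sc <- data.frame(
    gene = c("g1", "g1", "g2", "g2", "g3", "g3"),
    pos = c(62L, 152L, 92L, 182L, 122L, 212L),
    ref = c("T", "A", "T", "G", "C", "A"),
    outgroup = c("T", "A", "T", "G", "C", "A"),
    patient = "p01",
    stringsAsFactors = FALSE
  )
  sc <- cbind(sc, empty_counts(6))
  put <- function(sc, row, assay, condition, base, value) {
    sc[row, paste(assay, condition, base, sep = "_")] <- value
    sc
  }
  # s1 g1:62 T>C  strict pass
  sc <- put(sc, 1, "rna", "normal", "T", 25L)
  sc <- put(sc, 1, "rpf", "normal", "T", 22L)
  sc <- put(sc, 1, "rna", "tumor", c("T", "C"), c(30L, 10L))
  sc <- put(sc, 1, "rpf", "tumor", c("T", "C"), c(18L, 7L))
  # s2 g1:152 A>G  strict pass
  sc <- put(sc, 2, "rna", "normal", "A", 40L)
  sc <- put(sc, 2, "rpf", "normal", "A", 30L)
  sc <- put(sc, 2, "rna", "tumor", c("A", "G"), c(24L, 12L))
  sc <- put(sc, 2, "rpf", "tumor", c("A", "G"), c(18L, 6L))
  # s3 g2:92 T>C  normal RNA coverage 4: fails loose and strict (1)
  sc <- put(sc, 3, "rna", "normal", "T", 4L)
  sc <- put(sc, 3, "rpf", "normal", "T", 20L)
  sc <- put(sc, 3, "rna", "tumor", c("T", "C"), c(7L, 5L))
  sc <- put(sc, 3, "rpf", "tumor", c("T", "C"), c(10L, 5L))
  # s4 g2:182 G>A  derived read in normal A-site: fails strict (2)
  sc <- put(sc, 4, "rna", "normal", "G", 25L)
  sc <- put(sc, 4, "rpf", "normal", c("G", "A"), c(22L, 1L))
  sc <- put(sc, 4, "rna", "tumor", c("G", "A"), c(30L, 10L))
  sc <- put(sc, 4, "rpf", "tumor", c("G", "A"), c(20L, 5L))
  # s5 g3:122 C>A  tumor derived count 2: fails strict (3) and (4)
  sc <- put(sc, 5, "rna", "normal", "C", 30L)
  sc <- put(sc, 5, "rpf", "normal", "C", 25L)
  sc <- put(sc, 5, "rna", "tumor", c("C", "A"), c(28L, 2L))
  sc <- put(sc, 5, "rpf", "tumor", c("C", "A"), c(20L, 2L))
  # s6 g3:212 A>C  in the known-SNP panel: fails strict (5)
  sc <- put(sc, 6, "rna", "normal", "A", 30L)
  sc <- put(sc, 6, "rpf", "normal", "A", 25L)
  sc <- put(sc, 6, "rna", "tumor", c("A", "C"), c(25L, 8L))
  sc <- put(sc, 6, "rpf", "tumor", c("A", "C"), c(21L, 5L))

  panel <- data.frame(gene = c("g3", "g1"), pos = c(212L, 10L),
                      ref = c("A", "A"), alt = c("C", "G"),
                      stringsAsFactors = FALSE)

  offsets <- data.frame(length = 28L, offset = 12L, n_reads = NA_integer_,
                        peak_height = NA_integer_, median_bin = NA_real_,
                        qc_pass = TRUE, qc_reason = "",
                        stringsAsFactors = FALSE)

  # designed reads (all 28 nt, offset 12): variant-anchored reads place
  # the A-site over s1/s2 so that A-site counting reproduces the RPF
  # columns of the site-count table; two decoy reads put their P-site
  # (not A-site) on s1 and must not be counted.
  spread <- function(pos, n) pos - 12L - 3L - (seq_len(n) - 1L) %% 3L
  read_block <- function(gene, pos, n, condition, allele) {
    if (n == 0) return(NULL)
    data.frame(gene = gene, pos5 = spread(pos, n), length = 28L,
               sample = "p01", condition = condition,
               site_pos = pos, allele = allele, stringsAsFactors = FALSE)
  }
  start_block <- function(gene, n, rel) {
    data.frame(gene = gene, pos5 = 30L + rel, length = 28L, sample = "p01",
               condition = "tumor", site_pos = NA_integer_,
               allele = NA_character_, stringsAsFactors = FALSE)[rep(1, n), ]
  }
  reads <- rbind(
    read_block("g1", 62L, 22L, "normal", "T"),
    read_block("g1", 62L, 18L, "tumor", "T"),
    read_block("g1", 62L, 7L, "tumor", "C"),
    read_block("g1", 152L, 30L, "normal", "A"),
    read_block("g1", 152L, 18L, "tumor", "A"),
    read_block("g1", 152L, 6L, "tumor", "G"),
    # decoys: P-site on s1, A-site downstream of it
    data.frame(gene = "g1", pos5 = 49L, length = 28L, sample = "p01",
               condition = "tumor", site_pos = 62L, allele = "T",
               stringsAsFactors = FALSE)[rep(1, 2), ],
    # start-codon metagene reads: peak at 12 nt upstream of ATG
    start_block("g1", 40L, -12L), start_block("g2", 40L, -12L),
    start_block("g3", 40L, -12L),
    start_block("g1", 4L, -15L), start_block("g2", 4L, -15L)
  )
  rownames(reads) <- NULL

  gene_counts <- data.frame(
    gene = c("g1", "g2", "g3"), patient = "p01",
    rna_normal = c(660L, 360L, 360L), rna_tumor = c(660L, 360L, 360L),
    rpf_normal = c(330L, 720L, 360L), rpf_tumor = c(660L, 360L, 360L),
    stringsAsFactors = FALSE
  )
  covariates <- data.frame(
    gene = c("g1", "g2", "g3"), length = c(660, 360, 360),
    dn = c(0.1, 0.2, 0.3), expression = c(100, 100, 100),
    gc = vapply(seqs, function(s) {
      b <- strsplit(s, "")[[1]]; mean(b %in% c("G", "C"))
    }, 0),
    stringsAsFactors = FALSE
  )

  truth_variants <- data.frame(
    gene = sc$gene, pos = sc$pos, anc = sc$ref,
    der = c("C", "G", "C", "A", "A", "C"),
    optimality = c("optimal", "optimal", "optimal", "non_optimal",
                   "non_optimal", "optimal"),
    consequence = "synonymous",
    loose_expected = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    strict_expected = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    in_panel = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  truth_genes <- data.frame(
    gene = c("g1", "g2", "g3"), class = c("oncogene", "TSG", "other"),
    te_normal = c(0.5, 2, 1), te_tumor = c(1, 1, 1),
    stringsAsFactors = FALSE
  )

  ds <- list(
    config = NULL,
    cds = cds, seqs = seqs, site_counts = sc, reads = reads,
    panel = panel,
    gene_classes = truth_genes[, c("gene", "class")],
    covariates = covariates, gene_counts = gene_counts,
    truth = list(variants = truth_variants, genes = truth_genes),
    offsets = offsets,
    lib_sizes = list(rna_normal = 1e6, rna_tumor = 1e6,
                     rpf_normal = 1e6, rpf_tumor = 1e6)
  )
  class(ds) <- "synoribo_dataset"
  ds
}
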