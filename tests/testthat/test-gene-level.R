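# SNP density, class enrichment, top genes, RPKM/TE and the regression

test_that("snp density is linear in count and inverse in CDS length", {
  expect_equal(snp_density(3, 1500), 2)
  expect_equal(snp_density(0, 1500), 0)
  expect_equal(snp_density(2, 600), 10 / 3)
  expect_equal(snp_density(6, 1500), 3 * snp_density(2, 1500))
  expect_equal(snp_density(2, 3000), snp_density(2, 1500) / 2)
  expect_error(snp_density(1, 0), "cds_len")
})

test_that("gene summaries count synonymous variants by optimality class", {
  cds <- data.frame(gene = c("g1", "g2"), cds_len = c(600L, 300L))
  v <- data.frame(gene = c("g1", "g1", "g2", "g2", "g2"),
                  anc = c("A", "T", "C", "G", "A"),
                  der = c("G", "C", "A", "T", "T"),
                  consequence = c("synonymous", "synonymous", "synonymous",
                                  "synonymous", "synonymous"),
                  stringsAsFactors = FALSE)
  gs <- gene_mutation_summary(v, cds)
  expect_equal(gs$n_optimal, c(2L, 0L))
  expect_equal(gs$n_nonoptimal, c(0L, 2L))  # A>T is unclassified, not counted
  expect_equal(gs$density_opt, c(1000 * 2 / 600, 0))
  v_bad <- v; v_bad$gene[1] <- "g9"
  expect_error(gene_mutation_summary(v_bad, cds), "g9")
})

test_that("enrichment comparisons report direction and KS p-values", {
  # identical density vectors: D = 0, p = 1
  s <- data.frame(gene = sprintf("g%02d", 1:40),
                  class = rep(c("oncogene", "TSG"), each = 20),
                  cds_len = 900L,
                  n_optimal = rep(1:20, 2), n_nonoptimal = rep(1:20, 2))
  s$density_opt <- snp_density(s$n_optimal, s$cds_len)
  s$density_nonopt <- snp_density(s$n_nonoptimal, s$cds_len)
  en <- class_enrichment(s)
  expect_equal(en$p.value[en$comparison == "optimal_onco_vs_tsg"], 1)
  expect_error(class_enrichment(s[s$class == "TSG", ]), "oncogene")
})

test_that("top genes rank by density with count then id tie-breaks", {
  s <- data.frame(gene = c("g1", "g2", "g3", "g4", "g5"),
                  class = "oncogene", cds_len = c(1000, 400, 2000, 500, 500),
                  n_optimal = c(2L, 2L, 2L, 1L, 1L),
                  n_nonoptimal = 0L)
  s$density_opt <- snp_density(s$n_optimal, s$cds_len)
  s$density_nonopt <- 0
  top <- top_genes(s, "oncogene", "optimal", 3)
  expect_equal(top$gene, c("g2", "g1", "g4"))
  # tie at equal density: higher raw count first
  s2 <- data.frame(gene = c("ga", "gb"), class = "TSG",
                   cds_len = c(2000, 1000), n_optimal = 0L,
                   n_nonoptimal = c(4L, 2L))
  s2$density_opt <- 0
  s2$density_nonopt <- snp_density(s2$n_nonoptimal, s2$cds_len)
  top <- top_genes(s2, "TSG", "non_optimal", 2)
  expect_equal(top$gene, c("ga", "gb"))
  # k larger than the class returns the whole class
  expect_equal(nrow(top_genes(s, "oncogene", "optimal", 50)), 5)
})

test_that("RPKM and TE follow their closed forms and invariances", {
  expect_equal(rpkm(100, 1000, 1e6), 100)
  expect_equal(translation_efficiency(100, 100, 1000, 1e6, 1e6), 1)
  expect_equal(translation_efficiency(200, 50, 1000, 1e6, 1e6), 0.25)
  # scaling all counts and both libraries by k leaves TE unchanged
  k <- 7
  expect_equal(
    translation_efficiency(k * 200, k * 50, 1000, k * 1e6, k * 1e6),
    translation_efficiency(200, 50, 1000, 1e6, 1e6))
  # zero mRNA: undefined
  expect_true(is.na(translation_efficiency(0, 50, 1000, 1e6, 1e6)))
  expect_error(rpkm(-1, 1000, 1e6), "negative")
  expect_error(rpkm(1, 1000, 0), "library_size")
})

test_that("min-max scaling maps to [-1, 1] and rejects constants", {
  x <- c(3, 7, 11)
  expect_equal(range(scale_minmax(x)), c(-1, 1))
  expect_equal(scale_minmax(x)[2], 0)
  expect_error(scale_minmax(rep(2, 5)), "constant")
})

test_that("the regression recovers programmed effects and rejects collinearity", {
  set.seed(91)
  n <- 1000
  d <- data.frame(
    n_optimal = rpois(n, 2), n_nonoptimal = rpois(n, 2),
    length = runif(n, 300, 3000), dn = runif(n, 0, 0.5),
    expression = rlnorm(n, log(100), 0.5), gc = runif(n, 0.3, 0.7))
  d$log2_te_fc <- 0.5 * scale_minmax(d$n_optimal) -
    0.5 * scale_minmax(d$n_nonoptimal) + rnorm(n, 0, 0.25)
  fit <- te_regression(d)
  co <- fit$coefficients
  b <- function(t) co[co$term == t, ]
  expect_gt(b("n_optimal")$estimate, 0)
  expect_lt(b("n_optimal")$p.value, 0.01)
  expect_lt(b("n_nonoptimal")$estimate, 0)
  expect_lt(b("n_nonoptimal")$p.value, 0.01)
  expect_lt(abs(b("n_optimal")$estimate - 0.5), 0.1)
  # the design matrix is scaled to exactly [-1, 1]
  expect_equal(unname(fit$scaling$predictor), names(d)[1:6])
  # response duplicated as a predictor: identity regression up to scale
  d2 <- d
  d2$dup <- d$log2_te_fc
  fit2 <- suppressWarnings(  # perfect fit is the point here
    te_regression(d2, predictors = c("dup", "n_optimal")))
  slope <- diff(range(d2$dup)) / 2   # scaled dup = (y - mid) / slope...
  expect_equal(fit2$coefficients$estimate[fit2$coefficients$term == "dup"],
               slope, tolerance = 1e-8)
  # collinear predictors are named
  d3 <- d
  d3$length2 <- 2 * d3$length
  expect_error(te_regression(d3, predictors = c("length", "length2")),
               "length2")
  expect_error(te_regression(d[1:20, ]), "usable genes")
})

test_that("per-patient TE fold changes average to the gene-level table", {
  gc <- data.frame(gene = rep(c("g1", "g2"), 2),
                   patient = rep(c("p01", "p02"), each = 2),
                   rna_normal = c(100, 200, 100, 200),
                   rna_tumor = c(100, 200, 100, 200),
                   rpf_normal = c(50, 200, 50, 200),
                   rpf_tumor = c(100, 100, 100, 100))
  lengths <- data.frame(gene = c("g1", "g2"), length = c(1000, 1000))
  te <- te_fold_change(gc, lengths)
  # hand computation per patient (identical patients):
  # libraries: rna 300/300, rpf normal 250, rpf tumor 200
  # g1: TE_n = (50/250)/(100/300) = 0.6; TE_t = (100/200)/(100/300) = 1.5
  # g2: TE_n = (200/250)/(200/300) = 1.2; TE_t = (100/200)/(200/300) = 0.75
  expect_equal(te$log2_te_fc[te$gene == "g1"], log2(1.5 / 0.6))
  expect_equal(te$log2_te_fc[te$gene == "g2"], log2(0.75 / 1.2))
  expect_equal(te$te_normal, c(0.6, 1.2))
  expect_equal(te$te_tumor, c(1.5, 0.75))
  expect_equal(te$n_patients, c(2L, 2L))
})
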