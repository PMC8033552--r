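# polarization, the two filter tiers, consequence annotation, spectrum
# and the patient union

make_site <- function(ref, outgroup, rna_tumor = c(A = 0, C = 0, G = 0,
                                                   T = 0),
                      rna_normal = c(A = 0, C = 0, G = 0, T = 0),
                      rpf_normal = c(A = 0, C = 0, G = 0, T = 0),
                      rpf_tumor = c(A = 0, C = 0, G = 0, T = 0),
                      gene = "g1", pos = 100L) {
  d <- data.frame(gene = gene, pos = pos, ref = ref, outgroup = outgroup,
                  patient = "p01", stringsAsFactors = FALSE)
  for (b in c("A", "C", "G", "T")) {
    d[[paste0("rna_normal_", b)]] <- unname(rna_normal[b])
    d[[paste0("rna_tumor_", b)]] <- unname(rna_tumor[b])
    d[[paste0("rpf_normal_", b)]] <- unname(rpf_normal[b])
    d[[paste0("rpf_tumor_", b)]] <- unname(rpf_tumor[b])
  }
  d
}

test_that("polarization follows the outgroup rule", {
  # ref = outgroup, tumor shows ref + one alternative: polarized
  s <- polarize_sites(make_site("A", "A", c(A = 7, C = 0, G = 5, T = 0)))
  expect_equal(s$status, "polarized")
  expect_equal(s$anc, "A")
  expect_equal(s$der, "G")
  # ref != outgroup: non-ancestral, excluded downstream
  s <- polarize_sites(make_site("A", "G", c(A = 7, C = 0, G = 5, T = 0)))
  expect_equal(s$status, "non_ancestral_ref")
  expect_true(is.na(s$der))
  # outgroup N: ancestral state unknowable
  s <- polarize_sites(make_site("A", "N", c(A = 7, C = 0, G = 5, T = 0)))
  expect_equal(s$status, "missing_outgroup")
  # three observed alleles: multiallelic
  s <- polarize_sites(make_site("C", "C", c(A = 1, C = 9, G = 0, T = 2)))
  expect_equal(s$status, "multiallelic")
  # no non-reference base at all
  s <- polarize_sites(make_site("C", "C", c(A = 0, C = 9, G = 0, T = 0)))
  expect_equal(s$status, "monomorphic")
})

test_that("loose filter applies the normal-coverage and heterozygosity rules", {
  base <- function(normal_A, tumor_A, tumor_G) {
    polarize_sites(make_site(
      "A", "A",
      rna_normal = c(A = normal_A, C = 0, G = 0, T = 0),
      rna_tumor = c(A = tumor_A, C = 0, G = tumor_G, T = 0)))
  }
  expect_true(loose_filter(base(10, 7, 5)))
  expect_false(loose_filter(base(4, 7, 5)))    # normal coverage < 5
  expect_false(loose_filter(base(10, 0, 12)))  # 100% derived in tumor
  # a derived read in normal fails "no mutation detected"
  s <- polarize_sites(make_site(
    "A", "A", rna_normal = c(A = 10, C = 0, G = 1, T = 0),
    rna_tumor = c(A = 7, C = 0, G = 5, T = 0)))
  expect_false(loose_filter(s))
  expect_true(loose_filter(s, max_derived_in_normal = 1))
})

test_that("strict filter applies all five criteria", {
  ok <- make_site("A", "A",
                  rna_normal = c(A = 25, C = 0, G = 0, T = 0),
                  rpf_normal = c(A = 22, C = 0, G = 0, T = 0),
                  rna_tumor = c(A = 30, C = 0, G = 10, T = 0),
                  rpf_tumor = c(A = 18, C = 0, G = 7, T = 0))
  expect_true(strict_filter(polarize_sites(ok)))
  # tumor RPF derived count 2 < 3
  low <- ok
  low$rpf_tumor_G <- 2L
  low$rpf_tumor_A <- 20L
  expect_false(strict_filter(polarize_sites(low)))
  # panel membership
  panel <- data.frame(gene = "g1", pos = 100L, ref = "A", alt = "G")
  expect_false(strict_filter(polarize_sites(ok), panel))
  other_panel <- data.frame(gene = "g9", pos = 100L, ref = "A", alt = "G")
  expect_true(strict_filter(polarize_sites(ok), other_panel))
})

test_that("every strict-pass site also passes the loose filter", {
  cfg <- sim_config(rna_depth = 22, base_density = 0.5, seed = 7)
  set.seed(cfg$seed)
  sites <- rbind(make_truth_sites(300, "optimal"),
                 make_truth_sites(300, "non_optimal"))
  sites$gene <- sprintf("s%04d", seq_len(nrow(sites)))
  v <- polarize_sites(simulate_site_counts(cfg, sites))
  lo <- loose_filter(v)
  st <- strict_filter(v)
  expect_true(all(lo[st]))
  expect_gt(sum(st), 0)
  expect_gt(sum(lo & !st), 0)
})

test_that("strict filter agrees with the brute-force oracle on random sites", {
  cfg <- sim_config(rna_depth = 22, base_density = 0.5, seed = 17)
  set.seed(cfg$seed)
  sites <- rbind(make_truth_sites(500, "optimal"),
                 make_truth_sites(500, "non_optimal"))
  sites$gene <- sprintf("s%04d", seq_len(nrow(sites)))
  sites$outgroup[runif(1000) < 0.05] <- "N"
  sc <- simulate_site_counts(cfg, sites)
  in_panel <- runif(1000) < 0.2
  panel <- data.frame(gene = sc$gene[in_panel], pos = sc$pos[in_panel],
                      ref = sc$ref[in_panel], alt = "G")
  v <- polarize_sites(sc)
  expect_equal(strict_filter(v, panel), brute_force_strict(sc, panel))
  # all panel members are excluded
  expect_false(any(strict_filter(v, panel)[in_panel]))
})

test_that("consequence annotation translates both codons", {
  # one gene: 10 nt UTR5, CDS ATG TTT GAC TAA, 8 nt UTR3
  seqs <- c(gx = paste0(strrep("A", 10), "ATGTTTGACTAA", strrep("G", 8)))
  cds <- data.frame(gene = "gx", cds_start = 10L, cds_end = 22L)
  site <- function(pos, ref, der) {
    s <- make_site(ref, ref, setNames(c(10, 0, 0, 0) , c(ref,
           setdiff(c("A", "C", "G", "T"), ref))), gene = "gx", pos = pos)
    s[[paste0("rna_tumor_", der)]] <- 5
    s[[paste0("rna_tumor_", ref)]] <- 10
    polarize_sites(s)
  }
  ann <- function(pos, ref, der) {
    annotate_variants(site(pos, ref, der), cds, seqs)$consequence
  }
  expect_equal(ann(15L, "T", "C"), "synonymous")  # TTT -> TTC (Phe)
  expect_equal(ann(15L, "T", "A"), "missense")    # TTT -> TTA (Phe -> Leu)
  expect_equal(ann(14L, "T", "A"), "missense")    # TTT -> TAT (Phe -> Tyr)
  expect_equal(ann(20L, "A", "G"), "nonsense")    # stop codon TAA -> TGA
  expect_equal(ann(4L, "A", "G"), "utr5")
  expect_equal(ann(22L, "G", "A"), "utr3")
  bad_cds <- data.frame(gene = "gx", cds_start = 10L, cds_end = 21L)
  expect_error(annotate_variants(site(15L, "T", "C"), bad_cds, seqs),
               "malformed")
})

test_that("spectrum fractions follow the definition", {
  v <- data.frame(status = "polarized",
                  anc = c("A", "A", "A", "A"),
                  der = c("G", "G", "G", "C"), stringsAsFactors = FALSE)
  sp <- mutation_spectrum(v)
  expect_equal(sp$transition_fraction, 0.75)
  # all 12 classes equally represented: transitions are 4 of 12
  g <- expand.grid(a = c("A", "C", "G", "T"), d = c("A", "C", "G", "T"),
                   stringsAsFactors = FALSE)
  g <- g[g$a != g$d, ]
  sp <- mutation_spectrum(data.frame(status = "polarized", anc = g$a,
                                     der = g$d))
  expect_equal(sp$transition_fraction, 1 / 3)
  expect_error(mutation_spectrum(data.frame(status = "monomorphic",
                                            anc = "A", der = "G")),
               "no polarized")
})

test_that("patient union keys on gene, position and derived allele", {
  v <- data.frame(
    gene = c("g1", "g1", "g1", "g2", "g2"),
    pos = c(10L, 10L, 10L, 20L, 30L),
    der = c("G", "G", "T", "C", "C"),
    status = "polarized",
    patient = c("p01", "p02", "p02", "p01", "p02"),
    stringsAsFactors = FALSE
  )
  m <- merge_patients(v)
  expect_equal(nrow(m), 4)  # same site, two derived alleles: 2 entries
  g10 <- m[m$gene == "g1" & m$pos == 10 & m$der == "G", ]
  expect_equal(g10$patients, "p01;p02")
  expect_equal(g10$n_patients, 2L)
  # disjoint sets of sizes 4 and 5 union to 9 keys
  a <- data.frame(gene = "g1", pos = 1:4, der = "G", patient = "p01")
  b <- data.frame(gene = "g1", pos = 11:15, der = "G", patient = "p02")
  expect_equal(nrow(merge_patients(rbind(a, b))), 9)
})
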