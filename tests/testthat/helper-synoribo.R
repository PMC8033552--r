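# shared test helpers: small ground-truth site builders and an
# independent brute-force re-implementation of the strict filter used as
# an oracle against the vectorized implementation.

make_truth_sites <- function(n, optimality = "optimal",
                             outgroup_mismatch = FALSE) {
  ad <- switch(optimality,
               optimal = c("A", "G"),
               non_optimal = c("G", "A"),
               unclassified = c("A", "T"))
  data.frame(
    gene = sprintf("s%04d", seq_len(n)),
    pos = 100L,
    anc = ad[1], der = ad[2],
    outgroup = if (outgroup_mismatch) ad[2] else ad[1],
    optimality = optimality,
    stringsAsFactors = FALSE
  )
}

# literal row-by-row application of the five strict-filter criteria,
# written independently of the package's vectorized implementation
brute_force_strict <- function(site_counts, panel = NULL, min_cov = 20,
                               min_allele = 3) {
  panel_keys <- if (is.null(panel)) character() else
    paste(panel$gene, panel$pos)
  bases <- c("A", "C", "G", "T")
  pass <- logical(nrow(site_counts))
  for (i in seq_len(nrow(site_counts))) {
    row <- site_counts[i, ]
    ref <- row$ref
    if (row$outgroup == "N" || row$outgroup != ref) next
    tum_rna <- sapply(bases, function(b) row[[paste0("rna_tumor_", b)]])
    observed_nonref <- bases[bases != ref & tum_rna > 0]
    if (length(observed_nonref) != 1) next
    der <- observed_nonref
    g <- function(assay, cond, b) row[[paste(assay, cond, b, sep = "_")]]
    cov <- function(assay, cond) sum(sapply(bases, g, assay = assay,
                                            cond = cond))
    c1 <- cov("rna", "normal") >= min_cov && g("rna", "normal", der) == 0
    c2 <- cov("rpf", "normal") >= min_cov && g("rpf", "normal", der) == 0
    c3 <- cov("rna", "tumor") >= min_cov &&
      g("rna", "tumor", ref) >= min_allele &&
      g("rna", "tumor", der) >= min_allele
    c4 <- cov("rpf", "tumor") >= min_cov &&
      g("rpf", "tumor", ref) >= min_allele &&
      g("rpf", "tumor", der) >= min_allele
    c5 <- !(paste(row$gene, row$pos) %in% panel_keys)
    pass[i] <- c1 && c2 && c3 && c4 && c5
  }
  pass
}
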