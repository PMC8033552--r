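# Variant polarization against the outgroup, tumor-specific filtering,
# consequence annotation and mutation-spectrum summaries.
#
# A site is "polarized" when the reference base equals the outgroup base:
# the reference/outgroup base is then the ancestral allele and the single
# non-reference base observed in tumor RNA is the derived allele. Sites
# where reference != outgroup are non-ancestral and excluded; outgroup N
# means the ancestral state is unknowable; two or more distinct
# non-reference bases in tumor RNA make the site multiallelic.

#' Polarize variant sites against the outgroup base
#'
#' @param counts site-count data.frame (columns `gene`, `pos`, `ref`,
#'   `outgroup`, `patient` and the 16 assay/condition/base counts; see
#'   [simulate_site_counts()] for the schema).
#' @return `counts` with added columns `status` (`polarized`,
#'   `non_ancestral_ref`, `missing_outgroup`, `multiallelic`,
#'   `monomorphic`), `anc` and `der` (`NA` unless polarized).
#' @examples
#' fx <- worked_fixture()
#' table(polarize_sites(fx$site_counts)$status)
#' @export
polarize_sites <- function(counts) {
  if (!all(c("ref", "outgroup") %in% names(counts))) {
    stop("site counts must carry 'ref' and 'outgroup' bases")
  }
  n <- nrow(counts)
  rna_t <- as.matrix(counts[, paste("rna", "tumor", BASES, sep = "_")])
  ref_i <- match(counts$ref, BASES)
  nonref_n <- vapply(seq_len(n), function(i) {
    sum(rna_t[i, -ref_i[i]] > 0)
  }, 0L)
  der <- vapply(seq_len(n), function(i) {
    obs <- which(rna_t[i, ] > 0)
    obs <- setdiff(obs, ref_i[i])
    if (length(obs) == 1) BASES[obs] else NA_character_
  }, "")
  status <- ifelse(counts$outgroup == "N", "missing_outgroup",
            ifelse(counts$outgroup != counts$ref, "non_ancestral_ref",
            ifelse(nonref_n == 0, "monomorphic",
            ifelse(nonref_n > 1, "multiallelic", "polarized"))))
  counts$status <- status
  counts$anc <- ifelse(status == "polarized", counts$ref, NA_character_)
  counts$der <- ifelse(status == "polarized", der, NA_character_)
  counts
}

#' Loose tumor-specific filter
#'
#' A polarized site passes when the normal RNA coverage is at least
#' `min_normal_cov` with at most `max_derived_in_normal` derived-allele
#' reads, and the tumor RNA shows both alleles (derived fraction strictly
#' below 1, i.e. the site is heterozygous, not fixed).
#'
#' @param variants polarized site table from [polarize_sites()].
#' @param min_normal_cov minimum normal RNA coverage (default 5).
#' @param max_derived_in_normal maximum derived reads tolerated in normal
#'   tissue (default 0: "no mutation detected").
#' @return logical vector, `FALSE` for non-polarized rows.
#' @export
loose_filter <- function(variants, min_normal_cov = 5,
                         max_derived_in_normal = 0) {
  ok <- variants$status == "polarized"
  out <- rep(FALSE, nrow(variants))
  if (!any(ok)) return(out)
  v <- variants[ok, , drop = FALSE]
  norm_cov <- coverage_of(v, "rna", "normal")
  norm_der <- base_count(v, "rna", "normal", v$der)
  tum_anc <- base_count(v, "rna", "tumor", v$anc)
  tum_der <- base_count(v, "rna", "tumor", v$der)
  out[ok] <- norm_cov >= min_normal_cov &
    norm_der <= max_derived_in_normal &
    tum_der >= 1 & tum_anc >= 1       # both alleles present, not 100% derived
  out
}

#' Strict tumor-specific filter
#'
#' A polarized site passes when all five criteria hold:
#' 1. normal RNA coverage >= `min_cov` with no derived reads;
#' 2. normal RPF A-site coverage >= `min_cov` with no derived reads in the
#'    A-site tri-nucleotide;
#' 3. tumor RNA coverage >= `min_cov` with both alleles at count >=
#'    `min_allele`;
#' 4. tumor RPF A-site coverage >= `min_cov` with both alleles at count >=
#'    `min_allele`;
#' 5. the site is absent from the known-SNP panel.
#'
#' @param variants polarized site table.
#' @param panel known-SNP panel data.frame (`gene`, `pos` 0-based; see
#'   [read_panel()]) or `NULL` to skip criterion 5.
#' @param min_cov minimum coverage per assay and sample (default 20).
#' @param min_allele minimum per-allele count in tumor (default 3).
#' @param max_derived_in_normal as in [loose_filter()].
#' @return logical vector, `FALSE` for non-polarized rows.
#' @export
strict_filter <- function(variants, panel = NULL, min_cov = 20,
                          min_allele = 3, max_derived_in_normal = 0) {
  ok <- variants$status == "polarized"
  out <- rep(FALSE, nrow(variants))
  if (!any(ok)) return(out)
  v <- variants[ok, , drop = FALSE]
  c1 <- coverage_of(v, "rna", "normal") >= min_cov &
    base_count(v, "rna", "normal", v$der) <= max_derived_in_normal
  c2 <- coverage_of(v, "rpf", "normal") >= min_cov &
    base_count(v, "rpf", "normal", v$der) <= max_derived_in_normal
  c3 <- coverage_of(v, "rna", "tumor") >= min_cov &
    base_count(v, "rna", "tumor", v$anc) >= min_allele &
    base_count(v, "rna", "tumor", v$der) >= min_allele
  c4 <- coverage_of(v, "rpf", "tumor") >= min_cov &
    base_count(v, "rpf", "tumor", v$anc) >= min_allele &
    base_count(v, "rpf", "tumor", v$der) >= min_allele
  c5 <- if (is.null(panel)) TRUE else
    !(site_key(v$gene, v$pos) %in% site_key(panel$gene, panel$pos))
  out[ok] <- c1 & c2 & c3 & c4 & c5
  out
}

#' Apply both filter tiers and record the tier per site
#'
#' @inheritParams strict_filter
#' @param loose_cov,strict_cov coverage thresholds of the two tiers.
#' @return `variants` with a `tier` column (`none`, `loose`, `strict`);
#'   strict-pass sites are by construction also loose-pass.
#' @export
filter_tiers <- function(variants, panel = NULL, loose_cov = 5,
                         strict_cov = 20, min_allele = 3,
                         max_derived_in_normal = 0) {
  lo <- loose_filter(variants, loose_cov, max_derived_in_normal)
  st <- strict_filter(variants, panel, strict_cov, min_allele,
                      max_derived_in_normal)
  variants$tier <- ifelse(st, "strict", ifelse(lo, "loose", "none"))
  variants
}

#' Annotate variant consequences from the CDS model
#'
#' Positions upstream of the CDS are `utr5`, downstream are `utr3`; coding
#' positions are classified by translating the ancestral and derived
#' codons: same amino acid is `synonymous`, a stop codon gained, lost or
#' changed is `nonsense`, anything else `missense`. Genes absent from the
#' CDS model are `noncoding`.
#'
#' @param variants polarized site table (only polarized rows are
#'   annotated; others get `NA`).
#' @param cds CDS model data.frame (`gene`, `cds_start`, `cds_end`,
#'   0-based half-open).
#' @param seqs named character vector of transcript sequences.
#' @return `variants` with added `consequence`, `codon_index` and
#'   `codon_pos` columns.
#' @export
annotate_variants <- function(variants, cds, seqs) {
  gi <- match(variants$gene, cds$gene)
  cds_start <- cds$cds_start[gi]
  cds_end <- cds$cds_end[gi]
  bad <- !is.na(gi) & (cds_end - cds_start) %% 3L != 0L
  if (any(bad)) {
    stop("malformed CDS model: length not divisible by 3 for gene(s) ",
         paste(unique(variants$gene[bad]), collapse = ", "))
  }
  n <- nrow(variants)
  consequence <- rep(NA_character_, n)
  codon_index <- rep(NA_integer_, n)
  codon_pos <- rep(NA_integer_, n)
  pol <- which(variants$status == "polarized")
  gc_tab <- Biostrings::GENETIC_CODE
  for (i in pol) {
    if (is.na(gi[i])) { consequence[i] <- "noncoding"; next }
    pos <- variants$pos[i]
    if (pos < cds_start[i]) { consequence[i] <- "utr5"; next }
    if (pos >= cds_end[i]) { consequence[i] <- "utr3"; next }
    ci <- (pos - cds_start[i]) %/% 3L
    cp <- (pos - cds_start[i]) %% 3L
    codon_index[i] <- ci
    codon_pos[i] <- cp
    a <- cds_start[i] + ci * 3L + 1L  # 1-based
    anc_codon <- substr(seqs[[variants$gene[i]]], a, a + 2L)
    der_codon <- anc_codon
    substr(der_codon, cp + 1L, cp + 1L) <- variants$der[i]
    aa_anc <- gc_tab[[anc_codon]]
    aa_der <- gc_tab[[der_codon]]
    consequence[i] <-
      if (aa_anc == "*" || aa_der == "*") "nonsense"
      else if (aa_anc == aa_der) "synonymous"
      else "missense"
  }
  variants$consequence <- consequence
  variants$codon_index <- codon_index
  variants$codon_pos <- codon_pos
  variants
}

#' Mutation-spectrum summary
#'
#' Tallies the 12 ordered base changes over polarized variants, the
#' transition fraction (A<->G plus C<->T over all changes), and the
#' consequence fractions over annotated variants.
#'
#' @param variants polarized (and optionally annotated) site table.
#' @return list with `changes` (data.frame: change, n, fraction),
#'   `transition_fraction`, and `consequences` (data.frame or `NULL` if
#'   the input is unannotated).
#' @export
mutation_spectrum <- function(variants) {
  v <- variants[variants$status == "polarized", , drop = FALSE]
  if (nrow(v) == 0) stop("mutation_spectrum: no polarized variants")
  all_changes <- {
    g <- expand.grid(from = BASES, to = BASES, stringsAsFactors = FALSE)
    g <- g[g$from != g$to, ]
    paste0(g$from, ">", g$to)
  }
  chg <- paste0(v$anc, ">", v$der)
  tab <- table(factor(chg, levels = sort(all_changes)))
  changes <- data.frame(change = names(tab), n = as.integer(tab),
                        fraction = as.vector(tab) / nrow(v),
                        stringsAsFactors = FALSE)
  transitions <- c("A>G", "G>A", "C>T", "T>C")
  res <- list(
    changes = changes,
    transition_fraction = sum(chg %in% transitions) / nrow(v),
    consequences = NULL
  )
  if (!is.null(v$consequence)) {
    ct <- table(v$consequence[!is.na(v$consequence)])
    res$consequences <- data.frame(
      consequence = names(ct), n = as.integer(ct),
      fraction = as.vector(ct) / sum(ct), stringsAsFactors = FALSE)
  }
  res
}

#' Merge per-patient variant sets into a union
#'
#' Variants are keyed by (gene, position, derived allele); the same
#' position with different derived alleles in different patients stays as
#' separate entries. The merged record keeps the per-patient presence
#' list and count.
#'
#' @param variants site table with a `patient` column (one row per site x
#'   patient), typically pre-filtered to a tier.
#' @return data.frame with one row per unique (gene, pos, der) key,
#'   columns of the first occurrence plus `patients` (semicolon list) and
#'   `n_patients`.
#' @export
merge_patients <- function(variants) {
  if (nrow(variants) == 0) return(variants)
  key <- paste(variants$gene, variants$pos, variants$der, sep = ":")
  first <- !duplicated(key)
  out <- variants[first, setdiff(names(variants), "patient"), drop = FALSE]
  pl <- split(variants$patient, factor(key, levels = key[first]))
  out$patients <- vapply(pl, function(p) {
    paste(sort(unique(p)), collapse = ";")
  }, "")
  out$n_patients <- vapply(pl, function(p) length(unique(p)), 0L)
  out <- out[order(out$gene, out$pos, out$der), , drop = FALSE]
  rownames(out) <- NULL
  out
}
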