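# Allele-specific A-site densities at tumor-specific synonymous sites and
# the statistical comparisons between alleles and samples.
#
# A-site density = A-site read count / RNA read count for the same allele
# in the same sample. Because the two alleles of a heterozygous tumor site
# come from the same sequencing library and the same trans environment,
# their density comparison needs no library-size normalization; the
# normal-vs-tumor comparisons do not share a library and are reported with
# that caveat.

#' Classify the codon-optimality direction of a synonymous change
#'
#' A change from A/T to C/G increases codon optimality (`optimal`, faster
#' elongation); C/G to A/T decreases it (`non_optimal`, slower); A<->T and
#' C<->G changes are `unclassified`.
#'
#' @param anc,der ancestral and derived bases (vectors recycle).
#' @return character vector of classes.
#' @examples
#' classify_optimality("A", "G")  # optimal
#' classify_optimality("C", "A")  # non_optimal
#' classify_optimality("A", "T")  # unclassified
#' @export
classify_optimality <- function(anc, der) {
  n <- max(length(anc), length(der))
  anc <- rep_len(anc, n)
  der <- rep_len(der, n)
  if (!all(anc %in% BASES) || !all(der %in% BASES)) {
    stop("classify_optimality: bases must be A, C, G or T")
  }
  if (any(anc == der)) {
    stop("classify_optimality: ancestral and derived bases must differ")
  }
  weak <- c("A", "T")   # A/T
  strong <- c("C", "G") # C/G
  ifelse(anc %in% weak & der %in% strong, "optimal",
         ifelse(anc %in% strong & der %in% weak, "non_optimal",
                "unclassified"))
}

#' Allele-specific A-site densities
#'
#' Computes, for each strict-tier synonymous site, the A-site/RNA count
#' ratio for the ancestral allele in normal tissue and for both alleles in
#' tumor tissue, from raw counts (no within-sample normalization).
#'
#' @param variants polarized, annotated, filtered site table (rows should
#'   already be restricted to strict-tier synonymous sites; the function
#'   only requires `anc`/`der` and the count columns).
#' @param drop_zero_rna drop records where any needed RNA denominator is
#'   zero (cannot occur for strict-tier sites); the number dropped is
#'   attached as attribute `n_dropped`.
#' @return data.frame: gene, pos, patient (if present), anc, der,
#'   optimality, density_normal_anc, density_tumor_anc, density_tumor_der,
#'   plus the six underlying counts.
#' @export
allele_densities <- function(variants, drop_zero_rna = TRUE) {
  v <- variants
  rna_n_anc <- base_count(v, "rna", "normal", v$anc)
  rna_t_anc <- base_count(v, "rna", "tumor", v$anc)
  rna_t_der <- base_count(v, "rna", "tumor", v$der)
  rpf_n_anc <- base_count(v, "rpf", "normal", v$anc)
  rpf_t_anc <- base_count(v, "rpf", "tumor", v$anc)
  rpf_t_der <- base_count(v, "rpf", "tumor", v$der)
  out <- data.frame(
    gene = v$gene, pos = v$pos,
    anc = v$anc, der = v$der,
    optimality = classify_optimality(v$anc, v$der),
    rna_normal_anc = rna_n_anc, rpf_normal_anc = rpf_n_anc,
    rna_tumor_anc = rna_t_anc, rpf_tumor_anc = rpf_t_anc,
    rna_tumor_der = rna_t_der, rpf_tumor_der = rpf_t_der,
    density_normal_anc = rpf_n_anc / rna_n_anc,
    density_tumor_anc = rpf_t_anc / rna_t_anc,
    density_tumor_der = rpf_t_der / rna_t_der,
    stringsAsFactors = FALSE
  )
  if (!is.null(v$patient)) out <- cbind(out[, 1:2], patient = v$patient,
                                        out[, -(1:2)])
  n_dropped <- 0L
  if (drop_zero_rna) {
    bad <- rna_n_anc == 0 | rna_t_anc == 0 | rna_t_der == 0
    n_dropped <- sum(bad)
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Compare A-site density distributions between groups and alleles
#'
#' Runs two-sided two-sample Kolmogorov-Smirnov tests between the three
#' density groups (normal ancestral, tumor ancestral, tumor derived) and a
#' paired t-test between the two tumor alleles site by site. The
#' cross-sample KS comparisons involve different sequencing libraries and
#' are labeled accordingly; the within-tumor paired comparison is free of
#' library-size effects.
#'
#' @param records output of [allele_densities()].
#' @param class restrict to one optimality class (`"optimal"`,
#'   `"non_optimal"`) or `NULL` for all records.
#' @param min_sites minimum number of records required (default 10).
#' @param log2_densities apply log2 to densities before the paired t-test
#'   (zero densities are dropped for the transform); off by default.
#' @return list of class `allele_comparison`: `n_sites`, `class`,
#'   `ks` (data.frame of the three pairwise tests), `paired_t`
#'   (statistic, p.value, mean_anc, mean_der, mean_diff),
#'   `direction` (fraction of sites with ancestral density > derived).
#' @export
compare_groups <- function(records, class = NULL, min_sites = 10,
                           log2_densities = FALSE) {
  r <- records
  if (!is.null(class)) r <- r[r$optimality == class, , drop = FALSE]
  if (nrow(r) < min_sites) {
    stop(sprintf("compare_groups: %d site(s) available, need >= %d",
                 nrow(r), min_sites))
  }
  dn <- r$density_normal_anc
  da <- r$density_tumor_anc
  dd <- r$density_tumor_der
  ks_pair <- function(x, y, label, cross_library) {
    k <- suppressWarnings(ks.test(x, y))
    data.frame(comparison = label, statistic = unname(k$statistic),
               p.value = k$p.value,
               note = if (cross_library) "not library-size normalized"
                      else "", stringsAsFactors = FALSE)
  }
  ks <- rbind(
    ks_pair(dn, da, "normal_anc_vs_tumor_anc", TRUE),
    ks_pair(dn, dd, "normal_anc_vs_tumor_der", TRUE),
    ks_pair(da, dd, "tumor_anc_vs_tumor_der", FALSE)
  )
  xa <- da; xd <- dd
  if (log2_densities) {
    ok <- xa > 0 & xd > 0
    xa <- log2(xa[ok]); xd <- log2(xd[ok])
  }
  tt <- t.test(xa, xd, paired = TRUE)
  res <- list(
    n_sites = nrow(r),
    class = if (is.null(class)) "all" else class,
    ks = ks,
    paired_t = list(statistic = unname(tt$statistic),
                    p.value = tt$p.value,
                    mean_anc = mean(xa), mean_der = mean(xd),
                    mean_diff = mean(xa - xd)),
    direction = mean(da > dd)
  )
  class(res) <- "allele_comparison"
  res
}

#' @export
print.allele_comparison <- function(x, ...) {
  cat("A-site density comparison (", x$class, ", n = ", x$n_sites,
      " sites)\n", sep = "")
  cat(sprintf("  paired t (tumor anc vs der): t = %.3f, p = %.3g, mean diff = %.4f\n",
              x$paired_t$statistic, x$paired_t$p.value, x$paired_t$mean_diff))
  cat(sprintf("  ancestral > derived at %.1f%% of sites\n",
              100 * x$direction))
  for (i in seq_len(nrow(x$ks))) {
    cat(sprintf("  KS %s: D = %.3f, p = %.3g %s\n", x$ks$comparison[i],
                x$ks$statistic[i], x$ks$p.value[i],
                ifelse(nzchar(x$ks$note[i]), paste0("(", x$ks$note[i], ")"),
                       "")))
  }
  invisible(x)
}
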