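# Gene-level analyses: SNP density per kb CDS, oncogene/TSG enrichment,
# translation efficiency (TE) and the regression of TE fold change on
# mutation counts and nuisance covariates.

#' SNP density per kb of CDS
#'
#' @param n_snps number of tumor-specific synonymous SNPs in the gene's
#'   CDS (vectorized).
#' @param cds_len CDS length in nt (> 0).
#' @return density in SNPs per kb: `1000 * n_snps / cds_len`.
#' @examples
#' snp_density(3, 1500)  # 2 per kb
#' @export
snp_density <- function(n_snps, cds_len) {
  if (any(cds_len <= 0)) stop("snp_density: cds_len must be > 0")
  1000 * n_snps / cds_len
}

#' Per-gene mutation summaries
#'
#' Counts tumor-specific synonymous variants per gene and optimality
#' class (after merging patients) and converts them to densities per kb
#' CDS. Genes absent from the CDS model raise an error naming the gene;
#' genes with no variants get zero counts.
#'
#' @param variants merged, annotated, filtered variant table restricted
#'   to the desired tier (must carry `gene`, `anc`, `der`,
#'   `consequence`).
#' @param cds CDS model (`gene`, `cds_len`).
#' @param classes gene-class table (`gene`, `class` in
#'   `oncogene`/`TSG`/`other`); genes missing from it are `other`.
#' @return data.frame: gene, class, cds_len, n_optimal, n_nonoptimal,
#'   density_opt, density_nonopt.
#' @export
gene_mutation_summary <- function(variants, cds, classes = NULL) {
  syn <- variants[!is.na(variants$consequence) &
                    variants$consequence == "synonymous", , drop = FALSE]
  missing_genes <- setdiff(unique(syn$gene), cds$gene)
  if (length(missing_genes)) {
    stop("gene(s) absent from CDS model: ",
         paste(missing_genes, collapse = ", "))
  }
  opt <- classify_optimality(syn$anc, syn$der)
  n_opt <- table(factor(syn$gene[opt == "optimal"], levels = cds$gene))
  n_non <- table(factor(syn$gene[opt == "non_optimal"], levels = cds$gene))
  out <- data.frame(
    gene = cds$gene,
    class = if (is.null(classes)) "other" else {
      cl <- classes$class[match(cds$gene, classes$gene)]
      ifelse(is.na(cl), "other", cl)
    },
    cds_len = cds$cds_len,
    n_optimal = as.integer(n_opt),
    n_nonoptimal = as.integer(n_non),
    stringsAsFactors = FALSE
  )
  out$density_opt <- snp_density(out$n_optimal, out$cds_len)
  out$density_nonopt <- snp_density(out$n_nonoptimal, out$cds_len)
  out
}

#' Gene-class enrichment of speed-controlling synonymous mutations
#'
#' Compares optimal-SNP density between oncogenes and TSG, non-optimal-SNP
#' density between oncogenes and TSG, and optimal vs non-optimal density
#' within the remaining (`other`) genes, using two-sample KS tests.
#'
#' @param summaries output of [gene_mutation_summary()].
#' @return data.frame of class `enrichment_report`: comparison, n1, n2,
#'   mean1, mean2, direction, ks_statistic, p.value.
#' @export
class_enrichment <- function(summaries) {
  s <- summaries
  need <- c("oncogene", "TSG")
  for (cl in need) {
    if (!any(s$class == cl)) {
      stop("class_enrichment: no genes of class ", cl)
    }
  }
  onco <- s[s$class == "oncogene", ]
  tsg <- s[s$class == "TSG", ]
  other <- s[s$class == "other", ]
  row_of <- function(label, x, y, lab1, lab2) {
    k <- suppressWarnings(ks.test(x, y))
    data.frame(comparison = label, n1 = length(x), n2 = length(y),
               mean1 = mean(x), mean2 = mean(y),
               direction = ifelse(mean(x) > mean(y), paste(lab1, ">", lab2),
                                  paste(lab1, "<=", lab2)),
               ks_statistic = unname(k$statistic), p.value = k$p.value,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    row_of("optimal_onco_vs_tsg", onco$density_opt, tsg$density_opt,
           "oncogene", "TSG"),
    row_of("nonoptimal_onco_vs_tsg", onco$density_nonopt, tsg$density_nonopt,
           "oncogene", "TSG"),
    if (nrow(other)) {
      row_of("other_opt_vs_nonopt", other$density_opt, other$density_nonopt,
             "optimal", "non_optimal")
    }
  )
  class(out) <- c("enrichment_report", class(out))
  out
}

#' Top genes by SNP density
#'
#' Ranks genes of one class by the requested optimality-class density,
#' descending; ties are broken by raw SNP count (higher first), then by
#' gene id.
#'
#' @param summaries output of [gene_mutation_summary()].
#' @param class gene class to rank (`oncogene`, `TSG`, `other`).
#' @param optimality `"optimal"` or `"non_optimal"`.
#' @param k number of genes to report; the full class if smaller.
#' @return data.frame: gene, density, n_snps (the "Freq"), cds_len.
#' @export
top_genes <- function(summaries, class, optimality = "optimal", k = 10) {
  stopifnot(k >= 1)
  s <- summaries[summaries$class == class, , drop = FALSE]
  dens <- if (optimality == "optimal") s$density_opt else s$density_nonopt
  cnt <- if (optimality == "optimal") s$n_optimal else s$n_nonoptimal
  ord <- order(-dens, -cnt, s$gene)
  s <- s[ord, ]
  dens <- dens[ord]; cnt <- cnt[ord]
  n <- min(k, nrow(s))
  data.frame(gene = s$gene[seq_len(n)], density = dens[seq_len(n)],
             n_snps = cnt[seq_len(n)], cds_len = s$cds_len[seq_len(n)],
             stringsAsFactors = FALSE)
}

#' Reads per kilobase per million mapped reads
#'
#' @param count raw read count per gene.
#' @param length_nt gene (transcript) length in nt.
#' @param library_size total mapped reads of the library (> 0).
#' @return RPKM: `1e9 * count / (length_nt * library_size)`.
#' @examples
#' rpkm(100, 1000, 1e6)  # 100
#' @export
rpkm <- function(count, length_nt, library_size) {
  if (any(library_size <= 0)) stop("rpkm: library_size must be > 0")
  if (any(count < 0)) stop("rpkm: negative counts")
  1e9 * count / (length_nt * library_size)
}

#' Translation efficiency per gene
#'
#' TE = RPKM of RPF reads / RPKM of mRNA reads. Genes with zero mRNA RPKM
#' get `NA` (undefined) and are excluded downstream.
#'
#' @param rna_counts,rpf_counts raw read counts per gene.
#' @param length_nt gene lengths in nt.
#' @param rna_lib,rpf_lib library sizes; default to the respective count
#'   sums.
#' @return numeric vector of TE values (NA where undefined).
#' @export
translation_efficiency <- function(rna_counts, rpf_counts, length_nt,
                                   rna_lib = sum(rna_counts),
                                   rpf_lib = sum(rpf_counts)) {
  r_rna <- rpkm(rna_counts, length_nt, rna_lib)
  r_rpf <- rpkm(rpf_counts, length_nt, rpf_lib)
  ifelse(r_rna > 0, r_rpf / r_rna, NA_real_)
}

#' Per-gene TE fold change averaged across patients
#'
#' Computes TE per patient and condition from the long gene-count table,
#' then averages the per-patient log2 fold changes (tumor/normal) per
#' gene. Patients where either TE is undefined for a gene are skipped for
#' that gene.
#'
#' @param gene_counts data.frame: gene, patient, rna_normal, rna_tumor,
#'   rpf_normal, rpf_tumor.
#' @param lengths data.frame (`gene`, `length`) or named vector of gene
#'   lengths in nt.
#' @return data.frame: gene, te_normal, te_tumor (patient means),
#'   log2_te_fc (mean of per-patient log2 ratios), n_patients.
#' @export
te_fold_change <- function(gene_counts, lengths) {
  len <- if (is.data.frame(lengths)) {
    setNames(lengths$length, lengths$gene)
  } else lengths
  gc <- gene_counts
  gc$len <- len[gc$gene]
  res <- lapply(split(gc, gc$patient), function(d) {
    te_n <- translation_efficiency(d$rna_normal, d$rpf_normal, d$len)
    te_t <- translation_efficiency(d$rna_tumor, d$rpf_tumor, d$len)
    data.frame(gene = d$gene, te_normal = te_n, te_tumor = te_t,
               log2fc = log2(te_t / te_n), stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, res)
  long <- long[is.finite(long$log2fc), , drop = FALSE]
  agg <- aggregate(cbind(te_normal, te_tumor, log2fc) ~ gene, data = long,
                   FUN = mean)
  n <- aggregate(log2fc ~ gene, data = long, FUN = length)
  out <- data.frame(gene = agg$gene, te_normal = agg$te_normal,
                    te_tumor = agg$te_tumor, log2_te_fc = agg$log2fc,
                    n_patients = n$log2fc[match(agg$gene, n$gene)],
                    stringsAsFactors = FALSE)
  out[order(out$gene), ]
}

#' Min-max scale a variable to \[-1, 1\]
#'
#' `x' = 2 (x - min) / (max - min) - 1`. A constant vector cannot be
#' scaled and raises an error.
#'
#' @param x numeric vector.
#' @return scaled vector with range \[-1, 1\].
#' @export
scale_minmax <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (r[1] == r[2]) stop("scale_minmax: constant variable cannot be scaled")
  2 * (x - r[1]) / (r[2] - r[1]) - 1
}

#' Regression of TE fold change on scaled predictors
#'
#' Ordinary least squares of the response on min-max-scaled predictors
#' (each scaled to \[-1, 1\] so coefficient magnitudes are comparable).
#' The design is checked for collinearity before fitting; rank-deficient
#' designs raise an error listing the involved predictors.
#'
#' @param data data.frame containing the response and predictor columns;
#'   rows with missing values are dropped.
#' @param response name of the response column (e.g. the log2 TE fold
#'   change).
#' @param predictors character vector of predictor column names.
#' @param min_obs_per_predictor minimum observations required per
#'   predictor (default 10).
#' @return list of class `te_regression`: `coefficients` (data.frame:
#'   term, estimate, std_error, t, p.value), `n`, `r_squared`, `scaling`
#'   (per-predictor min/max used).
#' @export
te_regression <- function(data, response = "log2_te_fc",
                          predictors = c("n_optimal", "n_nonoptimal",
                                         "length", "dn", "expression",
                                         "gc"),
                          min_obs_per_predictor = 10) {
  cols <- c(response, predictors)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("te_regression: missing column(s): ",
                         paste(miss, collapse = ", "))
  d <- data[complete.cases(data[, cols]), cols, drop = FALSE]
  if (nrow(d) < min_obs_per_predictor * length(predictors)) {
    stop(sprintf("te_regression: %d usable genes < %d required",
                 nrow(d), min_obs_per_predictor * length(predictors)))
  }
  X <- vapply(predictors, function(p) scale_minmax(d[[p]]),
              numeric(nrow(d)))
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    drop_i <- qrX$pivot[seq.int(qrX$rank + 1, ncol(X) + 1)] - 1L
    stop("te_regression: rank-deficient design; collinear predictor(s): ",
         paste(predictors[drop_i], collapse = ", "))
  }
  df <- as.data.frame(X)
  df$.y <- d[[response]]
  fit <- lm(.y ~ ., data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  res <- list(
    coefficients = data.frame(
      term = rownames(co), estimate = co[, 1], std_error = co[, 2],
      t = co[, 3], p.value = co[, 4], row.names = NULL,
      stringsAsFactors = FALSE),
    n = nrow(d),
    r_squared = sm$r.squared,
    scaling = data.frame(predictor = predictors,
                         min = apply(d[, predictors, drop = FALSE], 2, min),
                         max = apply(d[, predictors, drop = FALSE], 2, max),
                         row.names = NULL)
  )
  class(res) <- "te_regression"
  res
}

#' @export
print.te_regression <- function(x, ...) {
  cat("TE fold-change regression on", x$n, "genes, R^2 =",
      round(x$r_squared, 3), "\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}
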