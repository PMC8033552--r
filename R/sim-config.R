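#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic tumor/normal
#' dataset generator. Defaults emulate the study conditions of a paired
#' tumor/normal liver cohort profiled by RNA-seq and ribosome profiling:
#' ten patients, oncogene/TSG sets of 240 and 242 genes, heterozygous
#' tumor-only mutations on a monomorphic normal background, RPF reads of
#' 28-31 nt with per-length P-site offsets.
#'
#' @param n_genes total number of genes (single isoform each).
#' @param n_onco,n_tsg number of genes labeled oncogene / tumor suppressor;
#'   the remainder are labeled `other`.
#' @param cds_len_range inclusive range (nt) of CDS lengths; draws are
#'   rounded to multiples of 3.
#' @param utr5_len,utr3_len UTR lengths (nt).
#' @param n_patients number of paired tumor/normal patients.
#' @param rna_depth mean RNA-seq read depth per site (Poisson mean).
#' @param rpf_depth mean RPF A-site depth per site implied for ancestral
#'   alleles; used to size the background read pool for offset calibration.
#' @param tumor_allele_fraction derived-allele fraction at heterozygous
#'   tumor sites (binomial sampling probability), strictly in (0, 1).
#' @param base_density expected A-site/RNA count ratio for ancestral alleles.
#' @param speed_factor_optimal multiplicative A-site density factor for
#'   derived alleles of optimal mutations; < 1 means faster elongation.
#' @param speed_factor_nonoptimal factor for derived non-optimal alleles;
#'   values above 1 mean slower elongation.
#' @param mut_rate_per_kb baseline synonymous-mutation density
#'   (expected mutations per kb CDS, per optimality class).
#' @param mut_rate_unclassified_per_kb rate of synonymous A<->T / C<->G
#'   changes, which fall in neither optimality class.
#' @param enrich_opt_onco fold enrichment of optimal mutations in oncogenes.
#' @param enrich_nonopt_tsg fold enrichment of non-optimal mutations in TSG.
#' @param offset_by_length named integer vector mapping RPF read length
#'   (nt, as names) to the true P-site offset (nt).
#' @param frame_fidelity fraction of RPF 5' ends placed on the true frame;
#'   the rest are shifted by +-1 nt with equal probability.
#' @param panel_fraction fraction of injected variants also placed in the
#'   known-SNP panel (to exercise the strict filter's panel exclusion).
#' @param frac_non_ancestral fraction of injected sites whose outgroup base
#'   is set different from the reference (non-ancestral decoys).
#' @param frac_missing_outgroup fraction of sites with outgroup base `N`.
#' @param reads_per_length start-codon-anchored background RPF reads
#'   generated per read length (for offset calibration).
#' @param te_beta_opt,te_beta_nonopt true effects (on min-max-scaled
#'   predictors) of optimal / non-optimal mutation counts on the log2
#'   translation-efficiency fold change tumor/normal.
#' @param te_noise_sd standard deviation of the log2 TE fold-change noise.
#' @param patient_share_prob probability that a variant carried by one
#'   patient is also carried by each additional patient.
#' @param seed integer seed; mandatory, all randomness derives from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 20, n_onco = 5, n_tsg = 5, seed = 1)
#' @export
sim_config <- function(n_genes = 1000,
                       n_onco = 240,
                       n_tsg = 242,
                       cds_len_range = c(300L, 1500L),
                       utr5_len = 60L,
                       utr3_len = 60L,
                       n_patients = 10L,
                       rna_depth = 50,
                       rpf_depth = 25,
                       tumor_allele_fraction = 0.5,
                       base_density = 0.5,
                       speed_factor_optimal = 0.5,
                       speed_factor_nonoptimal = 2,
                       mut_rate_per_kb = 1,
                       mut_rate_unclassified_per_kb = 0.1,
                       enrich_opt_onco = 3,
                       enrich_nonopt_tsg = 3,
                       offset_by_length = c("28" = 12L, "29" = 12L,
                                            "30" = 13L, "31" = 13L),
                       frame_fidelity = 0.9,
                       panel_fraction = 0.2,
                       frac_non_ancestral = 0.02,
                       frac_missing_outgroup = 0.02,
                       reads_per_length = 2000L,
                       te_beta_opt = 0.5,
                       te_beta_nonopt = -0.5,
                       te_noise_sd = 0.25,
                       patient_share_prob = 0.1,
                       seed) {
  if (missing(seed)) stop("sim_config: 'seed' is mandatory")
  cfg <- list(
    n_genes = as.integer(n_genes), n_onco = as.integer(n_onco),
    n_tsg = as.integer(n_tsg),
    cds_len_range = as.integer(cds_len_range),
    utr5_len = as.integer(utr5_len), utr3_len = as.integer(utr3_len),
    n_patients = as.integer(n_patients),
    rna_depth = rna_depth, rpf_depth = rpf_depth,
    tumor_allele_fraction = tumor_allele_fraction,
    base_density = base_density,
    speed_factor_optimal = speed_factor_optimal,
    speed_factor_nonoptimal = speed_factor_nonoptimal,
    mut_rate_per_kb = mut_rate_per_kb,
    mut_rate_unclassified_per_kb = mut_rate_unclassified_per_kb,
    enrich_opt_onco = enrich_opt_onco,
    enrich_nonopt_tsg = enrich_nonopt_tsg,
    offset_by_length = setNames(as.integer(offset_by_length),
                                names(offset_by_length)),
    frame_fidelity = frame_fidelity,
    panel_fraction = panel_fraction,
    frac_non_ancestral = frac_non_ancestral,
    frac_missing_outgroup = frac_missing_outgroup,
    reads_per_length = as.integer(reads_per_length),
    te_beta_opt = te_beta_opt, te_beta_nonopt = te_beta_nonopt,
    te_noise_sd = te_noise_sd,
    patient_share_prob = patient_share_prob,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every structural invariant of the generator; the error message
#' names the offending field.
#'
#' @param cfg a `sim_config`.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid sim_config: field '%s' %s", field, why),
         call. = FALSE)
  }
  pos_counts <- c("n_genes", "n_onco", "n_tsg", "n_patients",
                  "utr5_len", "utr3_len", "reads_per_length")
  for (f in pos_counts) {
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] <= 0) {
      fail(f, "must be a positive count")
    }
  }
  if (cfg$n_onco + cfg$n_tsg > cfg$n_genes) {
    fail("n_genes", "must be >= n_onco + n_tsg")
  }
  r <- cfg$cds_len_range
  if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
    fail("cds_len_range", "must be a positive increasing interval")
  }
  if (any(r %% 3L != 0L)) {
    fail("cds_len_range", "bounds must be divisible by 3")
  }
  for (f in c("rna_depth", "rpf_depth", "base_density", "mut_rate_per_kb")) {
    if (cfg[[f]] <= 0) fail(f, "must be > 0")
  }
  if (cfg$tumor_allele_fraction <= 0 || cfg$tumor_allele_fraction >= 1) {
    fail("tumor_allele_fraction", "must lie strictly in (0, 1)")
  }
  # 1 is allowed on both: the null (no-speed-effect) generator
  if (cfg$speed_factor_optimal <= 0 || cfg$speed_factor_optimal > 1) {
    fail("speed_factor_optimal", "must lie in (0, 1]")
  }
  if (cfg$speed_factor_nonoptimal < 1) {
    fail("speed_factor_nonoptimal", "must be >= 1")
  }
  off <- cfg$offset_by_length
  if (is.null(names(off)) || anyNA(suppressWarnings(as.integer(names(off))))) {
    fail("offset_by_length", "must be named by read length")
  }
  lens <- as.integer(names(off))
  if (any(off < 0) || any(off >= lens)) {
    fail("offset_by_length", "offsets must be >= 0 and < read length")
  }
  for (f in c("frame_fidelity", "panel_fraction", "frac_non_ancestral",
              "frac_missing_outgroup", "patient_share_prob")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) fail(f, "must lie in [0, 1]")
  }
  if (cfg$frame_fidelity <= 0) fail("frame_fidelity", "must be > 0")
  if (cfg$te_noise_sd < 0) fail("te_noise_sd", "must be >= 0")
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) {
    fail("seed", "must be a single integer")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes (", x$n_onco, "oncogene,", x$n_tsg,
      "TSG ),", x$n_patients, "patients, seed", x$seed, "\n")
  cat("  rna_depth", x$rna_depth, "| base_density", x$base_density,
      "| speed factors", x$speed_factor_optimal, "/",
      x$speed_factor_nonoptimal, "\n")
  cat("  mut_rate_per_kb", x$mut_rate_per_kb, "| enrichment",
      x$enrich_opt_onco, "(opt, onco) /", x$enrich_nonopt_tsg,
      "(non-opt, TSG)\n")
  invisible(x)
}

# speed factor applied to a derived allele of the given optimality class
speed_factor_for <- function(cfg, optimality) {
  ifelse(optimality == "optimal", cfg$speed_factor_optimal,
         ifelse(optimality == "non_optimal", cfg$speed_factor_nonoptimal, 1))
}
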