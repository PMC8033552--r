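# End-to-end orchestration: variants -> offsets -> allele densities ->
# gene level, with per-stage site accounting and a written report bundle.

#' Pipeline thresholds and options
#'
#' @param loose_cov,strict_cov normal/tumor coverage thresholds of the two
#'   filter tiers; `loose_cov` must not exceed `strict_cov`.
#' @param min_allele minimum per-allele tumor count at the strict tier.
#' @param max_derived_in_normal derived reads tolerated in normal tissue.
#' @param metagene_window window of 5'-end positions relative to the
#'   start codon used for offset calibration.
#' @param offset_min_reads minimum reads per length for calibration.
#' @param min_sites minimum sites per optimality class for the density
#'   comparisons.
#' @param log2_densities use log2 densities in the paired t-test.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(loose_cov = 5, strict_cov = 20, min_allele = 3,
                            max_derived_in_normal = 0,
                            metagene_window = c(-40L, 10L),
                            offset_min_reads = 200L, min_sites = 10,
                            log2_densities = FALSE) {
  if (loose_cov <= 0 || strict_cov <= 0 || min_allele <= 0) {
    stop("pipeline_config: thresholds must be positive")
  }
  if (loose_cov > strict_cov) {
    stop("pipeline_config: loose_cov must be <= strict_cov")
  }
  structure(list(loose_cov = loose_cov, strict_cov = strict_cov,
                 min_allele = min_allele,
                 max_derived_in_normal = max_derived_in_normal,
                 metagene_window = metagene_window,
                 offset_min_reads = offset_min_reads,
                 min_sites = min_sites, log2_densities = log2_densities),
            class = "pipeline_config")
}

#' Run the full analysis on a dataset bundle
#'
#' Executes polarization and annotation, the two filter tiers, P-site
#' offset calibration, allele-specific density comparisons, and the
#' gene-level analyses (enrichment, top genes, TE fold change, TE
#' regression at both tiers). Every input site is accounted for in the
#' stage counts: sites in = polarized + each exclusion reason.
#'
#' @param ds a `synoribo_dataset` (from [generate_dataset()],
#'   [read_dataset()] or [worked_fixture()]).
#' @param out_dir optional directory for the report files (TSV tables and
#'   a plain-text log); if a stage fails, partial outputs are retained
#'   next to a `FAILED` marker file naming the stage.
#' @param config a [pipeline_config()].
#' @return list of class `synoribo_report` with elements `variants`,
#'   `offsets`, `densities`, `comparisons`, `gene_summary` (per tier),
#'   `enrichment` (per tier), `top_genes`, `te`, `regression` (per tier)
#'   and `stage_counts`.
#' @export
run_all <- function(ds, out_dir = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  stage <- "ingest"
  on_fail <- function(e) {
    if (!is.null(out_dir)) {
      writeLines(paste("stage:", stage, "-", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    }
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    stage <- "variants"
    v <- polarize_sites(ds$site_counts)
    v <- annotate_variants(v, ds$cds, ds$seqs)
    v <- filter_tiers(v, ds$panel, loose_cov = config$loose_cov,
                      strict_cov = config$strict_cov,
                      min_allele = config$min_allele,
                      max_derived_in_normal = config$max_derived_in_normal)
    status_n <- table(factor(v$status, levels = c(
      "polarized", "non_ancestral_ref", "missing_outgroup", "multiallelic",
      "monomorphic")))
    stage_counts <- data.frame(
      stage = c("input_sites", paste0("status_", names(status_n)),
                "tier_loose", "tier_strict"),
      n = c(nrow(v), as.integer(status_n),
            sum(v$tier == "loose") + sum(v$tier == "strict"),
            sum(v$tier == "strict")),
      stringsAsFactors = FALSE)

    stage <- "offsets"
    offsets <- if (!is.null(ds$reads) && nrow(ds$reads) > 0) {
      infer_psite_offsets(ds$reads, ds$cds,
                          window = config$metagene_window,
                          min_reads = config$offset_min_reads)
    } else ds$offsets
    if (is.null(offsets)) stop("no RPF reads and no precomputed offsets")
    if (any(nzchar(offsets$qc_warn))) {
      warning("dispersed metagene peak for read length(s) ",
              paste(offsets$length[nzchar(offsets$qc_warn)],
                    collapse = ", "), call. = FALSE)
    }

    stage <- "densities"
    strict_syn <- v[v$tier == "strict" &
                      !is.na(v$consequence) &
                      v$consequence == "synonymous", , drop = FALSE]
    strict_syn <- strict_syn[classify_optimality(strict_syn$anc,
                                                 strict_syn$der) !=
                               "unclassified", , drop = FALSE]
    densities <- allele_densities(strict_syn)
    comparisons <- lapply(c(optimal = "optimal",
                            non_optimal = "non_optimal"), function(cl) {
      if (sum(densities$optimality == cl) >= config$min_sites) {
        compare_groups(densities, class = cl,
                       min_sites = config$min_sites,
                       log2_densities = config$log2_densities)
      }
    })

    stage <- "gene_level"
    tiers <- list(loose = v[v$tier %in% c("loose", "strict"), ],
                  strict = v[v$tier == "strict", ])
    gene_summary <- lapply(tiers, function(t) {
      gene_mutation_summary(merge_patients(t), ds$cds, ds$gene_classes)
    })
    enrichment <- lapply(gene_summary, function(gs) {
      tryCatch(class_enrichment(gs), error = function(e) NULL)
    })
    top <- list(
      oncogene_optimal = top_genes(gene_summary$loose, "oncogene",
                                   "optimal", 10),
      tsg_nonoptimal = top_genes(gene_summary$loose, "TSG",
                                 "non_optimal", 10))
    te <- te_fold_change(ds$gene_counts, ds$covariates[, c("gene", "length")])
    # regression needs enough genes; small worked examples skip it
    regression <- lapply(gene_summary, function(gs) {
      d <- merge(merge(te, gs[, c("gene", "n_optimal", "n_nonoptimal")],
                       by = "gene"), ds$covariates, by = "gene")
      tryCatch(te_regression(d), error = function(e) NULL)
    })

    report <- list(variants = v, offsets = offsets, densities = densities,
                   comparisons = comparisons, gene_summary = gene_summary,
                   enrichment = enrichment, top_genes = top, te = te,
                   regression = regression, stage_counts = stage_counts,
                   config = config)
    class(report) <- "synoribo_report"
    stage <- "write_report"
    if (!is.null(out_dir)) write_report(report, out_dir)
    report
  }, error = on_fail)
}

# serialize the report bundle as TSV tables plus a human-readable log
write_report <- function(report, out_dir) {
  p <- function(f) file.path(out_dir, f)
  write_tsv_table(report$variants, p("variants.tsv"))
  off <- report$offsets
  class(off) <- "data.frame"
  write_tsv_table(off, p("offsets.tsv"))
  write_tsv_table(report$densities, p("densities.tsv"))
  for (tier in names(report$gene_summary)) {
    write_tsv_table(report$gene_summary[[tier]],
                    p(sprintf("gene_summary_%s.tsv", tier)))
    en <- report$enrichment[[tier]]
    if (!is.null(en)) {
      class(en) <- "data.frame"
      write_tsv_table(en, p(sprintf("enrichment_%s.tsv", tier)))
    }
    if (!is.null(report$regression[[tier]])) {
      write_tsv_table(report$regression[[tier]]$coefficients,
                      p(sprintf("regression_%s.tsv", tier)))
    }
  }
  write_tsv_table(report$te, p("te_fold_change.tsv"))
  write_tsv_table(report$stage_counts, p("stage_counts.tsv"))
  log <- c("synoribo pipeline report", "",
           "stage counts:",
           sprintf("  %-28s %d", report$stage_counts$stage,
                   report$stage_counts$n), "")
  for (cl in names(report$comparisons)) {
    cmp <- report$comparisons[[cl]]
    log <- c(log, if (is.null(cmp)) {
      sprintf("density comparison (%s): insufficient sites", cl)
    } else {
      sprintf(paste0("density comparison (%s): n = %d, paired t p = %.4g,",
                     " mean diff = %.4f, ancestral > derived at %.1f%%",
                     " of sites"),
              cl, cmp$n_sites, cmp$paired_t$p.value,
              cmp$paired_t$mean_diff, 100 * cmp$direction)
    })
  }
  writeLines(log, p("report.txt"))
  invisible(out_dir)
}

#' @export
print.synoribo_report <- function(x, ...) {
  cat("synoribo_report\n")
  print(x$stage_counts, row.names = FALSE)
  invisible(x)
}

#' Generate synthetic data, run the pipeline, and check recovery
#'
#' The validation harness: simulates a dataset with known ground truth,
#' runs [run_all()], and compares every recovered quantity to the truth:
#' P-site offsets (integer equality), optimality calls at recovered
#' sites, exclusion of panel members from the strict tier, the direction
#' of the allele density difference per class, the direction of the
#' oncogene/TSG enrichment, and the signs of the TE-regression
#' coefficients. When the configured speed factors are exactly 1 the
#' density-direction properties are reported as `"null, as expected"`.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional report directory passed to [run_all()].
#' @param config a [pipeline_config()].
#' @return data.frame of class `recovery_summary` (property, pass,
#'   detail) with the full report attached as attribute `report`; if any
#'   property fails the data.frame is still returned (callers such as
#'   the command-line wrapper turn failures into a nonzero exit).
#' @export
simulate_and_validate <- function(cfg, out_dir = NULL,
                                  config = pipeline_config()) {
  ds <- generate_dataset(cfg)
  report <- run_all(ds, out_dir = out_dir, config = config)
  res <- list()
  add <- function(property, pass, detail = "") {
    res[[length(res) + 1]] <<- data.frame(
      property = property, pass = pass, detail = detail,
      stringsAsFactors = FALSE)
  }

  off <- report$offsets
  truth_off <- cfg$offset_by_length
  got <- off$offset[match(as.integer(names(truth_off)), off$length)]
  add("offset_recovery", identical(as.integer(got),
                                   unname(truth_off)),
      paste(got, collapse = ","))

  tv <- ds$truth$variants
  key_truth <- site_key(tv$gene, tv$pos)
  strict <- report$variants[report$variants$tier == "strict", ]
  m <- match(site_key(strict$gene, strict$pos), key_truth)
  calls <- classify_optimality(strict$anc, strict$der)
  add("optimality_calls", all(calls == tv$optimality[m]),
      sprintf("%d strict sites", nrow(strict)))

  panel_sites <- key_truth[tv$in_panel]
  add("panel_exclusion",
      !any(site_key(strict$gene, strict$pos) %in% panel_sites))

  null_speed <- cfg$speed_factor_optimal == 1 &&
    cfg$speed_factor_nonoptimal == 1
  for (cl in c("optimal", "non_optimal")) {
    cmp <- report$comparisons[[if (cl == "optimal") "optimal"
                               else "non_optimal"]]
    if (is.null(cmp)) { add(paste0("density_direction_", cl), FALSE,
                            "insufficient sites"); next }
    if (null_speed) {
      add(paste0("density_direction_", cl), TRUE, "null, as expected")
    } else if (cl == "optimal") {
      add("density_direction_optimal", cmp$paired_t$mean_diff > 0,
          sprintf("mean anc - der = %.4f", cmp$paired_t$mean_diff))
    } else {
      add("density_direction_non_optimal", cmp$paired_t$mean_diff < 0,
          sprintf("mean anc - der = %.4f", cmp$paired_t$mean_diff))
    }
  }

  en <- report$enrichment$loose
  if (cfg$enrich_opt_onco > 1) {
    r <- en[en$comparison == "optimal_onco_vs_tsg", ]
    add("enrichment_optimal_oncogene", r$mean1 > r$mean2,
        sprintf("KS p = %.3g", r$p.value))
  }
  if (cfg$enrich_nonopt_tsg > 1) {
    r <- en[en$comparison == "nonoptimal_onco_vs_tsg", ]
    add("enrichment_nonoptimal_tsg", r$mean1 < r$mean2,
        sprintf("KS p = %.3g", r$p.value))
  }

  co <- report$regression$loose$coefficients
  b_opt <- co$estimate[co$term == "n_optimal"]
  b_non <- co$estimate[co$term == "n_nonoptimal"]
  if (cfg$te_beta_opt > 0) {
    add("regression_sign_optimal", b_opt > 0, sprintf("%.3f", b_opt))
  }
  if (cfg$te_beta_nonopt < 0) {
    add("regression_sign_nonoptimal", b_non < 0, sprintf("%.3f", b_non))
  }

  out <- do.call(rbind, res)
  class(out) <- c("recovery_summary", class(out))
  attr(out, "report") <- report
  out
}
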