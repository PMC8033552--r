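# Synthetic tumor/normal RNA-seq + ribosome-profiling data with ground truth.
#
# The generator works entirely in transcript coordinates (0-based,
# half-open), one isoform per gene. Injected variants are synonymous
# third-codon-position changes; the derived allele of an "optimal"
# (A/T -> C/G) change gets its RPF A-site density multiplied by
# speed_factor_optimal, a "non-optimal" (C/G -> A/T) change by
# speed_factor_nonoptimal.

STOP_CODONS <- c("TAA", "TAG", "TGA")

sense_codons <- function() {
  all <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)), BASES,
                         paste0))
  setdiff(all, STOP_CODONS)
}

# two-base codon prefixes allowed for a third-position anc->der change so
# that the change is synonymous in both directions (no stop involved, no
# amino-acid change)
prefixes_for_change <- function(anc, der) {
  all16 <- as.vector(outer(BASES, BASES, paste0))
  fourfold <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
  pair <- paste0(sort(c(anc, der)), collapse = "")
  switch(pair,
    "CT" = all16,                       # NNT <-> NNC always synonymous
    "AG" = setdiff(all16, c("TA", "AT", "TG")),
    "AT" = fourfold,
    "CG" = fourfold,
    stop("unsupported third-position change ", anc, "->", der)
  )
}

# sample codon templates for n variants of one class; returns data.frame
# with anc, der, anc_codon, der_codon
sample_templates <- function(n, class) {
  if (n == 0) {
    return(data.frame(anc = character(), der = character(),
                      anc_codon = character(), der_codon = character(),
                      stringsAsFactors = FALSE))
  }
  changes <- switch(class,
    optimal = list(c("T", "C"), c("A", "G")),
    non_optimal = list(c("C", "T"), c("G", "A")),
    unclassified = list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  )
  pick <- sample(length(changes), n, replace = TRUE)
  anc <- vapply(changes[pick], `[`, "", 1)
  der <- vapply(changes[pick], `[`, "", 2)
  pre <- vapply(seq_len(n), function(i) {
    ok <- prefixes_for_change(anc[i], der[i])
    ok[sample.int(length(ok), 1)]
  }, "")
  data.frame(anc = anc, der = der,
             anc_codon = paste0(pre, anc), der_codon = paste0(pre, der),
             stringsAsFactors = FALSE)
}

#' Simulate gene models and transcript sequences
#'
#' Draws CDS lengths uniformly from `cds_len_range` (rounded to codons),
#' builds transcripts as 5'UTR + ATG + random sense codons + stop + 3'UTR,
#' and assigns gene classes (`oncogene`, `TSG`, `other`) at random.
#'
#' @param cfg a [sim_config()].
#' @return list with `cds` (data.frame: gene, tx_len, cds_start, cds_end,
#'   cds_len, class) and `seqs` (named character vector).
#' @export
simulate_genes <- function(cfg) {
  n <- cfg$n_genes
  gene <- sprintf("g%04d", seq_len(n))
  n_cod <- pmax(3L, round(runif(n, cfg$cds_len_range[1] / 3,
                                cfg$cds_len_range[2] / 3)))
  cds_len <- 3L * as.integer(n_cod)
  cds_start <- rep(cfg$utr5_len, n)
  cds_end <- cds_start + cds_len
  tx_len <- cds_end + cfg$utr3_len
  class <- rep("other", n)
  lab <- sample(n, cfg$n_onco + cfg$n_tsg)
  class[lab[seq_len(cfg$n_onco)]] <- "oncogene"
  class[lab[cfg$n_onco + seq_len(cfg$n_tsg)]] <- "TSG"
  sc <- sense_codons()
  seqs <- vapply(seq_len(n), function(i) {
    body <- paste(sample(sc, n_cod[i] - 2L, replace = TRUE), collapse = "")
    paste0(paste(sample(BASES, cfg$utr5_len, replace = TRUE), collapse = ""),
           "ATG", body, sample(STOP_CODONS, 1),
           paste(sample(BASES, cfg$utr3_len, replace = TRUE), collapse = ""))
  }, "")
  names(seqs) <- gene
  list(cds = data.frame(gene = gene, tx_len = tx_len, cds_start = cds_start,
                        cds_end = cds_end, cds_len = cds_len, class = class,
                        stringsAsFactors = FALSE),
       seqs = seqs)
}

#' Simulate per-gene synonymous mutation counts
#'
#' Counts per gene are Poisson with mean `mut_rate_per_kb * cds_kb`,
#' multiplied by `enrich_opt_onco` for optimal mutations in oncogenes and
#' by `enrich_nonopt_tsg` for non-optimal mutations in TSG.
#'
#' @param cfg a [sim_config()].
#' @param cds gene-model data.frame from [simulate_genes()].
#' @return data.frame: gene, class, cds_len, n_optimal, n_nonoptimal,
#'   n_unclassified.
#' @export
simulate_variant_counts <- function(cfg, cds) {
  kb <- cds$cds_len / 1000
  e_opt <- ifelse(cds$class == "oncogene", cfg$enrich_opt_onco, 1)
  e_non <- ifelse(cds$class == "TSG", cfg$enrich_nonopt_tsg, 1)
  data.frame(
    gene = cds$gene, class = cds$class, cds_len = cds$cds_len,
    n_optimal = rpois(nrow(cds), cfg$mut_rate_per_kb * kb * e_opt),
    n_nonoptimal = rpois(nrow(cds), cfg$mut_rate_per_kb * kb * e_non),
    n_unclassified = rpois(nrow(cds), cfg$mut_rate_unclassified_per_kb * kb),
    stringsAsFactors = FALSE
  )
}

#' Inject synonymous variants into simulated genes
#'
#' Places each variant at the third position of a distinct internal codon,
#' rewriting the codon to the sampled ancestral template so the reference
#' sequence carries the ancestral allele. A configurable fraction of sites
#' is turned into polarization decoys (outgroup base different from the
#' reference, or `N`), and a fraction is flagged as known-SNP-panel members.
#'
#' @param cfg a [sim_config()].
#' @param genes output of [simulate_genes()].
#' @return list with `variants` (ground-truth variant table) and `seqs`
#'   (sequences updated to the ancestral templates).
#' @export
simulate_variants <- function(cfg, genes) {
  cds <- genes$cds
  seqs <- genes$seqs
  counts <- simulate_variant_counts(cfg, cds)
  out <- vector("list", nrow(cds))
  for (i in seq_len(nrow(cds))) {
    n_cod <- cds$cds_len[i] / 3L
    avail <- seq.int(1L, n_cod - 2L)   # skip start and stop codons
    n_by_class <- c(optimal = counts$n_optimal[i],
                    non_optimal = counts$n_nonoptimal[i],
                    unclassified = counts$n_unclassified[i])
    n_tot <- min(sum(n_by_class), length(avail))
    if (n_tot == 0) next
    if (sum(n_by_class) > n_tot) {     # truncate, preserving proportions
      keep <- rep(names(n_by_class), n_by_class)[seq_len(n_tot)]
      n_by_class <- table(factor(keep, levels = names(n_by_class)))
    }
    codon_idx <- sample(avail, n_tot)
    tmpl <- do.call(rbind, lapply(names(n_by_class), function(cl) {
      t <- sample_templates(as.integer(n_by_class[[cl]]), cl)
      if (nrow(t)) t$optimality <- cl
      t
    }))
    tmpl$gene <- cds$gene[i]
    tmpl$codon_index <- sort(codon_idx)
    tmpl$pos <- cds$cds_start[i] + tmpl$codon_index * 3L + 2L
    out[[i]] <- tmpl
    # rewrite sequence codons to the ancestral template
    s <- seqs[[cds$gene[i]]]
    for (j in seq_len(nrow(tmpl))) {
      a <- cds$cds_start[i] + tmpl$codon_index[j] * 3L + 1L  # 1-based substr
      substr(s, a, a + 2L) <- tmpl$anc_codon[j]
    }
    seqs[[cds$gene[i]]] <- s
  }
  v <- do.call(rbind, out)
  if (is.null(v)) stop("no variants injected; increase mut_rate_per_kb")
  rownames(v) <- NULL
  # polarization status decoys
  u <- runif(nrow(v))
  v$truth_status <- ifelse(u < cfg$frac_non_ancestral, "non_ancestral_ref",
                    ifelse(u < cfg$frac_non_ancestral +
                             cfg$frac_missing_outgroup,
                           "missing_outgroup", "polarized"))
  v$outgroup <- v$anc
  nonanc <- v$truth_status == "non_ancestral_ref"
  v$outgroup[nonanc] <- vapply(v$anc[nonanc], function(b) {
    sample(setdiff(BASES, b), 1)
  }, "")
  v$outgroup[v$truth_status == "missing_outgroup"] <- "N"
  v$in_panel <- runif(nrow(v)) < cfg$panel_fraction
  # carrier patients: one primary plus occasional sharers
  pats <- sprintf("p%02d", seq_len(cfg$n_patients))
  v$patients <- vapply(seq_len(nrow(v)), function(i) {
    main <- sample(cfg$n_patients, 1)
    extra <- which(runif(cfg$n_patients) < cfg$patient_share_prob)
    paste(pats[sort(unique(c(main, extra)))], collapse = ";")
  }, "")
  v$density_anc <- cfg$base_density
  v$density_der <- cfg$base_density * speed_factor_for(cfg, v$optimality)
  v <- v[order(v$gene, v$pos), c("gene", "pos", "codon_index", "anc", "der",
                                 "anc_codon", "der_codon", "optimality",
                                 "truth_status", "outgroup", "in_panel",
                                 "patients", "density_anc", "density_der")]
  rownames(v) <- NULL
  list(variants = v, seqs = seqs)
}

# empty site-count skeleton with the standard 16 count columns
empty_counts <- function(n) {
  m <- as.data.frame(matrix(0L, nrow = n, ncol = length(count_cols())))
  names(m) <- count_cols()
  m
}

#' Simulate per-site allele-count pileups
#'
#' For each (variant, carrier patient) pair draws RNA depth as
#' `Poisson(rna_depth)` per sample; tumor derived counts as
#' `Binomial(depth, tumor_allele_fraction)`; and RPF A-site counts per
#' allele as `Poisson(rna_count_allele * base_density * speed_factor)`
#' where the speed factor is 1 for ancestral alleles and the class factor
#' for derived alleles. Normal samples carry only the ancestral allele.
#'
#' @param cfg a [sim_config()].
#' @param variants ground-truth variant table from [simulate_variants()];
#'   only `gene`, `pos`, `anc`, `der`, `outgroup`, `optimality` and
#'   (optionally) `patients` are used.
#' @return a site-count data.frame (one row per site x patient) with
#'   columns gene, pos, ref, outgroup, patient and the 16
#'   assay/condition/base count columns.
#' @export
simulate_site_counts <- function(cfg, variants) {
  pat <- if (!is.null(variants$patients)) {
    strsplit(variants$patients, ";", fixed = TRUE)
  } else {
    rep(list("p01"), nrow(variants))
  }
  idx <- rep(seq_len(nrow(variants)), lengths(pat))
  v <- variants[idx, , drop = FALSE]
  n <- nrow(v)
  sc <- data.frame(gene = v$gene, pos = v$pos, ref = v$anc,
                   outgroup = v$outgroup, patient = unlist(pat),
                   stringsAsFactors = FALSE)
  sc <- cbind(sc, empty_counts(n))
  sf <- speed_factor_for(cfg, v$optimality)

  rna_norm <- rpois(n, cfg$rna_depth)
  rna_tum <- rpois(n, cfg$rna_depth)
  rna_tum_der <- rbinom(n, rna_tum, cfg$tumor_allele_fraction)
  rna_tum_anc <- rna_tum - rna_tum_der
  rpf_norm <- rpois(n, rna_norm * cfg$base_density)
  rpf_tum_anc <- rpois(n, rna_tum_anc * cfg$base_density)
  rpf_tum_der <- rpois(n, rna_tum_der * cfg$base_density * sf)

  set_count <- function(sc, assay, condition, base, value) {
    m <- as.matrix(sc[, paste(assay, condition, BASES, sep = "_")])
    m[cbind(seq_len(nrow(sc)), match(base, BASES))] <- value
    sc[, paste(assay, condition, BASES, sep = "_")] <- m
    sc
  }
  sc <- set_count(sc, "rna", "normal", v$anc, rna_norm)
  sc <- set_count(sc, "rpf", "normal", v$anc, rpf_norm)
  sc <- set_count(sc, "rna", "tumor", v$anc, rna_tum_anc)
  sc <- set_count(sc, "rpf", "tumor", v$anc, rpf_tum_anc)
  # derived counts: add (anc and der are distinct, so plain set is safe)
  sc <- set_count(sc, "rna", "tumor", v$der, rna_tum_der)
  sc <- set_count(sc, "rpf", "tumor", v$der, rpf_tum_der)
  sc
}

# frame-noise offsets: 0 with prob frame_fidelity, +-1 with equal halves
frame_noise <- function(n, fidelity) {
  sample(c(-1L, 0L, 1L), n, replace = TRUE,
         prob = c((1 - fidelity) / 2, fidelity, (1 - fidelity) / 2))
}

#' Simulate RPF read alignments in transcript coordinates
#'
#' Two read populations are produced. Start-codon-anchored reads place the
#' P-site on the initiation codon (5' end at `cds_start - offset` plus
#' frame noise) and drive the metagene offset calibration. Variant-anchored
#' reads place the A-site on an injected variant's codon, one read per
#' simulated A-site count, labeled with the allele they carry.
#'
#' @param cfg a [sim_config()].
#' @param cds gene-model data.frame.
#' @param site_counts output of [simulate_site_counts()] (may be `NULL` to
#'   generate calibration reads only).
#' @return data.frame: gene, pos5 (0-based 5' end), length, sample,
#'   condition, site_pos, allele.
#' @export
simulate_rpf_reads <- function(cfg, cds, site_counts = NULL) {
  lens <- as.integer(names(cfg$offset_by_length))
  pats <- sprintf("p%02d", seq_len(cfg$n_patients))
  parts <- list()
  for (k in seq_along(lens)) {
    n <- cfg$reads_per_length
    gi <- sample(nrow(cds), n, replace = TRUE)
    parts[[k]] <- data.frame(
      gene = cds$gene[gi],
      pos5 = cds$cds_start[gi] - cfg$offset_by_length[[k]] +
        frame_noise(n, cfg$frame_fidelity),
      length = lens[k],
      sample = sample(pats, n, replace = TRUE),
      condition = sample(CONDITIONS, n, replace = TRUE),
      site_pos = NA_integer_, allele = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(site_counts) && nrow(site_counts)) {
    sc <- site_counts
    expand <- function(count, condition, base) {
      i <- rep(seq_len(nrow(sc)), count)
      if (!length(i)) return(NULL)
      L <- sample(lens, length(i), replace = TRUE)
      codon_start <- sc$pos[i] - 2L
      data.frame(
        gene = sc$gene[i],
        pos5 = codon_start - 3L - cfg$offset_by_length[as.character(L)] +
          frame_noise(length(i), cfg$frame_fidelity),
        length = L, sample = sc$patient[i], condition = condition,
        site_pos = sc$pos[i], allele = base[i],
        stringsAsFactors = FALSE
      )
    }
    anc <- sc$ref
    der_rna <- as.matrix(sc[, paste("rna", "tumor", BASES, sep = "_")])
    # derived base = the non-ref base with tumor RNA evidence (by design
    # exactly one exists)
    der <- vapply(seq_len(nrow(sc)), function(i) {
      cand <- setdiff(BASES[der_rna[i, ] > 0], anc[i])
      if (length(cand)) cand[1] else anc[i]
    }, "")
    parts <- c(parts, list(
      expand(base_count(sc, "rpf", "normal", anc), "normal", anc),
      expand(base_count(sc, "rpf", "tumor", anc), "tumor", anc),
      expand(base_count(sc, "rpf", "tumor", der), "tumor", der)
    ))
  }
  reads <- do.call(rbind, Filter(Negate(is.null), parts))
  reads <- reads[reads$pos5 >= 0, , drop = FALSE]
  rownames(reads) <- NULL
  reads
}

#' Simulate gene-level expression, TE ground truth and covariates
#'
#' The true log2 translation-efficiency fold change (tumor/normal) of each
#' gene is `te_beta_opt * scaled(n_optimal) + te_beta_nonopt *
#' scaled(n_nonoptimal) + noise`, with predictors min-max scaled to
#' \[-1, 1\]; nuisance covariates (length, a dN surrogate, expression, GC)
#' have no effect on TE. Per-sample gene read counts are Poisson around
#' expression x length x (TE for RPF), so RPKM-ratio estimates recover the
#' programmed TE.
#'
#' @param cfg a [sim_config()].
#' @param genes output of [simulate_genes()] (sequences used for GC).
#' @param variants ground-truth variant table.
#' @return list with `gene_truth`, `covariates` and `gene_counts`
#'   data.frames.
#' @export
simulate_gene_expression <- function(cfg, genes, variants) {
  cds <- genes$cds
  n <- nrow(cds)
  syn <- variants[variants$truth_status == "polarized", , drop = FALSE]
  n_opt <- as.integer(table(factor(
    syn$gene[syn$optimality == "optimal"], levels = cds$gene)))
  n_non <- as.integer(table(factor(
    syn$gene[syn$optimality == "non_optimal"], levels = cds$gene)))
  gc <- vapply(genes$seqs[cds$gene], function(s) {
    b <- strsplit(s, "")[[1]]
    mean(b %in% c("G", "C"))
  }, 0)
  expression <- rlnorm(n, log(100), 0.5)
  dn <- runif(n, 0, 0.5)
  log2fc <- cfg$te_beta_opt * scale_minmax(n_opt) +
    cfg$te_beta_nonopt * scale_minmax(n_non) +
    rnorm(n, 0, cfg$te_noise_sd)
  te_normal <- rlnorm(n, 0, 0.3)
  te_tumor <- te_normal * 2^log2fc

  pats <- sprintf("p%02d", seq_len(cfg$n_patients))
  gene_counts <- do.call(rbind, lapply(pats, function(p) {
    libf <- rlnorm(4, 0, 0.1)  # rna_n, rna_t, rpf_n, rpf_t
    kb <- cds$tx_len / 1000
    data.frame(
      gene = cds$gene, patient = p,
      rna_normal = rpois(n, expression * kb * libf[1]),
      rna_tumor = rpois(n, expression * kb * libf[2]),
      rpf_normal = rpois(n, expression * kb * te_normal * libf[3]),
      rpf_tumor = rpois(n, expression * kb * te_tumor * libf[4]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(gene_counts) <- NULL
  list(
    gene_truth = data.frame(
      gene = cds$gene, class = cds$class, cds_len = cds$cds_len,
      n_optimal = n_opt, n_nonoptimal = n_non,
      te_normal = te_normal, te_tumor = te_tumor, log2_te_fc = log2fc,
      stringsAsFactors = FALSE),
    covariates = data.frame(
      gene = cds$gene, length = cds$tx_len, dn = dn,
      expression = expression, gc = gc, stringsAsFactors = FALSE),
    gene_counts = gene_counts
  )
}

#' Generate a complete synthetic dataset
#'
#' Orchestrates gene, variant, pileup, read and gene-expression simulation
#' under a single seed and returns everything as one bundle, optionally
#' written to a directory of plain-text files (FASTA + TSV).
#'
#' @param cfg a [sim_config()]; `validate_sim_config()` is applied first
#'   and violations are rejected with a message naming the field.
#' @param dir optional output directory; created if missing.
#' @return an object of class `synoribo_dataset`: a list with elements
#'   `config`, `cds`, `seqs`, `site_counts`, `reads`, `panel`,
#'   `gene_classes`, `covariates`, `gene_counts` and `truth`
#'   (list of `variants` and `genes`).
#' @examples
#' ds <- generate_dataset(sim_config(n_genes = 20, n_onco = 5, n_tsg = 5,
#'                                   reads_per_length = 200, seed = 7))
#' nrow(ds$truth$variants)
#' @export
generate_dataset <- function(cfg, dir = NULL) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  genes <- simulate_genes(cfg)
  inj <- simulate_variants(cfg, genes)
  genes$seqs <- inj$seqs
  site_counts <- simulate_site_counts(cfg, inj$variants)
  reads <- simulate_rpf_reads(cfg, genes$cds, site_counts)
  gl <- simulate_gene_expression(cfg, genes, inj$variants)

  pv <- inj$variants[inj$variants$in_panel, , drop = FALSE]
  panel <- data.frame(gene = pv$gene, pos = pv$pos, ref = pv$anc,
                      alt = pv$der, stringsAsFactors = FALSE)
  # a few panel entries at non-variant positions (germline background)
  extra_gene <- sample(genes$cds$gene, 20, replace = TRUE)
  extra_pos <- genes$cds$cds_start[match(extra_gene, genes$cds$gene)] + 5L
  extra <- data.frame(gene = extra_gene, pos = extra_pos,
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  panel <- unique(rbind(panel, extra))
  panel <- panel[order(panel$gene, panel$pos), ]
  rownames(panel) <- NULL

  ds <- list(
    config = cfg,
    cds = genes$cds[, c("gene", "tx_len", "cds_start", "cds_end", "cds_len")],
    seqs = genes$seqs,
    site_counts = site_counts,
    reads = reads,
    panel = panel,
    gene_classes = genes$cds[, c("gene", "class")],
    covariates = gl$covariates,
    gene_counts = gl$gene_counts,
    truth = list(variants = inj$variants, genes = gl$gene_truth)
  )
  class(ds) <- "synoribo_dataset"
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' @export
print.synoribo_dataset <- function(x, ...) {
  cat("synoribo_dataset:", nrow(x$cds), "genes,",
      nrow(x$truth$variants), "injected variants,",
      nrow(x$site_counts), "site-count rows,",
      nrow(x$reads), "RPF reads\n")
  invisible(x)
}

#' Write a dataset bundle to plain-text files
#'
#' @param ds a `synoribo_dataset`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_transcripts(ds$seqs, p("transcripts.fasta"))
  write_tsv_table(ds$cds, p("cds_model.tsv"),
                  comment = "coordinates 0-based, half-open")
  write_tsv_table(ds$site_counts, p("site_counts.tsv"),
                  comment = "pos is 0-based transcript coordinate")
  write_tsv_table(ds$reads, p("rpf_reads.tsv"),
                  comment = "pos5 is the 0-based 5' end")
  write_panel(ds$panel, p("panel.tsv"))
  write_tsv_table(ds$gene_classes, p("gene_classes.tsv"))
  write_tsv_table(ds$covariates, p("covariates.tsv"))
  write_tsv_table(ds$gene_counts, p("gene_counts.tsv"))
  write_tsv_table(ds$truth$variants, p("ground_truth_variants.tsv"))
  write_tsv_table(ds$truth$genes, p("ground_truth_genes.tsv"))
  cfg <- ds$config
  cfg$offset_by_length <- as.list(cfg$offset_by_length)
  yaml::write_yaml(unclass(cfg), p("config.yaml"))
  invisible(dir)
}

#' Read a dataset bundle written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return a `synoribo_dataset` (ground-truth tables included only if
#'   present).
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  cfgl <- yaml::read_yaml(p("config.yaml"))
  cfgl$offset_by_length <- unlist(cfgl$offset_by_length)
  cfg <- do.call(sim_config, cfgl[names(cfgl) %in% names(formals(sim_config))])
  ds <- list(
    config = cfg,
    cds = read_tsv_table(p("cds_model.tsv")),
    seqs = read_transcripts(p("transcripts.fasta")),
    site_counts = read_tsv_table(p("site_counts.tsv")),
    reads = read_tsv_table(p("rpf_reads.tsv")),
    panel = read_panel(p("panel.tsv")),
    gene_classes = read_tsv_table(p("gene_classes.tsv")),
    covariates = read_tsv_table(p("covariates.tsv")),
    gene_counts = read_tsv_table(p("gene_counts.tsv")),
    truth = list(
      variants = if (file.exists(p("ground_truth_variants.tsv")))
        read_tsv_table(p("ground_truth_variants.tsv")),
      genes = if (file.exists(p("ground_truth_genes.tsv")))
        read_tsv_table(p("ground_truth_genes.tsv")))
  )
  class(ds) <- "synoribo_dataset"
  ds
}
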