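# P-site offset calibration and A-site assignment for ribosome-protected
# fragments (RPF).
#
# The 5' ends of RPF reads of a given length pile up at a fixed distance
# upstream of the start codon: that distance is the P-site offset. The
# A-site tri-nucleotide sits immediately downstream of the P-site, so for
# a read with 5' end p and offset d the P-site is [p+d, p+d+3) and the
# A-site [p+d+3, p+d+6) in transcript coordinates.

#' Per-length reading-frame fractions of RPF 5' ends
#'
#' Frame 0 means the 5' end falls on the first position of a codon, i.e.
#' `(pos5 - cds_start) mod 3 == 0`; frames 1 and 2 are the second and
#' third codon positions.
#'
#' @param reads RPF read table (`gene`, `pos5`, `length`).
#' @param cds CDS model (`gene`, `cds_start`, `cds_end`).
#' @return data.frame: length, n, frame0, frame1, frame2 (fractions).
#' @export
frame_fractions <- function(reads, cds) {
  gi <- match(reads$gene, cds$gene)
  keep <- !is.na(gi) & reads$pos5 + reads$length > cds$cds_start[gi] &
    reads$pos5 < cds$cds_end[gi]
  if (!any(keep)) stop("frame_fractions: no reads overlapping a CDS")
  fr <- (reads$pos5[keep] - cds$cds_start[gi][keep]) %% 3L
  len <- reads$length[keep]
  tab <- table(length = len, frame = factor(fr, levels = 0:2))
  frac <- prop.table(tab, margin = 1)
  data.frame(length = as.integer(rownames(tab)),
             n = as.integer(rowSums(tab)),
             frame0 = as.vector(frac[, "0"]),
             frame1 = as.vector(frac[, "1"]),
             frame2 = as.vector(frac[, "2"]))
}

#' Infer per-length P-site offsets from the start-codon metagene
#'
#' For each read length, 5' end positions relative to the start codon are
#' histogrammed over `window`; the offset is the distance from the
#' highest bin (upstream of the start codon) to the start codon, with
#' ties broken toward the smaller offset. Lengths with fewer than
#' `min_reads` reads in the window, a peak below `peak_ratio` times the
#' median bin height, or a peak downstream of the start codon are
#' QC-flagged and excluded from A-site assignment.
#'
#' @param reads RPF read table (`gene`, `pos5`, `length`).
#' @param cds CDS model (`gene`, `cds_start`).
#' @param window integer window of 5'-end positions relative to the start
#'   codon, default `c(-40, 10)`.
#' @param min_reads minimum reads per length inside the window.
#' @param peak_ratio minimum peak height as a multiple of the median bin.
#' @param min_peak_share advisory threshold on local phasing: the peak
#'   bin divided by the sum of the peak and its two 1-nt neighbors
#'   estimates the fraction of 5' ends on the true frame; lengths below
#'   the threshold are marked `qc_warn = "dispersed_peak"` but still
#'   used.
#' @return data.frame of class `offset_table`: length, offset, n_reads,
#'   peak_height, median_bin, qc_pass, qc_reason, qc_warn, plus frame
#'   fractions.
#' @export
infer_psite_offsets <- function(reads, cds, window = c(-40L, 10L),
                                min_reads = 200L, peak_ratio = 2,
                                min_peak_share = 0.7) {
  gi <- match(reads$gene, cds$gene)
  rel <- reads$pos5 - cds$cds_start[gi]
  keep <- !is.na(rel) & rel >= window[1] & rel <= window[2]
  lens <- sort(unique(reads$length))
  grid <- seq.int(window[1], window[2])
  rows <- lapply(lens, function(L) {
    r <- rel[keep & reads$length == L]
    h <- tabulate(match(r, grid), nbins = length(grid))
    peak <- max(h)
    med <- median(h)
    # tie-break: smaller offset = relative position closer to the start
    peak_rel <- grid[max(which(h == peak))]
    offset <- -peak_rel
    qc_reason <- if (length(r) < min_reads) "too_few_reads"
      else if (peak < peak_ratio * max(med, 1)) "weak_peak"
      else if (offset < 0) "peak_downstream_of_start"
      else ""
    pi <- max(which(h == peak))
    neigh <- sum(h[pmax(1, pi - 1):pmin(length(h), pi + 1)])
    qc_warn <- if (qc_reason == "" && neigh > 0 &&
                   peak / neigh < min_peak_share) "dispersed_peak" else ""
    data.frame(length = L, offset = ifelse(qc_reason == "", offset,
                                           NA_integer_),
               n_reads = length(r), peak_height = peak, median_bin = med,
               qc_pass = qc_reason == "", qc_reason = qc_reason,
               qc_warn = qc_warn,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!any(out$qc_pass)) {
    stop("P-site calibration failed for every read length")
  }
  ff <- frame_fractions(reads, cds)
  out <- merge(out, ff[, c("length", "frame0", "frame1", "frame2")],
               by = "length", all.x = TRUE, sort = TRUE)
  class(out) <- c("offset_table", class(out))
  out
}

# offset lookup by read length; NA for flagged/unknown lengths
offset_for_length <- function(offsets, length) {
  i <- match(length, offsets$length)
  off <- offsets$offset[i]
  off[!is.na(i) & !offsets$qc_pass[i]] <- NA_integer_
  off
}

#' A-site interval of RPF reads
#'
#' @param pos5 0-based 5'-end position(s).
#' @param length read length(s) in nt.
#' @param offsets an `offset_table` from [infer_psite_offsets()] (or a
#'   data.frame with `length`, `offset`, `qc_pass`).
#' @return data.frame with `start` and `end` (0-based, half-open) of the
#'   A-site tri-nucleotide; `NA` for reads whose length is absent or
#'   QC-flagged in the table.
#' @examples
#' offs <- data.frame(length = 28, offset = 12, qc_pass = TRUE)
#' asite_interval(100, 28, offs)  # [115, 118)
#' @export
asite_interval <- function(pos5, length, offsets) {
  off <- offset_for_length(offsets, length)
  data.frame(start = pos5 + off + 3L, end = pos5 + off + 6L)
}

#' Count A-site reads per allele at query sites
#'
#' A read contributes to a site when its A-site tri-nucleotide interval
#' contains the site's position. The base carried by the read at the site
#' is taken from the read's allele label when the read is annotated for
#' that site (`site_pos == pos`), otherwise from the transcript reference
#' sequence. Reads with QC-flagged or unknown lengths and reads whose
#' A-site extends beyond the transcript are skipped and counted.
#'
#' @param reads RPF read table (`gene`, `pos5`, `length`, `sample`,
#'   `condition`, optional `site_pos` and `allele`).
#' @param offsets an `offset_table`.
#' @param sites data.frame of query sites (`gene`, `pos`).
#' @param seqs named character vector of transcript sequences (used for
#'   reads without an allele label).
#' @return list with `counts` (data.frame: gene, pos, sample, condition,
#'   A, C, G, T) and `skipped` (named counts of dropped reads).
#' @export
asite_site_counts <- function(reads, offsets, sites, seqs) {
  iv <- asite_interval(reads$pos5, reads$length, offsets)
  known <- !is.na(iv$start)
  tx_len <- nchar(seqs)[reads$gene]
  inb <- known & iv$start >= 0 & iv$end <= ifelse(is.na(tx_len), 0, tx_len)
  skipped <- c(flagged_length = sum(!known),
               out_of_bounds = sum(known & !inb))
  r <- reads[inb, , drop = FALSE]
  ivr <- iv[inb, , drop = FALSE]
  # expand each read to its three A-site positions and join to sites
  pos <- c(ivr$start, ivr$start + 1L, ivr$start + 2L)
  rx <- r[rep(seq_len(nrow(r)), 3), , drop = FALSE]
  rx$at <- pos
  want <- site_key(sites$gene, sites$pos)
  hit <- site_key(rx$gene, rx$at) %in% want
  rx <- rx[hit, , drop = FALSE]
  if (nrow(rx) == 0) {
    return(list(counts = data.frame(gene = character(), pos = integer(),
                                    sample = character(),
                                    condition = character(),
                                    A = integer(), C = integer(),
                                    G = integer(), T = integer()),
                skipped = skipped))
  }
  lab <- !is.na(rx$site_pos) & rx$site_pos == rx$at & !is.na(rx$allele)
  base <- character(nrow(rx))
  base[lab] <- rx$allele[lab]
  if (any(!lab)) {
    base[!lab] <- substr(seqs[rx$gene[!lab]], rx$at[!lab] + 1L,
                         rx$at[!lab] + 1L)
  }
  tab <- as.data.frame(table(
    gene = rx$gene, pos = rx$at, sample = rx$sample,
    condition = rx$condition, base = factor(base, levels = BASES)),
    stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  wide <- reshape_counts(tab)
  wide <- wide[order(wide$gene, wide$pos, wide$sample, wide$condition), ]
  rownames(wide) <- NULL
  list(counts = wide, skipped = skipped)
}

# long (gene,pos,sample,condition,base,Freq) -> wide with A,C,G,T columns
reshape_counts <- function(tab) {
  key <- paste(tab$gene, tab$pos, tab$sample, tab$condition, sep = "\r")
  uk <- unique(key)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  wide <- data.frame(
    gene = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    sample = vapply(parts, `[`, "", 3),
    condition = vapply(parts, `[`, "", 4),
    stringsAsFactors = FALSE
  )
  for (b in BASES) wide[[b]] <- 0L
  m <- match(key, uk)
  for (i in seq_len(nrow(tab))) {
    wide[m[i], tab$base[i]] <- wide[m[i], tab$base[i]] + tab$Freq[i]
  }
  wide
}
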