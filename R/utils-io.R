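#' Read a tab-separated table
#'
#' All tables used by the package are plain TSV with a header row; lines
#' starting with `#` are comments. Strings are never converted to factors.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_tsv_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a tab-separated table
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param comment optional comment line(s) written before the header,
#'   each prefixed with `#`.
#' @export
write_tsv_table <- function(x, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of transcript sequences.
#' @export
read_transcripts <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write transcript sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_transcripts <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a known-SNP panel
#'
#' The panel is a VCF-like TSV with columns `CHROM` (transcript id), `POS`
#' (1-based, VCF convention), `REF` and `ALT`. Internally positions are
#' converted to the package's 0-based convention.
#'
#' @param path panel file.
#' @return data.frame with columns `gene`, `pos` (0-based), `ref`, `alt`.
#' @export
read_panel <- function(path) {
  p <- read_tsv_table(path)
  need <- c("CHROM", "POS", "REF", "ALT")
  if (!all(need %in% names(p))) {
    stop("panel must have columns CHROM, POS, REF, ALT")
  }
  data.frame(gene = p$CHROM, pos = p$POS - 1L, ref = p$REF, alt = p$ALT,
             stringsAsFactors = FALSE)
}

#' Write a known-SNP panel
#'
#' @param panel data.frame with columns `gene`, `pos` (0-based), `ref`, `alt`.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  out <- data.frame(CHROM = panel$gene, POS = panel$pos + 1L,
                    REF = panel$ref, ALT = panel$alt)
  write_tsv_table(out, path, comment = "POS is 1-based (VCF convention)")
}

# site key used for panel lookups and set operations
site_key <- function(gene, pos) paste(gene, pos, sep = ":")
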