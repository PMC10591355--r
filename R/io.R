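# Readers and writers for the standard formats the pipeline touches.
# Sequence formats go through Biostrings; BED through rtracklayer when it is
# available; tabular inputs are plain TSV.

#' Read sequences from a FASTA file
#'
#' @param file Path to an (uncompressed or gzipped) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readBStringSet(file, format = "fasta")
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector (RNA sequences are written as-is).
#' @param file Output path.
#' @export
write_fasta <- function(seqs, file) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), file)
  invisible(file)
}

#' Read read sequences from a FASTQ file
#'
#' @param file Path to an (uncompressed or gzipped) FASTQ file.
#' @return Character vector of read sequences (qualities dropped).
#' @export
read_fastq <- function(file) {
  as.character(Biostrings::readDNAStringSet(file, format = "fastq"))
}

#' Write reads to a FASTQ file with constant quality
#'
#' Simulated reads carry no meaningful quality information, so a constant
#' quality character is written; with fixed input the output is
#' byte-identical across runs.
#'
#' @param reads Character vector of read sequences.
#' @param file Output path.
#' @param id_prefix Read-name prefix (default `"read"`).
#' @param qual_char Quality character (default `"I"`, Phred 40).
#' @export
write_fastq <- function(reads, file, id_prefix = "read", qual_char = "I") {
  con <- file(file, "wb")  # binary mode: LF line endings everywhere
  on.exit(close(con))
  lines <- as.vector(rbind(
    paste0("@", id_prefix, seq_along(reads)),
    reads,
    "+",
    vapply(nchar(reads), function(n)
      paste(rep(qual_char, n), collapse = ""), character(1))))
  writeLines(lines, con)
  invisible(file)
}

#' Read a site-count table from TSV
#'
#' Expected columns: `site_id`, `group`, `replicate`, `ref_count`,
#' `alt_count` (tab-separated, with header).
#'
#' @param file Path to the TSV file.
#' @return A validated [site_count_table()].
#' @export
read_site_counts <- function(file) {
  site_count_table(read.delim(file, stringsAsFactors = FALSE))
}

#' Write a site-count table (or any call table) to TSV
#'
#' @param table data.frame to write.
#' @param file Output path.
#' @export
write_tsv <- function(table, file) {
  write.table(table, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a stranded pileup TSV
#'
#' Expected columns: `chrom`, `pos` (0-based), `ref`, `A`, `C`, `G`, `T`.
#'
#' @param file Path to the TSV file.
#' @return data.frame suitable for [compute_aei()].
#' @export
read_pileup_tsv <- function(file) {
  pu <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "A", "C", "G", "T")
  miss <- setdiff(need, names(pu))
  if (length(miss))
    stop("pileup TSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  pu
}

#' Read intervals from a BED file
#'
#' Uses rtracklayer when installed; falls back to a minimal 6-column
#' reader otherwise (BED is 0-based half-open; the returned data.frame
#' keeps that convention).
#'
#' @param file Path to a BED file.
#' @return data.frame with `chrom`, `start`, `end`, `strand`.
#' @export
read_bed <- function(file) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(file, format = "BED")
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               stringsAsFactors = FALSE)
  } else {
    x <- read.delim(file, header = FALSE, stringsAsFactors = FALSE)
    data.frame(chrom = x[[1]], start = as.integer(x[[2]]),
               end = as.integer(x[[3]]),
               strand = if (ncol(x) >= 6) x[[6]] else "*",
               stringsAsFactors = FALSE)
  }
}

#' Import an amplicon pileup from a BAM file
#'
#' Thin wrapper over `Rsamtools::pileup()` for pipelines whose reads were
#' aligned externally; counts are collapsed to the A/C/G/T/del columns of a
#' [pileup_matrix()].
#'
#' @param bam Path to an indexed BAM file.
#' @param ref An [amplicon_reference()] whose `name` matches the BAM
#'   sequence name.
#' @return A `pileup_matrix`.
#' @export
pileup_from_bam <- function(bam, ref) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("pileup_from_bam requires the Rsamtools package", call. = FALSE)
  stopifnot(is(ref, "amplicon_reference"))
  L <- nchar(ref$sequence)
  param <- Rsamtools::PileupParam(max_depth = 1e6L, min_base_quality = 0L,
                                  min_mapq = 0L, min_nucleotide_depth = 0L,
                                  distinguish_strands = FALSE,
                                  include_deletions = TRUE)
  sbp <- Rsamtools::ScanBamParam(which = GenomicRanges::GRanges(
    ref$name, IRanges::IRanges(1L, L)))
  res <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = param)
  counts <- matrix(0L, nrow = L, ncol = 5L,
                   dimnames = list(NULL, c(.BASES, "del")))
  nuc <- as.character(res$nucleotide)
  nuc[nuc == "-"] <- "del"
  keep <- nuc %in% colnames(counts)
  idx <- cbind(res$pos[keep], match(nuc[keep], colnames(counts)))
  for (i in seq_len(nrow(idx)))
    counts[idx[i, 1], idx[i, 2]] <- counts[idx[i, 1], idx[i, 2]] +
      res$count[keep][i]
  structure(counts, class = "pileup_matrix", ref = ref,
            n_used = NA_integer_, n_discarded = NA_integer_)
}
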