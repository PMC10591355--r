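# Simplified Alu Editing Index: the depth-weighted A>G mismatch rate over
# expressed Alu repeats, a proxy for global ADAR activity. Strand is taken
# from the interval annotation: on '+' intervals edited adenosines appear as
# G at reference A; on '-' intervals the sense-space mirror is C at
# reference T.

#' Compute the Alu Editing Index from stranded pileups
#'
#' Pools, over every position of the (merged) Alu intervals that carries the
#' strand-appropriate reference base, the edited-read count and the total
#' read count, and reports `100 * sum(edited) / sum(depth)`.
#'
#' @param pileup data.frame with columns `chrom`, `pos` (0-based), `ref`
#'   (reference base on the + genomic strand) and counts `A`, `C`, `G`, `T`.
#' @param intervals Alu annotation: a `GenomicRanges::GRanges` with strand,
#'   or a data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `strand`. Overlapping intervals are merged per strand.
#' @param snp_mask Optional positions to exclude (known SNPs): `GRanges` or
#'   data.frame `chrom`, `start`, `end` (0-based half-open).
#' @return Object of class `aei_result`: list with `aei_percent`,
#'   `numerator` (edited reads), `denominator` (total reads at counted
#'   positions), `n_positions`.
#' @examples
#' pu <- data.frame(chrom = "chr1", pos = 0:3, ref = c("A","A","T","C"),
#'                  A = c(95, 100, 0, 0), C = c(0, 0, 5, 100),
#'                  G = c(5, 0, 0, 0), T = c(0, 0, 95, 0))
#' iv <- data.frame(chrom = "chr1", start = 0, end = 4, strand = "+")
#' compute_aei(pu, iv)  # 5 G reads over 200 A-position reads -> 2.5%
#' @export
compute_aei <- function(pileup, intervals, snp_mask = NULL) {
  need <- c("chrom", "pos", "ref", "A", "C", "G", "T")
  miss <- setdiff(need, names(pileup))
  if (length(miss))
    stop("pileup lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  gr <- .as_granges_intervals(intervals)
  gr <- GenomicRanges::reduce(gr)  # merges within strand by default
  pos_gr <- GenomicRanges::GRanges(
    pileup$chrom, IRanges::IRanges(pileup$pos + 1L, width = 1L))
  if (!is.null(snp_mask)) {
    mask <- .as_granges_intervals(snp_mask, stranded = FALSE)
    masked <- IRanges::overlapsAny(pos_gr, mask, ignore.strand = TRUE)
  } else masked <- rep(FALSE, nrow(pileup))
  hits <- GenomicRanges::findOverlaps(pos_gr, gr, ignore.strand = TRUE)
  pid <- S4Vectors::queryHits(hits)
  strand <- as.character(GenomicRanges::strand(gr))[S4Vectors::subjectHits(hits)]
  ref <- toupper(pileup$ref)[pid]
  use_plus <- strand == "+" & ref == "A" & !masked[pid]
  use_minus <- strand == "-" & ref == "T" & !masked[pid]
  depth <- pileup$A + pileup$C + pileup$G + pileup$T
  num <- sum(pileup$G[pid[use_plus]]) + sum(pileup$C[pid[use_minus]])
  den <- sum(depth[pid[use_plus]]) + sum(depth[pid[use_minus]])
  if (den == 0)
    stop("undefined index: no covered strand-matched reference positions",
         call. = FALSE)
  structure(list(aei_percent = 100 * num / den,
                 numerator = num, denominator = den,
                 n_positions = sum(use_plus) + sum(use_minus)),
            class = "aei_result")
}

.as_granges_intervals <- function(x, stranded = TRUE) {
  if (is(x, "GRanges")) return(x)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x)))
    stop("intervals need columns chrom, start, end", call. = FALSE)
  strand <- if (stranded && "strand" %in% names(x)) x$strand else "*"
  if (any(x$start >= x$end))
    stop("intervals must satisfy start < end (0-based half-open)",
         call. = FALSE)
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(x$start + 1L, x$end),
                         strand = strand)
}

#' @export
print.aei_result <- function(x, ...) {
  cat(sprintf("AEI = %.3f%% (%d edited / %d total reads at %d positions)\n",
              x$aei_percent, x$numerator, x$denominator, x$n_positions))
  invisible(x)
}
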