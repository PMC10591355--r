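# Targeted amplicon A>G quantification.
#
# Reads are placed on the amplicon reference by a deterministic ungapped
# offset scan in both orientations (adequate for amplicon data, where reads
# are near-exact copies of a short known reference); a per-position pileup of
# A/C/G/T/deletion counts is accumulated, the empirical noise level is
# estimated from every substitution class other than A>G, and sites above
# mean + k*SD of that noise are called genuine edits.

.BASES <- c("A", "C", "G", "T")
.DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcomp_dna <- function(x) {
  chars <- rev(strsplit(chartr("U", "T", toupper(x)), "", fixed = TRUE)[[1]])
  paste(.DNA_COMPLEMENT[chars], collapse = "")
}

#' Define an amplicon reference
#'
#' @param name Amplicon name.
#' @param sequence Sense-strand DNA sequence of the amplified target region
#'   (RNA input is reverse-transcribed, U -> T).
#' @param target_index 0-based position of the target adenosine.
#' @return An object of class `amplicon_reference`.
#' @export
amplicon_reference <- function(name, sequence, target_index) {
  sequence <- chartr("Uu", "Tt", toupper(sequence))
  if (grepl("[^ACGTN]", sequence))
    stop("reference contains characters outside {A,C,G,T,N}", call. = FALSE)
  target_index <- as.integer(target_index)
  if (target_index < 0L || target_index >= nchar(sequence))
    stop("target_index out of bounds", call. = FALSE)
  if (substr(sequence, target_index + 1L, target_index + 1L) != "A")
    stop("base at target_index is not an adenosine", call. = FALSE)
  structure(list(name = as.character(name), sequence = sequence,
                 target_index = target_index),
            class = "amplicon_reference")
}

.encode_base <- function(chars) {
  code <- match(chars, .BASES)
  code[is.na(code)] <- 5L  # N / anything else: never matches, not counted
  code
}

#' Build a per-position pileup from amplicon reads
#'
#' Each read is placed at its best ungapped offset against the reference,
#' trying both orientations; the orientation/offset pair with the highest
#' identity over the overlap wins (ties: smaller offset, then forward
#' strand). Reads whose best identity is below `min_identity` or whose
#' overlap is shorter than `min_overlap` are discarded (and counted).
#'
#' @param reads Character vector or `Biostrings::DNAStringSet` of read
#'   sequences, or the path of a FASTQ file.
#' @param ref An [amplicon_reference()].
#' @param min_identity Minimum fraction of matching bases over the overlap
#'   (default 0.8).
#' @param min_overlap Minimum read/reference overlap in nt (default 20).
#' @return A `pileup_matrix`: integer matrix with one row per reference
#'   position and columns `A,C,G,T,del`, with attributes `ref`
#'   (the `amplicon_reference`), `n_used`, `n_discarded`.
#' @export
align_reads <- function(reads, ref, min_identity = 0.8, min_overlap = 20L) {
  stopifnot(is(ref, "amplicon_reference"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  if (is(reads, "XStringSet")) reads <- as.character(reads)
  reads <- chartr("Uu", "Tt", toupper(reads))
  if (length(reads) == 0L) stop("no reads supplied", call. = FALSE)
  L <- nchar(ref$sequence)
  refcode <- .encode_base(strsplit(ref$sequence, "", fixed = TRUE)[[1]])
  counts <- matrix(0L, nrow = L, ncol = 5L,
                   dimnames = list(NULL, c(.BASES, "del")))
  n_used <- 0L; n_discarded <- 0L

  for (rl in unique(nchar(reads))) {
    grp <- reads[nchar(reads) == rl]
    n <- length(grp)
    fwd <- matrix(.encode_base(unlist(strsplit(grp, "", fixed = TRUE),
                                      use.names = FALSE)),
                  nrow = n, byrow = TRUE)
    rev_ <- matrix(0L, nrow = n, ncol = rl)
    comp <- c(4L, 3L, 2L, 1L, 5L)  # A<->T, C<->G under the 1..5 encoding
    rev_[] <- comp[fwd[, rl:1, drop = FALSE]]
    mo <- min(min_overlap, rl, L)  # short amplicons/reads cap the overlap
    offsets <- seq.int(-(rl - mo), L - mo)
    best_id <- rep(-1, n); best_off <- rep(NA_integer_, n)
    best_strand <- rep(1L, n)
    for (strand in 1:2) {
      mat <- if (strand == 1L) fwd else rev_
      for (off in offsets) {
        rpos <- max(0L, -off) + 1L
        cpos <- max(0L, off) + 1L
        ov <- min(rl - rpos + 1L, L - cpos + 1L)
        if (ov < mo) next
        hits <- mat[, rpos:(rpos + ov - 1L), drop = FALSE] ==
          matrix(refcode[cpos:(cpos + ov - 1L)], nrow = n, ncol = ov,
                 byrow = TRUE)
        ident <- rowSums(hits) / ov
        # strict > keeps the first-seen candidate: smaller offsets and the
        # forward strand are scanned first, giving the documented tie-break
        upd <- ident > best_id + 1e-12
        best_id[upd] <- ident[upd]
        best_off[upd] <- off
        best_strand[upd] <- strand
      }
    }
    keep <- best_id >= min_identity
    n_used <- n_used + sum(keep)
    n_discarded <- n_discarded + sum(!keep)
    if (!any(keep)) next
    for (i in which(keep)) {
      mat <- if (best_strand[i] == 1L) fwd else rev_
      off <- best_off[i]
      rpos <- max(0L, -off) + 1L
      cpos <- max(0L, off) + 1L
      ov <- min(rl - rpos + 1L, L - cpos + 1L)
      codes <- mat[i, rpos:(rpos + ov - 1L)]
      pos <- cpos:(cpos + ov - 1L)
      ok <- codes <= 4L
      idx <- cbind(pos[ok], codes[ok])
      counts[idx] <- counts[idx] + 1L
    }
  }
  if (n_used == 0L)
    warning("no read passed the identity filter; pileup is empty")
  structure(counts, class = "pileup_matrix", ref = ref,
            n_used = n_used, n_discarded = n_discarded)
}

#' Construct a pileup matrix from pre-computed counts
#'
#' For pipelines that already produced a per-position base-count table
#' (e.g. from an external aligner): columns `A,C,G,T` and optionally `del`.
#'
#' @param counts Matrix or data.frame of non-negative counts, one row per
#'   reference position.
#' @param ref An [amplicon_reference()] with matching length.
#' @return A `pileup_matrix`.
#' @export
pileup_matrix <- function(counts, ref) {
  stopifnot(is(ref, "amplicon_reference"))
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    if (!ncol(counts) %in% 4:5)
      stop("unnamed count matrices must have columns A,C,G,T[,del]",
           call. = FALSE)
    colnames(counts) <- c(.BASES, "del")[seq_len(ncol(counts))]
  }
  if (!"del" %in% colnames(counts)) counts <- cbind(counts, del = 0L)
  counts <- counts[, c(.BASES, "del"), drop = FALSE]
  if (nrow(counts) != nchar(ref$sequence))
    stop("pileup has ", nrow(counts), " rows but reference has ",
         nchar(ref$sequence), " positions", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(counts, class = "pileup_matrix", ref = ref,
            n_used = NA_integer_, n_discarded = NA_integer_)
}

#' Per-position depth of a pileup
#'
#' Depth is the total read count at a position: the four base counts plus
#' deletions (deletions contribute to depth but never to substitutions).
#'
#' @param pileup A `pileup_matrix`.
#' @return Integer vector of depths.
#' @export
pileup_depth <- function(pileup) {
  as.integer(rowSums(unclass(pileup)))
}

#' Estimate the sequencing/RT noise threshold
#'
#' Collects the per-site frequency of every substitution class except A>G
#' (the editing signal) over all positions with depth at least `min_depth`,
#' and returns mean + `k` * SD of those frequencies. Any A>G frequency above
#' this value is unlikely to be explained by the noise floor.
#'
#' @param pileup A `pileup_matrix`.
#' @param k Multiplier on the sample standard deviation (default 1).
#' @param min_depth Minimum depth for a position to contribute (default 50).
#' @return An object of class `noise_threshold`: list with `mean_non_ag`,
#'   `sd_non_ag`, `k`, `value` (= mean + k*SD), `n_frequencies`.
#' @examples
#' # non-A>G frequencies 0.01, 0.02, 0.03 at k = 1 give a threshold of 0.03
#' @export
noise_threshold <- function(pileup, k = 1, min_depth = 50L) {
  stopifnot(is(pileup, "pileup_matrix"))
  freqs <- .non_ag_frequencies(pileup, min_depth)
  if (length(freqs) < 2L)
    stop("insufficient data: fewer than 2 non-A>G site frequencies at ",
         "depth >= ", min_depth, call. = FALSE)
  m <- mean(freqs); s <- sd(freqs)
  structure(list(mean_non_ag = m, sd_non_ag = s, k = k,
                 value = m + k * s, n_frequencies = length(freqs)),
            class = "noise_threshold")
}

.non_ag_frequencies <- function(pileup, min_depth) {
  ref <- attr(pileup, "ref")
  refchars <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  depth <- pileup_depth(pileup)
  counts <- unclass(pileup)
  freqs <- numeric(0)
  for (b in .BASES) {
    at <- which(refchars == b & depth >= min_depth)
    if (!length(at)) next
    for (alt in setdiff(.BASES, b)) {
      if (b == "A" && alt == "G") next
      freqs <- c(freqs, counts[at, alt] / depth[at])
    }
  }
  freqs
}

#' @export
print.noise_threshold <- function(x, ...) {
  cat(sprintf(
    "noise threshold: %.4g (mean %.4g + %g * SD %.4g; %d frequencies)\n",
    x$value, x$mean_non_ag, x$k, x$sd_non_ag, x$n_frequencies))
  invisible(x)
}

#' Call genuine A>G edits on an amplicon
#'
#' For every reference adenosine, the A>G frequency (G count / depth) is
#' compared to the noise threshold; a site is a genuine edit when its
#' frequency exceeds the threshold at sufficient depth. When a control
#' pileup is supplied, sites that also exceed the threshold in the control
#' are filtered out as SNP/germline-like high-frequency variants shared by
#' both samples.
#'
#' @param pileup `pileup_matrix` of the treated sample.
#' @param threshold A [noise_threshold()]; computed from `pileup` with the
#'   given `k`/`min_depth` when `NULL`.
#' @param control_pileup Optional `pileup_matrix` of an untreated control on
#'   the same reference.
#' @param k,min_depth Passed to [noise_threshold()] when it is computed here;
#'   `min_depth` also gates calling.
#' @return data.frame of class `site_editing_calls`, one row per reference
#'   adenosine: `position` (0-based), `offset` (relative to the target),
#'   `ref_base`, `substitution` (`"A>G"`), `frequency`, `depth`, `genuine`,
#'   and `control_frequency` (NA without a control). The threshold is
#'   attached as attribute `"threshold"`.
#' @export
call_edits <- function(pileup, threshold = NULL, control_pileup = NULL,
                       k = 1, min_depth = 50L) {
  stopifnot(is(pileup, "pileup_matrix"))
  ref <- attr(pileup, "ref")
  if (is.null(threshold)) threshold <- noise_threshold(pileup, k, min_depth)
  stopifnot(is(threshold, "noise_threshold"))
  if (!is.null(control_pileup)) {
    stopifnot(is(control_pileup, "pileup_matrix"))
    if (nrow(control_pileup) != nrow(pileup))
      stop("control pileup length differs from treated pileup",
           call. = FALSE)
  }
  refchars <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  a_pos <- which(refchars == "A")  # 1-based
  depth <- pileup_depth(pileup)[a_pos]
  gcount <- unclass(pileup)[a_pos, "G"]
  freq <- ifelse(depth > 0L, gcount / depth, 0)
  genuine <- depth >= min_depth & freq > threshold$value
  ctrl_freq <- rep(NA_real_, length(a_pos))
  if (!is.null(control_pileup)) {
    cdepth <- pileup_depth(control_pileup)[a_pos]
    cg <- unclass(control_pileup)[a_pos, "G"]
    ctrl_freq <- ifelse(cdepth > 0L, cg / cdepth, 0)
    shared <- cdepth >= min_depth & ctrl_freq > threshold$value
    genuine <- genuine & !shared
  }
  out <- data.frame(
    position = a_pos - 1L,
    offset = a_pos - 1L - ref$target_index,
    ref_base = "A", substitution = "A>G",
    frequency = freq, depth = depth,
    control_frequency = ctrl_freq,
    genuine = genuine,
    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("site_editing_calls", "data.frame")
  out
}

#' Editing profile across the guide-paired window
#'
#' Restricts site calls to the adenosines inside the arRNA-paired window
#' around the target (offset 0 is always reported, so the on-target row is
#' present even on an empty window).
#'
#' @param calls Output of [call_edits()].
#' @param window Length-2 integer vector `c(upstream, downstream)` of
#'   pairing arm lengths, or an [arrna_spec()].
#' @return data.frame with columns `offset`, `frequency`, `depth`,
#'   `genuine`, ordered by offset.
#' @export
bystander_profile <- function(calls, window) {
  stopifnot(is(calls, "site_editing_calls"))
  if (is(window, "arrna_spec"))
    window <- c(window$upstream_len, window$downstream_len)
  window <- abs(as.integer(window))
  keep <- calls$offset >= -window[1] & calls$offset <= window[2]
  out <- calls[keep, c("offset", "frequency", "depth", "genuine")]
  if (!0L %in% out$offset) {
    out <- rbind(out, data.frame(offset = 0L, frequency = NA_real_,
                                 depth = NA_integer_, genuine = NA))
  }
  out <- out[order(out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the codon-level effect of an A>G edit
#'
#' Applies A -> G at the given site inside its codon and classifies the
#' amino-acid consequence under the standard genetic code. The reading frame
#' is given as a phase: positions `i` with `(i - cds_frame_offset) %% 3 == 0`
#' are first codon bases.
#'
#' @param sequence Coding-strand sequence containing the site (DNA or RNA).
#' @param site_index 0-based position of the edited adenosine.
#' @param cds_frame_offset Frame phase 0..2, or `NULL` for a non-coding
#'   site.
#' @return One of `"synonymous"`, `"missense"`, `"stop_loss"`,
#'   `"stop_gain"`, `"noncoding"`, `"n/a"` (codon truncated at the sequence
#'   edge).
#' @examples
#' codon_effect("TAG", 1, 0)   # stop_loss: TAG -> TGG (Trp)
#' codon_effect("CCA", 2, 0)   # synonymous (Pro)
#' codon_effect("AAA", 1, 0)   # missense (Lys -> Arg)
#' @export
codon_effect <- function(sequence, site_index, cds_frame_offset = NULL) {
  if (is.null(cds_frame_offset)) return("noncoding")
  sequence <- chartr("Uu", "Tt", toupper(sequence))
  site_index <- as.integer(site_index)
  stopifnot(cds_frame_offset %in% 0:2,
            site_index >= 0L, site_index < nchar(sequence))
  if (substr(sequence, site_index + 1L, site_index + 1L) != "A")
    stop("site is not an adenosine", call. = FALSE)
  codon_pos <- (site_index - cds_frame_offset) %% 3L
  start <- site_index - codon_pos  # 0-based first base of the codon
  if (start < 0L || start + 2L >= nchar(sequence)) return("n/a")
  ref_codon <- substr(sequence, start + 1L, start + 3L)
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos + 1L, codon_pos + 1L) <- "G"
  ref_aa <- Biostrings::GENETIC_CODE[[ref_codon]]
  alt_aa <- Biostrings::GENETIC_CODE[[alt_codon]]
  if (ref_aa == alt_aa) return("synonymous")
  if (ref_aa == "*" && alt_aa != "*") return("stop_loss")
  if (alt_aa == "*" && ref_aa != "*") return("stop_gain")
  "missense"
}
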