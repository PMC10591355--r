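# Transcriptome-wide differential editing from replicate site-count tables.
#
# A site-count table is a long-format data.frame with one row per
# site x group x replicate:
#   site_id    chrom:pos:strand or any stable label
#   group      "control" or "treatment"
#   replicate  replicate label within the group
#   ref_count  reads supporting the reference base
#   alt_count  reads supporting the edited base (G at an A site)
# and optionally `annotation` (UTR / synonymous / missense / ...).
#
# The cascade mirrors common RNA-editing practice: exclude shallow or
# near-zero sites, pool replicates per group, Fisher's exact test on the
# pooled 2x2 table, BH correction across tested sites, and a call requiring
# both adjusted significance and a minimum absolute level difference.

#' Validate a site-count table
#'
#' @param table data.frame with columns `site_id`, `group`, `replicate`,
#'   `ref_count`, `alt_count` (see the module description above).
#' @return The table, with `group` normalized to `"control"`/`"treatment"`.
#' @export
site_count_table <- function(table) {
  need <- c("site_id", "group", "replicate", "ref_count", "alt_count")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("site-count table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  table$group <- tolower(as.character(table$group))
  if (!all(table$group %in% c("control", "treatment")))
    stop("group must be 'control' or 'treatment'", call. = FALSE)
  if (any(table$ref_count < 0) || any(table$alt_count < 0))
    stop("counts must be non-negative", call. = FALSE)
  nrep <- tapply(table$replicate, paste(table$site_id, table$group),
                 function(x) length(unique(x)))
  if (length(unique(nrep)) > 1L)
    stop("all sites must share the same replicate structure", call. = FALSE)
  table
}

.pooled_levels <- function(table) {
  agg <- stats::aggregate(cbind(ref_count, alt_count) ~ site_id + group,
                          data = table, FUN = sum)
  agg$total <- agg$ref_count + agg$alt_count
  agg$level <- ifelse(agg$total > 0, agg$alt_count / agg$total, NA_real_)
  agg
}

#' Filter sites before differential testing
#'
#' Excludes sites with fewer than `min_reads` total reads (summed over all
#' replicates of both groups) and sites whose pooled editing level stays
#' below `min_level` in every comparison group.
#'
#' @param table A [site_count_table()].
#' @param min_reads Minimum total read count (default 50).
#' @param min_level Minimum pooled editing level reached in at least one
#'   group (default 0.05).
#' @return List with `kept` (the table restricted to surviving sites) and
#'   `excluded` (data.frame `site_id`, `reason` in
#'   `"low_depth"`/`"low_editing"`; depth takes precedence).
#' @export
filter_sites <- function(table, min_reads = 50L, min_level = 0.05) {
  table <- site_count_table(table)
  if (nrow(table) == 0L)
    return(list(kept = table,
                excluded = data.frame(site_id = character(0),
                                      reason = character(0))))
  agg <- .pooled_levels(table)
  tot <- tapply(agg$total, agg$site_id, sum)
  maxlev <- tapply(agg$level, agg$site_id, function(x)
    if (all(is.na(x))) 0 else max(x, na.rm = TRUE))
  ids <- names(tot)
  low_depth <- tot < min_reads
  low_edit <- !low_depth & maxlev < min_level
  excluded <- data.frame(
    site_id = c(ids[low_depth], ids[low_edit]),
    reason = c(rep("low_depth", sum(low_depth)),
               rep("low_editing", sum(low_edit))),
    stringsAsFactors = FALSE)
  excluded <- excluded[order(excluded$site_id), , drop = FALSE]
  rownames(excluded) <- NULL
  keep_ids <- ids[!(low_depth | low_edit)]
  list(kept = table[table$site_id %in% keep_ids, , drop = FALSE],
       excluded = excluded)
}

#' Two-sided Fisher p-value for a pooled 2x2 site table
#'
#' @param ref_c,alt_c,ref_t,alt_t Pooled ref/alt counts in control and
#'   treatment.
#' @return The two-sided p-value of `stats::fisher.test` on the 2x2 table
#'   `rbind(c(ref_c, alt_c), c(ref_t, alt_t))`.
#' @keywords internal
#' @export
fisher_site_p <- function(ref_c, alt_c, ref_t, alt_t) {
  stats::fisher.test(matrix(c(ref_c, alt_c, ref_t, alt_t), nrow = 2L,
                            byrow = TRUE), conf.int = FALSE)$p.value
}

#' Call differentially edited sites
#'
#' Replicate counts are pooled per group; each site's pooled 2x2 table
#' (ref/alt x control/treatment) is tested with a two-sided Fisher's exact
#' test; p-values are BH-adjusted across all tested sites; a site is
#' differential when `p_adj < alpha` and the absolute difference in pooled
#' editing level exceeds `delta_min` (in either direction).
#'
#' @param table A [site_count_table()], normally the `kept` component of
#'   [filter_sites()]. No additional depth/level filter is applied here.
#' @param alpha Adjusted-p cutoff (default 0.01).
#' @param delta_min Minimum absolute level difference (default 0.10).
#' @return data.frame of class `differential_calls`, one row per site:
#'   `site_id`, `level_control`, `level_treatment`, `delta`
#'   (treatment - control), `p`, `p_adj`, `status`
#'   (`differential` / `not_differential` / `excluded`),
#'   `exclusion_reason`. Rows are ordered by `(p, site_id)`; BH rank ties
#'   are resolved by that same order.
#' @export
fisher_differential <- function(table, alpha = 0.01, delta_min = 0.10) {
  table <- site_count_table(table)
  if (nrow(table) == 0L) stop("no sites to test", call. = FALSE)
  agg <- .pooled_levels(table)
  wide <- merge(agg[agg$group == "control",
                    c("site_id", "ref_count", "alt_count", "total", "level")],
                agg[agg$group == "treatment",
                    c("site_id", "ref_count", "alt_count", "total", "level")],
                by = "site_id", suffixes = c("_c", "_t"))
  testable <- wide$total_c > 0 & wide$total_t > 0
  p <- rep(NA_real_, nrow(wide))
  p[testable] <- mapply(fisher_site_p,
                        wide$ref_count_c[testable], wide$alt_count_c[testable],
                        wide$ref_count_t[testable], wide$alt_count_t[testable])
  p_adj <- rep(NA_real_, nrow(wide))
  p_adj[testable] <- p.adjust(p[testable], method = "BH")
  delta <- wide$level_t - wide$level_c
  status <- ifelse(!testable, "excluded",
                   ifelse(p_adj < alpha & abs(delta) > delta_min,
                          "differential", "not_differential"))
  out <- data.frame(
    site_id = wide$site_id,
    level_control = wide$level_c,
    level_treatment = wide$level_t,
    delta = delta, p = p, p_adj = p_adj,
    status = status,
    exclusion_reason = ifelse(testable, NA_character_, "zero_depth_group"),
    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("differential_calls", "data.frame")
  out
}

#' Candidate treatment-only ("novel") editing sites
#'
#' A candidate off-target is a site detected (per-replicate editing level at
#' or above `detect_level`) in every treatment replicate while staying below
#' that level in every control replicate.
#'
#' @param table A [site_count_table()] with at least 2 treatment replicates.
#' @param detect_level Per-replicate detection threshold (default 0.05).
#' @return Character vector of candidate site ids, sorted.
#' @export
novel_site_candidates <- function(table, detect_level = 0.05) {
  table <- site_count_table(table)
  trt <- table[table$group == "treatment", ]
  if (length(unique(trt$replicate)) < 2L)
    stop("need at least 2 treatment replicates", call. = FALSE)
  tot <- table$ref_count + table$alt_count
  lev <- ifelse(tot > 0, table$alt_count / tot, 0)
  detected <- lev >= detect_level
  in_all_trt <- tapply(detected[table$group == "treatment"],
                       table$site_id[table$group == "treatment"], all)
  in_no_ctrl <- tapply(detected[table$group == "control"],
                       table$site_id[table$group == "control"],
                       function(x) !any(x))
  ids <- names(in_all_trt)[in_all_trt & in_no_ctrl[names(in_all_trt)]]
  sort(ids[!is.na(ids)])
}

#' Screen a candidate site for sequence-dependent complementarity
#'
#' Guide-dependent ("sequence-dependent") off-targets require the arRNA to
#' form a duplex with the transcript around the edited site. The screen
#' computes the best local alignment of the arRNA against the reverse
#' complement of the flanking window (match +1, mismatch -1, linear gap -2
#' by default) and compares it with an empirical null: the same score on
#' `n_shuffle` composition-preserving shuffles of the window. The site is
#' flagged `sequence_dependent` when the observed score reaches the
#' `null_quantile` quantile of the null scores.
#'
#' @param window Flanking sequence around the candidate site (typically the
#'   site with 100 nt on each side, clipped at contig ends); at least 15 nt.
#' @param arrna arRNA sequence (RNA or DNA alphabet) or an `arrna_design`.
#' @param match,mismatch,gap Alignment scores (gap is linear, per base).
#' @param n_shuffle Size of the empirical null (default 200).
#' @param null_quantile Quantile of the null used as cutoff (default 0.99).
#' @param seed Seed for the shuffle null (default 1), so the cutoff is
#'   reproducible.
#' @return List of class `offtarget_candidate`: `score`, `cutoff`,
#'   `sequence_dependent`, `null_scores`.
#' @export
homology_screen <- function(window, arrna, match = 1, mismatch = -1,
                            gap = -2, n_shuffle = 200L, null_quantile = 0.99,
                            seed = 1L) {
  if (is(arrna, "arrna_design")) arrna <- arrna$sequence
  window <- chartr("Uu", "Tt", toupper(window))
  arrna <- chartr("Uu", "Tt", toupper(arrna))
  if (nchar(window) < 15L)
    stop("insufficient context: window shorter than 15 nt", call. = FALSE)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                     mismatch = mismatch,
                                                     baseOnly = TRUE)
  score1 <- function(win) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(arrna),
      Biostrings::reverseComplement(Biostrings::DNAString(win)),
      type = "local", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = abs(gap), scoreOnly = TRUE)
  }
  obs <- score1(window)
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  null_scores <- withr_seed(seed, vapply(seq_len(n_shuffle), function(i)
    score1(paste(sample(chars), collapse = "")), numeric(1)))
  cutoff <- as.numeric(quantile(null_scores, null_quantile, type = 1))
  structure(list(score = obs, cutoff = cutoff,
                 sequence_dependent = obs >= cutoff,
                 null_scores = null_scores),
            class = "offtarget_candidate")
}

# evaluate `expr` under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Extract the flanking window around a site from a transcript
#'
#' @param sequence Transcript or genomic sequence.
#' @param site_index 0-based site position.
#' @param flank Flank length per side (default 100); clipped at the
#'   sequence ends.
#' @return The clipped window as a character string.
#' @export
site_flanks <- function(sequence, site_index, flank = 100L) {
  site_index <- as.integer(site_index); flank <- as.integer(flank)
  stopifnot(site_index >= 0L, site_index < nchar(sequence))
  from <- max(0L, site_index - flank)
  to <- min(nchar(sequence) - 1L, site_index + flank)
  substr(sequence, from + 1L, to + 1L)
}
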