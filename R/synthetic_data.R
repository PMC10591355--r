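# Simulators for every input the pipeline consumes. All generators are pure
# functions of their arguments plus a mandatory seed (local RNG state; the
# caller's RNG is untouched), and every dataset ships with its truth table
# so parameter-recovery tests can assert against known values.

#' Simulate targeted amplicon reads with site-specific editing
#'
#' Each read is a full-length copy of the amplicon reference. At every
#' position with a declared editing probability, an A becomes G with that
#' probability (independently per read); afterwards every base is replaced
#' by a uniformly chosen other base with probability `error_rate`
#' (strand-symmetric uniform sequencing error).
#'
#' @param ref An [amplicon_reference()].
#' @param edit_probs Named numeric vector of per-site editing
#'   probabilities; names are signed offsets relative to the target
#'   adenosine (e.g. `c("-28" = 0.1, "0" = 0.5, "5" = 0.2)`). Each
#'   addressed position must be an A.
#' @param error_rate Uniform per-base sequencing error probability.
#' @param n_reads Number of reads.
#' @param seed Mandatory integer seed; the same seed reproduces the reads
#'   byte for byte.
#' @return List with `reads` (character vector), `truth` (data.frame
#'   `offset`, `position`, `p_edit`), and `ref`.
#' @export
simulate_amplicon_reads <- function(ref, edit_probs, error_rate = 0.001,
                                    n_reads = 5000L, seed) {
  stopifnot(is(ref, "amplicon_reference"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (any(edit_probs < 0 | edit_probs > 1) || error_rate < 0 ||
      error_rate > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  offs <- as.integer(names(edit_probs))
  if (any(is.na(offs)))
    stop("edit_probs must be named by signed offsets", call. = FALSE)
  pos <- ref$target_index + offs  # 0-based
  if (any(pos < 0L | pos >= nchar(ref$sequence)))
    stop("edit offset outside the reference", call. = FALSE)
  refchars <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  if (any(refchars[pos + 1L] != "A"))
    stop("edit_probs address non-A reference positions", call. = FALSE)
  L <- length(refchars)
  withr_seed(seed, {
    mat <- matrix(refchars, nrow = n_reads, ncol = L, byrow = TRUE)
    for (i in seq_along(pos)) {
      hit <- runif(n_reads) < edit_probs[i]
      mat[hit, pos[i] + 1L] <- "G"
    }
    if (error_rate > 0) {
      err <- which(matrix(runif(n_reads * L) < error_rate, n_reads, L))
      if (length(err)) {
        cur <- mat[err]
        pick <- ceiling(runif(length(err)) * 3)
        alt <- vapply(seq_along(err), function(j)
          setdiff(.BASES, cur[j])[pick[j]], character(1))
        mat[err] <- alt
      }
    }
    reads <- apply(mat, 1L, paste, collapse = "")
  })
  list(reads = reads,
       truth = data.frame(offset = offs, position = pos,
                          p_edit = unname(edit_probs)),
       ref = ref)
}

#' Simulate replicate site-count tables for differential testing
#'
#' Per site and replicate, depth is drawn from a negative binomial
#' (RNA-seq-like overdispersion) and the alt count from a binomial with the
#' site's group-specific editing level. Null sites share one level across
#' groups (drawn from a Beta baseline); effect sites add `delta` in the
#' treatment group (capped at 0.95).
#'
#' @param n_sites Total number of sites.
#' @param n_effect Number of true differential sites (first `n_effect` ids
#'   in the truth table, positions randomized).
#' @param delta Editing-level increase of effect sites in treatment.
#' @param n_rep Replicates per group.
#' @param coverage_mean Mean per-replicate depth (default 200).
#' @param coverage_dispersion Negative-binomial `size` parameter (default
#'   10; larger = closer to Poisson).
#' @param baseline_shape Beta parameters of the null editing-level
#'   distribution, default `c(2, 18)` (mean 0.1, typical of native A-to-I
#'   sites after depth filtering).
#' @param seed Mandatory integer seed.
#' @return List with `table` (a long-format [site_count_table()]) and
#'   `truth` (data.frame `site_id`, `is_effect`, `p_control`,
#'   `p_treatment`).
#' @export
simulate_count_tables <- function(n_sites = 1000L, n_effect = 0L,
                                  delta = 0.30, n_rep = 3L,
                                  coverage_mean = 200,
                                  coverage_dispersion = 10,
                                  baseline_shape = c(2, 18), seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  n_sites <- as.integer(n_sites); n_effect <- as.integer(n_effect)
  if (n_effect > n_sites)
    stop("n_effect cannot exceed n_sites", call. = FALSE)
  withr_seed(seed, {
    ids <- sprintf("site%0*d", nchar(as.character(n_sites)),
                   seq_len(n_sites))
    is_effect <- rep(FALSE, n_sites)
    is_effect[sample.int(n_sites, n_effect)] <- TRUE
    p_ctrl <- rbeta(n_sites, baseline_shape[1], baseline_shape[2])
    p_trt <- ifelse(is_effect, pmin(p_ctrl + delta, 0.95), p_ctrl)
    rows <- vector("list", 2L * n_rep)
    k <- 0L
    for (grp in c("control", "treatment")) {
      p <- if (grp == "control") p_ctrl else p_trt
      for (r in seq_len(n_rep)) {
        depth <- rnbinom(n_sites, size = coverage_dispersion,
                         mu = coverage_mean)
        alt <- rbinom(n_sites, depth, p)
        k <- k + 1L
        rows[[k]] <- data.frame(site_id = ids, group = grp,
                                replicate = paste0("rep", r),
                                ref_count = depth - alt, alt_count = alt,
                                stringsAsFactors = FALSE)
      }
    }
  })
  list(table = do.call(rbind, rows),
       truth = data.frame(site_id = ids, is_effect = is_effect,
                          p_control = p_ctrl, p_treatment = p_trt,
                          stringsAsFactors = FALSE))
}

#' Simulate stranded Alu-region pileups with a known editing index
#'
#' Builds one interval per declared strand on a mock chromosome. Every
#' position of a '+' interval is a reference A whose G count is
#' binomial(depth, `true_editing`); '-' intervals are generated in mirrored
#' sense space (reference T, edited reads appear as C).
#'
#' @param true_editing True per-position editing level.
#' @param depth Per-position read depth.
#' @param n_positions Positions per interval.
#' @param strands Character vector of interval strands, e.g. `c("+", "-")`.
#' @param seed Mandatory integer seed.
#' @return List with `pileup` (data.frame `chrom`, `pos`, `ref`,
#'   `A`,`C`,`G`,`T`), `intervals` (data.frame `chrom`, `start`, `end`,
#'   `strand`), and `true_editing`.
#' @export
simulate_alu_pileups <- function(true_editing = 0.02, depth = 100L,
                                 n_positions = 500L, strands = c("+", "-"),
                                 seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(true_editing >= 0, true_editing <= 1, depth >= 1,
            n_positions >= 1, all(strands %in% c("+", "-")))
  gap <- 100L
  withr_seed(seed, {
    pu <- list(); iv <- list()
    start <- 0L
    for (i in seq_along(strands)) {
      pos <- start + seq_len(n_positions) - 1L
      edited <- rbinom(n_positions, depth, true_editing)
      zero <- integer(n_positions)
      if (strands[i] == "+") {
        df <- data.frame(chrom = "chrSim", pos = pos, ref = "A",
                         A = depth - edited, C = zero, G = edited, T = zero)
      } else {
        df <- data.frame(chrom = "chrSim", pos = pos, ref = "T",
                         A = zero, C = edited, G = zero, T = depth - edited)
      }
      pu[[i]] <- df
      iv[[i]] <- data.frame(chrom = "chrSim", start = start,
                            end = start + n_positions, strand = strands[i],
                            stringsAsFactors = FALSE)
      start <- start + n_positions + gap
    }
  })
  list(pileup = do.call(rbind, pu), intervals = do.call(rbind, iv),
       true_editing = true_editing)
}
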