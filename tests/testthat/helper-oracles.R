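# Independent oracles used across the suite. These stay deliberately
# brute-force: they must not share code paths with the implementation.

# Two-sided Fisher p for a 2x2 table by exhaustive hypergeometric
# enumeration: sum the probabilities of every table with the same margins
# whose probability does not exceed (up to rounding slack) that of the
# observed table.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  x <- max(0L, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# All A-positions of a window except the target, by a plain character scan.
oracle_bystanders <- function(window, target_idx0) {
  chars <- strsplit(chartr("T", "U", toupper(window)), "")[[1]]
  offs <- which(chars == "A") - 1L - target_idx0
  sort(offs[offs != 0L])
}

# Reverse complement in RNA space, by lookup.
oracle_revcomp_rna <- function(x) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(comp[strsplit(chartr("T", "U", toupper(x)), "")[[1]]]),
        collapse = "")
}

# Random RNA window with an A forced at the target position.
random_window <- function(up, down) {
  n <- up + down + 1L
  chars <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  chars[up + 1L] <- "A"
  paste(chars, collapse = "")
}

# Binomial standard error of a frequency estimate.
binom_se <- function(p, n) sqrt(p * (1 - p) / n)
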