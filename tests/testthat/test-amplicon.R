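# A 60-nt amplicon with a few adenosines, used throughout this file.
amp_seq <- paste0("GGCTACGGTACGATCGGACTGACCGTTAGC",
                  "CATGACGTCCGGATTACGTGCAACGGTTCG")
amp_ref <- function() amplicon_reference("amp1", amp_seq, 12)  # A at 12

test_that("error-free reads pile up at full depth and conserve counts", {
  reads <- rep(amp_seq, 100)
  pu <- align_reads(reads, amp_ref())
  expect_equal(pileup_depth(pu), rep(100L, nchar(amp_seq)))
  expect_equal(attr(pu, "n_used"), 100L)
  expect_equal(attr(pu, "n_discarded"), 0L)
  # conservation: base counts + deletions == depth at every position
  expect_equal(rowSums(unclass(pu)), pileup_depth(pu) + 0)
})

test_that("reverse-complement reads are counted on the sense strand", {
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", amp_seq), "")[[1]]),
              collapse = "")
  pu_fwd <- align_reads(rep(amp_seq, 10), amp_ref())
  pu_rc <- align_reads(rep(rc, 10), amp_ref())
  expect_identical(unclass(pu_fwd), unclass(pu_rc))
})

test_that("partial and junk reads are placed or discarded sensibly", {
  inner <- substr(amp_seq, 11, 40)     # 30-mer starting at 0-based 10
  pu <- align_reads(c(amp_seq, inner), amp_ref())
  expect_equal(pileup_depth(pu)[11:40], rep(2L, 30))
  expect_equal(pileup_depth(pu)[1:10], rep(1L, 10))

  junk <- strrep("A", 60)
  expect_warning(pu2 <- align_reads(junk, amp_ref()), "identity filter")
  expect_equal(attr(pu2, "n_discarded"), 1L)
  expect_equal(sum(pileup_depth(pu2)), 0L)
})

test_that("recovered frequencies lie within 3 binomial SE of simulated truth", {
  probs <- c("-8" = 0.10, "0" = 0.40, "5" = 0.05)
  # offsets -8, 0, +5 from position 12 are the As at 4, 12, 17
  sim <- simulate_amplicon_reads(amp_ref(), probs, error_rate = 0.001,
                                 n_reads = 3000, seed = 101)
  pu <- align_reads(sim$reads, amp_ref())
  calls <- call_edits(pu, min_depth = 50)
  for (i in seq_len(nrow(sim$truth))) {
    got <- calls$frequency[calls$offset == sim$truth$offset[i]]
    p <- sim$truth$p_edit[i]
    expect_lt(abs(got - p), 3 * binom_se(p, 3000) + 1e-9)
  }
})

test_that("the noise threshold reproduces hand arithmetic on a fixed pileup", {
  # reference CCCA: three C>X classes at the single deep C... use 3 C sites
  ref <- amplicon_reference("toy", "CCCA", 3)
  counts <- rbind(
    c(A = 1L, C = 99L, G = 0L, T = 0L, del = 0L),    # C>A = 0.01
    c(A = 0L, C = 98L, G = 2L, T = 0L, del = 0L),    # C>G = 0.02
    c(A = 0L, C = 97L, G = 0L, T = 3L, del = 0L),    # C>T = 0.03
    c(A = 10L, C = 0L, G = 0L, T = 0L, del = 0L))    # below min_depth
  pu <- pileup_matrix(counts, ref)
  th <- noise_threshold(pu, k = 1, min_depth = 50)
  # 9 class frequencies at the three C sites: {.01,0,0, 0,.02,0, 0,0,.03}
  fr <- c(0.01, 0, 0, 0, 0.02, 0, 0, 0, 0.03)
  expect_equal(th$mean_non_ag, mean(fr))
  expect_equal(th$sd_non_ag, sd(fr))
  expect_equal(th$value, mean(fr) + sd(fr))
  expect_equal(noise_threshold(pu, k = 0, min_depth = 50)$value, mean(fr))

  clean <- pileup_matrix(rbind(c(0L, 100L, 0L, 0L, 0L),
                               c(0L, 100L, 0L, 0L, 0L),
                               c(0L, 100L, 0L, 0L, 0L),
                               c(100L, 0L, 0L, 0L, 0L)), ref)
  expect_equal(noise_threshold(clean, min_depth = 50)$value, 0)
  shallow <- pileup_matrix(matrix(1L, 4, 5,
                                  dimnames = list(NULL,
                                                  c("A","C","G","T","del"))),
                           ref)
  expect_error(noise_threshold(shallow, min_depth = 50), "insufficient")
})

test_that("genuine calls respect the threshold and the shared-control filter", {
  ref <- amplicon_reference("toy2", "CACGA", 1)
  mk <- function(a_g1, a_g2) pileup_matrix(rbind(
    c(100L, 0L, 0L, 0L, 0L),
    c(100L - a_g1, 0L, a_g1, 0L, 0L),   # target A
    c(0L, 100L, 0L, 0L, 0L),
    c(0L, 0L, 100L, 0L, 0L),
    c(100L - a_g2, 0L, a_g2, 0L, 0L)), ref)
  th <- structure(list(mean_non_ag = 0.02, sd_non_ag = 0.01, k = 1,
                       value = 0.03, n_frequencies = 3L),
                  class = "noise_threshold")
  treated <- mk(30L, 29L)
  calls <- call_edits(treated, th, min_depth = 50)
  expect_true(calls$genuine[calls$offset == 0])
  # both target (0.30) and the +3 A (0.29) clear the threshold alone
  expect_true(calls$genuine[calls$offset == 3])

  control <- mk(1L, 29L)
  calls2 <- call_edits(treated, th, control_pileup = control, min_depth = 50)
  expect_true(calls2$genuine[calls2$offset == 0])     # absent in control
  expect_false(calls2$genuine[calls2$offset == 3])    # SNP-like, shared

  zero <- mk(0L, 0L)
  calls3 <- call_edits(zero, th, min_depth = 50)
  expect_equal(calls3$frequency, c(0, 0))
  expect_false(any(calls3$genuine))

  short_ctrl <- pileup_matrix(
    matrix(0L, 3, 5, dimnames = list(NULL, c("A","C","G","T","del"))),
    amplicon_reference("t", "CAC", 1))
  expect_error(call_edits(treated, th, control_pileup = short_ctrl),
               "length differs")
})

test_that("raising k never increases the number of genuine calls", {
  sim <- simulate_amplicon_reads(
    amp_ref(), c("-8" = 0.02, "0" = 0.30, "5" = 0.01),
    error_rate = 0.005, n_reads = 1500, seed = 55)
  pu <- align_reads(sim$reads, amp_ref())
  n_genuine <- vapply(c(0, 0.5, 1, 2, 4), function(k)
    sum(call_edits(pu, k = k, min_depth = 50)$genuine), numeric(1))
  expect_true(all(diff(n_genuine) <= 0))
})

test_that("with no true editing, called A>G reflects only the error floor", {
  sim <- simulate_amplicon_reads(amp_ref(), c("0" = 0), error_rate = 0.005,
                                 n_reads = 4000, seed = 77)
  pu <- align_reads(sim$reads, amp_ref())
  calls <- call_edits(pu, k = 1, min_depth = 50)
  # expected A>G frequency is e/3
  expect_lt(abs(mean(calls$frequency) - 0.005 / 3),
            3 * binom_se(0.005 / 3, 4000 * nrow(calls)))
  expect_lt(mean(calls$genuine), 0.10)
})

test_that("bystander profiles are window-restricted and keep the target row", {
  ref <- amplicon_reference("toy3", "AACGA", 1)  # As at offsets -1, 0, +3
  pu <- pileup_matrix(rbind(
    c(100L, 0L, 0L, 0L, 0L), c(70L, 0L, 30L, 0L, 0L),
    c(0L, 100L, 0L, 0L, 0L), c(0L, 0L, 100L, 0L, 0L),
    c(95L, 0L, 5L, 0L, 0L)), ref)
  calls <- call_edits(pu, k = 1, min_depth = 50,
                      threshold = structure(
                        list(mean_non_ag = 0, sd_non_ag = 0, k = 1,
                             value = 0.02, n_frequencies = 2L),
                        class = "noise_threshold"))
  prof <- bystander_profile(calls, c(1, 3))
  expect_equal(prof$offset, c(-1L, 0L, 3L))
  prof0 <- bystander_profile(calls, c(1, 1))
  expect_equal(prof0$offset, c(-1L, 0L))
  # a window with no called A rows still reports the target row
  empty <- calls[calls$offset > 90, ]
  class(empty) <- class(calls)
  expect_equal(bystander_profile(empty, c(0, 0))$offset, 0L)
})

test_that("codon effects follow the standard genetic code", {
  expect_equal(codon_effect("TAG", 1, 0), "stop_loss")    # TAG -> TGG (Trp)
  expect_equal(codon_effect("CCA", 2, 0), "synonymous")   # Pro -> Pro
  expect_equal(codon_effect("AAA", 1, 0), "missense")     # Lys -> Arg
  expect_equal(codon_effect("TCATAG", 4, 0), "stop_loss") # phase across codons
  expect_equal(codon_effect("TAG", 1, NULL), "noncoding")
  expect_equal(codon_effect("AGG", 0, 1), "n/a")          # truncated codon
  expect_error(codon_effect("TAG", 0, 0), "not an adenosine")
})

test_that("pileups imported from BAM count deletions in depth only", {
  ref <- amplicon_reference("amp", "GGATAGGCAT", 4)
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           "@SQ\tSN:amp\tLN:10",
           paste0("r1\t0\tamp\t1\t60\t10M\t*\t0\t0\tGGATGGGCAT\t",
                  strrep("I", 10)),
           paste0("r2\t0\tamp\t1\t60\t10M\t*\t0\t0\tGGATAGGCAT\t",
                  strrep("I", 10)),
           paste0("r3\t0\tamp\t3\t60\t3M1D4M\t*\t0\t0\tATGGGCA\t",
                  strrep("I", 7)))
  samfile <- tempfile(fileext = ".sam")
  writeLines(sam, samfile)
  bam <- Rsamtools::asBam(samfile, tempfile(), overwrite = TRUE)
  pu <- pileup_from_bam(bam, ref)
  expect_equal(pileup_depth(pu), c(2L, 2L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L))
  expect_equal(unclass(pu)[6, "del"], c(del = 1L))
  expect_equal(unclass(pu)[5, "G"], c(G = 2L))  # r1 edit + r3 mismatch
})
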