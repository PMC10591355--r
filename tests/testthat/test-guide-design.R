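test_that("design names parse into arm lengths around the mismatch base", {
  s <- parse_design_name("85-C-15")
  expect_equal(s$upstream_len, 85L)
  expect_equal(s$downstream_len, 15L)
  expect_equal(s$mismatch_base, "C")

  s <- parse_design_name("75-c-25")
  expect_equal(s$upstream_len, 75L)
  expect_equal(s$downstream_len, 25L)
  expect_equal(s$mismatch_base, "C")

  s <- parse_design_name("3-C-3")
  expect_equal(c(s$upstream_len, s$downstream_len), c(3L, 3L))
  expect_equal(s$linker_end, "none")
  expect_equal(s$linker_len, 0L)

  flipped <- parse_design_name("85-C-15", name_orientation = "downstream_first")
  expect_equal(flipped$upstream_len, 15L)
  expect_equal(flipped$downstream_len, 85L)

  expect_error(parse_design_name("85-CC-15"), "offending token 'CC'")
  expect_error(parse_design_name("eighty-C-15"), "offending token")
})

test_that("bystander enumeration matches a brute-force scan", {
  ts <- target_site("demo", "GAUAGCA", 3)
  expect_identical(enumerate_bystanders(ts, arrna_spec(3, 3)), c(-2L, 3L))

  no_a <- target_site("demo", "GCUACGC", 3)
  expect_identical(enumerate_bystanders(no_a, arrna_spec(3, 3)), integer(0))

  aaa <- target_site("demo", "AAA", 1)
  expect_identical(enumerate_bystanders(aaa, arrna_spec(1, 1)), c(-1L, 1L))

  expect_error(enumerate_bystanders(ts, arrna_spec(5, 3)), "window")

  set.seed(42)
  for (i in 1:50) {
    up <- sample(1:30, 1); down <- sample(1:30, 1)
    win <- random_window(up, down)
    ts <- target_site("r", win, up)
    expect_identical(enumerate_bystanders(ts, arrna_spec(up, down)),
                     oracle_bystanders(win, up))
  }
})

test_that("arRNA realization places the mismatch, deletions and linker", {
  ts <- target_site("demo", "GAUAGCA", 3)
  expect_equal(design_arrna(ts, arrna_spec(3, 3))$sequence, "UGCCAUC")
  expect_equal(design_arrna(ts, arrna_spec(3, 3, deletions = -2))$sequence,
               "UGCCAC")
  expect_equal(
    design_arrna(ts, arrna_spec(3, 3, linker_end = "three_prime",
                                linker_len = 4))$sequence,
    paste0("UGCCAUC", "ACAC"))
  expect_equal(
    design_arrna(ts, arrna_spec(3, 3, linker_end = "five_prime",
                                linker_len = 3))$sequence,
    paste0("ACA", "UGCCAUC"))

  expect_error(arrna_spec(3, 3, deletions = 0), "offset 0")
  expect_error(design_arrna(ts, arrna_spec(3, 3, deletions = 1)),
               "bystander adenosine")
})

test_that("the duplex map has no partner at deleted offsets and marks linkers unpaired", {
  ts <- target_site("demo", "GAUAGCA", 3)
  d <- design_arrna(ts, arrna_spec(3, 3, deletions = c(-2, 3),
                                   linker_end = "both", linker_len = 5))
  expect_false(any(d$duplex_map$target_offset %in% c(-2L, 3L)))
  # 5 linker bases on each side, all unpaired
  expect_equal(sum(is.na(d$duplex_map$target_offset)), 10L)
  paired <- d$duplex_map[!is.na(d$duplex_map$target_offset), ]
  # paired offsets descend from +down to -up along the guide (antisense)
  expect_true(all(diff(paired$target_offset) < 0))
})

test_that("round-trip and length law hold over random designs", {
  set.seed(7)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  for (i in 1:100) {
    up <- sample(1:40, 1); down <- sample(1:40, 1)
    win <- random_window(up, down)
    ts <- target_site("r", win, up)
    plain <- design_arrna(ts, arrna_spec(up, down))
    # reverse-complementing the guide and restoring A at the mismatch
    # position reproduces the window
    back <- strsplit(oracle_revcomp_rna(plain$sequence), "")[[1]]
    back[up + 1L] <- "A"
    expect_equal(paste(back, collapse = ""), win)

    bys <- enumerate_bystanders(ts, arrna_spec(up, down))
    dels <- bys[sample.int(length(bys),
                           sample(0:min(3, length(bys)), 1))]
    lend <- sample(c("none", "five_prime", "three_prime", "both"), 1)
    llen <- if (lend == "none") 0L else sample(1:30, 1)
    spec <- arrna_spec(up, down, deletions = dels, linker_end = lend,
                       linker_len = llen)
    d <- design_arrna(ts, spec)
    n_link <- llen * switch(lend, none = 0L, both = 2L, 1L)
    expect_equal(nchar(d$sequence),
                 up + down + 1L - length(dels) + n_link)
    expect_false(any(d$duplex_map$target_offset %in% dels))
    # every paired base is Watson-Crick complementary except the mismatch
    pm <- d$duplex_map[!is.na(d$duplex_map$target_offset) &
                         d$duplex_map$target_offset != 0L, ]
    gchars <- strsplit(d$sequence, "")[[1]]
    tchars <- strsplit(win, "")[[1]]
    expect_true(all(
      gchars[pm$arrna_index + 1L] ==
        comp[tchars[up + 1L + pm$target_offset]]))
  }
})

test_that("engineered bulges insert unpaired bases or break pairing", {
  ts <- target_site("demo", "GAUAGCA", 3)
  ins <- design_arrna(ts, arrna_spec(
    3, 3, bulges = list(list(offset = 2, bases = "GG", type = "insertion"))))
  expect_equal(nchar(ins$sequence), 7L + 2L)
  expect_equal(sum(is.na(ins$duplex_map$target_offset)), 2L)

  mis <- design_arrna(ts, arrna_spec(
    3, 3, bulges = list(list(offset = -1, bases = "A", type = "mismatch"))))
  expect_equal(nchar(mis$sequence), 7L)
  # offset -1 pairs U on the target; complementary would be A -> here forced A
  idx <- mis$duplex_map$arrna_index[
    !is.na(mis$duplex_map$target_offset) &
      mis$duplex_map$target_offset == -1L]
  expect_equal(substr(mis$sequence, idx + 1, idx + 1), "A")
})

test_that("cassette assembly follows ribozyme-ligation-guide order", {
  parts <- cassette_parts("TTT", "CCC", "GGG", "AAA")
  expect_equal(assemble_circ_cassette("AUGC", parts), "TTTCCCATGCGGGAAA")
  expect_equal(nchar(assemble_circ_cassette("AUGC", parts)),
               sum(nchar(unlist(parts))) + 4L)
  expect_error(cassette_parts("TTT", "", "GGG", "AAA"), "non-empty")
  expect_error(assemble_circ_cassette("", parts), "empty arRNA")
})

test_that("reporter fragments are mutation-centered with symmetric flanks", {
  ctx <- paste(sample(c("A", "C", "G", "T"), 301, replace = TRUE),
               collapse = "")
  frag <- build_reporter_fragment(ctx, 150, 100)
  expect_equal(nchar(frag), 201L)
  expect_equal(substr(frag, 101, 101), substr(ctx, 151, 151))

  expect_equal(build_reporter_fragment("ACGTACG", 3, 0), "T")
  expect_equal(build_reporter_fragment("ACGTACG", 3, 3), "ACGTACG")
  expect_error(build_reporter_fragment("ACGTACG", 3, 4), "exceeds")
})

test_that("design reports tabulate one row per design", {
  ts <- target_site("demo", "GAUAGCA", 3)
  d1 <- design_arrna(ts, arrna_spec(3, 3))
  d2 <- design_arrna(ts, arrna_spec(3, 3, deletions = -2,
                                    linker_end = "three_prime",
                                    linker_len = 4))
  rep_ <- design_report(list(d1, d2))
  expect_equal(nrow(rep_), 2L)
  expect_equal(rep_$length, c(7L, 10L))
  expect_equal(rep_$deletions[2], "-2")
  f <- tempfile(fileext = ".tsv")
  design_report(list(d1, d2), file = f)
  expect_equal(read.delim(f)$sequence, rep_$sequence)
})
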