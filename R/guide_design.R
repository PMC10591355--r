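# arRNA guide design: window nomenclature, C mismatch, bystander deletions,
# poly(AC) linkers, and circularization cassette assembly.
#
# Conventions used throughout this module:
#  * positions are 0-based; offsets are signed and relative to the target
#    adenosine on the target strand (negative = 5' of the target);
#  * the pairing window on the target strand is
#    [target_index - upstream_len, target_index + downstream_len];
#  * arRNA sequences are RNA-alphabet, written 5'->3'; cassettes are DNA.

.RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

.as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

.as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

.seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.check_alphabet <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || nchar(x) < 1L)
    stop(what, " must be a single non-empty string", call. = FALSE)
  if (grepl("[^ACGU]", .as_rna(x)))
    stop(what, " contains characters outside {A,C,G,T,U}", call. = FALSE)
  invisible(TRUE)
}

#' Define a target site on a transcript
#'
#' A target site is a transcript sequence together with the 0-based position
#' of the adenosine to be edited. DNA input is transcribed automatically
#' (T -> U); the base at `target_index` must be an adenosine.
#'
#' @param transcript_id Character scalar naming the transcript.
#' @param sequence Target-strand sequence (RNA or DNA alphabet).
#' @param target_index 0-based position of the target adenosine.
#' @param cds_frame_offset Optional integer in 0..2: the phase of the reading
#'   frame, i.e. positions `i` with `(i - cds_frame_offset) %% 3 == 0` are
#'   first codon bases. `NULL` (default) marks the site as non-coding for
#'   codon annotation.
#' @return An object of class `target_site` with fields `transcript_id`,
#'   `sequence` (RNA alphabet), `target_index`, `cds_frame_offset`.
#' @examples
#' ts <- target_site("demo", "GAUAGCA", target_index = 3)
#' @export
target_site <- function(transcript_id, sequence, target_index,
                        cds_frame_offset = NULL) {
  .check_alphabet(sequence, "target sequence")
  sequence <- .as_rna(sequence)
  target_index <- as.integer(target_index)
  if (is.na(target_index) || target_index < 0L ||
      target_index >= nchar(sequence))
    stop("target_index out of bounds [0, ", nchar(sequence) - 1L, "]",
         call. = FALSE)
  if (substr(sequence, target_index + 1L, target_index + 1L) != "A")
    stop("base at target_index is not an adenosine", call. = FALSE)
  if (!is.null(cds_frame_offset)) {
    cds_frame_offset <- as.integer(cds_frame_offset)
    stopifnot(cds_frame_offset %in% 0:2)
  }
  structure(
    list(transcript_id = as.character(transcript_id), sequence = sequence,
         target_index = target_index, cds_frame_offset = cds_frame_offset),
    class = "target_site"
  )
}

#' Specify an arRNA design
#'
#' Captures everything that determines a guide: the pairing arm lengths
#' around the target adenosine, the base placed opposite it (a cytidine by
#' default, creating the A:C mismatch ADAR prefers), uracil deletions
#' opposite bystander adenosines, engineered bulges, and unpaired poly(AC)
#' linker extensions.
#'
#' @param upstream_len Bases paired 5' of the target adenosine on the target
#'   strand (the first number of `"85-C-15"`-style names by default).
#' @param downstream_len Bases paired 3' of the target adenosine.
#' @param mismatch_base Base placed opposite the target A (default `"C"`).
#' @param linker_end Where the unpaired linker is appended on the arRNA:
#'   `"none"`, `"five_prime"`, `"three_prime"`, or `"both"`.
#' @param linker_len Linker length in nt (per end).
#' @param linker_unit Repeat unit, default `"AC"`; the repeat starts with the
#'   first character of the unit and is truncated to exactly `linker_len`.
#' @param deletions Integer vector of target-strand offsets (relative to the
#'   target A) whose opposing arRNA uracil is deleted; each must address an
#'   adenosine, and 0 is not allowed.
#' @param bulges Optional list of engineered bubbles, each a list with
#'   `offset`, `bases`, and `type` (`"insertion"`: `bases` inserted unpaired
#'   into the arRNA immediately 3' of the base pairing `offset`;
#'   `"mismatch"`: the arRNA base opposite `offset` is replaced by `bases`,
#'   a single non-complementary base).
#' @return An object of class `arrna_spec`.
#' @examples
#' arrna_spec(85, 15)                       # the plain 85-C-15 guide
#' arrna_spec(85, 15, deletions = c(-28, -23, 5),
#'            linker_end = "three_prime", linker_len = 30)
#' @export
arrna_spec <- function(upstream_len, downstream_len, mismatch_base = "C",
                       linker_end = c("none", "five_prime", "three_prime",
                                      "both"),
                       linker_len = 0L, linker_unit = "AC",
                       deletions = integer(), bulges = list()) {
  upstream_len <- as.integer(upstream_len)
  downstream_len <- as.integer(downstream_len)
  linker_end <- match.arg(linker_end)
  linker_len <- as.integer(linker_len)
  deletions <- sort(unique(as.integer(deletions)))
  mismatch_base <- .as_rna(mismatch_base)
  if (upstream_len < 0L || downstream_len < 0L)
    stop("arm lengths must be non-negative", call. = FALSE)
  if (upstream_len + downstream_len < 1L)
    stop("at least one pairing arm must be non-empty", call. = FALSE)
  if (!mismatch_base %in% names(.RNA_COMPLEMENT))
    stop("mismatch_base must be one of A, C, G, U/T", call. = FALSE)
  if (0L %in% deletions)
    stop("deletion at offset 0 would remove the mismatch position",
         call. = FALSE)
  if (linker_end != "none" && linker_len < 1L)
    stop("linker_len must be >= 1 when a linker end is declared",
         call. = FALSE)
  if (linker_end == "none") linker_len <- 0L
  .check_alphabet(linker_unit, "linker_unit")
  for (b in bulges) {
    if (!all(c("offset", "bases") %in% names(b)))
      stop("each bulge needs fields 'offset' and 'bases'", call. = FALSE)
    type <- if (is.null(b$type)) "insertion" else b$type
    if (!type %in% c("insertion", "mismatch"))
      stop("bulge type must be 'insertion' or 'mismatch'", call. = FALSE)
    .check_alphabet(b$bases, "bulge bases")
    if (type == "mismatch" && nchar(b$bases) != 1L)
      stop("a mismatch bulge replaces exactly one base", call. = FALSE)
  }
  bulges <- lapply(bulges, function(b) {
    list(offset = as.integer(b$offset), bases = .as_rna(b$bases),
         type = if (is.null(b$type)) "insertion" else b$type)
  })
  structure(
    list(upstream_len = upstream_len, downstream_len = downstream_len,
         mismatch_base = mismatch_base, linker_end = linker_end,
         linker_len = linker_len, linker_unit = .as_rna(linker_unit),
         deletions = deletions, bulges = bulges),
    class = "arrna_spec"
  )
}

#' Parse an "85-C-15"-style design name
#'
#' Guides are conventionally named `<X>-<base>-<Y>` where X and Y are the
#' pairing arm lengths flanking the base placed opposite the target
#' adenosine (so the mismatch base is its own middle position and is counted
#' in neither arm). The orientation of the two numbers is a convention, not
#' a fact of the name, so it is exposed as a switch: the default reads the
#' first number as the arm pairing 5' of the target on the target strand.
#'
#' @param name Design name matching `<int>-<base>-<int>`, case-insensitive.
#' @param name_orientation `"upstream_first"` (default) or
#'   `"downstream_first"`: which target-strand arm the first number denotes.
#' @return An [arrna_spec()] with no linker, deletions, or bulges.
#' @examples
#' parse_design_name("85-C-15")
#' parse_design_name("75-c-25")
#' @export
parse_design_name <- function(name,
                              name_orientation = c("upstream_first",
                                                   "downstream_first")) {
  name_orientation <- match.arg(name_orientation)
  if (!is.character(name) || length(name) != 1L)
    stop("name must be a single string", call. = FALSE)
  m <- regmatches(name, regexec("^([0-9]+)-([ACGUTacgut])-([0-9]+)$", name))[[1]]
  if (length(m) != 4L) {
    bad <- strsplit(name, "-", fixed = TRUE)[[1]]
    ok1 <- length(bad) >= 1L && grepl("^[0-9]+$", bad[1])
    ok2 <- length(bad) >= 2L && grepl("^[ACGUTacgut]$", bad[2])
    tok <- if (!ok1) bad[1] else if (!ok2) bad[2] else name
    stop("cannot parse design name '", name, "': offending token '",
         if (is.na(tok)) name else tok, "' (expected <int>-<base>-<int>)",
         call. = FALSE)
  }
  first <- as.integer(m[2]); second <- as.integer(m[4])
  if (name_orientation == "upstream_first")
    arrna_spec(upstream_len = first, downstream_len = second,
               mismatch_base = m[3])
  else
    arrna_spec(upstream_len = second, downstream_len = first,
               mismatch_base = m[3])
}

.window_bounds <- function(target, spec) {
  from <- target$target_index - spec$upstream_len
  to <- target$target_index + spec$downstream_len
  if (from < 0L || to >= nchar(target$sequence))
    stop("pairing window [", from, ", ", to, "] falls outside the target ",
         "sequence (length ", nchar(target$sequence), ")", call. = FALSE)
  c(from = from, to = to)
}

#' Enumerate bystander adenosines in the pairing window
#'
#' Every adenosine other than the target that falls inside the arRNA-paired
#' duplex is a potential bystander editing site. Offsets are signed,
#' relative to the target adenosine, negative 5' of it.
#'
#' @param target A [target_site()].
#' @param spec An [arrna_spec()] (only the arm lengths are used).
#' @return Sorted integer vector of bystander offsets (never includes 0).
#' @examples
#' ts <- target_site("demo", "GAUAGCA", 3)
#' enumerate_bystanders(ts, arrna_spec(3, 3))  # -2, +3
#' @export
enumerate_bystanders <- function(target, spec) {
  stopifnot(is(target, "target_site"), is(spec, "arrna_spec"))
  b <- .window_bounds(target, spec)
  chars <- .seq_chars(target$sequence)[(b["from"] + 1L):(b["to"] + 1L)]
  offs <- seq.int(-spec$upstream_len, spec$downstream_len)
  sort(offs[chars == "A" & offs != 0L])
}

#' Realize an arRNA design
#'
#' Builds the guide sequence 5'->3': the reverse complement of the pairing
#' window with (a) `mismatch_base` substituted opposite the target adenosine,
#' (b) the uracil deleted opposite every declared bystander deletion offset,
#' (c) engineered bulges applied, and (d) the poly(AC) linker appended at the
#' declared arRNA end(s). A duplex map records, for every arRNA base, the
#' target-strand offset it pairs with (`NA` for unpaired linker/insertion
#' bases).
#'
#' @param target A [target_site()].
#' @param spec An [arrna_spec()]; every deletion offset must be a bystander
#'   adenosine of the window (see [enumerate_bystanders()]).
#' @return An object of class `arrna_design`: list with `spec`, `target`,
#'   `sequence` (RNA, 5'->3'), and `duplex_map`, a data.frame with columns
#'   `arrna_index` (0-based) and `target_offset` (integer or `NA`).
#' @examples
#' ts <- target_site("demo", "GAUAGCA", 3)
#' design_arrna(ts, arrna_spec(3, 3))$sequence             # "UGCCAUC"
#' design_arrna(ts, arrna_spec(3, 3, deletions = -2))$sequence  # "UGCCAC"
#' @export
design_arrna <- function(target, spec) {
  stopifnot(is(target, "target_site"), is(spec, "arrna_spec"))
  .window_bounds(target, spec)  # range check
  bystanders <- enumerate_bystanders(target, spec)
  bad <- setdiff(spec$deletions, bystanders)
  if (length(bad))
    stop("deletion offset(s) ", paste(bad, collapse = ", "),
         " do not address a bystander adenosine in the window",
         call. = FALSE)
  tchars <- .seq_chars(target$sequence)
  # walk the window 3'->5' on the target strand = 5'->3' on the arRNA
  offs <- seq.int(spec$downstream_len, -spec$upstream_len)
  mism_by_offset <- list()
  ins_by_offset <- list()
  for (b in spec$bulges) {
    if (!b$offset %in% offs)
      stop("bulge offset ", b$offset, " outside the pairing window",
           call. = FALSE)
    if (b$type == "mismatch") {
      if (b$offset == 0L)
        stop("use mismatch_base, not a bulge, for the target position",
             call. = FALSE)
      mism_by_offset[[as.character(b$offset)]] <- b$bases
    } else {
      key <- as.character(b$offset)
      ins_by_offset[[key]] <- paste0(
        if (is.null(ins_by_offset[[key]])) "" else ins_by_offset[[key]],
        b$bases)
    }
  }
  bases <- character(0)
  partner <- integer(0)
  for (o in offs) {
    if (o %in% spec$deletions) next
    tb <- tchars[target$target_index + o + 1L]
    ab <- if (o == 0L) spec$mismatch_base
          else if (!is.null(mism_by_offset[[as.character(o)]]))
            mism_by_offset[[as.character(o)]]
          else .RNA_COMPLEMENT[[tb]]
    bases <- c(bases, ab)
    partner <- c(partner, o)
    ins <- ins_by_offset[[as.character(o)]]
    if (!is.null(ins)) {
      ib <- .seq_chars(ins)
      bases <- c(bases, ib)
      partner <- c(partner, rep(NA_integer_, length(ib)))
    }
  }
  if (spec$linker_len > 0L) {
    unit <- .seq_chars(spec$linker_unit)
    linker <- paste(rep(unit, length.out = spec$linker_len), collapse = "")
    lb <- .seq_chars(linker)
    if (spec$linker_end %in% c("five_prime", "both")) {
      bases <- c(lb, bases)
      partner <- c(rep(NA_integer_, length(lb)), partner)
    }
    if (spec$linker_end %in% c("three_prime", "both")) {
      bases <- c(bases, lb)
      partner <- c(partner, rep(NA_integer_, length(lb)))
    }
  }
  structure(
    list(spec = spec, target = target,
         sequence = paste(bases, collapse = ""),
         duplex_map = data.frame(arrna_index = seq_along(bases) - 1L,
                                 target_offset = partner)),
    class = "arrna_design"
  )
}

#' @export
print.arrna_design <- function(x, ...) {
  s <- x$spec
  cat(sprintf("arRNA design %d-%s-%d on %s (target A at %d)\n",
              s$upstream_len, s$mismatch_base, s$downstream_len,
              x$target$transcript_id, x$target$target_index))
  if (length(s$deletions))
    cat("  deletions at offsets:", paste(s$deletions, collapse = ", "), "\n")
  if (s$linker_len > 0L)
    cat(sprintf("  %d-nt %s linker at %s end\n", s$linker_len,
                s$linker_unit, sub("_", " ", s$linker_end)))
  cat("  sequence (", nchar(x$sequence), " nt): ", x$sequence, "\n", sep = "")
  invisible(x)
}

#' Parts of a circular arRNA expression cassette
#'
#' The guide is circularized in vivo by flanking it with Twister ribozymes
#' and a ligation stem: the cassette order is Twister P3 U2A, 5' ligation
#' sequence, arRNA, 3' ligation sequence, Twister P1. The shipped defaults
#' are clearly-labelled synthetic placeholders — real ribozyme and ligation
#' sequences must be supplied for any wet-lab use.
#'
#' @param twister_p3_u2a,lig5,lig3,twister_p1 DNA sequences of the four
#'   parts; all must be non-empty.
#' @return An object of class `cassette_parts`.
#' @export
cassette_parts <- function(twister_p3_u2a = "AAAATTTTGGGG",
                           lig5 = "ACGTACGT",
                           lig3 = "TGCATGCA",
                           twister_p1 = "CCCCAAAATTTT") {
  parts <- list(twister_p3_u2a = twister_p3_u2a, lig5 = lig5,
                lig3 = lig3, twister_p1 = twister_p1)
  for (nm in names(parts)) {
    if (!is.character(parts[[nm]]) || length(parts[[nm]]) != 1L ||
        nchar(parts[[nm]]) < 1L)
      stop("cassette part '", nm, "' must be a non-empty sequence",
           call. = FALSE)
    parts[[nm]] <- .as_dna(parts[[nm]])
  }
  structure(parts, class = "cassette_parts")
}

#' Assemble the circularization expression cassette
#'
#' Concatenates, in 5'->3' plasmid order: Twister P3 U2A, 5' ligation
#' sequence, the arRNA (converted to DNA alphabet for the plasmid context),
#' 3' ligation sequence, Twister P1.
#'
#' @param design An [design_arrna()] result, or a raw arRNA sequence.
#' @param parts A [cassette_parts()] object.
#' @return DNA sequence of the full cassette.
#' @export
assemble_circ_cassette <- function(design, parts = cassette_parts()) {
  stopifnot(is(parts, "cassette_parts"))
  arrna <- if (is(design, "arrna_design")) design$sequence else design
  if (!is.character(arrna) || length(arrna) != 1L || nchar(arrna) < 1L)
    stop("invalid design: empty arRNA sequence", call. = FALSE)
  paste0(parts$twister_p3_u2a, parts$lig5, .as_dna(arrna), parts$lig3,
         parts$twister_p1)
}

#' Extract a mutation-centered reporter fragment
#'
#' For reporter constructs the mutant base and its symmetric flanks are
#' synthesized, e.g. a pathogenic G>A site with 100 bp on each side gives a
#' 201-bp fragment.
#'
#' @param context Sequence containing the mutation (DNA or RNA).
#' @param mut_index 0-based index of the mutant base within `context`.
#' @param flank Flank length on each side, in nt.
#' @return The fragment `context[mut_index - flank .. mut_index + flank]`,
#'   of length `2 * flank + 1`.
#' @examples
#' build_reporter_fragment("GGATAGG", 3, 3)  # whole 7-mer
#' @export
build_reporter_fragment <- function(context, mut_index, flank) {
  .check_alphabet(context, "context")
  mut_index <- as.integer(mut_index); flank <- as.integer(flank)
  if (flank < 0L) stop("flank must be non-negative", call. = FALSE)
  if (mut_index - flank < 0L || mut_index + flank >= nchar(context))
    stop("flank of ", flank, " nt exceeds the available context around ",
         "index ", mut_index, call. = FALSE)
  substr(context, mut_index - flank + 1L, mut_index + flank + 1L)
}

#' Tabulate one or more designs as a TSV-ready report
#'
#' @param designs A single `arrna_design` or list of them.
#' @param file Optional path; when given the table is written as TSV.
#' @return data.frame with one row per design: name, sequence, length,
#'   deletions, linker description.
#' @export
design_report <- function(designs, file = NULL) {
  if (is(designs, "arrna_design")) designs <- list(designs)
  rows <- lapply(designs, function(d) {
    s <- d$spec
    data.frame(
      name = sprintf("%d-%s-%d", s$upstream_len, s$mismatch_base,
                     s$downstream_len),
      transcript_id = d$target$transcript_id,
      sequence = d$sequence,
      length = nchar(d$sequence),
      deletions = paste(s$deletions, collapse = ","),
      linker = if (s$linker_len > 0L)
        sprintf("%s:%d:%s", s$linker_end, s$linker_len, s$linker_unit)
      else "none",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file))
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
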