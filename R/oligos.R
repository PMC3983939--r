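#' Reverse complement of a DNA sequence
#'
#' Strict-alphabet Watson-Crick reverse complement. Only the four
#' unambiguous DNA bases are accepted: the cloning oligonucleotides this
#' package designs must never carry ambiguity codes or uracil.
#'
#' @param seq Character scalar over the alphabet A, C, G, T.
#' @return Character scalar, the reverse complement. An involution:
#'   `reverse_complement(reverse_complement(s)) == s`.
#' @examples
#' reverse_complement("GTACGTCAGCAATATGAAA")
#' @export
reverse_complement <- function(seq) {
  .check_dna(seq)
  if (nchar(seq) == 0L) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

.check_dna <- function(seq, len = NULL, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  if (grepl("[^ACGT]", seq))
    stop(what, " contains characters outside A/C/G/T: ",
         gsub("[ACGT]", "", seq), call. = FALSE)
  if (!is.null(len) && nchar(seq) != len)
    stop(what, " must be exactly ", len, " nt (got ", nchar(seq), ")",
         call. = FALSE)
  invisible(seq)
}

#' Construct a 19-nt target sequence record
#'
#' @param name Identifier for the target (e.g. a gene/candidate label).
#' @param bases 19-nt sequence, 5' to 3', alphabet A/C/G/T.
#' @param gene Optional gene label.
#' @return A `target_sequence` object (list with name, bases, gene).
#' @export
target_sequence <- function(name, bases, gene = NA_character_) {
  .check_dna(bases, len = 19L, what = "target sequence")
  structure(list(name = as.character(name), bases = bases,
                 gene = as.character(gene)),
            class = "target_sequence")
}

#' @export
print.target_sequence <- function(x, ...) {
  cat("<target_sequence> ", x$name, ": 5'-", x$bases, "-3'",
      if (!is.na(x$gene)) paste0("  (", x$gene, ")"), "\n", sep = "")
  invisible(x)
}

# Hairpin loop spacer between sense and antisense arms of the expressed
# shRNA; derived from the human miR23 gene.
MIR23_LOOP <- "GCTTCCTGTCAC"

#' Design the four cloning oligonucleotides for an shRNA expression insert
#'
#' Produces the four-oligo set that, after pairwise annealing and tandem
#' ligation, assembles into a hairpin insert of the form
#' sense(19) - loop - antisense(19) - TTTT terminator. The loop spacer
#' (`GCTTCCTGTCAC`) comes from the human miR23 gene. The antisense arm is
#' the reverse complement of the target, so the transcribed RNA folds back
#' into a stem-loop.
#'
#' Oligo templates (xxx = target, yyy = reverse complement of target):
#' \describe{
#'   \item{#1-fwd}{`GATCCCC` + xxx + `GC` (28 nt)}
#'   \item{#1-rev}{`ACAGGAAGC` + yyy + `GGG` (31 nt)}
#'   \item{#2-fwd}{`TTCCTGTCAC` + yyy + `TTTT` (33 nt)}
#'   \item{#2-rev}{xxx + `GTG` (22 nt)}
#' }
#'
#' @param target A `target_sequence`, or a bare 19-nt string.
#' @return An `oligo_set` of kind `"shrna_four_oligo"`.
#' @seealso [validate_hairpin()], [assembled_top_strand()]
#' @export
design_shrna_oligos <- function(target) {
  target <- .as_target(target)
  xxx <- target$bases
  yyy <- reverse_complement(xxx)
  oligos <- c(
    "#1-fwd" = paste0("GATCCCC", xxx, "GC"),
    "#1-rev" = paste0("ACAGGAAGC", yyy, "GGG"),
    "#2-fwd" = paste0("TTCCTGTCAC", yyy, "TTTT"),
    "#2-rev" = paste0(xxx, "GTG")
  )
  structure(list(kind = "shrna_four_oligo", target = target,
                 oligos = oligos, loop = MIR23_LOOP),
            class = "oligo_set")
}

#' Design the two reporter-insert oligonucleotides for a target
#'
#' The red-reporter plasmid carries the 19-nt target proxy in the 3'-UTR of
#' the red fluorescent protein. The insert is built from two oligos whose
#' 19-bp cores anneal, leaving 4-nt single-stranded extensions for
#' directional ligation: sense = target + `TTCG`, antisense =
#' reverse_complement(target) + `TTGC`.
#'
#' @inheritParams design_shrna_oligos
#' @return An `oligo_set` of kind `"reporter_two_oligo"` (two 23-nt oligos).
#' @export
design_reporter_oligos <- function(target) {
  target <- .as_target(target)
  oligos <- c(
    sense = paste0(target$bases, "TTCG"),
    antisense = paste0(reverse_complement(target$bases), "TTGC")
  )
  structure(list(kind = "reporter_two_oligo", target = target,
                 oligos = oligos, loop = NA_character_),
            class = "oligo_set")
}

#' Negative-control shRNA oligonucleotides
#'
#' Returns, verbatim, the two-oligo negative-control hairpin insert. Its
#' loop (`TTCAAGAGA`) differs from the miR23 loop used by the four-oligo
#' scheme; this is a property of the control construct, not an error.
#'
#' @return An `oligo_set` of kind `"shrna_control_two_oligo"`.
#' @export
control_shrna_oligos <- function() {
  oligos <- c(
    top = "GATCCCCATGTACTGCGCGTGGAGACTTCAAGAGAGTCTCCACGCGCAGTACATTTTT",
    bottom = "ATGTACTGCGCGTGGAGACTCTCTTGAAGTCTCCACGCGCAGTACATGGG"
  )
  structure(list(kind = "shrna_control_two_oligo",
                 target = target_sequence("neg-control",
                                          "ATGTACTGCGCGTGGAGAC",
                                          "Scramble control"),
                 oligos = oligos, loop = "TTCAAGAGA"),
            class = "oligo_set")
}

.as_target <- function(target) {
  if (inherits(target, "target_sequence")) return(target)
  target_sequence("target", target)
}

#' @export
print.oligo_set <- function(x, ...) {
  cat("<oligo_set> kind:", x$kind, "\n")
  if (!is.null(x$target)) cat("  target:", x$target$name, x$target$bases, "\n")
  if (!is.na(x$loop)) cat("  loop:  ", x$loop, "\n")
  for (nm in names(x$oligos))
    cat(sprintf("  %-10s 5'-%s-3'  (%d nt)\n", nm, x$oligos[[nm]],
                nchar(x$oligos[[nm]])))
  invisible(x)
}

#' Assembled top strand of an shRNA insert
#'
#' Concatenates the top-strand oligos of a hairpin set into the full insert
#' top strand. For the four-oligo scheme this is
#' `GATCCCC + target + loop + revcomp(target) + TTTT` (61 nt).
#'
#' @param x An `oligo_set` of a hairpin kind.
#' @return Character scalar.
#' @export
assembled_top_strand <- function(x) {
  stopifnot(inherits(x, "oligo_set"))
  switch(x$kind,
    shrna_four_oligo = paste0(x$oligos[["#1-fwd"]], x$oligos[["#2-fwd"]]),
    shrna_control_two_oligo = x$oligos[["top"]],
    stop("no hairpin top strand for kind ", x$kind, call. = FALSE))
}

# bottom strand (5'->3') of the duplex region for each scheme
.bottom_strand <- function(x) {
  switch(x$kind,
    shrna_four_oligo = paste0(x$oligos[["#2-rev"]], x$oligos[["#1-rev"]]),
    shrna_control_two_oligo = x$oligos[["bottom"]],
    reporter_two_oligo = x$oligos[["antisense"]],
    stop("unknown oligo_set kind"))
}

#' Validate the sequence-level structure of a designed oligo set
#'
#' Audits an oligo set for the properties the cloning scheme relies on:
#' \enumerate{
#'   \item the double-stranded cores of the annealed duplexes are perfectly
#'     Watson-Crick complementary;
#'   \item for hairpin kinds, the assembled insert encodes
#'     sense - loop - antisense with antisense equal to the reverse
#'     complement of sense;
#'   \item single-stranded extensions are directionally safe: the two
#'     terminal extensions are mutually incompatible (neither anneals to
#'     the other), the terminator-side and any internal junction overhangs
#'     are non-palindromic, and in the four-oligo scheme the junction
#'     overhangs of duplex #1 and duplex #2 are exactly complementary so
#'     the duplexes can only ligate in the intended order;
#'   \item a run of >= 4 consecutive T on the top strand provides the
#'     polymerase-III transcription terminator (hairpin kinds only).
#' }
#' Reporter sets undergo checks 1 and 3 only; hairpin-specific checks are
#' reported as skipped. The 5' `GATC` extension of hairpin inserts is
#' self-complementary by construction (it mates a BglII-cut vector end);
#' directionality there is enforced by the vector, so it is reported but
#' not failed.
#'
#' @param oligo_set An `oligo_set` from one of the designers.
#' @return A `hairpin_report`: data.frame of (check, status, detail). All
#'   statuses are `"pass"` or `"skip"`; any failed assertion raises an error
#'   naming the rule and position.
#' @export
validate_hairpin <- function(oligo_set) {
  stopifnot(inherits(oligo_set, "oligo_set"))
  checks <- list()
  add <- function(check, status, detail = "")
    checks[[length(checks) + 1L]] <<- data.frame(check = check,
                                                 status = status,
                                                 detail = detail)

  if (oligo_set$kind == "reporter_two_oligo") {
    sense <- oligo_set$oligos[["sense"]]
    bottom <- .bottom_strand(oligo_set)
    core_top <- substr(sense, 1L, 19L)
    core_bot <- substr(bottom, 1L, 19L)
    .assert_complementary(core_top, core_bot, "reporter core complementarity")
    add("core_complementarity", "pass", "19-bp core anneals")
    ext_top <- substr(sense, 20L, 23L)
    ext_bot <- substr(bottom, 20L, 23L)
    .assert_overhangs(ext_top, ext_bot, check_palindrome = c(TRUE, TRUE))
    add("overhang_incompatibility", "pass",
        paste(ext_top, ext_bot, sep = "/"))
    add("hairpin_structure", "skip", "not a hairpin insert")
    add("terminator", "skip", "not a hairpin insert")
  } else {
    top <- assembled_top_strand(oligo_set)
    bottom <- .bottom_strand(oligo_set)
    # the annealed insert is double-stranded except for 4 nt at each end of
    # the top strand (5' GATC, 3' TTTT)
    ds_top <- substr(top, 5L, nchar(top) - 4L)
    .assert_complementary(ds_top, bottom, "duplex complementarity")
    add("core_complementarity", "pass",
        sprintf("%d-bp double-stranded core", nchar(ds_top)))

    sense <- substr(top, 8L, 26L)
    loop_len <- nchar(oligo_set$loop)
    loop <- substr(top, 27L, 26L + loop_len)
    antisense <- substr(top, 27L + loop_len, 45L + loop_len)
    if (loop != oligo_set$loop)
      stop("hairpin validation failed: loop mismatch (found ", loop, ")",
           call. = FALSE)
    if (antisense != reverse_complement(sense))
      stop("hairpin validation failed: antisense arm is not the reverse ",
           "complement of the sense arm", call. = FALSE)
    add("hairpin_structure", "pass",
        paste0("sense-", oligo_set$loop, "-antisense"))

    ext5 <- substr(top, 1L, 4L)                     # vector BglII side
    ext3 <- substr(top, nchar(top) - 3L, nchar(top))  # terminator side
    .assert_overhangs(ext5, ext3, check_palindrome = c(FALSE, TRUE))
    add("overhang_incompatibility", "pass", paste(ext5, ext3, sep = "/"))

    if (oligo_set$kind == "shrna_four_oligo") {
      # duplex #1 leaves a 7-nt 5' overhang on its bottom strand; duplex #2
      # a 7-nt 5' overhang on its top strand; they must mate exactly, and
      # be non-palindromic so neither duplex can self-ligate in tandem
      j1 <- substr(oligo_set$oligos[["#1-rev"]], 1L, 7L)
      j2 <- substr(oligo_set$oligos[["#2-fwd"]], 1L, 7L)
      .assert_complementary(j2, j1, "duplex junction complementarity")
      if (j1 == reverse_complement(j1) || j2 == reverse_complement(j2))
        stop("hairpin validation failed: palindromic junction overhang",
             call. = FALSE)
      add("junction_overhang", "pass", paste(j1, j2, sep = "/"))
    }

    if (!grepl("TTTT", top))
      stop("hairpin validation failed: no >=4 T transcription terminator ",
           "on the top strand", call. = FALSE)
    add("terminator", "pass", "TTTT+ run present")
  }
  report <- do.call(rbind, checks)
  class(report) <- c("hairpin_report", "data.frame")
  report
}

.assert_complementary <- function(a, b, rule) {
  if (nchar(a) != nchar(b))
    stop("hairpin validation failed: ", rule, " (length mismatch ",
         nchar(a), " vs ", nchar(b), ")", call. = FALSE)
  rb <- reverse_complement(b)
  if (a != rb) {
    pos <- which(strsplit(a, "")[[1]] != strsplit(rb, "")[[1]])
    stop("hairpin validation failed: ", rule, " at position(s) ",
         paste(pos, collapse = ","), call. = FALSE)
  }
  invisible(TRUE)
}

.assert_overhangs <- function(e1, e2, check_palindrome = c(TRUE, TRUE)) {
  is_palindrome <- function(s) nchar(s) > 0 && s == reverse_complement(s)
  for (i in seq_along(c(e1, e2))) {
    e <- c(e1, e2)[i]
    if (check_palindrome[i] && is_palindrome(e))
      stop("hairpin validation failed: palindromic terminal extension ",
           e, " permits tandem insertion", call. = FALSE)
  }
  if (e1 == reverse_complement(e2))
    stop("hairpin validation failed: terminal extensions ", e1, "/", e2,
         " are mutually compatible and permit tandem insertion",
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.hairpin_report <- function(x, ...) {
  cat("<hairpin_report>\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Bundled 19-nt validation target sequences
#'
#' The panel of 22 published/designed 19-nt target sequences (vimentin,
#' lamin A/C, Arp3, and two scramble controls) bundled with the package for
#' oligo-design examples and round-trip tests.
#'
#' @return data.frame with columns name, sequence, gene.
#' @export
validation_targets <- function() {
  path <- system.file("extdata", "validation_targets.tsv",
                      package = "ratiokd", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write an oligo set to FASTA
#'
#' @param x An `oligo_set`.
#' @param path Output FASTA path; one record per oligo, named
#'   `<target>|<oligo name>`.
#' @return `path`, invisibly.
#' @export
write_oligo_fasta <- function(x, path) {
  stopifnot(inherits(x, "oligo_set"))
  set <- Biostrings::DNAStringSet(x$oligos)
  names(set) <- paste(x$target$name, names(x$oligos), sep = "|")
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
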