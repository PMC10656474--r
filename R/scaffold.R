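#' VHH scaffold consensus used for annotation and simulation
#'
#' A single-domain antibody (VHH) framework consensus with hallmark anchor
#' residues: FR1 terminates in the conserved first cysteine, FR2 opens with
#' the conserved tryptophan, FR3 terminates in the second conserved cysteine,
#' and FR4 opens with the J-segment `[WF]-G-x-G` motif. The three CDR loops
#' between the frameworks are free in both length and composition.
#'
#' The same scaffold drives both sides of the package: the simulator threads
#' random CDRs between these frameworks, and the annotator aligns observed
#' amino-acid sequences back onto them to transfer FR/CDR boundaries. Real
#' repertoire data would substitute a germline-database aligner at the
#' annotation stage; the single-scaffold surrogate keeps the pipeline contract
#' (full FR1-FR4 reconstruction) exactly testable.
#'
#' @param fr1,fr2,fr3,fr4 Framework amino-acid strings. The defaults follow
#'   camelid VHH consensus; overriding them lets the annotator track a
#'   different single-framework library.
#' @return A list of class `vhh_scaffold` with the framework strings, their
#'   lengths, and the anchor descriptions.
#' @export
#' @examples
#' sc <- vhh_scaffold()
#' sc$fr1
vhh_scaffold <- function(fr1 = "QVQLVESGGGLVQPGGSLRLSC",
                         fr2 = "WFRQAPGKEREFVA",
                         fr3 = "RFTISRDNAKNTVYLQMNSLKPEDTAVYYC",
                         fr4 = "WGQGTQVTVSS") {
  assert_that(substring(fr1, nchar(fr1)) == "C",
              "fr1 must terminate in the conserved cysteine")
  assert_that(substring(fr2, 1, 1) == "W",
              "fr2 must open with the conserved tryptophan")
  assert_that(substring(fr3, nchar(fr3)) == "C",
              "fr3 must terminate in the conserved cysteine")
  assert_that(grepl("^[WF]G.G", fr4), "fr4 must open with the [WF]GxG J-motif")
  structure(
    list(fr1 = fr1, fr2 = fr2, fr3 = fr3, fr4 = fr4,
         fr_lengths = c(fr1 = nchar(fr1), fr2 = nchar(fr2),
                        fr3 = nchar(fr3), fr4 = nchar(fr4))),
    class = "vhh_scaffold")
}

#' @export
print.vhh_scaffold <- function(x, ...) {
  cat("VHH scaffold consensus\n")
  for (fr in c("fr1", "fr2", "fr3", "fr4")) {
    cat(sprintf("  %s (%2d aa): %s\n", toupper(fr), nchar(x[[fr]]), x[[fr]]))
  }
  invisible(x)
}

#' Cell-subtype roster used throughout the package
#'
#' The six sorted leukocyte pools sequenced per biopanning round: the bulk
#' CD45 pool (which seeds the next round) plus five sorted subtypes used for
#' selectivity scoring.
#'
#' @param selectable If `TRUE`, return only the five sorted subtypes
#'   (excluding the bulk CD45 pool).
#' @return Character vector of subtype labels.
#' @export
subtype_roster <- function(selectable = FALSE) {
  all <- c("CD45", "CD11b", "CD11c", "CD8", "CD4CD25neg", "CD4CD25pos")
  if (selectable) all[-1] else all
}

# amino-acid composition for simulated CDR loops: loop-prone residues
# (G/S/Y/D/R/T/N) weighted up, C/W/M down
cdr_aa_composition <- function() {
  c(A = 0.07, C = 0.01, D = 0.06, E = 0.04, F = 0.04, G = 0.10, H = 0.02,
    I = 0.04, K = 0.04, L = 0.06, M = 0.01, N = 0.05, P = 0.04, Q = 0.04,
    R = 0.07, S = 0.11, T = 0.07, V = 0.05, W = 0.02, Y = 0.06)
}

# aa -> synonymous codon list (standard code, stops excluded)
codon_choices <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))[setdiff(unique(gc), "*")]
}

#' Default amplicon flanking sequences
#'
#' Fixed vector-derived flanks placed on either side of the VHH coding
#' sequence in the simulated PCR amplicon; the annotation stage locates them
#' to excise the CDS and anchor the reading frame.
#'
#' @return Named list with `primer5` and `primer3` nucleotide strings.
#' @export
default_primers <- function() {
  list(primer5 = "ACGCTCAGTGGAACGAAAACTCACG",
       primer3 = "TATTCACTGGCCGTCGTTTTACAAC")
}
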