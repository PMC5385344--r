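#' Amplicon primer specification
#'
#' The nanobody amplicon is PCR-amplified with a forward primer annealing in
#' framework region 1 (FR1, encoding the peptide EVQLVES) and a reverse primer
#' annealing in framework region 4 (FR4, encoding T(L/Q)VTVSS; the degenerate
#' IUPAC base W = A/T realizes the L/Q choice). A correctly oriented amplicon
#' therefore starts with `fr1` and ends with the reverse complement of `fr4`.
#'
#' @param fr1 forward primer DNA (21-mer, must encode EVQLVES).
#' @param fr4 reverse primer DNA (21-mer, may contain the IUPAC code W).
#' @return An object of class `primer_spec` with elements `fr1`, `fr4` and
#'   `fr4_rc` (reverse complement of `fr4`, as it appears at the amplicon
#'   3' end).
#' @examples
#' primer_spec()
#' @export
primer_spec <- function(fr1 = "GAGGTGCAGCTGGTGGAGTCT",
                        fr4 = "TGAGGAGACGGTGACCWGGGT") {
  fr1 <- toupper(fr1); fr4 <- toupper(fr4)
  if (nchar(fr1) %% 3L != 0L)
    stop_input("fr1 primer length must be a multiple of 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(fr1)))
  if (aa != "EVQLVES")
    stop_input("fr1 primer must encode EVQLVES, got ", aa)
  fr4_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fr4)))
  structure(list(fr1 = fr1, fr4 = fr4, fr4_rc = fr4_rc), class = "primer_spec")
}

# per-read mismatch counts of a fixed-position primer against equal-length
# sequence windows; honors IUPAC degeneracy in the primer (W = A/T), never
# counts N in the read as a match
primer_mismatches <- function(windows, primer) {
  p <- strsplit(primer, "", fixed = TRUE)[[1]]
  n <- length(windows)
  mm <- integer(n)
  short <- nchar(windows) < length(p)
  for (j in seq_along(p)) {
    ch <- substring(windows, j, j)
    ok <- switch(p[j],
      W = ch == "A" | ch == "T",
      ch == p[j])
    mm <- mm + as.integer(!ok)
  }
  mm[short] <- length(p) # too short to carry the primer
  mm
}

#' Trim primer-encoded termini from a nanobody peptide
#'
#' Removes the first and last `n` residues (IMGT V-domain positions 1-7 and
#' 122-128 for the default `n = 7`), the parts of FR1 and FR4 whose sequence
#' is dictated by the PCR primers rather than the clone.
#'
#' @param peptide character vector of full-length peptides.
#' @param n number of residues to strip from each end.
#' @return Character vector of trimmed peptides.
#' @examples
#' trim_termini("EVQLVESAAAWTLVTVSS")
#' @export
trim_termini <- function(peptide, n = 7L) {
  if (any(nchar(peptide) <= 2L * n))
    stop_input("peptide shorter than 2*n residues cannot be trimmed")
  substr(peptide, n + 1L, nchar(peptide) - n)
}
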