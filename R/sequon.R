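#' Scan a protein sequence for N-glycosylation sequons
#'
#' A sequon is the tripeptide consensus N-X-S/T with X any amino acid except
#' proline; the asparagine of a sequon is the only residue that can carry an
#' N-linked glycan. Overlapping sequons are reported as independent sites, and
#' windows running past the C-terminus are excluded. `X` (unknown residue)
#' never satisfies the N or S/T positions; at the middle position it is
#' accepted, since the rule excludes only proline.
#'
#' @param sequence an amino-acid string.
#' @return a `data.frame` with columns `position` (1-based index of the N,
#'   ascending) and `motif` (the 3-letter sequon).
#' @export
scan_sequons <- function(sequence) {
  sequence <- as.character(sequence)
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    stop("empty sequence")
  }
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(s)
  if (n < 3L) {
    return(data.frame(position = integer(0), motif = character(0)))
  }
  i <- seq_len(n - 2L)
  hit <- s[i] == "N" & s[i + 1L] != "P" & (s[i + 2L] == "S" | s[i + 2L] == "T")
  pos <- i[hit]
  data.frame(
    position = pos,
    motif = paste0(s[pos], s[pos + 1L], s[pos + 2L]),
    stringsAsFactors = FALSE
  )
}

#' Count putative sequons per protein
#'
#' Proteins with zero sequons are retained (they are the input to the
#' "non-N-glycoprotein" filter downstream).
#'
#' @param proteome a proteome `data.frame` (see [proteome()]).
#' @return a `data.frame` with columns `accession`, `sequon_count`.
#' @export
count_sequons <- function(proteome) {
  if (is.null(nrow(proteome)) || nrow(proteome) == 0L) {
    stop("empty proteome")
  }
  data.frame(
    accession = proteome$accession,
    sequon_count = vapply(proteome$sequence,
                          function(s) nrow(scan_sequons(s)), integer(1),
                          USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Precompute sequon positions for a proteome
#'
#' @param proteome a proteome `data.frame`.
#' @return named list, accession -> integer vector of sequon N positions.
#' @export
sequon_index <- function(proteome) {
  idx <- lapply(proteome$sequence, function(s) scan_sequons(s)$position)
  names(idx) <- proteome$accession
  idx
}
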