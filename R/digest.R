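#' In-silico tryptic digestion
#'
#' Trypsin cleaves C-terminal to K or R unless the next residue is proline.
#' All fully tryptic peptides with at most `max_missed` internal (missed)
#' cleavage sites and at least `min_length` residues are returned, with
#' 1-based inclusive coordinates on the parent sequence.
#'
#' @param sequence amino-acid string.
#' @param max_missed maximum number of missed cleavages (default 2, the usual
#'   search-engine setting).
#' @param min_length minimum peptide length retained (default 1; identified
#'   PSMs are typically >= 5 residues).
#' @return `data.frame` with columns `peptide`, `start`, `end`, `missed`.
#' @export
tryptic_digest <- function(sequence, max_missed = 2L, min_length = 1L) {
  stopifnot(max_missed >= 0L, min_length >= 1L)
  sequence <- toupper(as.character(sequence))
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(s)
  if (n == 0L) {
    return(data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), missed = integer(0)))
  }
  cut_after <- which(s %in% c("K", "R") & c(s[-1], "") != "P" &
                       seq_len(n) < n)
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  nf <- length(starts)
  rows <- vector("list", nf * (max_missed + 1L))
  k <- 0L
  for (i in seq_len(nf)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nf) break
      k <- k + 1L
      rows[[k]] <- c(starts[i], ends[j], m)
    }
  }
  mat <- do.call(rbind, rows[seq_len(k)])
  len <- mat[, 2] - mat[, 1] + 1L
  keep <- len >= min_length
  mat <- mat[keep, , drop = FALSE]
  data.frame(
    peptide = substring(sequence, mat[, 1], mat[, 2]),
    start = as.integer(mat[, 1]),
    end = as.integer(mat[, 2]),
    missed = as.integer(mat[, 3]),
    stringsAsFactors = FALSE
  )
}

#' Which sequons are coverable by a detectable tryptic peptide?
#'
#' A glycosite can only be observed if some fully tryptic peptide of
#' detectable length covers its asparagine. This is a property of the
#' sequence and the digestion parameters alone, independent of occupancy,
#' and is used to separate digestion losses from occupancy estimation.
#'
#' @param proteome a proteome `data.frame`.
#' @param max_missed,min_length as in [tryptic_digest()].
#' @param max_length maximum detectable peptide length.
#' @return `data.frame` with `accession`, `position`, `coverable`.
#' @export
coverable_sequons <- function(proteome, max_missed = 2L, min_length = 5L,
                              max_length = 60L) {
  rows <- lapply(seq_len(nrow(proteome)), function(i) {
    sq <- scan_sequons(proteome$sequence[i])$position
    if (!length(sq)) return(NULL)
    peps <- tryptic_digest(proteome$sequence[i], max_missed, min_length)
    peps <- peps[nchar(peps$peptide) <= max_length, , drop = FALSE]
    cov <- vapply(sq, function(p)
      any(peps$start <= p & peps$end >= p), TRUE)
    data.frame(accession = proteome$accession[i], position = sq,
               coverable = cov, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(accession = character(0), position = integer(0),
                      coverable = logical(0)))
  }
  do.call(rbind, rows)
}
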