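#' Build a proteome table
#'
#' A proteome is a plain `data.frame` with columns `accession`, `sequence` and
#' `description`, one row per protein. Sequences are upper-cased, a terminal
#' stop character (`*`) is stripped, and any letter outside the 20 standard
#' amino acids is normalized to `X`. `X` never satisfies the N or S/T position
#' of a sequon and scores as hydrophilic in transmembrane prediction.
#'
#' @param accession character vector of unique protein identifiers.
#' @param sequence character vector of amino-acid sequences.
#' @param description optional character vector of free-text descriptions.
#' @return a `data.frame` of class `glyco_proteome`.
#' @export
proteome <- function(accession, sequence, description = "") {
  accession <- as.character(accession)
  sequence <- normalize_sequence(sequence)
  if (length(accession) != length(sequence)) {
    stop("accession and sequence must have the same length")
  }
  dup <- unique(accession[duplicated(accession)])
  if (length(dup)) {
    stop("duplicate accession(s): ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(sequence))) {
    stop("empty sequence for accession(s): ",
         paste(accession[!nzchar(sequence)], collapse = ", "))
  }
  out <- data.frame(
    accession = accession,
    sequence = sequence,
    description = rep_len(as.character(description), length(accession)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("glyco_proteome", "data.frame")
  out
}

normalize_sequence <- function(x) {
  x <- toupper(gsub("[[:space:]]", "", as.character(x)))
  x <- sub("\\*$", "", x)
  gsub(paste0("[^", paste(AA_STANDARD, collapse = ""), "]"), "X", x)
}

#' Read a protein FASTA file
#'
#' The accession is the first whitespace-delimited token after `>`; the rest of
#' the header line becomes the description. Wrapped sequence lines are
#' concatenated. Duplicate accessions and empty files are errors.
#'
#' @param path path to a FASTA file.
#' @return a proteome `data.frame` (see [proteome()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path)
  headers <- names(set)
  accession <- sub("[[:space:]].*$", "", headers)
  description <- ifelse(grepl("[[:space:]]", headers),
                        sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  proteome(accession, as.character(set), description)
}

#' Write a proteome to FASTA
#'
#' Inverse of [read_fasta()] on valid data (round-trip identity).
#'
#' @param x a proteome `data.frame`.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  seqs <- Biostrings::AAStringSet(x$sequence)
  names(seqs) <- ifelse(nzchar(x$description),
                        paste(x$accession, x$description), x$accession)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read a peptide-spectrum-match (PSM) table
#'
#' Tab-separated with header columns `peptide`, `proteins`
#' (semicolon-separated candidate accessions, order preserved), `spectra`
#' (positive), and optionally `probability` (in \[0,1\], default 1). Peptides
#' are the sequences as searched, i.e. with `D` written where a glycosylated
#' `N` was deglycosylated. Lines starting with `#` are ignored.
#'
#' @param path path to the TSV file.
#' @return a `data.frame` of class `glyco_psms` with columns `peptide`,
#'   `proteins` (list column), `spectra`, `probability`.
#' @export
read_psm_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  n_lead <- 0L
  while (n_lead < length(raw) && grepl("^#", raw[n_lead + 1L])) {
    n_lead <- n_lead + 1L
  }
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
  needed <- c("peptide", "proteins", "spectra")
  miss <- setdiff(needed, names(tab))
  if (length(miss)) {
    stop("PSM table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  if (is.null(tab$probability)) tab$probability <- 1.0
  # physical file line of row i: leading comments + header + i
  line_of <- function(i) n_lead + 1L + i
  psm_table(
    peptide = tab$peptide,
    proteins = strsplit(as.character(tab$proteins), ";", fixed = TRUE),
    spectra = tab$spectra,
    probability = tab$probability,
    .line = vapply(seq_len(nrow(tab)), line_of, integer(1))
  )
}

#' Construct/validate a PSM table
#'
#' @param peptide character vector of searched peptide sequences (length >= 5).
#' @param proteins list of character vectors of candidate accessions.
#' @param spectra positive spectral counts.
#' @param probability identification probabilities in \[0,1\].
#' @param .line optional file line numbers used in error messages.
#' @return a `data.frame` of class `glyco_psms`.
#' @export
psm_table <- function(peptide, proteins, spectra, probability = 1.0,
                      .line = NULL) {
  peptide <- toupper(as.character(peptide))
  if (!is.list(proteins)) proteins <- strsplit(as.character(proteins), ";")
  proteins <- lapply(proteins, function(p) trimws(as.character(p)))
  n <- length(peptide)
  spectra <- as.numeric(spectra)
  probability <- rep_len(as.numeric(probability), n)
  where <- if (is.null(.line)) paste("row", seq_len(n)) else paste("line", .line)
  bad <- which(is.na(spectra) | spectra <= 0)
  if (length(bad)) {
    stop("spectra must be > 0 (", where[bad[1]], ")")
  }
  bad <- which(is.na(probability) | probability < 0 | probability > 1)
  if (length(bad)) {
    stop("probability must be in [0,1] (", where[bad[1]], ")")
  }
  bad <- which(nchar(peptide) < 5)
  if (length(bad)) {
    stop("peptide length must be >= 5 (", where[bad[1]], ")")
  }
  bad <- which(!vapply(proteins, length, 1L) | !vapply(proteins, function(p)
    all(nzchar(p)), TRUE))
  if (length(bad)) {
    stop("empty protein accession list (", where[bad[1]], ")")
  }
  out <- data.frame(peptide = peptide, spectra = spectra,
                    probability = probability, stringsAsFactors = FALSE)
  out$proteins <- proteins
  out <- out[, c("peptide", "proteins", "spectra", "probability")]
  class(out) <- c("glyco_psms", "data.frame")
  out
}

#' Write a PSM table
#'
#' @param x a `glyco_psms` data frame.
#' @param path output path.
#' @param params named list recorded in the `#` header.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(x, path, params = list()) {
  flat <- data.frame(
    peptide = x$peptide,
    proteins = vapply(x$proteins, paste, "", collapse = ";"),
    spectra = x$spectra,
    probability = x$probability,
    stringsAsFactors = FALSE
  )
  write_tsv(flat, path, params = params)
}

#' Read transmembrane-domain annotations
#'
#' Two dialects: `"plain"` is a two-column TSV `accession<TAB>tm_count`
#' (an optional header line `accession tm_count` is tolerated); `"tmhmm_short"`
#' is the one-line-per-protein short output of TMHMM, in which the number of
#' predicted helices is carried in the `PredHel=` field.
#'
#' @param path input file.
#' @param dialect `"plain"` or `"tmhmm_short"`.
#' @return named integer vector, accession -> TM count.
#' @export
read_tm_annotations <- function(path, dialect = c("plain", "tmhmm_short")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  out <- integer(0)
  for (i in which(keep)) {
    ln <- lines[i]
    if (dialect == "plain") {
      fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(fields) < 2) {
        stop("cannot parse TM annotation at line ", i, ": ", ln)
      }
      if (i == which(keep)[1] && identical(tolower(fields[1]), "accession")) {
        next  # header line
      }
      cnt <- suppressWarnings(as.integer(fields[2]))
      if (is.na(cnt) || cnt < 0) {
        stop("invalid TM count at line ", i, ": ", ln)
      }
      out[fields[1]] <- cnt
    } else {
      m <- regmatches(ln, regexpr("PredHel=[0-9]+", ln))
      if (!length(m)) stop("no PredHel= field at line ", i, ": ", ln)
      acc <- strsplit(trimws(ln), "[[:space:]]+")[[1]][1]
      out[acc] <- as.integer(sub("PredHel=", "", m))
    }
  }
  out
}

#' Read a functional class map
#'
#' TSV with columns `accession` and `class`; classes must belong to the closed
#' set receptor/transporter/enzyme/miscellaneous/unclassified (mutually
#' exclusive).
#'
#' @param path input TSV.
#' @return named character vector, accession -> class.
#' @export
read_class_map <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(c("accession", "class"), names(tab))
  if (length(miss)) {
    stop("class map is missing column(s): ", paste(miss, collapse = ", "))
  }
  cls <- tolower(trimws(tab$class))
  bad <- setdiff(unique(cls), FUNCTIONAL_CLASSES)
  if (length(bad)) {
    stop("unknown functional class(es): ", paste(bad, collapse = ", "))
  }
  setNames(cls, tab$accession)
}

#' Read an ortholog group table
#'
#' TSV with columns `group_id`, `species`, `accession`; a usable group has at
#' least two species.
#'
#' @param path input TSV.
#' @return a `data.frame` with those three columns.
#' @export
read_ortholog_table <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(c("group_id", "species", "accession"), names(tab))
  if (length(miss)) {
    stop("ortholog table is missing column(s): ", paste(miss, collapse = ", "))
  }
  tab[, c("group_id", "species", "accession")]
}

#' Write a TSV with a `#`-prefixed provenance header
#'
#' Every pipeline output uses this writer. The header records the package
#' version, the coordinate convention, and any parameters passed; no
#' timestamps, so re-runs are byte-identical.
#'
#' @param x data frame (list columns are collapsed with `;`).
#' @param path output path.
#' @param params named list of parameters to record.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, params = list()) {
  x <- as.data.frame(x)
  for (cn in names(x)) {
    if (is.list(x[[cn]])) {
      x[[cn]] <- vapply(x[[cn]], paste, "", collapse = ";")
    }
  }
  hdr <- c(
    paste0("# nglyco ", as.character(packageVersion("nglyco"))),
    "# coordinates: 1-based, inclusive, on the protein sequence",
    if (length(params)) {
      paste0("# ", names(params), " = ",
             vapply(params, function(v) paste(format(v), collapse = ","), ""))
    }
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input path.
#' @return data frame (header comments dropped).
#' @export
read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
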