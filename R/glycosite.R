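#' Locate a deglycosylated peptide in a proteome
#'
#' PNGase F converts a glycosylated asparagine to aspartate, so a searched
#' peptide may carry `D` where the protein has `N`. Matching therefore allows
#' peptide `D` to align to protein `N`, but only at positions that are sequon
#' asparagines; everywhere else the match must be exact. Every matching
#' location in every protein is reported.
#'
#' @param peptide peptide string as searched.
#' @param proteome a proteome `data.frame`.
#' @param sequons precomputed [sequon_index()] for `proteome` (computed if
#'   omitted).
#' @param accessions optional subset of accessions to search.
#' @return `data.frame` with columns `accession`, `start`, `end` and a list
#'   column `glycosites` holding, per match, the protein positions where a
#'   peptide `D` aligned to a sequon `N` (deamidation evidence).
#' @export
locate_peptide <- function(peptide, proteome, sequons = sequon_index(proteome),
                           accessions = NULL) {
  peptide <- toupper(as.character(peptide))
  plen <- nchar(peptide)
  pchars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  d_off <- which(pchars == "D")  # offsets that may tolerate protein N
  pattern <- gsub("D", "[DN]", peptide, fixed = TRUE)
  rows <- list()
  target <- if (is.null(accessions)) proteome$accession else accessions
  for (acc in target) {
    ridx <- match(acc, proteome$accession)
    if (is.na(ridx)) next
    prot <- proteome$sequence[ridx]
    hits <- gregexpr(pattern, prot)[[1]]
    if (hits[1] == -1L) next
    pv <- strsplit(prot, "", fixed = TRUE)[[1]]
    sq <- sequons[[acc]] %||% integer(0)
    for (st in as.integer(hits)) {
      ok <- TRUE
      deam <- integer(0)
      for (o in d_off) {
        j <- st + o - 1L
        if (pv[j] == "N") {
          if (j %in% sq) deam <- c(deam, j) else { ok <- FALSE; break }
        }
      }
      if (!ok) next
      rows[[length(rows) + 1L]] <-
        list(accession = acc, start = st, end = st + plen - 1L,
             glycosites = deam)
    }
  }
  if (!length(rows)) {
    out <- data.frame(accession = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
    out$glycosites <- list()
    return(out)
  }
  out <- data.frame(
    accession = vapply(rows, `[[`, "", "accession"),
    start = vapply(rows, `[[`, 1L, "start"),
    end = vapply(rows, `[[`, 1L, "end"),
    stringsAsFactors = FALSE
  )
  out$glycosites <- lapply(rows, `[[`, "glycosites")
  out
}

#' Call glycosites from deglycosylated PSMs
#'
#' Each PSM with at least one deamidated sequon match yields glycosite
#' assignments. When the matched peptide span contains two or more sequons the
#' exact site cannot be determined from a low-resolution spectrum, so all
#' candidate sequons in the span are emitted flagged `ambiguous`, each carrying
#' a crediting weight according to `credit`:
#' \describe{
#'   \item{fractional}{(default) each of the k candidate sites receives 1/k,
#'     conserving total site credit per peptide;}
#'   \item{first}{the N-terminal-most candidate receives 1, the rest 0;}
#'   \item{all}{every candidate receives 1.}
#' }
#' PSMs whose peptides span no sequon, carry no deamidation evidence, or match
#' nothing are excluded and tallied (see `attr(, "tally")`). Peptides matching
#' more than one protein are credited to every protein and flagged `shared`.
#'
#' @param psms a `glyco_psms` table (see [psm_table()]).
#' @param proteome a proteome `data.frame`.
#' @param credit ambiguity crediting rule.
#' @param sequons precomputed [sequon_index()].
#' @return `data.frame` of class `glyco_assignments` with columns `psm_id`,
#'   `accession`, `position`, `motif`, `peptide`, `spectra`, `credit`,
#'   `ambiguous`, `shared`, `deamidated`; attribute `tally` records PSM and
#'   spectra counts per fate (conservation: assigned + dropped = input).
#' @export
assign_glycosites <- function(psms, proteome,
                              credit = c("fractional", "first", "all"),
                              sequons = sequon_index(proteome)) {
  credit <- match.arg(credit)
  missing_acc <- setdiff(unique(unlist(psms$proteins)), proteome$accession)
  if (length(missing_acc)) {
    stop("PSM(s) reference accession(s) absent from the proteome: ",
         paste(missing_acc, collapse = ", "))
  }
  tally <- c(psms_in = nrow(psms), assigned = 0, no_sequon = 0,
             no_deamidation = 0, unmatched = 0)
  spectra_tally <- c(psms_in = sum(psms$spectra), assigned = 0, no_sequon = 0,
                     no_deamidation = 0, unmatched = 0)
  out <- list()
  for (i in seq_len(nrow(psms))) {
    pep <- psms$peptide[i]
    loc <- locate_peptide(pep, proteome, sequons,
                          accessions = psms$proteins[[i]])
    fate <- "unmatched"
    if (nrow(loc)) {
      # candidate sites per protein: all sequon N positions inside any span
      per_acc <- lapply(split(loc, loc$accession), function(lf) {
        cand <- integer(0); deam <- integer(0)
        for (r in seq_len(nrow(lf))) {
          sq <- sequons[[lf$accession[1]]]
          cand <- union(cand, sq[sq >= lf$start[r] & sq <= lf$end[r]])
          deam <- union(deam, lf$glycosites[[r]])
        }
        list(cand = sort(cand), deam = deam)
      })
      any_sequon <- any(vapply(per_acc, function(a) length(a$cand) > 0, TRUE))
      any_deam <- any(vapply(per_acc, function(a) length(a$deam) > 0, TRUE))
      if (!any_sequon) {
        fate <- "no_sequon"
      } else if (!any_deam) {
        fate <- "no_deamidation"
      } else {
        fate <- "assigned"
        hit_accs <- names(per_acc)[vapply(per_acc, function(a)
          length(a$deam) > 0, TRUE)]
        shared <- length(hit_accs) > 1L
        for (acc in hit_accs) {
          cand <- per_acc[[acc]]$cand
          k <- length(cand)
          w <- switch(credit,
                      fractional = rep(1 / k, k),
                      first = c(1, rep(0, k - 1L)),
                      all = rep(1, k))
          prot <- proteome$sequence[match(acc, proteome$accession)]
          out[[length(out) + 1L]] <- data.frame(
            psm_id = i,
            accession = acc,
            position = cand,
            motif = substring(prot, cand, cand + 2L),
            peptide = pep,
            spectra = psms$spectra[i],
            credit = w,
            ambiguous = k >= 2L,
            shared = shared,
            deamidated = cand %in% per_acc[[acc]]$deam,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    tally[fate] <- tally[fate] + 1
    spectra_tally[fate] <- spectra_tally[fate] + psms$spectra[i]
  }
  res <- if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(psm_id = integer(0), accession = character(0),
               position = integer(0), motif = character(0),
               peptide = character(0), spectra = numeric(0),
               credit = numeric(0), ambiguous = logical(0),
               shared = logical(0), deamidated = logical(0),
               stringsAsFactors = FALSE)
  }
  class(res) <- c("glyco_assignments", "data.frame")
  attr(res, "tally") <- tally
  attr(res, "spectra_tally") <- spectra_tally
  res
}

#' Fraction of identified peptides with ambiguous site assignment
#'
#' A peptide is ambiguous when its matched span contains two or more sequons.
#' The denominator is distinct identified peptides by default; `"psm"` uses
#' PSM rows instead (the published ~5.6% figure does not state which, so both
#' are available).
#'
#' @param assignments a `glyco_assignments` table.
#' @param denominator `"peptide"` or `"psm"`.
#' @return fraction in \[0,1\].
#' @export
ambiguity_rate <- function(assignments, denominator = c("peptide", "psm")) {
  denominator <- match.arg(denominator)
  if (nrow(assignments) == 0L) stop("no assignments")
  if (denominator == "peptide") {
    amb <- tapply(assignments$ambiguous, assignments$peptide, any)
  } else {
    amb <- tapply(assignments$ambiguous, assignments$psm_id, any)
  }
  mean(amb)
}

#' Filter identifications and group degenerate proteins
#'
#' Applies the identification filters: PSMs with probability below
#' `min_probability` are removed; proteins identified by an identical peptide
#' set are merged into one group represented by the first accession in input
#' order (degenerate entries); and protein groups whose total spectral count
#' is 1 ("single hits", where false positives concentrate) are removed when
#' `remove_single_hits` is set.
#'
#' @param psms a `glyco_psms` table.
#' @param min_probability keep PSMs with probability >= this (default 0.9).
#' @param remove_single_hits drop groups with total spectra == 1.
#' @return list with `psms` (filtered), `groups` (`data.frame`: representative,
#'   members list column, n_peptides, total_spectra, kept), `representatives`
#'   (kept representative accessions) and `tally` (dropped counts).
#' @export
filter_identifications <- function(psms, min_probability = 0.9,
                                   remove_single_hits = TRUE) {
  if (min_probability < 0 || min_probability > 1) {
    stop("min_probability must be in [0,1]")
  }
  keep <- psms$probability >= min_probability
  dropped_prob <- sum(!keep)
  kept <- psms[keep, , drop = FALSE]
  # peptide set per accession, preserving first-appearance order of accessions
  acc_order <- unique(unlist(kept$proteins))
  pep_sets <- lapply(acc_order, function(acc) {
    hit <- vapply(kept$proteins, function(p) acc %in% p, TRUE)
    sort(unique(kept$peptide[hit]))
  })
  names(pep_sets) <- acc_order
  keys <- vapply(pep_sets, paste, "", collapse = "|")
  group_ids <- match(keys, unique(keys))
  groups <- lapply(seq_along(unique(keys)), function(g) {
    members <- acc_order[group_ids == g]
    hit <- vapply(kept$proteins, function(p) any(members %in% p), TRUE)
    data.frame(representative = members[1],
               n_peptides = length(pep_sets[[members[1]]]),
               total_spectra = sum(kept$spectra[hit]),
               stringsAsFactors = FALSE)
  })
  groups <- do.call(rbind, groups)
  groups$members <- split(acc_order, group_ids)[
    as.character(seq_len(nrow(groups)))]
  groups$kept <- !(remove_single_hits & groups$total_spectra <= 1)
  list(
    psms = kept,
    groups = groups[, c("representative", "members", "n_peptides",
                        "total_spectra", "kept")],
    representatives = groups$representative[groups$kept],
    tally = c(psms_in = nrow(psms), below_probability = dropped_prob,
              groups = nrow(groups),
              single_hit_groups = sum(!groups$kept))
  )
}
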