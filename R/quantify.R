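#' Stoichiometry-normalized protein spectral counts
#'
#' For each protein the summed peptide spectral count is divided by the
#' N-glycan stoichiometry -- the number of distinct detected glycosites -- to
#' yield the protein spectral count used as relative protein quantity. A
#' protein carrying 9 detected glycosites and 153 summed peptide spectra is
#' reported at 17 protein spectra. Under fractional ambiguity crediting each
#' candidate site contributes its credit (capped at 1 per site), so an
#' ambiguous peptide still adds exactly one glycan to the stoichiometry.
#'
#' @param assignments a `glyco_assignments` table (see [assign_glycosites()]).
#' @return `data.frame` with columns `accession`, `total_peptide_spectra`,
#'   `stoichiometry`, `protein_spectra`. Proteins with zero stoichiometry are
#'   excluded with a warning.
#' @export
protein_spectra <- function(assignments) {
  if (nrow(assignments) == 0L) {
    return(data.frame(accession = character(0),
                      total_peptide_spectra = numeric(0),
                      stoichiometry = numeric(0),
                      protein_spectra = numeric(0)))
  }
  out <- lapply(split(seq_len(nrow(assignments)), assignments$accession),
                function(idx) {
    a <- assignments[idx, , drop = FALSE]
    # each PSM counts once toward the peptide spectra of this protein
    psm_first <- !duplicated(a$psm_id)
    total <- sum(a$spectra[psm_first])
    site_credit <- tapply(a$credit, a$position, sum)
    stoich <- sum(pmin(1, site_credit))
    data.frame(accession = a$accession[1],
               total_peptide_spectra = total,
               stoichiometry = stoich,
               protein_spectra = if (stoich > 0) total / stoich else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  zero <- out$stoichiometry == 0
  if (any(zero)) {
    warning("excluding ", sum(zero),
            " protein(s) with zero glycan stoichiometry (non-glycoproteins)")
    out <- out[!zero, , drop = FALSE]
  }
  out[order(out$accession), , drop = FALSE]
}

#' Assign an abundance tier to a protein spectral count
#'
#' Empirical quantity levels: fewer than 5 protein spectra is `low`, 5--12
#' inclusive is `medium`, more than 12 is `high`. Fractional counts are tiered
#' without rounding.
#'
#' @param x positive protein spectral counts (vectorized).
#' @return character vector of `"low"`, `"medium"`, `"high"`.
#' @export
abundance_tier <- function(x) {
  x <- as.numeric(x)
  if (any(is.na(x) | x <= 0)) stop("protein spectra must be positive")
  ifelse(x < 5, "low", ifelse(x <= 12, "medium", "high"))
}

#' Calibrate spectral counts to copies per cell
#'
#' Linear scaling through the origin against a reference protein of known
#' expression (the Lifr anchor: 4.4 protein spectra at ~100 copies/cell).
#' Doubling the spectral count doubles the estimate.
#'
#' @param x protein spectral counts (>= 0, vectorized).
#' @param ref_spectra reference protein spectral count (> 0).
#' @param ref_copies reference copies per cell (> 0).
#' @return estimated copies per cell.
#' @export
calibrate_copies <- function(x, ref_spectra, ref_copies) {
  if (length(ref_spectra) != 1L || is.na(ref_spectra) || ref_spectra <= 0) {
    stop("ref_spectra must be a single positive number")
  }
  if (length(ref_copies) != 1L || is.na(ref_copies) || ref_copies <= 0) {
    stop("ref_copies must be a single positive number")
  }
  x <- as.numeric(x)
  if (any(is.na(x) | x < 0)) stop("protein spectra must be >= 0")
  x * ref_copies / ref_spectra
}

#' Roll assignments up to per-protein glycoprotein profiles
#'
#' Combines [protein_spectra()] with sequon counts, abundance tiers, sequon
#' occupancy, and optional transmembrane counts and functional classes into
#' the per-protein profile table used by all downstream statistics.
#'
#' @param assignments a `glyco_assignments` table.
#' @param proteome the proteome the assignments were called on (used for
#'   sequon counts; optional if `sequon_counts` given).
#' @param sequon_counts optional `data.frame` from [count_sequons()].
#' @param tm_counts optional named vector accession -> TM count (from
#'   [read_tm_annotations()] or [predict_tm()]).
#' @param class_map optional named vector accession -> functional class.
#' @param accessions optional restriction (e.g. kept group representatives).
#' @return `data.frame` of class `glyco_profiles` with columns `accession`,
#'   `total_peptide_spectra`, `stoichiometry`, `protein_spectra`, `tier`,
#'   `sequon_count`, `occupancy`, `tm_count`, `functional_class`.
#' @export
build_profiles <- function(assignments, proteome = NULL, sequon_counts = NULL,
                           tm_counts = NULL, class_map = NULL,
                           accessions = NULL) {
  if (is.null(sequon_counts)) {
    if (is.null(proteome)) stop("need proteome or sequon_counts")
    sequon_counts <- count_sequons(proteome)
  }
  if (!is.null(accessions)) {
    assignments <- assignments[assignments$accession %in% accessions, ,
                               drop = FALSE]
  }
  prof <- protein_spectra(assignments)
  sc <- setNames(sequon_counts$sequon_count, sequon_counts$accession)
  prof$tier <- abundance_tier(prof$protein_spectra)
  prof$sequon_count <- as.integer(sc[prof$accession])
  if (any(is.na(prof$sequon_count))) {
    stop("no sequon count for accession(s): ",
         paste(prof$accession[is.na(prof$sequon_count)], collapse = ", "))
  }
  bad <- prof$stoichiometry > prof$sequon_count + 1e-9
  if (any(bad)) {
    stop("stoichiometry exceeds sequon count for: ",
         paste(prof$accession[bad], collapse = ", "))
  }
  prof$occupancy <- pmin(1, prof$stoichiometry / prof$sequon_count)
  prof$tm_count <- if (is.null(tm_counts)) NA_integer_ else
    as.integer(tm_counts[prof$accession])
  prof$functional_class <- if (is.null(class_map)) "unclassified" else {
    cl <- unname(class_map[prof$accession])
    ifelse(is.na(cl), "unclassified", cl)
  }
  class(prof) <- c("glyco_profiles", "data.frame")
  prof
}
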