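#' Published glyco-enzyme profiles (bundled reference table)
#'
#' The 9 glycosyl transferases and 14 glycosyl hydrolases identified in the
#' mES E14.Tg2a N-glycoproteome, with their stoichiometry-normalized spectral
#' counts, detected glycosites, putative sequons and TM counts. Used as a
#' worked input for the occupancy statistics (all transferases are
#' monoglycosylated; their unweighted glycosylation rate is 28.1%).
#'
#' @return `data.frame` with columns `gene_id`, `symbol`, `family`, `tms`,
#'   `protein_spectra`, `detected_glycosites`, `putative_glycosites`.
#' @export
glycoenzyme_table <- function() {
  read.delim(system.file("extdata", "glycoenzymes.tsv", package = "nglyco"),
             comment.char = "#", stringsAsFactors = FALSE)
}

#' Published CD-protein profiles (bundled reference table)
#'
#' CD (cluster of differentiation) surface markers identified in the mES
#' E14.Tg2a N-glycoproteome with their quantification: e.g. Lamp2 at 153
#' summed peptide spectra over 9 glycosites = 17 protein spectra.
#'
#' @return `data.frame` with columns `cd_name`, `symbol`, `tms`,
#'   `protein_spectra`, `detected_glycosites`, `putative_glycosites`.
#' @export
cd_protein_table <- function() {
  read.delim(system.file("extdata", "cd_glycoproteins.tsv",
                         package = "nglyco"),
             comment.char = "#", stringsAsFactors = FALSE)
}
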