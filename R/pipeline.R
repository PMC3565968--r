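#' Read a flat key-value pipeline configuration file
#'
#' Sections are `[name]` headers; entries are `key = value` lines; `#` starts
#' a comment. Values are returned as strings; [run_pipeline()] coerces them.
#'
#' @param path config file path.
#' @return nested named list, section -> key -> value.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      cfg[[section]][[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    } else {
      stop("cannot parse config line: ", ln)
    }
  }
  cfg
}

#' Run the end-to-end N-glycoproteome analysis
#'
#' Stages run in order: sequon scan, PSM probability filter, glycosite
#' mapping, degenerate-protein grouping and single-hit removal, stoichiometry-
#' normalized quantification, and occupancy/class/stoichiometry statistics.
#' Every output TSV carries a `#` provenance header with version and
#' parameters; a machine-readable run summary records the filter tallies
#' (input PSMs = used + each dropped category, exactly). All randomness lives
#' in the optional simulation block, so a fixed config and seed reproduce
#' byte-identical outputs.
#'
#' @param config nested list as from [read_pipeline_config()], or a path to a
#'   config file. Recognized entries:
#'   \describe{
#'     \item{input}{`fasta`, `psms`, optional `classes`, `tm`, `tm_dialect`.}
#'     \item{simulate}{`n_proteins`, `seed`, optional `occupancy_rate` --
#'       used instead of `input` to generate data on the fly.}
#'     \item{filter}{`min_probability` (default 0.9), `drop_single_hits`
#'       (default true).}
#'     \item{map}{`credit` (fractional/first/all).}
#'     \item{quantify}{optional `ref_accession`, `ref_copies` for copy-number
#'       calibration.}
#'   }
#' @param out_dir output directory (created if missing).
#' @param verbose emit progress messages to standard error.
#' @return invisibly, a list with `profiles`, `assignments`, `groups`,
#'   `summary` (tally data frame) and the paths written.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  say <- function(...) if (verbose) message("[nglyco] ", ...)
  num <- function(x, default) if (is.null(x)) default else as.numeric(x)
  flag <- function(x, default) if (is.null(x)) default else
    tolower(x) %in% c("true", "1", "yes", "on")

  min_prob <- num(config$filter$min_probability, 0.9)
  if (is.na(min_prob) || min_prob < 0 || min_prob > 1) {
    stop("filter stage: min_probability must be in [0,1], got ", min_prob)
  }
  drop_single <- flag(config$filter$drop_single_hits, TRUE)
  credit <- config$map$credit %||% "fractional"

  tm_counts <- NULL
  class_map <- NULL
  if (!is.null(config$simulate)) {
    seed <- as.integer(num(config$simulate$seed, NA))
    if (is.na(seed)) stop("simulate stage: seed is required")
    say("simulating proteome (seed ", seed, ")")
    sim <- generate_proteome(
      n_proteins = as.integer(num(config$simulate$n_proteins, 100)),
      seed = seed)
    simp <- simulate_psms(
      sim, seed = seed + 1L,
      occupancy = list(rate = num(config$simulate$occupancy_rate, 0.444)))
    prot <- sim$proteome
    psms <- simp$psms
    class_map <- sim$class_map
    tm_counts <- setNames(sim$truth$proteins$tm_count,
                          sim$truth$proteins$accession)
  } else if (!is.null(config$input)) {
    say("reading inputs")
    prot <- tryCatch(read_fasta(config$input$fasta),
                     error = function(e) stop("input stage (fasta): ",
                                              conditionMessage(e)))
    psms <- tryCatch(read_psm_table(config$input$psms),
                     error = function(e) stop("input stage (psms): ",
                                              conditionMessage(e)))
    if (!is.null(config$input$classes)) {
      class_map <- read_class_map(config$input$classes)
    }
    if (!is.null(config$input$tm)) {
      tm_counts <- read_tm_annotations(config$input$tm,
                                       config$input$tm_dialect %||% "plain")
    }
  } else {
    stop("config must contain an [input] or [simulate] section")
  }

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  params <- list(min_probability = min_prob, drop_single_hits = drop_single,
                 credit = credit)

  say("scanning sequons in ", nrow(prot), " proteins")
  sqc <- count_sequons(prot)
  sqi <- sequon_index(prot)

  say("filtering ", nrow(psms), " PSMs at probability >= ", min_prob)
  filt <- filter_identifications(psms, min_prob, drop_single)

  say("mapping glycosites")
  asg <- tryCatch(
    assign_glycosites(filt$psms, prot, credit = credit, sequons = sqi),
    error = function(e) stop("map stage: ", conditionMessage(e)))
  tally <- attr(asg, "tally")

  say("building profiles")
  profiles <- build_profiles(asg, sequon_counts = sqc, tm_counts = tm_counts,
                             class_map = class_map,
                             accessions = filt$representatives)
  if (!is.null(config$quantify$ref_accession)) {
    ref <- config$quantify$ref_accession
    idx <- match(ref, profiles$accession)
    if (is.na(idx)) stop("quantify stage: reference accession ", ref,
                         " not in profiles")
    profiles$copies_per_cell <- calibrate_copies(
      profiles$protein_spectra, profiles$protein_spectra[idx],
      num(config$quantify$ref_copies, 100))
  }

  say("computing statistics")
  groups_tab <- stoichiometry_groups(profiles)
  class_tab <- class_summary(profiles)

  summary_tab <- data.frame(
    stage = c("psms_in", "below_probability", "sequon_free_dropped",
              "no_deamidation_dropped", "unmatched_dropped", "psms_assigned",
              "protein_groups", "single_hit_groups_dropped",
              "glycoproteins_profiled"),
    count = c(filt$tally[["psms_in"]], filt$tally[["below_probability"]],
              tally[["no_sequon"]], tally[["no_deamidation"]],
              tally[["unmatched"]], tally[["assigned"]],
              filt$tally[["groups"]], filt$tally[["single_hit_groups"]],
              nrow(profiles))
  )

  paths <- c(
    sites = write_tsv(as.data.frame(asg), file.path(out_dir, "sites.tsv"),
                      params),
    profiles = write_tsv(as.data.frame(profiles),
                         file.path(out_dir, "profiles.tsv"), params),
    groups = write_tsv(filt$groups, file.path(out_dir, "protein_groups.tsv"),
                       params),
    stoichiometry = write_tsv(groups_tab,
                              file.path(out_dir, "stoichiometry_groups.tsv"),
                              params),
    classes = write_tsv(class_tab, file.path(out_dir, "class_summary.tsv"),
                        params),
    summary = write_tsv(summary_tab, file.path(out_dir, "run_summary.tsv"),
                        params)
  )
  say("done: ", nrow(profiles), " glycoproteins profiled; overall rate ",
      sprintf("%.1f%%", 100 * set_glycosylation_rate(profiles)))
  invisible(list(profiles = profiles, assignments = asg, groups = filt$groups,
                 summary = summary_tab, paths = paths))
}
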