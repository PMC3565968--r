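#' Default per-class transmembrane-count models
#'
#' Receptors are mostly single-pass (low TM), transporters polytopic (~7
#' helices), enzymes and miscellaneous proteins mostly soluble or single-pass,
#' mirroring the qualitative pattern seen in membrane-proteome
#' classifications.
#'
#' @return named list, class -> function(n) drawing n TM counts.
#' @export
default_tm_model <- function() {
  list(
    receptor = function(n) sample(0:3, n, TRUE, prob = c(0.25, 0.45, 0.2, 0.1)),
    transporter = function(n) pmin(12L, pmax(3L, rpois(n, 7))),
    enzyme = function(n) sample(0:1, n, TRUE, prob = c(0.5, 0.5)),
    miscellaneous = function(n) sample(0:2, n, TRUE, prob = c(0.5, 0.35, 0.15)),
    unclassified = function(n) sample(0:2, n, TRUE, prob = c(0.5, 0.35, 0.15))
  )
}

# Geometry of planted TM segments. Gaps below ~23 residues would let the
# 19-residue hydropathy window bridge two helices, so keep them well apart.
TM_LEN_RANGE <- 19:23
TM_MIN_GAP <- 25L
TM_MARGIN <- 8L

#' Generate a synthetic proteome with known ground truth
#'
#' Sequences are drawn i.i.d. from a background residue distribution (uniform
#' over the 20 standard residues by default). Transmembrane segments are
#' planted as hydrophobic stretches (L/I/V/F/A/M) with per-class TM-count
#' distributions; sequons (N, non-P, S/T) are planted at the requested density
#' outside TM segments, honoring a buffer of `tm_buffer` residues around each
#' helix (N-glycosylation requires the sequon to sit clear of the membrane).
#' Incidental sequons also arise from the background at rate
#' p(N) (1 - p(P)) (p(S) + p(T)) per position; the truth table records every
#' sequon in the final sequence and flags which were planted. With
#' `background_sequons = FALSE` incidental sequons are mutated away so planted
#' counts are exact (used by the complementarity cohort).
#'
#' @param n_proteins number of proteins.
#' @param seed integer seed; generation is fully deterministic given it.
#' @param length_dist list(meanlog, sdlog, min, max) for log-normal protein
#'   lengths (default centered near 420 residues, typical for membrane
#'   proteins). Lengths are raised when needed to fit the requested helices.
#' @param class_mix named class probabilities (default 42/17/15/26
#'   receptor/transporter/enzyme/miscellaneous).
#' @param sequon_density planted sequons per residue (default 0.016, ~7.5
#'   sequons on a 470-residue protein).
#' @param tm_model named list class -> function(n) of TM-count samplers
#'   (default [default_tm_model()]).
#' @param residue_freq optional named background residue probabilities.
#' @param tm_buffer min distance between a planted sequon and a TM segment.
#' @param background_sequons keep incidental background sequons (default TRUE).
#' @param tm_counts,sequon_counts optional explicit per-protein counts
#'   (length `n_proteins`), overriding the models.
#' @param lengths optional explicit protein lengths; an error is raised if a
#'   requested length cannot hold the requested helices.
#' @return list with `proteome`, `class_map` (named vector), and `truth`
#'   (list: `proteins` data frame with class/length/planted counts, `tms`
#'   segment table, `sequons` per-site table with `planted` flag, `seed`).
#' @export
generate_proteome <- function(n_proteins, seed,
                              length_dist = list(meanlog = log(420),
                                                 sdlog = 0.35,
                                                 min = 120L, max = 3000L),
                              class_mix = c(receptor = 0.42,
                                            transporter = 0.17,
                                            enzyme = 0.15,
                                            miscellaneous = 0.26),
                              sequon_density = 0.016,
                              tm_model = default_tm_model(),
                              residue_freq = NULL,
                              tm_buffer = 12L,
                              background_sequons = TRUE,
                              tm_counts = NULL, sequon_counts = NULL,
                              lengths = NULL) {
  stopifnot(n_proteins >= 1, sequon_density >= 0)
  if (abs(sum(class_mix) - 1) > 1e-6) stop("class_mix must sum to 1")
  set.seed(seed)
  if (is.null(residue_freq)) {
    residue_freq <- setNames(rep(1 / 20, 20), AA_STANDARD)
  }
  residue_freq <- residue_freq / sum(residue_freq)
  classes <- sample(names(class_mix), n_proteins, TRUE, prob = class_mix)
  if (is.null(tm_counts)) {
    tm_counts <- integer(n_proteins)
    for (cc in unique(classes)) {
      idx <- which(classes == cc)
      sampler <- tm_model[[cc]]
      if (is.null(sampler)) stop("no TM model for class ", cc)
      tm_counts[idx] <- sampler(length(idx))
    }
  }
  explicit_len <- !is.null(lengths)
  if (!explicit_len) {
    lengths <- pmin(length_dist$max, pmax(length_dist$min, round(
      rlnorm(n_proteins, length_dist$meanlog, length_dist$sdlog))))
  }
  hydro <- c("L", "I", "V", "F", "A", "M")
  hydro_p <- c(0.3, 0.2, 0.2, 0.1, 0.1, 0.1)
  seqs <- character(n_proteins)
  tm_rows <- list()
  seq_rows <- list()
  planted_n <- integer(n_proteins)
  accs <- sprintf("SYN%04d", seq_len(n_proteins))
  for (i in seq_len(n_proteins)) {
    m <- tm_counts[i]
    tm_lens <- if (m > 0) sample(TM_LEN_RANGE, m, TRUE) else integer(0)
    required <- if (m > 0) {
      sum(tm_lens) + (m - 1L) * TM_MIN_GAP + 2L * TM_MARGIN
    } else 3L
    len <- lengths[i]
    if (len < required) {
      if (explicit_len) {
        stop("protein ", accs[i], ": length ", len,
             " cannot hold ", m, " TM segment(s) (needs >= ", required, ")")
      }
      len <- required + 30L
    }
    s <- sample(AA_STANDARD, len, TRUE, prob = residue_freq)
    # place TM segments: distribute slack over the m+1 gaps
    tms <- matrix(integer(0), ncol = 2)
    if (m > 0) {
      slack <- len - required
      extra <- as.vector(rmultinom(1, slack, rep(1, m + 1L)))
      pos <- TM_MARGIN + extra[1L] + 1L
      tms <- matrix(NA_integer_, m, 2)
      for (t in seq_len(m)) {
        tms[t, ] <- c(pos, pos + tm_lens[t] - 1L)
        s[pos:(pos + tm_lens[t] - 1L)] <-
          sample(hydro, tm_lens[t], TRUE, prob = hydro_p)
        pos <- pos + tm_lens[t] + TM_MIN_GAP + extra[t + 1L]
      }
    }
    # candidate sequon positions: outside TM +/- buffer, inside the sequence
    blocked <- rep(FALSE, len)
    if (m > 0) {
      for (t in seq_len(m)) {
        lo <- max(1L, tms[t, 1] - tm_buffer)
        hi <- min(len, tms[t, 2] + tm_buffer)
        blocked[lo:hi] <- TRUE
      }
    }
    allowed <- which(!blocked)
    allowed <- allowed[allowed >= 2L & allowed <= len - 2L]
    want <- if (!is.null(sequon_counts)) sequon_counts[i] else
      rpois(1, len * sequon_density)
    planted <- integer(0)
    if (want > 0 && length(allowed)) {
      for (p in sample(allowed)) {
        if (length(planted) >= want) break
        if (!length(planted) || min(abs(planted - p)) >= 3L) {
          planted <- c(planted, p)
        }
      }
      planted <- sort(planted)
      for (p in planted) {
        s[p] <- "N"
        s[p + 1L] <- sample(setdiff(AA_STANDARD, "P"), 1)
        s[p + 2L] <- sample(c("S", "T"), 1)
      }
    }
    seq_str <- paste(s, collapse = "")
    if (!background_sequons) {
      sc <- scan_sequons(seq_str)$position
      extra_sq <- setdiff(sc, planted)
      if (length(extra_sq)) {
        s[extra_sq] <- "Q"  # Q can neither seed nor complete a sequon
        seq_str <- paste(s, collapse = "")
      }
    }
    seqs[i] <- seq_str
    planted_n[i] <- length(planted)
    if (nrow(tms)) {
      tm_rows[[length(tm_rows) + 1L]] <- data.frame(
        accession = accs[i], start = tms[, 1], end = tms[, 2],
        stringsAsFactors = FALSE)
    }
    all_sq <- scan_sequons(seq_str)$position
    if (length(all_sq)) {
      seq_rows[[length(seq_rows) + 1L]] <- data.frame(
        accession = accs[i], position = all_sq,
        planted = all_sq %in% planted, stringsAsFactors = FALSE)
    }
  }
  prot <- proteome(accs, seqs, paste("synthetic", classes))
  truth <- list(
    proteins = data.frame(accession = accs, class = classes,
                          length = nchar(seqs), tm_count = tm_counts,
                          planted_sequons = planted_n,
                          stringsAsFactors = FALSE),
    tms = if (length(tm_rows)) do.call(rbind, tm_rows) else
      data.frame(accession = character(0), start = integer(0),
                 end = integer(0)),
    sequons = if (length(seq_rows)) do.call(rbind, seq_rows) else
      data.frame(accession = character(0), position = integer(0),
                 planted = logical(0)),
    seed = seed
  )
  list(proteome = prot, class_map = setNames(classes, accs), truth = truth)
}

#' Simulate deglycosylated PSM tables from a synthetic proteome
#'
#' Protein abundances are log-normal copies per cell; every sequon (planted or
#' incidental) is independently occupied with a Bernoulli rate (global or
#' per-class); fully tryptic peptides within the detectable length range that
#' cover at least one occupied sequon are each detected with a peptide-level
#' Bernoulli probability (attenuated per missed cleavage) and receive a
#' Poisson spectral count with mean proportional to protein abundance
#' (detected only if positive, keeping expected spectra linear in abundance).
#' Occupied sequons covered by an emitted peptide are written as `D`
#' (deamidated); unoccupied sequons never are.
#'
#' @param sim result of [generate_proteome()].
#' @param seed integer seed.
#' @param abundance list(meanlog, sdlog) for log-normal copies/cell.
#' @param occupancy list(rate = global Bernoulli rate, by_class = optional
#'   named per-class rates overriding it).
#' @param detection list(prob, max_missed, min_length, max_length,
#'   spectra_per_copy, missed_penalty) -- peptide-level detection model.
#' @param probability_range identification probabilities are drawn uniformly
#'   from this interval.
#' @return list with `psms` (a `glyco_psms` table), `truth` (list: `abundance`
#'   data frame, `occupancy` per-sequon data frame with `occupied` flag,
#'   `seed`).
#' @export
simulate_psms <- function(sim, seed,
                          abundance = list(meanlog = log(150), sdlog = 1.0),
                          occupancy = list(rate = 0.444, by_class = NULL),
                          detection = list(prob = 0.8, max_missed = 2L,
                                           min_length = 5L, max_length = 60L,
                                           spectra_per_copy = 0.05,
                                           missed_penalty = c(1, 0.3, 0.1)),
                          probability_range = c(0.95, 1)) {
  det <- utils::modifyList(
    list(prob = 0.8, max_missed = 2L, min_length = 5L, max_length = 60L,
         spectra_per_copy = 0.05, missed_penalty = c(1, 0.3, 0.1)),
    detection)
  set.seed(seed)
  prot <- sim$proteome
  truth_sq <- sim$truth$sequons
  classes <- setNames(sim$truth$proteins$class, sim$truth$proteins$accession)
  n <- nrow(prot)
  copies <- rlnorm(n, abundance$meanlog, abundance$sdlog)
  names(copies) <- prot$accession
  rate_of <- function(acc) {
    cls <- classes[[acc]]
    r <- occupancy$by_class[[cls]] %||% occupancy$rate
    r
  }
  occ_rows <- list()
  psm_rows <- list()
  for (i in seq_len(n)) {
    acc <- prot$accession[i]
    sq <- truth_sq$position[truth_sq$accession == acc]
    if (!length(sq)) next
    occ <- rbinom(length(sq), 1, rate_of(acc)) == 1
    occ_rows[[length(occ_rows) + 1L]] <- data.frame(
      accession = acc, position = sq, occupied = occ,
      stringsAsFactors = FALSE)
    occupied <- sq[occ]
    if (!length(occupied)) next
    peps <- tryptic_digest(prot$sequence[i], det$max_missed, det$min_length)
    peps <- peps[nchar(peps$peptide) <= det$max_length, , drop = FALSE]
    covers <- vapply(seq_len(nrow(peps)), function(r)
      any(occupied >= peps$start[r] & occupied <= peps$end[r]), TRUE)
    peps <- peps[covers, , drop = FALSE]
    if (!nrow(peps)) next
    lambda <- copies[i] * det$spectra_per_copy
    for (r in seq_len(nrow(peps))) {
      p_det <- det$prob * det$missed_penalty[peps$missed[r] + 1L]
      if (runif(1) >= p_det) next
      spectra <- rpois(1, lambda)
      if (spectra < 1) next
      chars <- strsplit(peps$peptide[r], "", fixed = TRUE)[[1]]
      inpep <- occupied[occupied >= peps$start[r] & occupied <= peps$end[r]]
      chars[inpep - peps$start[r] + 1L] <- "D"
      psm_rows[[length(psm_rows) + 1L]] <- data.frame(
        peptide = paste(chars, collapse = ""),
        proteins = acc, spectra = spectra,
        probability = round(runif(1, probability_range[1],
                                  probability_range[2]), 4),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(psm_rows)) {
    stop("no peptides detected; increase abundance, detection probability ",
         "or spectra_per_copy")
  }
  tab <- do.call(rbind, psm_rows)
  psms <- psm_table(tab$peptide, as.list(tab$proteins), tab$spectra,
                    tab$probability)
  list(
    psms = psms,
    truth = list(
      abundance = data.frame(accession = prot$accession,
                             copies = unname(copies),
                             stringsAsFactors = FALSE),
      occupancy = do.call(rbind, occ_rows),
      seed = seed
    )
  )
}

#' Generate a cohort with a planted TM--glycan complementarity
#'
#' Per protein, a TM count is drawn uniformly from `tm_levels` and the planted
#' sequon count follows `base + slope * tm` plus Gaussian noise (floored at 1).
#' A negative slope plants the complementarity pattern in which heavily
#' glycosylated proteins have few membrane helices; slope 0 plants no
#' association. Background (incidental) sequons are suppressed so planted
#' counts are exact.
#'
#' @param n number of proteins.
#' @param slope change in planted sequon count per TM helix (<= 0 for the
#'   complementarity pattern).
#' @param seed integer seed.
#' @param base expected sequon count at zero TMs (default 9).
#' @param noise_sd Gaussian noise on the planted count (default 0.5).
#' @param tm_levels TM counts to sample from (default 0:8).
#' @return as [generate_proteome()]; `truth$proteins` carries the planted
#'   `tm_count` and `planted_sequons`.
#' @export
generate_complementarity_cohort <- function(n, slope, seed, base = 9,
                                            noise_sd = 0.5, tm_levels = 0:8) {
  set.seed(seed)
  tm <- sample(tm_levels, n, TRUE)
  sq <- pmax(1L, as.integer(round(base + slope * tm +
                                    rnorm(n, 0, noise_sd))))
  # derive a fresh sub-seed for sequence generation so set.seed inside
  # generate_proteome does not replay the draws above
  sub_seed <- (seed * 7919L + 13L) %% .Machine$integer.max
  generate_proteome(
    n_proteins = n, seed = sub_seed,
    class_mix = c(unclassified = 1),
    tm_counts = tm, sequon_counts = sq,
    background_sequons = FALSE,
    lengths = NULL,
    length_dist = list(meanlog = log(350), sdlog = 0.25,
                       min = 150L, max = 2500L)
  )
}
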