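#' Per-protein sequon occupancy
#'
#' The fraction of a protein's putative sequons that were observed glycosylated:
#' detected glycosites over total sequons. Vectorized.
#'
#' @param detected number of detected glycosites (0 <= detected <= sequons).
#' @param sequons number of putative sequons (>= 1).
#' @return fractions in \[0,1\].
#' @export
occupancy <- function(detected, sequons) {
  detected <- as.numeric(detected)
  sequons <- as.numeric(sequons)
  if (any(is.na(sequons) | sequons < 1)) {
    stop("sequon count must be >= 1")
  }
  if (any(is.na(detected) | detected < 0 | detected > sequons)) {
    stop("detected glycosites must satisfy 0 <= detected <= sequons")
  }
  detected / sequons
}

#' Set-level glycosylation rate
#'
#' The unweighted mean of per-protein sequon occupancies (not a pooled ratio
#' of sites): each protein contributes equally regardless of its sequon count.
#'
#' @param profiles a `glyco_profiles` table, or any data frame carrying either
#'   an `occupancy` column or `stoichiometry` + `sequon_count` columns.
#' @return mean occupancy in \[0,1\].
#' @export
set_glycosylation_rate <- function(profiles) {
  if (is.null(nrow(profiles)) || nrow(profiles) == 0L) {
    stop("empty profile set")
  }
  occ <- if (!is.null(profiles$occupancy)) {
    profiles$occupancy
  } else if (!is.null(profiles$stoichiometry) &&
             !is.null(profiles$sequon_count)) {
    occupancy(profiles$stoichiometry, profiles$sequon_count)
  } else {
    stop("profiles must carry occupancy or stoichiometry + sequon_count")
  }
  mean(occ)
}

#' Group glycoproteins by glycan stoichiometry
#'
#' Proteins are binned by their (rounded) number of detected glycans, with
#' stoichiometries above `k_max` pooled into the top bin. Each group reports
#' its size, mean protein spectral count, and -- over members with a TM
#' annotation -- the percentage split between low-TM (`< tm_high` helices) and
#' high-TM (`>= tm_high`) proteins, the complementarity statistic.
#'
#' @param profiles a `glyco_profiles` table.
#' @param k_max top stoichiometry bin (default 8; higher values pooled).
#' @param tm_high TM count at or above which a protein counts as high-TM
#'   (default 3, i.e. low is <= 2 TMs).
#' @return `data.frame` with columns `k`, `n`, `mean_protein_spectra`,
#'   `n_tm_annotated`, `pct_low_tm`, `pct_high_tm`.
#' @export
stoichiometry_groups <- function(profiles, k_max = 8L, tm_high = 3L) {
  if (nrow(profiles) == 0L) stop("empty profile set")
  k <- pmin(k_max, pmax(1L, as.integer(round(profiles$stoichiometry))))
  out <- lapply(sort(unique(k)), function(kk) {
    p <- profiles[k == kk, , drop = FALSE]
    tm <- p$tm_count[!is.na(p$tm_count)]
    data.frame(
      k = kk,
      n = nrow(p),
      mean_protein_spectra = mean(p$protein_spectra),
      n_tm_annotated = length(tm),
      pct_low_tm = if (length(tm)) 100 * mean(tm < tm_high) else NA_real_,
      pct_high_tm = if (length(tm)) 100 * mean(tm >= tm_high) else NA_real_
    )
  })
  do.call(rbind, out)
}

#' Predict transmembrane segments by hydropathy (TMHMM surrogate)
#'
#' A sliding-window Kyte--Doolittle average: every window of `window` residues
#' with mean hydropathy at or above `threshold` marks a candidate membrane
#' span; maximal runs of qualifying windows become segments, and segments
#' separated by fewer than `min_gap` residues are merged. This is a simple,
#' deterministic surrogate for an HMM-based predictor -- all TM-dependent
#' statistics also accept precomputed counts via `tm_counts` arguments.
#' Sequences shorter than one window yield zero segments. `X` scores -3.5
#' (hydrophilic).
#'
#' @param sequence amino-acid string.
#' @param window window length in residues (default 19, a typical helix span).
#' @param threshold mean-hydropathy cutoff (default 1.6).
#' @param min_gap minimum residue gap between distinct segments (default 5).
#' @return list with `count` (integer) and `segments` (`data.frame` of
#'   1-based inclusive `start`, `end`).
#' @export
predict_tm <- function(sequence, window = 19L, threshold = 1.6, min_gap = 5L) {
  s <- strsplit(toupper(as.character(sequence)), "", fixed = TRUE)[[1]]
  n <- length(s)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (n < window) return(list(count = 0L, segments = empty))
  h <- unname(KYTE_DOOLITTLE[s])
  h[is.na(h)] <- KYTE_DOOLITTLE[["X"]]
  csum <- c(0, cumsum(h))
  nw <- n - window + 1L
  wmean <- (csum[(window + 1L):(n + 1L)] - csum[1:nw]) / window
  above <- wmean >= threshold
  if (!any(above)) return(list(count = 0L, segments = empty))
  r <- rle(above)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  seg <- cbind(starts_idx[r$values], ends_idx[r$values] + window - 1L)
  # merge segments separated by < min_gap residues
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) {
    for (i in 2:nrow(seg)) {
      gap <- seg[i, 1] - merged[nrow(merged), 2] - 1L
      if (gap < min_gap) {
        merged[nrow(merged), 2] <- seg[i, 2]
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
  }
  list(count = nrow(merged),
       segments = data.frame(start = as.integer(merged[, 1]),
                             end = as.integer(merged[, 2])))
}

#' Predict TM counts for a whole proteome
#'
#' @param proteome a proteome `data.frame`.
#' @param ... passed to [predict_tm()].
#' @return named integer vector accession -> TM count.
#' @export
predict_tm_counts <- function(proteome, ...) {
  setNames(
    vapply(proteome$sequence, function(s) predict_tm(s, ...)$count, 0L,
           USE.NAMES = FALSE),
    proteome$accession
  )
}

#' Summarize glycoprotein profiles by functional class
#'
#' Per class: member count, mean detected glycans (stoichiometry), mean
#' sequons, mean TM count (over annotated members), glycosylation rate
#' (unweighted mean occupancy, see [set_glycosylation_rate()]) and mean
#' protein spectral count. Classes absent from the cohort are omitted.
#'
#' @param profiles a `glyco_profiles` table.
#' @param class_map optional named vector accession -> class overriding the
#'   `functional_class` column.
#' @return `data.frame` with one row per represented class.
#' @export
class_summary <- function(profiles, class_map = NULL) {
  if (nrow(profiles) == 0L) stop("empty profile set")
  cls <- if (!is.null(class_map)) {
    cl <- unname(class_map[profiles$accession])
    ifelse(is.na(cl), "unclassified", cl)
  } else {
    profiles$functional_class
  }
  out <- lapply(intersect(FUNCTIONAL_CLASSES, unique(cls)), function(cc) {
    p <- profiles[cls == cc, , drop = FALSE]
    tm <- p$tm_count[!is.na(p$tm_count)]
    data.frame(
      functional_class = cc,
      n = nrow(p),
      mean_glycans = mean(p$stoichiometry),
      mean_sequons = mean(p$sequon_count),
      mean_tms = if (length(tm)) mean(tm) else NA_real_,
      glycosylation_rate = set_glycosylation_rate(p),
      mean_protein_spectra = mean(p$protein_spectra),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Cross-species sequon/TM profiles over ortholog groups
#'
#' For each ortholog group member, sequon counts come from [scan_sequons()] on
#' the member's sequence and TM counts from [predict_tm()] (or supplied
#' annotations); results are averaged per species and functional class. The
#' class of a group is taken from the first member present in `class_map`.
#' Unresolvable accessions are excluded with a warning and counted.
#'
#' @param orthologs `data.frame` with `group_id`, `species`, `accession`.
#' @param proteomes named list, species -> proteome `data.frame`.
#' @param class_map named vector accession -> class (usually for the reference
#'   species).
#' @param tm_counts optional named vector accession -> TM count.
#' @param ... passed to [predict_tm()].
#' @return `data.frame` with `species`, `functional_class`, `n`,
#'   `mean_sequons`, `mean_tms`; attribute `n_unresolved`.
#' @export
cross_species_profile <- function(orthologs, proteomes, class_map = NULL,
                                  tm_counts = NULL, ...) {
  rows <- list()
  unresolved <- 0L
  for (g in unique(orthologs$group_id)) {
    grp <- orthologs[orthologs$group_id == g, , drop = FALSE]
    cls <- "unclassified"
    if (!is.null(class_map)) {
      hit <- grp$accession[grp$accession %in% names(class_map)]
      if (length(hit)) cls <- unname(class_map[hit[1]])
    }
    for (r in seq_len(nrow(grp))) {
      sp <- grp$species[r]
      acc <- grp$accession[r]
      prot <- proteomes[[sp]]
      idx <- if (is.null(prot)) NA_integer_ else match(acc, prot$accession)
      if (is.na(idx)) {
        unresolved <- unresolved + 1L
        warning("unresolvable accession ", acc, " (", sp, "); excluded")
        next
      }
      seqn <- prot$sequence[idx]
      tm <- if (!is.null(tm_counts) && acc %in% names(tm_counts)) {
        unname(tm_counts[acc])
      } else {
        predict_tm(seqn, ...)$count
      }
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, functional_class = cls,
        sequons = nrow(scan_sequons(seqn)), tms = tm,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) stop("no resolvable ortholog entries")
  tab <- do.call(rbind, rows)
  out <- aggregate(cbind(sequons, tms) ~ species + functional_class, tab, mean)
  cnt <- aggregate(sequons ~ species + functional_class, tab, length)
  out <- data.frame(species = out$species,
                    functional_class = out$functional_class,
                    n = cnt$sequons,
                    mean_sequons = out$sequons,
                    mean_tms = out$tms,
                    stringsAsFactors = FALSE)
  attr(out, "n_unresolved") <- unresolved
  out
}
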