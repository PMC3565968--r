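test_that("occupancy is detected/sequons with validated domain", {
  expect_equal(occupancy(1, 4), 0.25)
  expect_equal(occupancy(4, 4), 1.0)
  expect_equal(occupancy(0, 5), 0)
  expect_error(occupancy(5, 4), "detected")
  expect_error(occupancy(0, 0), "sequon")
})

test_that("set glycosylation rate is the unweighted mean over proteins", {
  gz <- glycoenzyme_table()
  tr <- gz[gz$family == "transferase", ]
  hy <- gz[gz$family == "hydrolase", ]
  rate_tr <- set_glycosylation_rate(
    data.frame(stoichiometry = tr$detected_glycosites,
               sequon_count = tr$putative_glycosites))
  expect_equal(round(100 * rate_tr, 1), 28.1)
  # the hydrolase companion value: unweighted mean of the 14 row ratios
  rate_hy <- set_glycosylation_rate(
    data.frame(stoichiometry = hy$detected_glycosites,
               sequon_count = hy$putative_glycosites))
  expect_equal(round(100 * rate_hy, 1), 58.1)
  # single protein: its own occupancy
  expect_equal(set_glycosylation_rate(data.frame(occupancy = 0.3)), 0.3)
  expect_error(set_glycosylation_rate(data.frame(occupancy = numeric(0))),
               "empty")
})

test_that("stoichiometry groups bin, pool and split by TM count", {
  prof <- data.frame(
    accession = paste0("P", 1:6),
    stoichiometry = c(1, 1, 2, 9, 12, 3),
    protein_spectra = c(2, 4, 6, 8, 10, 12),
    tm_count = c(0L, 2L, 3L, 7L, 1L, NA)
  )
  g <- stoichiometry_groups(prof)
  expect_equal(g$k, c(1, 2, 3, 8))
  expect_equal(g$n, c(2, 1, 1, 2))           # 9 and 12 pooled into k=8
  expect_equal(g$mean_protein_spectra[1], 3)
  expect_equal(g$pct_low_tm[1], 100)
  expect_equal(g$pct_high_tm[2], 100)
  expect_true(is.na(g$pct_high_tm[g$k == 3])) # only an unannotated member
  expect_equal(g$pct_low_tm[g$k == 8], 50)
  # percentages always complement on annotated members
  ann <- !is.na(g$pct_low_tm)
  expect_equal(g$pct_low_tm[ann] + g$pct_high_tm[ann], rep(100, sum(ann)))
  # cohort where every protein has one glycan: a single group with everyone
  g1 <- stoichiometry_groups(data.frame(accession = "x",
                                        stoichiometry = c(1, 1, 1),
                                        protein_spectra = 1,
                                        tm_count = NA_integer_))
  expect_equal(nrow(g1), 1L)
  expect_equal(g1$n, 3L)
})

test_that("hydropathy TM prediction finds planted helices", {
  # 30-residue poly-leucine flanked by poly-serine: one segment
  one <- paste0(strrep("S", 25), strrep("L", 30), strrep("S", 25))
  p1 <- predict_tm(one)
  expect_equal(p1$count, 1L)
  # the detected segment covers the hydrophobic core
  expect_lte(p1$segments$start, 30)
  expect_gte(p1$segments$end, 51)

  # poly-glycine: hydropathy below threshold everywhere
  expect_equal(predict_tm(strrep("G", 200))$count, 0L)

  # two 25-leucine stretches separated by 40 serines: two segments
  two <- paste0(strrep("S", 20), strrep("L", 25), strrep("S", 40),
                strrep("L", 25), strrep("S", 20))
  expect_equal(predict_tm(two)$count, 2L)

  # shorter than one window: no prediction
  expect_equal(predict_tm("LLLLL")$count, 0L)
})

test_that("predict_tm is deterministic and position-covariant", {
  s <- paste0(strrep("S", 20), strrep("L", 25), strrep("S", 20))
  a <- predict_tm(s)
  b <- predict_tm(paste0(strrep("D", 17), s))  # prepend hydrophilic residues
  expect_equal(a$count, b$count)
  expect_equal(b$segments$start - a$segments$start, 17L)
  expect_equal(predict_tm(s), predict_tm(s))
})

test_that("class summaries reproduce the glyco-enzyme reference values", {
  gz <- glycoenzyme_table()
  prof <- data.frame(
    accession = gz$symbol,
    stoichiometry = gz$detected_glycosites,
    sequon_count = gz$putative_glycosites,
    occupancy = gz$detected_glycosites / gz$putative_glycosites,
    protein_spectra = gz$protein_spectra,
    tm_count = gz$tms,
    functional_class = ifelse(gz$family == "transferase", "enzyme",
                              "miscellaneous")
  )
  cs <- class_summary(prof)
  tr <- cs[cs$functional_class == "enzyme", ]
  expect_equal(tr$n, 9L)
  expect_equal(tr$mean_tms, 15 / 9)            # Table of 9 transferases
  expect_equal(tr$mean_glycans, 1)             # all monoglycosylated
  expect_equal(round(tr$glycosylation_rate, 4), 0.2809)
  hy <- cs[cs$functional_class == "miscellaneous", ]
  expect_equal(hy$mean_sequons, 4.5)           # 14 hydrolases
  # classes absent from the cohort are omitted
  expect_false("receptor" %in% cs$functional_class)

  # pooled consistency: class means recombine to whole-cohort means
  expect_equal(sum(cs$n * cs$glycosylation_rate) / sum(cs$n),
               set_glycosylation_rate(prof))
  expect_equal(sum(cs$n * cs$mean_sequons) / sum(cs$n),
               mean(prof$sequon_count))
})

test_that("cross-species profiles are invariant for identical sequences", {
  seqs <- c(paste0("MK", strrep("A", 5), "NATAAANGSAAR"))
  prots <- list(
    mouse = proteome("m1", seqs),
    human = proteome("h1", seqs),
    fish = proteome("f1", seqs)
  )
  orth <- data.frame(group_id = 1,
                     species = c("mouse", "human", "fish"),
                     accession = c("m1", "h1", "f1"))
  prof <- cross_species_profile(orth, prots,
                                class_map = c(m1 = "receptor"))
  expect_equal(length(unique(prof$mean_sequons)), 1L)
  expect_equal(length(unique(prof$mean_tms)), 1L)
  expect_true(all(prof$functional_class == "receptor"))
})

test_that("cross-species profiles preserve a planted receptor/transporter pattern", {
  # receptors: many sequons, no TM; transporters: few sequons, two TMs --
  # the same planted contrast in each of three species (glycine filler: its
  # hydropathy sits safely below the TM threshold, unlike alanine)
  receptor_seq <- function() paste0("MK", strrep("NATGG", 6), strrep("G", 30), "R")
  transporter_seq <- function() paste0(
    "MK", "NATGG", strrep("G", 10), strrep("L", 21), strrep("G", 30),
    strrep("L", 21), strrep("G", 10), "R")
  species <- c("mouse", "human", "worm")
  prots <- setNames(lapply(species, function(sp) {
    proteome(paste0(sp, c("_r", "_t")), c(receptor_seq(), transporter_seq()))
  }), species)
  orth <- rbind(
    data.frame(group_id = "r", species = species,
               accession = paste0(species, "_r")),
    data.frame(group_id = "t", species = species,
               accession = paste0(species, "_t"))
  )
  cmap <- c(mouse_r = "receptor", mouse_t = "transporter")
  prof <- cross_species_profile(orth, prots, class_map = cmap)
  for (sp in species) {
    r <- prof[prof$species == sp & prof$functional_class == "receptor", ]
    t <- prof[prof$species == sp & prof$functional_class == "transporter", ]
    expect_gt(r$mean_sequons, t$mean_sequons)
    expect_gt(t$mean_tms, r$mean_tms)
  }
  # unresolvable accessions: warning + exclusion, counted
  orth2 <- rbind(orth, data.frame(group_id = "r", species = "mouse",
                                  accession = "ghost"))
  expect_warning(prof2 <- cross_species_profile(orth2, prots,
                                                class_map = cmap), "ghost")
  expect_equal(attr(prof2, "n_unresolved"), 1L)
})
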