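test_that("locate_peptide tolerates D only at sequon asparagines", {
  p <- proteome("P1", "MKLNGSAK")  # sequon at position 4 (NGS)
  loc <- locate_peptide("LDGSAK", p)
  expect_equal(loc$accession, "P1")
  expect_equal(loc$start, 3L)
  expect_equal(loc$glycosites[[1]], 4L)

  # exact match without deamidation: located, no glycosite evidence
  loc2 <- locate_peptide("LNGSAK", p)
  expect_equal(loc2$start, 3L)
  expect_equal(length(loc2$glycosites[[1]]), 0L)

  # D aligned to a non-sequon N never matches
  p2 <- proteome("P2", "MKLNAAAK")  # N4 is not a sequon
  expect_equal(nrow(locate_peptide("LDAAAK", p2)), 0L)

  # peptide absent anywhere: empty result, not an error
  expect_equal(nrow(locate_peptide("WWWWW", p)), 0L)
})

test_that("assign_glycosites calls sites, flags ambiguity, conserves spectra", {
  prot <- toy_proteome()
  psms <- toy_psms()
  asg <- assign_glycosites(psms, prot)
  tally <- attr(asg, "tally")

  # PSM1: unambiguous site 4 with 3 spectra, full credit
  a1 <- asg[asg$psm_id == 1, ]
  expect_equal(a1$position, 4L)
  expect_equal(a1$spectra, 3)
  expect_equal(a1$credit, 1)
  expect_false(a1$ambiguous)
  expect_equal(a1$motif, "NGS")

  # PSM2 spans two sequons: both emitted, ambiguous, fractional credit
  a2 <- asg[asg$psm_id == 2, ]
  expect_equal(sort(a2$position), c(4L, 9L))
  expect_true(all(a2$ambiguous))
  expect_equal(a2$credit, c(0.5, 0.5))

  # fates: sequon-free and non-deamidated PSMs are dropped and tallied
  expect_equal(unname(tally[c("assigned", "no_sequon", "no_deamidation")]),
               c(4, 1, 1))
  st <- attr(asg, "spectra_tally")
  expect_equal(st[["psms_in"]],
               sum(st[c("assigned", "no_sequon", "no_deamidation",
                        "unmatched")]))

  # every emitted site satisfies the sequon rule on the parent protein
  for (r in seq_len(nrow(asg))) {
    sq <- scan_sequons(prot$sequence[match(asg$accession[r], prot$accession)])
    expect_true(asg$position[r] %in% sq$position)
  }
})

test_that("crediting rules: first and all", {
  prot <- toy_proteome()
  psms <- toy_psms()[2, ]  # the ambiguous two-sequon peptide
  first <- assign_glycosites(psms, prot, credit = "first")
  expect_equal(first$credit[order(first$position)], c(1, 0))
  all_r <- assign_glycosites(psms, prot, credit = "all")
  expect_equal(all_r$credit, c(1, 1))
})

test_that("unknown accessions are reported", {
  expect_error(
    assign_glycosites(psm_table("LDGSAK", list("GHOST"), 1, 1),
                      toy_proteome()),
    "GHOST")
})

test_that("on synthetic data no false sites are called and recall is complete", {
  sim <- generate_proteome(30, seed = 31)
  sp <- simulate_psms(sim, seed = 32,
                      occupancy = list(rate = 0.5),
                      detection = list(prob = 1, missed_penalty = c(1, 1, 1)))
  asg <- assign_glycosites(sp$psms, sim$proteome)
  occ <- sp$truth$occupancy
  occupied <- paste(occ$accession, occ$position)[occ$occupied]

  # soundness: every deamidation-evidenced site is truth-occupied (no leakage)
  called <- unique(paste(asg$accession, asg$position)[asg$deamidated])
  expect_true(all(called %in% occupied))

  # completeness for unambiguous single-sequon peptides: site-level recall 1
  unamb <- asg[!asg$ambiguous, ]
  expect_true(all(unamb$deamidated))

  # spectra conservation through the mapping
  st <- attr(asg, "spectra_tally")
  expect_equal(st[["psms_in"]], sum(sp$psms$spectra))
  expect_equal(st[["psms_in"]],
               sum(st[c("assigned", "no_sequon", "no_deamidation",
                        "unmatched")]))
})

test_that("ambiguity_rate uses the chosen denominator", {
  prot <- toy_proteome()
  asg <- assign_glycosites(toy_psms(), prot)
  # distinct peptides with assignments: LDGSAK, LDGSAKDATR, DDTAAAR -> 1 of 3
  expect_equal(ambiguity_rate(asg), 1 / 3)
  # PSM denominator: psms 1,2,3,6 carry assignments -> 1 of 4
  expect_equal(ambiguity_rate(asg, "psm"), 1 / 4)
  expect_error(ambiguity_rate(asg[0, ]), "no assignments")
})

test_that("multi-sequon peptide frequency is recovered", {
  # a cohort where a planted 40% of tryptic peptides span two sequons; the
  # random flanks occasionally add incidental sequons, so the exact expected
  # ambiguity rate comes from the exhaustive window oracle per peptide
  set.seed(301)
  safe_flank <- function(n) {  # flank free of K/R/P so each core is one peptide
    paste(sample(setdiff(nglyco:::AA_STANDARD, c("K", "R", "P")), n, TRUE),
          collapse = "")
  }
  n_two <- 40; n_one <- 60
  cores <- c(
    replicate(n_two, paste0(safe_flank(3), "NAT", safe_flank(2), "NGSA",
                            safe_flank(3))),
    replicate(n_one, paste0(safe_flank(6), "NAT", safe_flank(6)))
  )
  seqs <- paste0("MK", cores, "R")
  prot <- proteome(paste0("Q", seq_along(seqs)), seqs)
  peps <- sub("NAT", "DAT", paste0(cores, "R"), fixed = TRUE)
  psms <- psm_table(peps, as.list(prot$accession), rep(1, length(peps)))
  asg <- assign_glycosites(psms, prot)
  rate <- ambiguity_rate(asg)
  n_sequons <- vapply(cores, function(cc)
    length(oracle_scan_sequons(paste0(cc, "R"))), 1L, USE.NAMES = FALSE)
  expected <- mean(n_sequons >= 2)
  expect_equal(rate, expected)
  # and the realized frequency sits inside a 3-sigma binomial band of the
  # planted 40%
  expect_lt(abs(expected - 0.4), 3 * sqrt(0.4 * 0.6 / length(peps)))
})

test_that("filter_identifications thresholds, groups and drops single hits", {
  psms <- psm_table(
    peptide = c("LDGSAK", "LDGSAK", "DATRAK", "WWWWWK"),
    proteins = list(c("P1", "P2"), c("P1", "P2"), "P3", "P4"),
    spectra = c(3, 2, 1, 2),
    probability = c(0.99, 0.85, 0.95, 0.95)
  )
  res <- filter_identifications(psms, min_probability = 0.9,
                                remove_single_hits = TRUE)
  expect_equal(res$tally[["below_probability"]], 1)
  # P1 and P2 share an identical peptide set -> one group, first accession wins
  g12 <- res$groups[vapply(res$groups$members, function(m) "P2" %in% m, TRUE), ]
  expect_equal(g12$representative, "P1")
  expect_equal(g12$members[[1]], c("P1", "P2"))
  # P3 has a single 1-spectrum peptide -> removed under the single-hit rule
  g3 <- res$groups[res$groups$representative == "P3", ]
  expect_false(g3$kept)
  expect_setequal(res$representatives, c("P1", "P4"))
  expect_error(filter_identifications(psms, min_probability = 1.1), "0,1")
})
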