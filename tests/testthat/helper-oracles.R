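# Independent oracles and shared fixtures. These stay deliberately naive so
# they cannot share a bug with the implementation they check.

# Exhaustive window scan: every length-3 window tested against the raw rule.
oracle_scan_sequons <- function(sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  hits <- integer(0)
  if (length(s) >= 3) {
    for (i in 1:(length(s) - 2)) {
      w <- s[i:(i + 2)]
      if (w[1] == "N" && w[2] != "P" && (w[3] == "S" || w[3] == "T")) {
        hits <- c(hits, i)
      }
    }
  }
  hits
}

# Exhaustive tryptic digestion: test every substring against the rule.
oracle_tryptic <- function(sequence, max_missed) {
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  is_cut <- function(i) {  # cleavage boundary after residue i
    i >= 1 && i < n && s[i] %in% c("K", "R") && s[i + 1] != "P"
  }
  out <- list()
  for (i in 1:n) for (j in i:n) {
    start_ok <- i == 1 || is_cut(i - 1)
    end_ok <- j == n || is_cut(j)
    if (!start_ok || !end_ok) next
    internal <- sum(vapply(i:(j - 1), is_cut, TRUE)[seq_len(max(0, j - i))])
    if (internal <= max_missed) {
      out[[length(out) + 1]] <- c(i, j, internal)
    }
  }
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of the
# background and count those with >= x in-term members. Feasible for N <= 12.
oracle_hypergeom_tail <- function(N, K, n, x) {
  subsets <- utils::combn(N, n)
  in_term <- seq_len(K)  # wlog the first K elements carry the term
  hits <- apply(subsets, 2, function(ss) sum(ss %in% in_term))
  mean(hits >= x)
}

random_aa_sequence <- function(len, alphabet = nglyco:::AA_STANDARD) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Hand-computable 3-protein fixture used across mapping/quantify/pipeline
# tests. Sequon positions: TOY1 "MKLNGSAKNATR" has sequons at 4 (NGS) and
# 9 (NAT); TOY2 "MMKNDTAAAR" a sequon at 4 (NDT); TOY3 "MKAAAAAR" none.
toy_proteome <- function() {
  proteome(
    accession = c("TOY1", "TOY2", "TOY3"),
    sequence = c("MKLNGSAKNATR", "MMKNDTAAAR", "MKAAAAAR"),
    description = c("two sequons", "one sequon", "no sequon")
  )
}

toy_psms <- function() {
  psm_table(
    peptide = c(
      "LDGSAK",     # TOY1 site 4, deamidated, unambiguous (span 3-8 holds one sequon)
      "LDGSAKDATR", # TOY1 1-missed peptide spanning both sequons, both deamidated
      "DDTAAAR",    # TOY2 site 4 deamidated
      "NDTAAAR",    # TOY2 same peptide without deamidation
      "AAAAAR",     # TOY3 sequon-free
      "LDGSAK"      # duplicate peptide, second run
    ),
    proteins = list("TOY1", "TOY1", "TOY2", "TOY2", "TOY3", "TOY1"),
    spectra = c(3, 2, 4, 1, 5, 1),
    probability = c(0.99, 0.95, 0.98, 0.97, 0.99, 0.85)
  )
}
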