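#' Overlap statistics for two or three accession sets
#'
#' Identifiers are normalized (case-insensitive, whitespace-stripped) and
#' de-duplicated. Reports exact intersection counts for every region of the
#' Venn diagram, asymmetric overlap percentages (percentage of A found in B =
#' |A n B| / |A| x 100), and pairwise Jaccard indices.
#'
#' @param sets named list of 2 or 3 non-empty character vectors.
#' @return list with `sizes`, `intersections` (named counts, including the
#'   triple intersection for 3 sets), `pct` (matrix, row set in column set)
#'   and `jaccard` (symmetric matrix).
#' @export
overlap_stats <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L) {
    stop("sets must be a named list of 2 or 3 accession vectors")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- LETTERS[seq_along(sets)]
  }
  sets <- lapply(sets, function(x) unique(tolower(trimws(as.character(x)))))
  if (any(vapply(sets, length, 1L) == 0L)) stop("empty set after normalization")
  nm <- names(sets)
  k <- length(sets)
  pairs <- utils::combn(k, 2)
  inter <- numeric(0)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    inter[paste(nm[a], nm[b], sep = "&")] <-
      length(intersect(sets[[a]], sets[[b]]))
  }
  if (k == 3L) {
    inter[paste(nm, collapse = "&")] <-
      length(Reduce(intersect, sets))
  }
  pct <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  jac <- matrix(1, k, k, dimnames = list(nm, nm))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a == b) { pct[a, b] <- 100; next }
    i <- length(intersect(sets[[a]], sets[[b]]))
    u <- length(union(sets[[a]], sets[[b]]))
    pct[a, b] <- 100 * i / length(sets[[a]])
    jac[a, b] <- i / u
  }
  list(sizes = vapply(sets, length, 1L), intersections = inter,
       pct = pct, jaccard = jac)
}

#' Hypergeometric annotation enrichment
#'
#' For each annotation term, the upper-tail hypergeometric probability of
#' observing at least the query's term count given the background composition
#' (Fisher's exact test, one-sided), with Benjamini--Hochberg adjustment
#' across terms and -log10(p) for heatmap display. Terms with zero query hits
#' get fold 0 and p = 1.
#'
#' @param query character vector of query accessions (must be a subset of the
#'   background after normalization).
#' @param annotations `data.frame` with columns `accession`, `term`.
#' @param background character vector of background accessions.
#' @return `data.frame` with columns `term`, `query_hits`, `background_hits`,
#'   `query_size`, `background_size`, `fold`, `p`, `q`, `minus_log10_p`,
#'   sorted by `p`.
#' @export
hypergeom_enrichment <- function(query, annotations, background) {
  norm <- function(x) unique(tolower(trimws(as.character(x))))
  query <- norm(query)
  background <- norm(background)
  if (!length(query) || !length(background)) stop("empty query or background")
  extra <- setdiff(query, background)
  if (length(extra)) {
    stop("query accessions not in background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  miss <- setdiff(c("accession", "term"), names(annotations))
  if (length(miss)) {
    stop("annotations missing column(s): ", paste(miss, collapse = ", "))
  }
  ann_acc <- tolower(trimws(annotations$accession))
  keep <- ann_acc %in% background
  terms <- split(ann_acc[keep], annotations$term[keep])
  N <- length(background)
  n <- length(query)
  out <- lapply(names(terms), function(tm) {
    in_term <- unique(terms[[tm]])
    K <- length(in_term)
    x <- length(intersect(query, in_term))
    p <- phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, query_hits = x, background_hits = K,
               query_size = n, background_size = N,
               fold = if (x == 0) 0 else (x / n) / (K / N),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$q <- p.adjust(out$p, method = "BH")
  out$minus_log10_p <- -log10(out$p)
  out[order(out$p, out$term), , drop = FALSE]
}
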