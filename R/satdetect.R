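# Satellite detection: self-dot-plots, tandem periodicity, and the
# cluster classifier (circular consensus closure + read-mapping fraction).

#' Self (or pairwise) dot plot of DNA sequences
#'
#' A hit is recorded at (i, j) when the `window`-bp windows starting at i in
#' `sequence_a` and j in `sequence_b` match with at least `stringency_pct`
#' identity (ungapped, position-wise). Computed lag by lag with rolling match
#' sums, so the full matrix costs O(n^2) bit operations rather than
#' O(n^2 window).
#'
#' @param sequence_a,sequence_b DNA strings; `sequence_b` defaults to
#'   `sequence_a` (self-plot).
#' @param window Window length in bp (>= 4).
#' @param stringency_pct Minimum window identity in percent.
#' @return A `dot_plot` object: tibble `hits` with columns `i`, `j` (1-based
#'   window starts) plus parameters; self-plots are symmetric and their main
#'   diagonal is always fully hit.
#' @export
self_dotplot <- function(sequence_a, sequence_b = sequence_a, window = 15,
                         stringency_pct = 60) {
  if (window < 4) stop("window < 4 rejected")
  a <- seq_chars(sequence_a); b <- seq_chars(sequence_b)
  na <- length(a); nb <- length(b)
  if (window > min(na, nb)) stop("window exceeds sequence length")
  need <- ceiling(window * stringency_pct / 100 - 1e-9)
  wa <- na - window + 1L; wb <- nb - window + 1L
  hi <- integer(0); hj <- integer(0)
  for (lag in (-(wa - 1L)):(wb - 1L)) {
    # compare a[i] with b[i + lag]
    i0 <- max(1L, 1L - lag); i1 <- min(na, nb - lag)
    if (i1 - i0 + 1L < window) next
    m <- as.integer(a[i0:i1] == b[(i0:i1) + lag])
    cs <- c(0L, cumsum(m))
    wsum <- cs[(window + 1L):length(cs)] - cs[seq_len(length(cs) - window)]
    ok <- which(wsum >= need)
    if (length(ok) > 0) {
      ii <- i0 + ok - 1L
      hi <- c(hi, ii); hj <- c(hj, ii + lag)
    }
  }
  structure(list(hits = tibble::tibble(i = hi, j = hj),
                 window = window, stringency_pct = stringency_pct,
                 n_a = na, n_b = nb,
                 self = identical(sequence_a, sequence_b)),
            class = "dot_plot")
}

#' @export
print.dot_plot <- function(x, ...) {
  cat("<dot_plot> ", x$n_a, " x ", x$n_b, " bp, window ", x$window,
      " bp @ ", x$stringency_pct, "% : ", nrow(x$hits), " hits\n", sep = "")
  invisible(x)
}

#' Detect tandem periods from self-dot-plot lag histograms
#'
#' The support of a lag d is the fraction of valid window offsets whose
#' d-shifted window matches at the given stringency -- a column of the
#' off-diagonal hit histogram. The primary period is the smallest lag whose
#' support reaches `support_floor` at the high stringency (for a tandem array
#' this equals the monomer length); secondary sub-repeat periods are lags
#' below the primary that reach the floor only at the low stringency,
#' capturing degenerate internal structure.
#'
#' @param sequence DNA string (a monomer concatenated >= 3x, an array, or
#'   concatenated reads).
#' @param window Window length in bp.
#' @param low_stringency_pct,high_stringency_pct The two dot-plot
#'   stringencies.
#' @param support_floor Minimum support for a lag to be reported.
#' @return A `subrepeat_structure` object: tibble `periods` (`lag`,
#'   `support`, `level` = "primary"/"secondary"), `primary_period` (NA when
#'   no lag reaches the floor).
#' @export
detect_periods <- function(sequence, window = 15, low_stringency_pct = 60,
                           high_stringency_pct = 85, support_floor = 0.5) {
  s <- seq_chars(sequence)
  n <- length(s)
  sup <- function(stringency) {
    need <- ceiling(window * stringency / 100 - 1e-9)
    vapply(seq_len(n - window), function(lag) {
      span <- n - lag
      if (span < window) return(NA_real_)
      m <- as.integer(s[1:span] == s[(1:span) + lag])
      cs <- c(0L, cumsum(m))
      wsum <- cs[(window + 1L):length(cs)] - cs[seq_len(length(cs) - window)]
      mean(wsum >= need)
    }, numeric(1))
  }
  hi <- sup(high_stringency_pct)
  lags <- seq_len(n - window)
  cand_hi <- lags[!is.na(hi) & hi >= support_floor]
  primary <- if (length(cand_hi) > 0) cand_hi[1] else NA_integer_
  lo <- sup(low_stringency_pct)
  cand_lo <- lags[!is.na(lo) & lo >= support_floor]
  secondary <- if (!is.na(primary)) setdiff(cand_lo[cand_lo < primary], cand_hi) else integer(0)
  periods <- dplyr::bind_rows(
    if (!is.na(primary)) {
      tibble::tibble(lag = cand_hi, support = hi[cand_hi], level = "primary")
    },
    if (length(secondary) > 0) {
      tibble::tibble(lag = secondary, support = lo[secondary], level = "secondary")
    }
  )
  if (is.null(periods)) {
    periods <- tibble::tibble(lag = integer(0), support = numeric(0),
                              level = character(0))
  }
  structure(list(periods = periods, primary_period = primary,
                 window = window,
                 low_stringency_pct = low_stringency_pct,
                 high_stringency_pct = high_stringency_pct,
                 support_floor = support_floor),
            class = "subrepeat_structure")
}

#' @export
print.subrepeat_structure <- function(x, ...) {
  cat("<subrepeat_structure> primary period: ",
      if (is.na(x$primary_period)) "none" else paste0(x$primary_period, " bp"),
      "; ", nrow(x$periods), " supported lag(s)\n", sep = "")
  invisible(x)
}

#' Classify one read cluster as satellite or not
#'
#' A cluster is called a satellite when (a) the greedy k-mer walk over its
#' reads closes into a circular consensus, and (b) at least
#' `satellite_mapping_fraction` of its reads align back to the (doubled)
#' circular consensus at `min_identity_pct` identity over at least half the
#' read. Clusters below `min_size` reads are left unclassified. Graph density
#' is carried along as auxiliary evidence but is not decisive.
#'
#' @param cluster_reads `read_set` rows belonging to the cluster.
#' @param k k-mer length for the consensus walk.
#' @param min_identity_pct Identity threshold for read-to-consensus mapping.
#' @param satellite_mapping_fraction Minimum mapped read fraction.
#' @param min_size Minimum cluster size to attempt classification.
#' @param graph_density Optional density of the cluster's subgraph (reported,
#'   not used in the decision).
#' @return A one-row `satellite_call` tibble: `is_satellite`,
#'   `consensus_closed`, `monomer_length`, `mapped_fraction`, `graph_density`,
#'   `classification`; the consensus itself is in attribute `"monomer"`.
#' @export
classify_cluster <- function(cluster_reads, k = 25, min_identity_pct = 90,
                             satellite_mapping_fraction = 0.80, min_size = 10,
                             graph_density = NA_real_) {
  seqs <- if (is.data.frame(cluster_reads)) cluster_reads$sequence else cluster_reads
  n <- length(seqs)
  if (n < min_size) {
    out <- tibble::tibble(is_satellite = NA, consensus_closed = NA,
                          monomer_length = NA_integer_,
                          mapped_fraction = NA_real_,
                          graph_density = graph_density,
                          classification = "unclassified")
    class(out) <- c("satellite_call", class(out))
    return(out)
  }
  usable <- seqs[nchar(seqs) >= k]
  mono <- if (length(usable) > 0) {
    walk_consensus(suppressWarnings(count_kmers(usable, k = k)))
  } else NULL
  closed <- !is.null(mono) && mono$closed && mono$length > k
  mapped_frac <- NA_real_
  if (closed) {
    mapped_frac <- mapped_fraction(seqs, mono$sequence, min_identity_pct)
  }
  is_sat <- isTRUE(closed) && isTRUE(mapped_frac >= satellite_mapping_fraction)
  out <- tibble::tibble(
    is_satellite = is_sat,
    consensus_closed = closed,
    monomer_length = if (closed) mono$length else NA_integer_,
    mapped_fraction = mapped_frac,
    graph_density = graph_density,
    classification = if (is_sat) "satellite" else "dispersed"
  )
  attr(out, "monomer") <- mono
  class(out) <- c("satellite_call", class(out))
  out
}

# fraction of reads whose better-strand local alignment to the doubled
# circular consensus reaches the identity threshold over >= half the read
mapped_fraction <- function(seqs, monomer, min_identity_pct) {
  L <- nchar(monomer)
  n_rep <- max(2L, ceiling(max(nchar(seqs)) / L) + 1L)
  subject <- Biostrings::DNAString(paste(rep(monomer, n_rep), collapse = ""))
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  dna <- Biostrings::DNAStringSet(seqs)
  fwd <- Biostrings::pairwiseAlignment(dna, subject, type = "local",
                                       substitutionMatrix = sub_mat,
                                       gapOpening = 2, gapExtension = 1)
  rev <- Biostrings::pairwiseAlignment(Biostrings::reverseComplement(dna),
                                       subject, type = "local",
                                       substitutionMatrix = sub_mat,
                                       gapOpening = 2, gapExtension = 1)
  use_fwd <- Biostrings::score(fwd) >= Biostrings::score(rev)
  len <- ifelse(use_fwd, Biostrings::nchar(fwd), Biostrings::nchar(rev))
  nm <- ifelse(use_fwd, Biostrings::nmatch(fwd), Biostrings::nmatch(rev))
  ident <- ifelse(len > 0, 100 * nm / len, 0)
  mean(ident >= min_identity_pct & len >= 0.5 * nchar(seqs))
}

#' Classify every cluster in a cluster set
#'
#' Runs [classify_cluster()] on each cluster and fills the `classification`
#' column; consensus monomers for satellite calls are attached as the
#' `"monomers"` attribute (named by cluster id).
#'
#' @param clusters A `cluster_set` from [cluster_graph()].
#' @param reads The `read_set` the clusters were built from.
#' @inheritParams classify_cluster
#' @return The `cluster_set` with `classification` filled, plus columns
#'   `consensus_closed`, `monomer_length`, `mapped_fraction`.
#' @export
classify_clusters <- function(clusters, reads, k = 25, min_identity_pct = 90,
                              satellite_mapping_fraction = 0.80, min_size = 10) {
  calls <- lapply(seq_len(nrow(clusters)), function(i) {
    member <- reads[reads$id %in% clusters$read_ids[[i]], , drop = FALSE]
    classify_cluster(member, k = k, min_identity_pct = min_identity_pct,
                     satellite_mapping_fraction = satellite_mapping_fraction,
                     min_size = min_size,
                     graph_density = clusters$graph_density[i])
  })
  out <- clusters
  out$classification <- vapply(calls, function(x) x$classification, character(1))
  out$consensus_closed <- vapply(calls, function(x) x$consensus_closed, NA)
  out$monomer_length <- vapply(calls, function(x) x$monomer_length, NA_integer_)
  out$mapped_fraction <- vapply(calls, function(x) x$mapped_fraction, NA_real_)
  monos <- lapply(calls, attr, "monomer")
  names(monos) <- clusters$cluster_id
  attr(out, "monomers") <- monos
  attr(out, "total_reads") <- attr(clusters, "total_reads")
  class(out) <- unique(c("cluster_set", class(out)))
  out
}
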