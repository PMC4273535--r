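# Monomer annotation: GC content, telomeric and other motifs in circular
# coordinates, IUPAC restriction-site scanning, and in-silico digestion
# ladders including methylation sensitivity.

TELOMERE_MOTIF <- "TTAGGG"

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Restriction enzymes known to the digestion model
#'
#' `BstNI` (CCWGG, methylation-insensitive) and `ScrFI` (CCNGG, blocked by
#' internal cytosine methylation) recognise nearly the same site, which is
#' what makes their ladder contrast a methylation assay. Both sites are
#' IUPAC palindromes, so top-strand scanning finds every site.
#'
#' @return Tibble: `enzyme`, `site`, `methylation_sensitive`, `cut_offset`.
#' @export
restriction_enzymes <- function() {
  tibble::tibble(
    enzyme = c("BstNI", "ScrFI"),
    site = c("CCWGG", "CCNGG"),
    methylation_sensitive = c(FALSE, TRUE),
    cut_offset = c(2L, 2L)
  )
}

#' Find IUPAC pattern matches in a sequence
#'
#' Reports all (overlapping) match start positions of an IUPAC-coded pattern;
#' matches of the reverse-complement pattern are reported on top-strand
#' coordinates with `strand == "-"` (collapsed to one row when the pattern is
#' its own reverse complement).
#'
#' @param sequence DNA string.
#' @param pattern IUPAC pattern (e.g. "CCWGG").
#' @param both_strands Also scan the reverse-complement pattern.
#' @param circular Treat the sequence as circular (start positions in
#'   `[1, L]`, matches may wrap).
#' @return Tibble: `start` (1-based), `strand`.
#' @export
iupac_sites <- function(sequence, pattern, both_strands = TRUE,
                        circular = FALSE) {
  pat <- seq_chars(pattern)
  if (!all(pat %in% names(IUPAC_SETS))) {
    stop("invalid IUPAC letter in pattern: ",
         paste(setdiff(pat, names(IUPAC_SETS)), collapse = ", "))
  }
  s <- toupper(sequence)
  L <- nchar(s)
  scan_one <- function(p) {
    m <- Biostrings::matchPattern(p, Biostrings::DNAString(
      if (circular) paste0(s, substr(s, 1L, min(L, length(seq_chars(p)) - 1L))) else s
    ), fixed = FALSE)
    st <- Biostrings::start(m)
    st[st <= L]
  }
  fwd <- scan_one(pattern)
  out <- tibble::tibble(start = fwd, strand = rep("+", length(fwd)))
  if (both_strands) {
    rc <- revcomp_iupac(pattern)
    if (!identical(rc, toupper(pattern))) {
      rev_hits <- scan_one(rc)
      out <- dplyr::bind_rows(out, tibble::tibble(start = rev_hits,
                                                  strand = rep("-", length(rev_hits))))
    }
  }
  dplyr::arrange(out, .data$start, .data$strand)
}

# reverse complement of an IUPAC pattern
revcomp_iupac <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[seq_chars(pattern)]), collapse = "")
}

#' Motif report for a circular consensus monomer
#'
#' Scans the top strand of the canonical monomer in circular coordinates:
#' GC content; perfect telomeric hexamers (TTAGGG); imperfect telomeric
#' hexamers (exactly one substitution from TTAGGG, never double-counting a
#' perfect window); CAAAA pentanucleotides; and maximal A-tracts of >= 4 A.
#' Motif occurrences are counted with overlap allowed (every circular start
#' position tested once); both-strand telomeric counts are reported alongside
#' for reference.
#'
#' @param monomer A closed `consensus_monomer` or a monomer string.
#' @return A `motif_report` object: `gc_pct`, position tibbles
#'   `perfect_telomeric`, `imperfect_telomeric`, `caaaa`, `a4_tracts`
#'   (1-based circular starts), both-strand telomere counts, and `length`.
#' @export
scan_motifs <- function(monomer) {
  mono <- if (inherits(monomer, "consensus_monomer")) {
    if (!monomer$closed) stop("motif scan requires a closed monomer")
    monomer$sequence
  } else toupper(monomer)
  L <- nchar(mono)
  gc <- 100 * gc_fraction(mono)

  perfect <- circular_match_starts(mono, TELOMERE_MOTIF)
  imperfect <- circular_near_match_starts(mono, TELOMERE_MOTIF, max_mismatch = 1)
  imperfect <- setdiff(imperfect, perfect)
  caaaa <- circular_match_starts(mono, "CAAAA")
  a4 <- circular_a_tracts(mono, min_run = 4L)

  rc <- revcomp(mono)
  perfect_rc <- circular_match_starts(rc, TELOMERE_MOTIF)
  imperfect_rc <- setdiff(
    circular_near_match_starts(rc, TELOMERE_MOTIF, max_mismatch = 1), perfect_rc)

  structure(list(
    length = L,
    gc_pct = gc,
    perfect_telomeric = tibble::tibble(start = perfect),
    imperfect_telomeric = tibble::tibble(start = imperfect),
    caaaa = tibble::tibble(start = caaaa),
    a4_tracts = a4,
    perfect_telomeric_both_strands = length(perfect) + length(perfect_rc),
    imperfect_telomeric_both_strands = length(imperfect) + length(imperfect_rc)
  ), class = "motif_report")
}

#' @export
print.motif_report <- function(x, ...) {
  cat("<motif_report> ", x$length, " bp, GC ", round(x$gc_pct, 1), "%\n",
      "  perfect TTAGGG: ", nrow(x$perfect_telomeric),
      "  imperfect (1 sub): ", nrow(x$imperfect_telomeric),
      "  CAAAA: ", nrow(x$caaaa),
      "  A4 tracts: ", nrow(x$a4_tracts), "\n", sep = "")
  invisible(x)
}

# circular exact-match start positions (1-based, in [1, L]); overlap allowed
circular_match_starts <- function(s, motif) {
  L <- nchar(s); w <- nchar(motif)
  if (L < w) return(integer(0))
  dbl <- paste0(s, substr(s, 1L, w - 1L))
  m <- Biostrings::start(Biostrings::matchPattern(motif, Biostrings::DNAString(dbl)))
  sort(m[m <= L])
}

# circular start positions of windows within max_mismatch substitutions
circular_near_match_starts <- function(s, motif, max_mismatch = 1) {
  L <- nchar(s); w <- nchar(motif)
  if (L < w) return(integer(0))
  dbl <- paste0(s, substr(s, 1L, w - 1L))
  m <- Biostrings::start(Biostrings::matchPattern(
    motif, Biostrings::DNAString(dbl), max.mismatch = max_mismatch,
    with.indels = FALSE))
  sort(m[m <= L])
}

# maximal runs of >= min_run consecutive A on the circular top strand
circular_a_tracts <- function(s, min_run = 4L) {
  ch <- seq_chars(s)
  L <- length(ch)
  if (all(ch == "A")) {
    return(tibble::tibble(start = 1L, length = L))
  }
  # rotate so position 1 is not an A: runs then never wrap ambiguously
  off <- which(ch != "A")[1] - 1L
  rot <- c(ch[(off + 1L):L], ch[seq_len(off)])
  r <- rle(rot == "A")
  ends <- cumsum(r$lengths)
  starts_rot <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  starts <- ((starts_rot[keep] - 1L + off) %% L) + 1L
  tibble::tibble(start = as.integer(starts), length = r$lengths[keep])
}

#' In-silico digestion of a tandem array
#'
#' Builds a linear head-to-tail array of `copies` monomers, finds the
#' enzyme's recognition sites, independently knocks out each site with
#' probability `per_copy_site_loss` (sequence divergence destroying sites is
#' what produces the dimer/trimer ladder above the monomer band), masks all
#' sites when the array is methylated and the enzyme is
#' methylation-sensitive, cuts after `cut_offset` bases of each remaining
#' site, and returns the fragment-length multiset.
#'
#' @param monomer Monomer string or closed `consensus_monomer`.
#' @param copies Number of head-to-tail copies (>= 1).
#' @param enzyme "BstNI" or "ScrFI" (see [restriction_enzymes()]), or a list
#'   with `enzyme`, `site`, `methylation_sensitive`, `cut_offset`.
#' @param per_copy_site_loss Probability that any given site is lost.
#' @param methylated Is the array CHG-methylated?
#' @param seed Seed for the site-loss draws.
#' @return A `digest_result` object: `fragments` (integer lengths, summing to
#'   the array length), `ladder` (tibble `length`, `n`), `enzyme`, `site`,
#'   `n_sites`, `no_sites` flag.
#' @export
digest_array <- function(monomer, copies = 100, enzyme = "BstNI",
                         per_copy_site_loss = 0, methylated = FALSE,
                         seed = 1L) {
  mono <- if (inherits(monomer, "consensus_monomer")) monomer$sequence else toupper(monomer)
  stopifnot(copies >= 1, per_copy_site_loss >= 0, per_copy_site_loss <= 1)
  enz <- if (is.character(enzyme)) {
    tab <- restriction_enzymes()
    row <- tab[tab$enzyme == enzyme, ]
    if (nrow(row) == 0) stop("unknown enzyme: ", enzyme)
    as.list(row)
  } else enzyme
  arr <- paste(rep(mono, copies), collapse = "")
  alen <- nchar(arr)
  sites <- unique(iupac_sites(arr, enz$site, both_strands = FALSE)$start)
  blocked <- methylated && isTRUE(enz$methylation_sensitive)
  no_sites <- length(sites) == 0
  if (!blocked && !no_sites && per_copy_site_loss > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    sites <- sites[stats::runif(length(sites)) >= per_copy_site_loss]
  }
  cuts <- if (blocked || no_sites) integer(0) else sites + enz$cut_offset - 1L
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < alen]))
  fragments <- diff(c(0L, cuts, alen))
  ladder <- dplyr::count(tibble::tibble(length = fragments), .data$length,
                         name = "n")
  structure(list(fragments = as.integer(fragments), ladder = ladder,
                 enzyme = enz$enzyme, site = enz$site,
                 methylation_sensitive = isTRUE(enz$methylation_sensitive),
                 methylated = methylated,
                 n_sites = length(sites), no_sites = no_sites || blocked,
                 array_length = alen, monomer_length = nchar(mono),
                 copies = copies),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat("<digest_result> ", x$enzyme, " (", x$site, ") on ", x$copies,
      "-copy array: ", length(x$fragments), " fragment(s)",
      if (x$no_sites) " [uncut]" else "", "\n", sep = "")
  invisible(x)
}
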