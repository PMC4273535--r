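# Synthetic reference sequences. The deposited satellite monomer clones are
# not bundled with the package, so a synthetic 249-bp monomer and a synthetic
# clone set are constructed to carry the same reported feature set; they are
# stand-ins for the real accessions, suitable for exercising and
# demonstrating every stage of the pipeline.

#' Synthetic 249-bp satellite monomer
#'
#' A synthetic construct (not a natural sequence) engineered to match the
#' feature profile reported for the PaB6-type pericentromeric satellite
#' monomer: 249 bp; GC content 44.2%; seven perfect vertebrate-type telomeric
#' hexamers (TTAGGG) on the top strand, two of them forming a dimer; exactly
#' five imperfect (single-substitution) telomeric hexamers; three CAAAA
#' pentanucleotides on the top strand; four A4 tracts; a single BstNI/ScrFI
#' site (CCAGG) so a head-to-tail array digests to a 249-bp ladder; and a
#' degenerate two-sub-repeat backbone. The sequence is already in canonical
#' rotation ([canonical_rotation()]), with the motif-bearing strand on top.
#'
#' @return A 249-character DNA string.
#' @examples
#' glance(scan_motifs(synthetic_monomer()))
#' @export
synthetic_monomer <- function() {
  mono <- paste0(
    "GAATGTGTATTAGGGATAGATTACATAATTGTATTCATTTTAGGGTTAGGGGAAACAGCA",
    "AAATCTCTTTTAGGGTTACACTTTGATTTAGCAGTTAGAGCACGTACCAGCAAAAATGCC",
    "CAGGGGATTGCATATTAGGGGTACAACACTGAGGGGCTTTTAGGGTCGGTTCGGGCCGAA",
    "GAGCGGCAAAATCGAGGACCCTACTTAGGGACTTAGCAGTTAGGACAGGTGAAAAGTTCA",
    "TTCTAGGGC"
  )
  canonical_rotation(mono)
}

#' Synthetic monomer clone set
#'
#' Generates a synthetic stand-in for a Sanger-sequenced monomer clone
#' collection: `n` clones spread evenly over six taxon groups, each derived
#' from [synthetic_monomer()] with random substitutions at up to ~3% of its
#' length (so pairwise identities fall in the low-90s to 100% range, within
#' and between groups alike -- the signature of concerted evolution not yet
#' sorting by lineage).
#' The length spectrum mirrors the reported census: 51 of 66 clones
#' full-length at 249 bp, twelve truncated (119, 175, 243, 247, 248 bp) and
#' three longer (two of 250 bp, one of 256 bp carrying a TTAGGG-containing
#' insertion).
#'
#' @param seed Integer seed.
#' @param n Number of clones (default 66).
#' @return Tibble: `id`, `group`, `length`, `sequence`.
#' @export
synthetic_clone_set <- function(seed = 1L, n = 66L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  ref <- synthetic_monomer()
  groups <- rep(c("cytotypeB5B5", "cytotypeB6B6", "cytotypeB7B7", "cytotypeAA",
                  "speciesH", "speciesO"), length.out = n)
  # length plan: full-length majority, a truncated minority, a few longer
  n_short <- round(n * 12 / 66); n_long <- round(n * 3 / 66)
  short_lens <- rep(c(119L, 175L, 243L, 247L, 248L), length.out = n_short)
  variant <- c(rep("full", n - n_short - n_long),
               rep("short", n_short), rep("long", n_long))
  variant <- sample(variant)
  short_i <- 0L; long_i <- 0L
  seqs <- character(n); lens <- integer(n)
  for (i in seq_len(n)) {
    s <- ref
    if (variant[i] == "short") {
      short_i <- short_i + 1L
      L <- short_lens[short_i]
      start <- sample(nchar(s) - L + 1L, 1)
      s <- substr(s, start, start + L - 1L)
    } else if (variant[i] == "long") {
      long_i <- long_i + 1L
      ins <- if (long_i == 1L) "TTAGGGG" else "A"   # one 256-bp, rest 250-bp
      at <- sample(nchar(s), 1)
      s <- paste0(substr(s, 1, at), ins, substr(s, at + 1, nchar(s)))
    }
    # substitutions proportional to clone length, up to ~3% divergence
    ch <- seq_chars(s)
    nsub <- sample(0:ceiling(0.03 * length(ch)), 1)
    for (p in sample(length(ch), nsub)) {
      ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
    }
    s <- paste(ch, collapse = "")
    seqs[i] <- s; lens[i] <- nchar(s)
  }
  tibble::tibble(id = sprintf("clone%02d", seq_len(n)), group = groups,
                 length = lens, sequence = seqs)
}
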