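# Low-level sequence helpers shared across modules. Sequences are plain
# uppercase character scalars over {A,C,G,T,N}; Biostrings objects are used
# only at the edges (I/O, alignment).

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return Character vector of reverse complements, uppercase.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  stringi::stri_reverse(chartr("acgtnACGTN", "tgcanTGCAN", x))
}

# split a sequence into a character vector of single bases
seq_chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]

# fraction of G+C among non-N bases
gc_fraction <- function(s) {
  ch <- seq_chars(s)
  ch <- ch[ch != "N"]
  if (length(ch) == 0L) return(NA_real_)
  mean(ch %in% c("G", "C"))
}

# random DNA of length n with expected GC fraction; uses the current RNG state
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# all k-length windows of a string, in order (character(0) if too short)
kmer_windows <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

# canonical form: lexicographic min of a k-mer and its reverse complement
canonical_kmer <- function(kmers) {
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Canonical rotation of a circular sequence
#'
#' Returns the lexicographically smallest string among all rotations of the
#' sequence and of its reverse complement, giving every circular monomer a
#' unique linear representative independent of the origin and strand it was
#' reconstructed on. Idempotent.
#'
#' @param sequence A DNA string.
#' @return A single string, the canonical rotation.
#' @examples
#' canonical_rotation("GTAC")
#' @export
canonical_rotation <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  s <- toupper(sequence)
  n <- nchar(s)
  strands <- c(s, revcomp(s))
  cands <- unlist(lapply(strands, function(str) {
    dbl <- paste0(str, str)
    substring(dbl, seq_len(n), seq_len(n) + n - 1L)
  }))
  min(cands)
}

# TRUE if a equals some rotation of b on either strand (circular equality)
same_circular_sequence <- function(a, b) {
  nchar(a) == nchar(b) && canonical_rotation(a) == canonical_rotation(b)
}

# apply per-base substitutions (prob p) and indels (prob q) to a sequence;
# substitutions always change the base
mutate_sequence <- function(s, sub_rate = 0, indel_rate = 0) {
  ch <- seq_chars(s)
  n <- length(ch)
  if (sub_rate > 0) {
    hit <- which(stats::runif(n) < sub_rate)
    for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  }
  if (indel_rate > 0) {
    hit <- which(stats::runif(length(ch)) < indel_rate)
    if (length(hit) > 0) {
      # half deletions, half single-base insertions
      del <- hit[stats::runif(length(hit)) < 0.5]
      ins <- setdiff(hit, del)
      if (length(ins) > 0) {
        ch[ins] <- paste0(ch[ins], sample(DNA_BASES, length(ins), replace = TRUE))
      }
      if (length(del) > 0) ch <- ch[-del]
    }
  }
  paste(ch, collapse = "")
}
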