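# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidy.consensus_monomer
#' @export
glance.consensus_monomer <- function(x, ...) {
  tibble::tibble(length = x$length, closed = x$closed, k = x$k,
                 gc_pct = 100 * gc_fraction(x$sequence),
                 start_count = x$start_count)
}

#' Tidy a consensus monomer or its logo
#'
#' `tidy()` returns one row per circular position with the consensus base;
#' `glance()` returns the one-row summary (length, closure, k, GC).
#'
#' @param x A `consensus_monomer`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.consensus_monomer <- function(x, ...) {
  tibble::tibble(position = seq_len(nchar(x$sequence)),
                 base = seq_chars(x$sequence))
}

#' @export
tidy.consensus_logo <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), cols = c("fA", "fC", "fG", "fT"),
                      names_to = "base", names_prefix = "f",
                      values_to = "frequency")
}

#' @export
tidy.motif_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(motif = "TTAGGG", kind = "perfect_telomeric",
                   start = x$perfect_telomeric$start),
    tibble::tibble(motif = "TTAGGG~1", kind = "imperfect_telomeric",
                   start = x$imperfect_telomeric$start),
    tibble::tibble(motif = "CAAAA", kind = "caaaa", start = x$caaaa$start),
    tibble::tibble(motif = "AAAA+", kind = "a4_tract", start = x$a4_tracts$start)
  )
}

#' @export
glance.motif_report <- function(x, ...) {
  tibble::tibble(length = x$length, gc_pct = x$gc_pct,
                 perfect_telomeric = nrow(x$perfect_telomeric),
                 imperfect_telomeric = nrow(x$imperfect_telomeric),
                 caaaa = nrow(x$caaaa), a4_tracts = nrow(x$a4_tracts),
                 perfect_telomeric_both_strands = x$perfect_telomeric_both_strands)
}

#' @export
tidy.digest_result <- function(x, ...) {
  x$ladder
}

#' @export
glance.digest_result <- function(x, ...) {
  tibble::tibble(enzyme = x$enzyme, site = x$site,
                 methylated = x$methylated,
                 methylation_sensitive = x$methylation_sensitive,
                 n_fragments = length(x$fragments), n_sites = x$n_sites,
                 array_length = x$array_length,
                 dominant_length = x$ladder$length[which.max(x$ladder$n)],
                 uncut = x$no_sites)
}

#' @export
tidy.identity_matrix <- function(x, ...) {
  m <- x$matrix
  idx <- which(upper.tri(m), arr.ind = TRUE)
  lab <- x$labels
  tibble::tibble(id_a = rownames(m)[idx[, 1]], id_b = colnames(m)[idx[, 2]],
                 group_a = lab$group[idx[, 1]], group_b = lab$group[idx[, 2]],
                 identity_pct = m[idx])
}

#' @export
glance.identity_matrix <- function(x, ...) {
  off <- x$matrix[upper.tri(x$matrix)]
  tibble::tibble(n_sequences = nrow(x$matrix), n_pairs = length(off),
                 min_identity = if (length(off)) min(off) else NA_real_,
                 max_identity = if (length(off)) max(off) else NA_real_,
                 mean_identity = if (length(off)) mean(off) else NA_real_)
}

#' @export
tidy.dot_plot <- function(x, ...) {
  x$hits
}

#' @export
tidy.subrepeat_structure <- function(x, ...) {
  x$periods
}

#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, r_squared = x$r_squared,
                 n_points = nrow(x$points))
}
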