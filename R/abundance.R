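# Conversions between genome proportion, copy number per 1C genome, genome
# size in pg, and monomer length, plus the slot-blot calibration estimator and
# the NGS-vs-blot comparison.

#' Genome proportion from satellite copy number
#'
#' Converts copies per 1C to the percentage of the genome occupied by the
#' satellite, using a C-value conversion constant (1 pg = 978 Mbp by default).
#'
#' @param copies_per_1C Number of monomer copies per unreplicated haploid (1C)
#'   genome. Vectorised.
#' @param genome_pg 1C genome size in picograms.
#' @param monomer_bp Monomer length in base pairs.
#' @param mbp_per_pg Conversion constant, megabases per picogram (default 978).
#' @return Genome proportion in percent (0-100 scale).
#' @examples
#' proportion_from_copies(2.11e4, genome_pg = 4.45, monomer_bp = 249)
#' @seealso [copies_from_proportion()]
#' @export
proportion_from_copies <- function(copies_per_1C, genome_pg, monomer_bp,
                                   mbp_per_pg = 978) {
  if (any(genome_pg <= 0)) stop("`genome_pg` must be positive")
  if (any(monomer_bp <= 0)) stop("`monomer_bp` must be positive")
  if (any(mbp_per_pg <= 0)) stop("`mbp_per_pg` must be positive")
  if (any(copies_per_1C < 0)) stop("`copies_per_1C` must be non-negative")
  100 * copies_per_1C * monomer_bp / (genome_pg * mbp_per_pg * 1e6)
}

#' Satellite copy number from genome proportion
#'
#' Exact algebraic inverse of [proportion_from_copies()].
#'
#' @param proportion_pct Genome proportion in percent.
#' @inheritParams proportion_from_copies
#' @return Copies per 1C genome.
#' @examples
#' copies_from_proportion(0.1207, genome_pg = 4.45, monomer_bp = 249)
#' @export
copies_from_proportion <- function(proportion_pct, genome_pg, monomer_bp,
                                   mbp_per_pg = 978) {
  if (any(genome_pg <= 0)) stop("`genome_pg` must be positive")
  if (any(monomer_bp <= 0)) stop("`monomer_bp` must be positive")
  if (any(mbp_per_pg <= 0)) stop("`mbp_per_pg` must be positive")
  if (any(proportion_pct < 0)) stop("`proportion_pct` must be non-negative")
  proportion_pct / 100 * genome_pg * mbp_per_pg * 1e6 / monomer_bp
}

#' Genome proportion of a cluster from read counts
#'
#' The cluster's share of the genome is estimated as its share of the
#' (quality-filtered) read set. The denominator convention is a recorded
#' choice: read counts over quality-filtered reads by default; base counts can
#' be supplied instead.
#'
#' @param cluster_size Number of reads in the cluster (or bases, if
#'   `total` is total bases).
#' @param total Denominator: total quality-filtered reads (or bases).
#' @return Proportion in percent.
#' @examples
#' ngs_proportion(50, 10000)
#' @export
ngs_proportion <- function(cluster_size, total) {
  stopifnot(total > 0, all(cluster_size >= 0))
  100 * cluster_size / total
}

#' Fit a slot-blot standard curve
#'
#' Least-squares line through the origin for the unlabelled-standard dilution
#' series: signal = slope x amount. Zero amount must give zero signal, so the
#' fit has no intercept. A robust alternative (median of per-point
#' signal/amount ratios) is available.
#'
#' @param blot A data frame with columns `role`, `amount_ng`, `signal`, as
#'   written by [simulate_slot_blot()]; rows with `role == "standard"` are the
#'   calibration points.
#' @param robust If `TRUE`, the slope is the median of per-point ratios rather
#'   than the least-squares estimate.
#' @return An object of class `standard_curve`: list with `slope` (signal per
#'   ng), `r_squared`, and the calibration `points` tibble.
#' @export
fit_standard_curve <- function(blot, robust = FALSE) {
  stopifnot(is.data.frame(blot),
            all(c("role", "amount_ng", "signal") %in% names(blot)))
  pts <- dplyr::filter(blot, .data$role == "standard")
  if (nrow(pts) < 2) stop("standard curve needs at least 2 calibration points")
  if (any(pts$amount_ng <= 0)) stop("standard amounts must be positive")
  if (robust) {
    slope <- stats::median(pts$signal / pts$amount_ng)
    fitted <- slope * pts$amount_ng
    ss_res <- sum((pts$signal - fitted)^2)
    r2 <- 1 - ss_res / sum(pts$signal^2)
  } else {
    fit <- stats::lm(signal ~ amount_ng - 1, data = pts)
    slope <- unname(stats::coef(fit)[1])
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum(pts$signal^2)
  }
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration error: standard curve slope is not positive ",
         "(saturated or all-zero standards?)")
  }
  structure(list(slope = slope, r_squared = r2,
                 points = tibble::as_tibble(pts)),
            class = "standard_curve")
}

#' Estimate satellite abundance from a slot-blot table
#'
#' Calibrates against the standard dilution series ([fit_standard_curve()]),
#' converts each genomic-DNA signal to satellite mass (signal / slope),
#' divides by the loaded genomic mass to get a per-dilution proportion,
#' averages over dilutions, and converts to copies per 1C.
#'
#' @inheritParams fit_standard_curve
#' @param genome_pg 1C genome size in pg.
#' @param monomer_bp Monomer length in bp.
#' @param mbp_per_pg Mbp per pg conversion constant.
#' @param sample_label Label carried into the output row.
#' @return A one-row tibble of class `abundance_estimate` with columns
#'   `sample_label`, `method`, `proportion_pct`, `copies_per_1C`, `genome_pg`,
#'   `monomer_bp`, `mbp_per_pg`, `n_dilutions`, `curve_r_squared`.
#' @examples
#' blot <- simulate_slot_blot(0.10, noise_cv = 0, seed = 1)
#' slot_blot_estimate(blot, genome_pg = 6.27, monomer_bp = 249)
#' @export
slot_blot_estimate <- function(blot, genome_pg, monomer_bp, mbp_per_pg = 978,
                               robust = FALSE, sample_label = "sample") {
  curve <- fit_standard_curve(blot, robust = robust)
  smp <- dplyr::filter(blot, .data$role == "sample")
  if (nrow(smp) < 1) stop("no sample rows in slot-blot table")
  prop <- mean(smp$signal / curve$slope / smp$amount_ng)
  prop_pct <- 100 * prop
  out <- tibble::tibble(
    sample_label = sample_label,
    method = "slot_blot",
    proportion_pct = prop_pct,
    copies_per_1C = copies_from_proportion(prop_pct, genome_pg, monomer_bp,
                                           mbp_per_pg),
    genome_pg = genome_pg,
    monomer_bp = monomer_bp,
    mbp_per_pg = mbp_per_pg,
    n_dilutions = nrow(smp),
    curve_r_squared = curve$r_squared
  )
  class(out) <- c("abundance_estimate", class(out))
  out
}

#' Abundance estimate from an NGS repeat cluster
#'
#' @param cluster One row of the cluster table from [cluster_graph()] (or any
#'   data frame with `size`), or a plain read count.
#' @param total_reads Quality-filtered read-count denominator.
#' @inheritParams slot_blot_estimate
#' @return A one-row `abundance_estimate` tibble (see [slot_blot_estimate()]).
#' @export
ngs_abundance <- function(cluster, total_reads, genome_pg, monomer_bp,
                          mbp_per_pg = 978, sample_label = "sample") {
  size <- if (is.data.frame(cluster)) cluster$size[1] else cluster[1]
  prop_pct <- ngs_proportion(size, total_reads)
  out <- tibble::tibble(
    sample_label = sample_label,
    method = "ngs",
    proportion_pct = prop_pct,
    copies_per_1C = copies_from_proportion(prop_pct, genome_pg, monomer_bp,
                                           mbp_per_pg),
    genome_pg = genome_pg,
    monomer_bp = monomer_bp,
    mbp_per_pg = mbp_per_pg,
    n_dilutions = NA_integer_,
    curve_r_squared = NA_real_
  )
  class(out) <- c("abundance_estimate", class(out))
  out
}

#' Compare NGS and slot-blot abundance estimates
#'
#' Reports the NGS/blot proportion ratio and flags satellite
#' under-representation in the read data when the ratio falls below a cutoff.
#' Low-coverage 454 libraries are known to under-sample satellite arrays, so a
#' read-count proportion well below the hybridisation estimate is expected
#' behaviour worth flagging, not an error.
#'
#' @param ngs_pct,slot_pct Genome proportions in percent from the two methods
#'   (scalars or `abundance_estimate` rows).
#' @param flag_below Ratio threshold below which under-representation is
#'   flagged (default 0.5).
#' @return A one-row tibble with `ngs_pct`, `slot_pct`, `ratio`,
#'   `under_represented`.
#' @examples
#' compare_methods(1.8, 7.2)
#' @export
compare_methods <- function(ngs_pct, slot_pct, flag_below = 0.5) {
  if (is.data.frame(ngs_pct)) ngs_pct <- ngs_pct$proportion_pct[1]
  if (is.data.frame(slot_pct)) slot_pct <- slot_pct$proportion_pct[1]
  stopifnot(ngs_pct >= 0, slot_pct > 0)
  ratio <- ngs_pct / slot_pct
  tibble::tibble(ngs_pct = ngs_pct, slot_pct = slot_pct, ratio = ratio,
                 under_represented = ratio < flag_below)
}
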