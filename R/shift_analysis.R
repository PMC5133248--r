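#' Build a normalized per-OTU density profile
#'
#' The profile of one OTU in one gradient: read counts over the sequenced
#' fractions, normalized as the ratio of each fraction's reads to the maximum
#' read count of that OTU in that gradient ("ratio of quantities"). The
#' normalization makes profiles comparable across gradients of different
#' sequencing depth; ratios lie in \[0, 1\] with the mode at exactly 1.
#'
#' @param counts Numeric vector of read counts, aligned with the run's
#'   sequenced fractions in fraction-index order.
#' @param run A [gradient_run()].
#' @param otu_id OTU identifier carried along for reporting.
#' @return Object of class `otu_profile` with fields `densities`, `reads`,
#'   `ratios` and a `no_signal` flag (all reads zero).
#' @examples
#' fr <- data.frame(fraction_index = 1:3, density = c(1.72, 1.71, 1.70),
#'                  dna_quantity = 1, sequenced = TRUE)
#' build_profile(c(10, 50, 25), gradient_run("G", fr), "OTU1")$ratios
#' @export
build_profile <- function(counts, run, otu_id = NA_character_) {
  stopifnot(inherits(run, "gradient_run"))
  fr <- run$fractions[run$fractions$sequenced, , drop = FALSE]
  if (length(counts) != nrow(fr))
    stop(sprintf("OTU '%s', gradient '%s': %d counts for %d sequenced fractions",
                 otu_id, run$gradient_id, length(counts), nrow(fr)))
  reads <- as.numeric(counts)
  if (anyNA(reads) || any(reads < 0))
    stop("read counts must be non-negative and finite")
  no_signal <- max(reads) <= 0
  ratios <- if (no_signal) reads else reads / max(reads)
  structure(list(otu_id = otu_id, gradient_id = run$gradient_id,
                 densities = fr$density, reads = reads, ratios = ratios,
                 no_signal = no_signal),
            class = "otu_profile")
}

# Maximal contiguous run of indices with r >= thr containing index i.
.support_run <- function(r, i, thr) {
  lo <- i; hi <- i; n <- length(r)
  while (lo > 1L && r[lo - 1L] >= thr) lo <- lo - 1L
  while (hi < n && r[hi + 1L] >= thr) hi <- hi + 1L
  lo:hi
}

# Sub-fraction refinement of the band center by log-quadratic interpolation
# through the modal fraction and its two neighbours (exact for a Gaussian
# band sampled on an even density grid). Falls back to the modal fraction
# density at profile edges, zero neighbours, or non-concave triplets.
.refine_peak_density <- function(d, reads, i) {
  n <- length(reads)
  if (i == 1L || i == n) return(d[i])
  if (reads[i - 1L] <= 0 || reads[i + 1L] <= 0 || reads[i] <= 0) return(d[i])
  a <- log(reads[i - 1L]); b <- log(reads[i]); c <- log(reads[i + 1L])
  den <- a - 2 * b + c
  if (den >= 0) return(d[i])
  p <- 0.5 * (a - c) / den
  p <- max(-1, min(1, p))
  d[i] + p * (d[i + 1L] - d[i - 1L]) / 2
}

.empty_secondary <- function() {
  data.frame(density = numeric(0), ratio = numeric(0),
             support_size = integer(0))
}

.peak_call <- function(mode_density, support_size, secondary_peaks, valid,
                       method, centroid_density, refined_density, no_signal) {
  structure(list(mode_density = mode_density, support_size = support_size,
                 secondary_peaks = secondary_peaks, valid = valid,
                 method = method, centroid_density = centroid_density,
                 refined_density = refined_density, no_signal = no_signal),
            class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  if (x$no_signal) {
    cat("Peak call: no signal (all-zero profile)\n")
    return(invisible(x))
  }
  cat(sprintf("Peak call (%s%s): density %.4f g/ml, support %d fraction(s)\n",
              x$method, if (x$valid) "" else ", invalid peak", x$mode_density,
              x$support_size))
  if (nrow(x$secondary_peaks))
    cat(sprintf("  secondary peak at %.4f g/ml (support %d)\n",
                x$secondary_peaks$density, x$secondary_peaks$support_size))
  invisible(x)
}

#' Call the DNA band peak of a density profile
#'
#' The primary peak is the global maximum fraction. Its supporting run is the
#' maximal contiguous set of fractions with ratio at or above
#' `support_threshold` (half-maximum by default) that contains the mode; the
#' peak is valid only if this run spans at least `min_support` fractions, so
#' single-point spikes are rejected automatically. When no valid peak exists
#' the overall distribution is summarized instead: `method = "centroid"` and
#' the band position is the read-weighted mean density.
#'
#' Additional local maxima with ratio at or above `secondary_min_ratio`,
#' whose own half-maximum run (relative to their height) spans at least
#' `min_support` fractions and lies outside the primary run, are reported as
#' secondary peaks sorted by density; these capture bimodal banding produced
#' by differentially active subpopulations.
#'
#' A `refined_density` field carries a sub-fraction estimate of the band
#' center obtained by log-quadratic interpolation about the mode (exact for a
#' Gaussian band); see [compute_shift()].
#'
#' @param profile An [build_profile()] result.
#' @param support_threshold Fraction of the maximum defining the supporting
#'   run (default 0.5).
#' @param min_support Minimum supporting run length for a valid peak
#'   (default 3).
#' @param secondary_min_ratio Minimum ratio for a secondary peak candidate
#'   (default 0.25).
#' @return Object of class `peak_call`.
#' @export
detect_peaks <- function(profile, support_threshold = 0.5, min_support = 3L,
                         secondary_min_ratio = 0.25) {
  stopifnot(inherits(profile, "otu_profile"))
  if (profile$no_signal)
    return(.peak_call(NA_real_, 0L, .empty_secondary(), FALSE,
                      NA_character_, NA_real_, NA_real_, TRUE))
  ord <- order(profile$densities)          # ascending density
  d <- profile$densities[ord]
  r <- profile$ratios[ord]
  reads <- profile$reads[ord]
  n <- length(d)
  centroid <- stats::weighted.mean(d, reads)

  rmax <- max(reads)
  tied <- which(reads == rmax)
  i <- tied[1L]
  run <- .support_run(r, i, support_threshold)
  support <- length(run)
  valid <- support >= as.integer(min_support)
  mode_density <- if (length(tied) > 1L)
    stats::weighted.mean(d[tied], reads[tied]) else d[i]
  refined <- if (length(tied) > 1L) mode_density
             else .refine_peak_density(d, reads, i)

  sec <- .empty_secondary()
  if (valid) {
    cand <- which(r >= secondary_min_ratio & r > 0)
    cand <- cand[!(cand %in% run)]
    is_lmax <- vapply(cand, function(j) {
      left <- if (j == 1L) TRUE else r[j] >= r[j - 1L]
      right <- if (j == n) TRUE else r[j] >= r[j + 1L]
      strict <- (j > 1L && r[j] > r[j - 1L]) || (j < n && r[j] > r[j + 1L])
      left && right && strict
    }, logical(1))
    cand <- cand[is_lmax]
    claimed <- run
    for (j in cand[order(-r[cand])]) {
      if (j %in% claimed) next
      own <- .support_run(r, j, support_threshold * r[j])
      if (length(own) >= as.integer(min_support)) {
        sec <- rbind(sec, data.frame(density = d[j], ratio = r[j],
                                     support_size = length(own)))
        claimed <- union(claimed, own)
      }
    }
    if (nrow(sec)) sec <- sec[order(sec$density), , drop = FALSE]
    rownames(sec) <- NULL
  }

  if (!valid)
    return(.peak_call(centroid, support, sec, FALSE, "centroid",
                      centroid, centroid, FALSE))
  .peak_call(mode_density, support, sec, TRUE, "peak", centroid, refined,
             FALSE)
}

#' Density shift between a control and a labeled peak call
#'
#' Returns the labeled-minus-control band density in g/ml. Comparisons are
#' like-for-like: when both peaks are valid the peak positions are compared
#' (by default the interpolated sub-fraction estimates); when either side
#' fell back to the distribution summary, both sides are compared
#' centroid-vs-centroid. The sign is preserved -- negative shifts are
#' reported (and flagged downstream), since a consistent banding method
#' should produce none.
#'
#' @param control,labeled [detect_peaks()] results for the paired gradients.
#' @param use_secondary When `TRUE`, the labeled position is the densest of
#'   the primary and any secondary peaks, for subpopulation analysis of
#'   bimodal labeled profiles. Default `FALSE` (conservative, primary only).
#' @param density_estimate `"interpolated"` (default) compares sub-fraction
#'   refined peak positions; `"mode"` compares raw modal fraction densities
#'   (quantized to the fraction spacing).
#' @return Numeric shift in g/ml with attribute `method` (`"peak"`,
#'   `"centroid"`, or `"no-signal"`); `NA` when either side has no reads, in
#'   which case the OTU is excluded from enrichment calling.
#' @export
compute_shift <- function(control, labeled, use_secondary = FALSE,
                          density_estimate = c("interpolated", "mode")) {
  stopifnot(inherits(control, "peak_call"), inherits(labeled, "peak_call"))
  density_estimate <- match.arg(density_estimate)
  if (control$no_signal || labeled$no_signal) {
    out <- NA_real_
    attr(out, "method") <- "no-signal"
    return(out)
  }
  if (control$valid && labeled$valid) {
    pick <- function(p) if (density_estimate == "interpolated")
      p$refined_density else p$mode_density
    cd <- pick(control)
    ld <- pick(labeled)
    if (use_secondary && nrow(labeled$secondary_peaks))
      ld <- max(ld, labeled$secondary_peaks$density)
    method <- "peak"
  } else {
    cd <- control$centroid_density
    ld <- labeled$centroid_density
    method <- "centroid"
  }
  out <- ld - cd
  attr(out, "method") <- method
  out
}

#' Standardized distance of a cutoff from a null mean
#'
#' `(cutoff - mean) / sd`, the number of null-distribution standard
#' deviations between the enrichment cutoff and the mean null shift.
#'
#' @param cutoff,mean,sd Numeric scalars (g/ml).
#' @return Dimensionless distance.
#' @export
lod_sd_distance <- function(cutoff, mean, sd) (cutoff - mean) / sd

#' Calibrate the limit of detection from null-treatment shifts
#'
#' The limit of detection (LOD) for enrichment is set conservatively at
#' `factor` times the largest absolute shift observed between control and
#' labeled profiles of a null treatment -- an incubation whose expected
#' labeling is below detectability, so its apparent shifts measure the
#' method's banding reproducibility alone.
#'
#' @param null_shifts Numeric vector of null-treatment shifts (g/ml); `NA`s
#'   are dropped.
#' @param factor Multiplier on the largest absolute null shift (default 1.5).
#' @param min_n Minimum acceptable number of null shifts (default 10); fewer
#'   triggers a warning and flags the calibration.
#' @return Object of class `lod_calibration` with fields `cutoff`, `factor`,
#'   `null_shifts`, `n`, `mean`, `sd` (n-1 denominator), `max_abs`,
#'   `sd_distance` and a histogram of shift magnitudes.
#' @examples
#' calibrate_lod(c(0, 0.001, 0.002), min_n = 3)$cutoff   # 0.003
#' @export
calibrate_lod <- function(null_shifts, factor = 1.5, min_n = 10L) {
  s <- null_shifts[!is.na(null_shifts)]
  n <- length(s)
  if (n == 0L || all(s == 0))
    stop(errorCondition(
      "degenerate null (no non-zero null shifts); specify the cutoff manually",
      class = c("tagsip_degenerate_null", "error", "condition")))
  low_n <- n < as.integer(min_n)
  if (low_n)
    warning(sprintf("only %d null shift(s) (< %d); calibration flagged low-n",
                    n, min_n))
  max_abs <- max(abs(s))
  cutoff <- factor * max_abs
  mu <- mean(s)
  sd_ <- stats::sd(s)
  structure(list(cutoff = cutoff, factor = factor, null_shifts = s, n = n,
                 mean = mu, sd = sd_, max_abs = max_abs,
                 sd_distance = lod_sd_distance(cutoff, mu, sd_),
                 magnitude_hist = table(round(abs(s), 3)),
                 low_n = low_n, manual = FALSE),
            class = "lod_calibration")
}

#' A manually specified limit of detection
#'
#' For analyses without a null treatment; wraps a user-chosen cutoff in the
#' same container as [calibrate_lod()].
#'
#' @param cutoff Enrichment cutoff in g/ml.
#' @return An `lod_calibration` with `manual = TRUE` and no null statistics.
#' @export
manual_lod <- function(cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  structure(list(cutoff = cutoff, factor = NA_real_,
                 null_shifts = numeric(0), n = 0L, mean = NA_real_,
                 sd = NA_real_, max_abs = NA_real_, sd_distance = NA_real_,
                 magnitude_hist = NULL, low_n = FALSE, manual = TRUE),
            class = "lod_calibration")
}

#' @export
print.lod_calibration <- function(x, ...) {
  if (x$manual) {
    cat(sprintf("Limit of detection (manual): cutoff %.4f g/ml\n", x$cutoff))
    return(invisible(x))
  }
  cat(sprintf("Limit of detection: cutoff %.4f g/ml = %.2g x largest |null shift| (%.4f)\n",
              x$cutoff, x$factor, x$max_abs))
  cat(sprintf("  null shifts: n = %d, mean = %.4g, SD = %.4g (cutoff is %.1f SD above the mean)\n",
              x$n, x$mean, x$sd, x$sd_distance))
  if (x$low_n) cat("  WARNING: fewer null shifts than requested minimum\n")
  invisible(x)
}

#' Call isotopic enrichment for a shift
#'
#' An OTU is enriched when its labeled-minus-control density shift is at or
#' above the limit of detection (inclusive).
#'
#' @param shift Numeric shift(s) in g/ml (`NA` stays `NA`).
#' @param lod An [calibrate_lod()]/[manual_lod()] object, or a numeric
#'   cutoff.
#' @return Logical vector.
#' @export
call_enrichment <- function(shift, lod) {
  cutoff <- if (inherits(lod, "lod_calibration")) lod$cutoff else lod
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  as.vector(shift) >= cutoff
}

#' Summarize enrichment by clade
#'
#' Tallies, for each clade at the requested taxonomic rank, how many OTUs
#' were analyzed and what fraction was called enriched. OTUs absent from the
#' taxonomy (or with an empty rank) are grouped as `"unclassified"`; an
#' overall row (`"(all)"`) is appended.
#'
#' @param results data.frame with columns `otu_id` and `enriched` (logical;
#'   `NA` rows -- undefined shifts -- are dropped).
#' @param taxonomy data.frame with columns `otu_id`, `lineage`.
#' @param rank Taxonomic rank for grouping (default `"family"`).
#' @return data.frame with columns `clade`, `rank`, `n_otus`, `n_enriched`,
#'   `percent_enriched`.
#' @export
summarize_clades <- function(results, taxonomy, rank = "family") {
  stopifnot(all(c("otu_id", "enriched") %in% names(results)))
  res <- results[!is.na(results$enriched), , drop = FALSE]
  lin <- taxonomy$lineage[match(res$otu_id, taxonomy$otu_id)]
  clade <- ifelse(is.na(lin), "unclassified", lineage_at_rank(lin, rank))
  tally <- function(cl, enr) {
    data.frame(clade = cl, rank = rank, n_otus = length(enr),
               n_enriched = sum(enr),
               percent_enriched = 100 * sum(enr) / length(enr),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(sort(unique(clade)), function(cl)
    tally(cl, res$enriched[clade == cl])))
  out <- rbind(out, tally("(all)", res$enriched))
  rownames(out) <- NULL
  out
}
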