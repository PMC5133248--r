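#' Fit a Tag-SIP enrichment analysis
#'
#' The full Tag-SIP procedure on one experiment: select each gradient's
#' sequencing window from the DNA distribution (when the metadata does not
#' already restrict it), filter OTUs by abundance rank and per-fraction read
#' support, build normalized density profiles, call band peaks, compute the
#' paired control/labeled density shift of every OTU, calibrate the limit of
#' detection from the null treatment (or accept a manual cutoff), and call
#' enrichment.
#'
#' @param counts An [otu_table()] or path to one.
#' @param metadata A list of [gradient_run()]s (as from
#'   [read_fraction_metadata()]) or path to a fraction metadata file.
#' @param manifest A [manifest()] or path to a manifest YAML.
#' @param taxonomy Optional taxonomy data.frame or path; enables clade
#'   summaries.
#' @param n_select_fractions Sequencing window size applied to runs whose
#'   metadata does not already restrict the sequenced fractions (default
#'   20).
#' @param min_mean_reads,top_n,read_stat OTU filters; see [filter_otus()].
#' @param support_threshold,min_support,secondary_min_ratio Peak-calling
#'   parameters; see [detect_peaks()].
#' @param density_estimate,use_secondary Shift computation; see
#'   [compute_shift()].
#' @param lod_factor Multiplier for the null-calibrated cutoff (default
#'   1.5).
#' @param cutoff Manual enrichment cutoff in g/ml; bypasses null
#'   calibration.
#' @param clade_rank Rank for clade summaries (default `"family"`).
#' @return An object of class `tagsip`: a list with components `shifts` (one
#'   row per OTU x treatment), `lod` (the calibration), `clades` (per
#'   treatment, when taxonomy is given), `profiles`, `peaks`, `params`,
#'   `runs` and `manifest`. Methods: [print.tagsip()], [summary.tagsip()],
#'   [coef.tagsip()], [plot.tagsip()].
#' @export
tag_sip <- function(counts, metadata, manifest, taxonomy = NULL,
                    n_select_fractions = 20L,
                    min_mean_reads = 400, top_n = 100L,
                    read_stat = c("mean", "min"),
                    support_threshold = 0.5, min_support = 3L,
                    secondary_min_ratio = 0.25,
                    density_estimate = c("interpolated", "mode"),
                    use_secondary = FALSE,
                    lod_factor = 1.5, cutoff = NULL,
                    clade_rank = "family") {
  if (is.character(counts)) counts <- read_otu_table(counts)
  if (is.character(metadata)) metadata <- read_fraction_metadata(metadata)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.character(taxonomy)) taxonomy <- read_taxonomy(taxonomy)
  stopifnot(inherits(counts, "otu_table"),
            inherits(manifest, "tagsip_manifest"))
  read_stat <- match.arg(read_stat)
  density_estimate <- match.arg(density_estimate)

  runs <- metadata
  if (inherits(runs, "gradient_run")) runs <- list(runs)
  if (is.null(names(runs)))
    names(runs) <- vapply(runs, `[[`, "", "gradient_id")
  pairs <- manifest$pairs
  used <- unique(c(pairs$labeled, pairs$control))
  miss <- setdiff(used, names(runs))
  if (length(miss))
    stop("manifest references gradient(s) missing from the metadata: ",
         paste(miss, collapse = ", "))
  runs <- runs[used]
  for (i in seq_along(pairs$labeled)) {
    runs[[pairs$labeled[i]]]$treatment <- "labeled"
    runs[[pairs$control[i]]]$treatment <- "control"
  }

  # Select the sequencing window wherever the metadata has not already
  # restricted it.
  runs <- lapply(runs, function(r) {
    if (all(r$fractions$sequenced) &&
        nrow(r$fractions) > n_select_fractions)
      select_fractions(r, n_select_fractions)
    else r
  })

  counts <- align_otu_table(counts, runs)
  filtered <- filter_otus(counts, pairs = pairs,
                          min_mean_reads = min_mean_reads, top_n = top_n,
                          stat = read_stat)
  otus <- rownames(filtered$counts)
  if (!length(otus))
    stop("no OTUs pass the abundance filters; nothing to analyze")

  profiles <- lapply(names(runs), function(g) {
    cols <- which(filtered$gradient_id == g)
    cols <- cols[order(filtered$fraction_index[cols])]
    lapply(stats::setNames(otus, otus), function(o)
      build_profile(filtered$counts[o, cols], runs[[g]], o))
  })
  names(profiles) <- names(runs)
  peaks <- lapply(profiles, function(pg)
    lapply(pg, detect_peaks, support_threshold = support_threshold,
           min_support = min_support,
           secondary_min_ratio = secondary_min_ratio))

  shifts <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    lg <- pairs$labeled[i]; cg <- pairs$control[i]
    do.call(rbind, lapply(otus, function(o) {
      cp <- peaks[[cg]][[o]]; lp <- peaks[[lg]][[o]]
      delta <- compute_shift(cp, lp, use_secondary = use_secondary,
                             density_estimate = density_estimate)
      method <- attr(delta, "method")
      est <- function(p) {
        if (p$no_signal) return(NA_real_)
        if (method == "centroid") return(p$centroid_density)
        if (density_estimate == "interpolated") p$refined_density
        else p$mode_density
      }
      data.frame(otu_id = o, treatment = pairs$treatment[i],
                 labeled_gradient = lg, control_gradient = cg,
                 control_density = est(cp), labeled_density = est(lp),
                 delta_density = as.vector(delta),
                 control_support = cp$support_size,
                 labeled_support = lp$support_size,
                 n_secondary = nrow(lp$secondary_peaks),
                 method = method,
                 negative_shift = isTRUE(as.vector(delta) < 0),
                 no_signal = cp$no_signal || lp$no_signal,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(shifts) <- NULL

  if (is.null(cutoff)) {
    nt <- manifest$null_treatment
    if (is.na(nt))
      stop(paste0("no null treatment in the manifest and no manual cutoff; ",
                  "supply `cutoff` (g/ml) or add a null-treatment pair for ",
                  "LOD calibration"))
    null_shifts <- shifts$delta_density[shifts$treatment == nt]
    lod <- calibrate_lod(null_shifts, factor = lod_factor)
  } else {
    lod <- manual_lod(cutoff)
  }
  shifts$enriched <- call_enrichment(shifts$delta_density, lod)

  clades <- NULL
  if (!is.null(taxonomy)) {
    clades <- lapply(split(shifts, shifts$treatment), summarize_clades,
                     taxonomy = taxonomy, rank = clade_rank)
  }

  structure(list(shifts = shifts, lod = lod, clades = clades,
                 profiles = profiles, peaks = peaks, runs = runs,
                 manifest = manifest, taxonomy = taxonomy,
                 params = list(n_select_fractions = n_select_fractions,
                               min_mean_reads = min_mean_reads,
                               top_n = top_n, read_stat = read_stat,
                               support_threshold = support_threshold,
                               min_support = min_support,
                               secondary_min_ratio = secondary_min_ratio,
                               density_estimate = density_estimate,
                               use_secondary = use_secondary,
                               lod_factor = lod_factor,
                               cutoff = cutoff,
                               clade_rank = clade_rank)),
            class = "tagsip")
}

#' @export
print.tagsip <- function(x, ...) {
  s <- x$shifts
  cat(sprintf("Tag-SIP analysis: %d OTUs, %d treatment pair(s)\n",
              length(unique(s$otu_id)), nrow(x$manifest$pairs)))
  cat(sprintf("Enrichment cutoff: %.4f g/ml (%s)\n", x$lod$cutoff,
              if (x$lod$manual) "manual"
              else sprintf("1.5-type rule: %.2g x largest null shift, n = %d",
                           x$lod$factor, x$lod$n)))
  for (tn in unique(s$treatment)) {
    ss <- s[s$treatment == tn & !is.na(s$enriched), ]
    cat(sprintf("  %s: %d/%d OTUs enriched (%.1f%%)\n", tn,
                sum(ss$enriched), nrow(ss),
                100 * mean(ss$enriched)))
  }
  invisible(x)
}

#' Summarize a Tag-SIP analysis
#'
#' @param object A [tag_sip()] fit.
#' @param ... Unused.
#' @return Object of class `summary.tagsip` with a per-treatment table
#'   (OTUs analyzed, enriched, percent, median and maximum shift, negative
#'   and no-signal flags) and the LOD calibration.
#' @export
summary.tagsip <- function(object, ...) {
  s <- object$shifts
  by_tr <- do.call(rbind, lapply(split(s, s$treatment), function(ss) {
    ok <- !is.na(ss$enriched)
    data.frame(treatment = ss$treatment[1L],
               n_otus = nrow(ss), n_called = sum(ok),
               n_enriched = sum(ss$enriched[ok]),
               percent_enriched = 100 * mean(ss$enriched[ok]),
               median_shift = stats::median(ss$delta_density, na.rm = TRUE),
               max_shift = max(ss$delta_density, na.rm = TRUE),
               n_negative = sum(ss$negative_shift),
               n_no_signal = sum(ss$no_signal),
               stringsAsFactors = FALSE)
  }))
  rownames(by_tr) <- NULL
  structure(list(treatments = by_tr, lod = object$lod,
                 params = object$params),
            class = "summary.tagsip")
}

#' @export
print.summary.tagsip <- function(x, ...) {
  cat("Tag-SIP summary\n---------------\n")
  print(x$lod)
  df <- x$treatments
  df$percent_enriched <- round(df$percent_enriched, 1)
  df$median_shift <- round(df$median_shift, 4)
  df$max_shift <- round(df$max_shift, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Extract density shifts from a Tag-SIP fit
#'
#' @param object A [tag_sip()] fit.
#' @param ... Unused.
#' @return Named numeric vector of labeled-minus-control density shifts
#'   (g/ml), named `<treatment>:<otu_id>`.
#' @export
coef.tagsip <- function(object, ...) {
  stats::setNames(object$shifts$delta_density,
                  paste(object$shifts$treatment, object$shifts$otu_id,
                        sep = ":"))
}

#' Plot paired density profiles of one OTU
#'
#' Draws the control and labeled "ratio of quantities" profiles of an OTU in
#' one treatment: control fractions as blue diamonds, labeled as red
#' squares, connected by lines, with the called peak positions marked.
#'
#' @param x A [tag_sip()] fit.
#' @param otu_id OTU to plot.
#' @param treatment Treatment name (defaults to the first in the manifest).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.tagsip <- function(x, otu_id, treatment = NULL, ...) {
  pairs <- x$manifest$pairs
  if (is.null(treatment)) treatment <- pairs$treatment[1L]
  i <- match(treatment, pairs$treatment)
  if (is.na(i)) stop("unknown treatment: ", treatment)
  pc <- x$profiles[[pairs$control[i]]][[otu_id]]
  pl <- x$profiles[[pairs$labeled[i]]][[otu_id]]
  if (is.null(pc) || is.null(pl))
    stop("OTU not analyzed: ", otu_id)
  xr <- range(pc$densities, pl$densities)
  graphics::plot(NA, xlim = rev(xr), ylim = c(0, 1.05),
                 xlab = expression(paste("Buoyant density (g ",
                                         ml^-1, ")")),
                 ylab = "Ratio of quantities",
                 main = sprintf("%s (%s)", otu_id, treatment), ...)
  graphics::lines(pc$densities, pc$ratios, col = "blue")
  graphics::points(pc$densities, pc$ratios, col = "blue", pch = 5)
  graphics::lines(pl$densities, pl$ratios, col = "red")
  graphics::points(pl$densities, pl$ratios, col = "red", pch = 15)
  row <- x$shifts[x$shifts$otu_id == otu_id &
                    x$shifts$treatment == treatment, ]
  if (nrow(row) && !is.na(row$delta_density))
    graphics::legend("topleft", bty = "n",
                     legend = c("control", "labeled",
                                sprintf("shift %+.4f g/ml%s",
                                        row$delta_density,
                                        if (isTRUE(row$enriched))
                                          " (enriched)" else "")),
                     col = c("blue", "red", NA), pch = c(5, 15, NA))
  invisible(x)
}
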