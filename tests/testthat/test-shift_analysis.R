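test_that("profiles normalize to the gradient-wise maximum (ratio of quantities)", {
  p <- make_profile(c(10, 50, 25))
  expect_equal(p$ratios, c(0.2, 1.0, 0.5))
  expect_equal(max(p$ratios), 1)

  expect_equal(make_profile(c(7, 7, 7, 7))$ratios, rep(1, 4))

  a <- make_profile(c(3, 9, 6, 1))
  b <- make_profile(2 * c(3, 9, 6, 1))
  expect_equal(a$ratios, b$ratios)   # depth cancels

  z <- make_profile(c(0, 0, 0))
  expect_true(z$no_signal)
  expect_equal(z$ratios, c(0, 0, 0))

  run <- make_run(n = 5)
  expect_error(build_profile(c(1, 2), run, "x"), "counts for")
})

test_that("peak support rules: three-fraction bands accepted, spikes rejected, bimodal secondaries found", {
  # supported peak: ratios 0.1 0.6 1.0 0.7 0.2 -> valid, support 3
  p <- make_profile(c(1, 6, 10, 7, 2))
  pk <- detect_peaks(p)
  expect_true(pk$valid)
  expect_equal(pk$method, "peak")
  expect_equal(pk$support_size, 3L)
  expect_equal(pk$mode_density, p$densities[3])

  # single-point spike -> invalid, centroid fallback at the spike density
  sp <- detect_peaks(make_profile(c(0, 0, 10, 0, 0)))
  expect_false(sp$valid)
  expect_equal(sp$method, "centroid")
  expect_equal(sp$support_size, 1L)
  expect_equal(sp$mode_density, make_profile(c(0, 0, 10, 0, 0))$densities[3])

  # bimodal: ratios 0.5 1.0 0.6 0.1 0.4 0.8 0.5 -> primary + one 3-fraction
  # secondary
  bp <- make_profile(c(5, 10, 6, 1, 4, 8, 5))
  bk <- detect_peaks(bp)
  expect_true(bk$valid)
  expect_equal(bk$support_size, 3L)
  expect_equal(nrow(bk$secondary_peaks), 1L)
  expect_equal(bk$secondary_peaks$support_size, 3L)
  expect_equal(bk$secondary_peaks$density, bp$densities[6])

  # all-zero profile -> no-signal flag, no usable call
  nz <- detect_peaks(make_profile(c(0, 0, 0, 0)))
  expect_true(nz$no_signal)
  expect_false(nz$valid)
})

test_that("peak calls are invariant to fraction order", {
  reads <- c(2, 7, 10, 8, 3, 1, 5)
  p <- make_profile(reads)
  rev_p <- structure(list(otu_id = "OTU1", gradient_id = "G1",
                          densities = rev(p$densities),
                          reads = rev(p$reads), ratios = rev(p$ratios),
                          no_signal = FALSE), class = "otu_profile")
  a <- detect_peaks(p)
  b <- detect_peaks(rev_p)
  expect_equal(b$mode_density, a$mode_density)
  expect_equal(b$refined_density, a$refined_density)
  expect_equal(b$centroid_density, a$centroid_density)
  expect_equal(b$support_size, a$support_size)
})

test_that("shifts subtract labeled minus control, like for like", {
  ctrl <- detect_peaks(make_profile(c(1, 5, 10, 5, 1), dmax = 1.704))
  lab <- detect_peaks(make_profile(c(1, 5, 10, 5, 1), dmax = 1.708))
  expect_equal(ctrl$mode_density, 1.700)
  expect_equal(as.vector(compute_shift(ctrl, lab)), 0.004)

  expect_equal(as.vector(compute_shift(ctrl, ctrl)), 0)  # identity

  neg <- compute_shift(lab, ctrl)
  expect_equal(as.vector(neg), -0.004)                   # sign preserved

  # mixed valid/invalid -> centroid-vs-centroid for both sides
  spike <- detect_peaks(make_profile(c(0, 0, 10, 0, 0), dmax = 1.708))
  mix <- compute_shift(ctrl, spike)
  expect_equal(attr(mix, "method"), "centroid")
  expect_equal(as.vector(mix), spike$centroid_density - ctrl$centroid_density)

  # no signal on either side -> undefined shift
  nz <- detect_peaks(make_profile(c(0, 0, 0, 0, 0)))
  expect_true(is.na(compute_shift(ctrl, nz)))

  # normalization cancels depth: scaling one gradient's counts changes nothing
  lab7 <- detect_peaks(make_profile(7 * c(1, 5, 10, 5, 1), dmax = 1.708))
  expect_equal(as.vector(compute_shift(ctrl, lab7)), 0.004)
})

test_that("secondary peaks can carry the shift for bimodal labeled profiles", {
  # fraction order is densest-first, so the main band sits late in the vector
  ctrl <- detect_peaks(make_profile(c(0, 0, 1, 4, 8, 10, 7, 3), dmax = 1.714))
  # labeled: dominant subpopulation unshifted, active subset banding denser
  lab <- detect_peaks(make_profile(c(4, 7, 4, 4, 8, 10, 7, 3), dmax = 1.714))
  expect_equal(nrow(lab$secondary_peaks), 1L)
  primary_only <- compute_shift(ctrl, lab)
  with_sub <- compute_shift(ctrl, lab, use_secondary = TRUE)
  expect_equal(as.vector(primary_only), 0)
  expect_gt(as.vector(with_sub), 0)
})

test_that("LOD calibration implements the 1.5-x-largest-null-shift rule", {
  lod <- suppressWarnings(calibrate_lod(c(0, 0.001, 0.002), min_n = 3))
  expect_equal(lod$cutoff, 0.003)
  expect_equal(lod$mean, 0.001)
  expect_equal(lod$sd, sd(c(0, 0.001, 0.002)))   # n-1 denominator
  expect_equal(lod$n, 3L)
  expect_equal(lod$max_abs, 0.002)

  # cutoff scales linearly with the factor
  set.seed(9)
  s <- rnorm(40, 0, 5e-4)
  f1 <- calibrate_lod(s, factor = 1.5)
  f2 <- calibrate_lod(s, factor = 3.0)
  expect_equal(f2$cutoff, 2 * f1$cutoff)

  # the null-distribution distance of the published-style calibration:
  # cutoff 0.003 with null mean 4e-4 and SD 7e-4 sits ~3.7 SD out
  expect_equal(lod_sd_distance(0.003, 4e-4, 7e-4), 3.714286,
               tolerance = 1e-6)
  expect_equal(f1$sd_distance, (f1$cutoff - mean(s)) / sd(s))

  expect_error(calibrate_lod(rep(0, 20)), class = "tagsip_degenerate_null")
  expect_warning(calibrate_lod(c(0, 1e-3), min_n = 10), "low-n")
})

test_that("enrichment calls use an inclusive cutoff and flag negatives", {
  lod <- manual_lod(0.003)
  expect_true(call_enrichment(0.003, lod))     # boundary is enriched
  expect_false(call_enrichment(0.002, lod))    # largest null-type shift is not
  expect_false(call_enrichment(-0.004, lod))
  expect_true(is.na(call_enrichment(NA_real_, lod)))
  expect_equal(call_enrichment(c(0.004, 0.001), 0.003), c(TRUE, FALSE))
})

test_that("clade summaries tally enrichment fractions per lineage", {
  tax <- data.frame(
    otu_id = sprintf("o%02d", 1:14),
    lineage = c(rep("Bacteria;P;C;O;FlavoF;G", 10),
                rep("Bacteria;P;C;O;OtherF;G", 4)))
  res <- data.frame(otu_id = tax$otu_id,
                    enriched = c(rep(TRUE, 9), FALSE, rep(FALSE, 4)))
  cs <- summarize_clades(res, tax, rank = "family")
  expect_equal(cs$percent_enriched[cs$clade == "FlavoF"], 90)
  expect_equal(cs$percent_enriched[cs$clade == "OtherF"], 0)
  expect_equal(cs$n_otus[cs$clade == "(all)"], 14L)
  expect_equal(cs$n_enriched[cs$clade == "(all)"], 9L)

  # independent group-by oracle on a random mixed taxonomy
  set.seed(3)
  tax2 <- data.frame(otu_id = sprintf("x%02d", 1:30),
                     lineage = sprintf("B;P;C;O;Fam%d;G", sample(1:4, 30,
                                                                 TRUE)))
  res2 <- data.frame(otu_id = tax2$otu_id, enriched = runif(30) < 0.4)
  cs2 <- summarize_clades(res2, tax2, rank = "family")
  fam <- lineage_at_rank(tax2$lineage, "family")
  for (f in unique(fam)) {
    expect_equal(cs2$n_otus[cs2$clade == f], sum(fam == f))
    expect_equal(cs2$n_enriched[cs2$clade == f],
                 sum(res2$enriched[fam == f]))
  }
  # OTUs missing from the taxonomy fall into "unclassified"
  res3 <- rbind(res2, data.frame(otu_id = "mystery", enriched = TRUE))
  cs3 <- summarize_clades(res3, tax2, rank = "family")
  expect_equal(cs3$n_otus[cs3$clade == "unclassified"], 1L)
})
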