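test_that("buoyant density follows the linear GC + isotope relation", {
  expect_equal(buoyant_density(0.5), 1.709)
  expect_equal(buoyant_density(0.5, 1), 1.725)
  # linearity: excess 0.25 sits exactly 0.004 above unlabeled
  expect_equal(buoyant_density(0.37, 0.25) - buoyant_density(0.37), 0.004)
  expect_error(buoyant_density(1.5), "gc")
})

test_that("simulated gradients conserve reads and band where told to", {
  cfg <- sim_config(reads_per_gradient = 5e4, seed = 21)
  cm <- sim_community(15, seed = 21)
  g <- simulate_gradient(cm, "control", "G1", cfg)
  expect_equal(sum(g$counts), 5e4)                 # multinomial conservation
  expect_equal(ncol(g$counts), cfg$n_select)
  expect_equal(sum(g$run$fractions$sequenced), cfg$n_select)

  # band_sd -> 0: a single OTU's reads collapse into the fraction holding
  # its band center
  cfg0 <- sim_config(reads_per_gradient = 1e4, band_sd = 1e-6, seed = 5)
  one <- sim_community(1, seed = 5)
  g0 <- simulate_gradient(one, "control", "G0", cfg0)
  expect_equal(sum(g0$counts > 0), 1L)
  expect_equal(sum(g0$counts), 1e4)
  hot <- g0$run$fractions$density[g0$run$fractions$sequenced][which(g0$counts > 0)]
  expect_lt(abs(hot - buoyant_density(one$gc)), 0.0022 / 2 + 1e-9)

  # a band center too close to the gradient edge is flagged
  edge <- sim_community(1, gc_range = c(0.0, 0.01), seed = 2)
  expect_warning(simulate_gradient(edge, "control", "GE", cfg),
                 "band truncated")
})

test_that("paired experiments are byte-deterministic under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    cm <- sim_community(20, seed = 33)
    cm$atom_fraction_excess <- rep(c(0.5, 0), 10)
    generate_paired_experiment(cm, list(
      assay = list(substrate = "nitrate", excess = "community"),
      nullrun = list(substrate = "nitrate", excess = "null")),
      sim_config(seed = 33, reads_per_gradient = 2e4), dir = d)
  }
  f1 <- list.files(d1)
  expect_setequal(f1, c("fractions.tsv", "otu_counts.tsv", "taxonomy.tsv",
                        "manifest.yml", "truth.tsv"))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("per-gradient substreams are independent of other treatments", {
  cm <- sim_community(20, seed = 8)
  cm$atom_fraction_excess <- rep(c(0.4, 0), 10)
  cfg <- sim_config(seed = 8, reads_per_gradient = 2e4)
  a <- generate_paired_experiment(cm, list(
    assay = list(substrate = "nitrate", excess = "community")), cfg)
  b <- generate_paired_experiment(cm, list(
    assay = list(substrate = "nitrate", excess = "community"),
    extra = list(substrate = "ammonium", excess = 0.2)), cfg)
  expect_identical(
    a$counts$counts[, a$counts$gradient_id == "assay_labeled"],
    b$counts$counts[, b$counts$gradient_id == "assay_labeled"])
})

test_that("simulator outputs parse cleanly through the readers, warning-free", {
  d <- withr::local_tempdir()
  x <- small_experiment(n_otus = 20, seed = 13, reads = 2e4, dir = d,
                        n_labeled = 10)
  expect_no_warning({
    runs <- read_fraction_metadata(file.path(d, "fractions.tsv"))
    tab <- read_otu_table(file.path(d, "otu_counts.tsv"))
    tax <- read_taxonomy(file.path(d, "taxonomy.tsv"))
    man <- read_manifest(file.path(d, "manifest.yml"))
    align_otu_table(tab, runs)
  })
  expect_length(runs, 4)
  expect_equal(nrow(tab$counts), 20)
  expect_equal(man$null_treatment, "nullrun")
  # written tables match the in-memory objects
  expect_equal(tab$counts, x$sim$counts$counts)
})

test_that("the truth table records imposed centers and shifts", {
  cm <- sim_community(4, seed = 19)
  cm$atom_fraction_excess <- c(0.25, 0, 0.5, 0)
  cm <- set_subpopulations(cm, cm$otu_id[4], weights = c(0.6, 0.4),
                           excess = c(0, 0.5))
  cfg <- sim_config(seed = 19, reads_per_gradient = 1e4)
  sim <- generate_paired_experiment(cm, list(
    assay = list(substrate = "nitrate", excess = "community")), cfg)
  tr <- sim$truth
  expect_equal(tr$true_shift[tr$otu_id == cm$otu_id[1]], 0.004)  # 0.25 x 0.016
  expect_equal(tr$true_shift[tr$otu_id == cm$otu_id[2]], 0)
  # bimodal OTU: dominant (inactive) subpopulation defines the labeled
  # center; the active subset bands 0.008 g/ml denser
  r4 <- tr[tr$otu_id == cm$otu_id[4], ]
  expect_equal(r4$true_shift, 0)
  expect_equal(r4$true_center_secondary - r4$true_center_labeled, 0.008)

  # a null-style treatment imposes only sub-detection shifts
  simn <- generate_paired_experiment(cm, list(
    nullrun = list(substrate = "nitrate", excess = "null")), cfg)
  expect_true(all(abs(simn$truth$true_shift) < 0.002))
})
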