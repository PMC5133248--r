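# Shared fixture builders; everything is generated in code.

# A gradient run with strictly decreasing density (fraction 1 densest).
make_run <- function(id = "G1", n = 50, dmax = 1.77, dmin = 1.66,
                     dna = NULL, sequenced = TRUE) {
  d <- seq(dmax, dmin, length.out = n)
  gradient_run(id, data.frame(
    fraction_index = seq_len(n), density = round(d, 6),
    dna_quantity = if (is.null(dna)) rep(1, n) else dna,
    sequenced = sequenced))
}

# A profile over an even density grid, given read counts in fraction order
# (densest first).
make_profile <- function(reads, dmax = 1.72, step = 0.002,
                         otu_id = "OTU1", id = "G1") {
  n <- length(reads)
  run <- make_run(id, n = n, dmax = dmax, dmin = dmax - step * (n - 1))
  build_profile(reads, run, otu_id)
}

# A small complete simulated experiment (one labeled + one null treatment).
small_experiment <- function(n_otus = 40, seed = 11, reads = 4e5,
                             dir = NULL, n_labeled = n_otus / 2) {
  cm <- sim_community(n_otus, seed = seed)
  cm$atom_fraction_excess <- c(stats::runif(n_labeled, 0.3, 1),
                               rep(0, n_otus - n_labeled))
  cfg <- sim_config(seed = seed, reads_per_gradient = reads)
  sim <- generate_paired_experiment(cm, list(
    assay = list(substrate = "nitrate", excess = "community"),
    nullrun = list(substrate = "nitrate", excess = "null")),
    cfg, dir = dir)
  list(community = cm, cfg = cfg, sim = sim)
}
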