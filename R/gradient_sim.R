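#' Simulator configuration
#'
#' Parameters of the gradient simulator: fraction collection, the GC-to-
#' density relation, band width, sequencing depth and the RNG seed. The
#' defaults emulate a 50-fraction CsCl gradient spanning 1.66-1.77 g/ml
#' (0.0022 g/ml per fraction) of which the 20 highest-DNA contiguous
#' fractions are sequenced, with Gaussian DNA bands of SD 0.004 g/ml and
#' 10^6 amplicon reads per gradient.
#'
#' @param n_fractions Fractions collected per gradient (default 50).
#' @param density_min,density_max Density window of the gradient, g/ml
#'   (defaults 1.66 and 1.77).
#' @param band_sd Gaussian band SD in density units, g/ml (default 0.004).
#' @param reads_per_gradient Total amplicon reads per gradient, distributed
#'   multinomially over the sequenced fractions (default 1e6).
#' @param n_select Fractions selected for sequencing (default 20).
#' @param gc_intercept,gc_slope Linear GC-to-buoyant-density relation, g/ml
#'   (defaults 1.660 and 0.098).
#' @param delta_max_15N Full-label 15N density gain, g/ml (default 0.016).
#' @param dna_noise_sd Lognormal (sdlog) noise on per-fraction DNA quantity
#'   (default 0.10).
#' @param dna_scale Total DNA per gradient, ng (default 750).
#' @param seed Experiment seed; per-gradient substreams are derived from it
#'   deterministically, so adding a treatment never perturbs earlier
#'   gradients.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_fractions = 50L, density_min = 1.66,
                       density_max = 1.77, band_sd = 0.004,
                       reads_per_gradient = 1e6, n_select = 20L,
                       gc_intercept = 1.660, gc_slope = 0.098,
                       delta_max_15N = 0.016, dna_noise_sd = 0.10,
                       dna_scale = 750, seed = 1L) {
  stopifnot(density_max > density_min, band_sd > 0,
            n_fractions >= n_select, reads_per_gradient >= 1)
  structure(list(n_fractions = as.integer(n_fractions),
                 density_min = density_min, density_max = density_max,
                 band_sd = band_sd,
                 reads_per_gradient = as.integer(reads_per_gradient),
                 n_select = as.integer(n_select),
                 gc_intercept = gc_intercept, gc_slope = gc_slope,
                 delta_max_15N = delta_max_15N,
                 dna_noise_sd = dna_noise_sd, dna_scale = dna_scale,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic 31-bit substream seed from the experiment seed and a label.
.gradient_seed <- function(seed, id) {
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Buoyant density of DNA from GC content and isotope incorporation
#'
#' The classical linear GC relation plus a linear isotope term:
#' `intercept + slope * gc + excess * delta_max_15N`.
#'
#' @param gc GC content as a fraction in \[0, 1\].
#' @param atom_fraction_excess 15N atom fraction excess in \[0, 1\].
#' @param cfg A [sim_config()] supplying the constants.
#' @return Buoyant density, g/ml (vectorized).
#' @examples
#' buoyant_density(0.5)          # 1.709
#' buoyant_density(0.5, 1)       # 1.725
#' @export
buoyant_density <- function(gc, atom_fraction_excess = 0,
                            cfg = sim_config()) {
  stopifnot(all(gc >= 0 & gc <= 1),
            all(atom_fraction_excess >= 0 & atom_fraction_excess <= 1))
  cfg$gc_intercept + cfg$gc_slope * gc +
    atom_fraction_excess * cfg$delta_max_15N
}

.marine_lineages <- c(
  "Bacteria;Proteobacteria;Alphaproteobacteria;Pelagibacterales;SAR11;SAR11",
  "Bacteria;Proteobacteria;Gammaproteobacteria;Oceanospirillales;SAR86;SAR86",
  "Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales;Flavobacteriaceae;Flavobacterium",
  "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales;Rhodobacteraceae;Roseobacter",
  "Bacteria;Cyanobacteria;Cyanobacteria;Synechococcales;Cyanobiaceae;Prochlorococcus",
  "Bacteria;Cyanobacteria;Cyanobacteria;Synechococcales;Cyanobiaceae;Synechococcus",
  "Archaea;Euryarchaeota;Thermoplasmata;MarineGroupII;MG-IIa;MG-IIa",
  "Archaea;Euryarchaeota;Thermoplasmata;MarineGroupII;MG-IIb;MG-IIb")

#' Build a simulated community
#'
#' A data.frame of simulated OTUs: GC content (uniform over `gc_range`, the
#' mid-GC band where a mixed marine community's DNA concentrates), relative
#' abundance (equal by default), per-OTU 15N atom fraction excess and a
#' lineage cycled over a small set of marine clades. A `subpops` list column
#' (all `NULL` by default) can impose bimodal banding via
#' [set_subpopulations()].
#'
#' @param n_otus Number of OTUs (default 100).
#' @param gc_range Range of GC content (default `c(0.40, 0.55)`).
#' @param atom_fraction_excess Per-OTU excess, recycled (default 0).
#' @param rel_abundance Relative abundances (normalized to sum 1); equal by
#'   default.
#' @param lineage Lineage strings, recycled; defaults to a built-in marine
#'   clade set.
#' @param seed Optional seed for the GC draw.
#' @return data.frame of class `sim_community`.
#' @export
sim_community <- function(n_otus = 100L, gc_range = c(0.40, 0.55),
                          atom_fraction_excess = 0, rel_abundance = NULL,
                          lineage = NULL, seed = NULL) {
  n_otus <- as.integer(n_otus)
  if (!is.null(seed)) set.seed(seed)
  gc <- stats::runif(n_otus, gc_range[1], gc_range[2])
  rel <- if (is.null(rel_abundance)) rep(1 / n_otus, n_otus)
         else rel_abundance / sum(rel_abundance)
  stopifnot(length(rel) == n_otus)
  cm <- data.frame(otu_id = sprintf("OTU%04d", seq_len(n_otus)),
                   gc = gc, rel_abundance = rel,
                   atom_fraction_excess =
                     rep_len(atom_fraction_excess, n_otus),
                   lineage = rep_len(if (is.null(lineage)) .marine_lineages
                                     else lineage, n_otus),
                   stringsAsFactors = FALSE)
  cm$subpops <- vector("list", n_otus)
  class(cm) <- c("sim_community", "data.frame")
  cm
}

#' Impose subpopulations on a simulated OTU
#'
#' Splits an OTU into weighted subpopulations with distinct atom fraction
#' excess, producing bimodal banding in the labeled gradient (a
#' differentially active subset of the population).
#'
#' @param community A [sim_community()].
#' @param otu_id OTU to split.
#' @param weights Subpopulation weights (normalized to sum 1).
#' @param excess Atom fraction excess per subpopulation.
#' @return The modified community.
#' @export
set_subpopulations <- function(community, otu_id, weights, excess) {
  stopifnot(length(weights) == length(excess), all(weights > 0),
            all(excess >= 0 & excess <= 1))
  i <- match(otu_id, community$otu_id)
  if (is.na(i)) stop("unknown otu_id: ", otu_id)
  community$subpops[[i]] <- data.frame(weight = weights / sum(weights),
                                       atom_fraction_excess = excess)
  community
}

# Band components (weight, excess) of one OTU for a given treatment.
.otu_components <- function(community, i, treatment) {
  sp <- community$subpops[[i]]
  if (is.null(sp))
    sp <- data.frame(weight = 1,
                     atom_fraction_excess =
                       community$atom_fraction_excess[i])
  if (treatment == "control") sp$atom_fraction_excess <- 0
  sp
}

#' Simulate one gradient
#'
#' Isopycnic banding of a community in one CsCl gradient: each OTU (or
#' subpopulation) contributes Gaussian band mass `N(center, band_sd^2)`
#' integrated over each fraction's density interval, where the center comes
#' from [buoyant_density()] (isotope term zeroed in controls). Per-fraction
#' DNA quantity is the community band mass with lognormal noise; the
#' sequencing window is then chosen with [select_fractions()] and
#' `reads_per_gradient` reads are drawn multinomially over the selected
#' fractions with expected proportions proportional to relative abundance
#' times band mass. Fraction boundaries are uniform in density and fraction
#' 1 is the densest.
#'
#' @param community A [sim_community()].
#' @param treatment `"control"` (isotope term zeroed) or `"labeled"`.
#' @param gradient_id Identifier for the simulated gradient.
#' @param cfg A [sim_config()].
#' @param substrate Substrate label recorded on the run.
#' @return List with elements `run` (a [gradient_run()] with the sequencing
#'   window flagged), `counts` (OTU x selected-fraction integer matrix) and
#'   `centers` (per-component true band centers).
#' @export
simulate_gradient <- function(community, treatment = c("control", "labeled"),
                              gradient_id, cfg = sim_config(),
                              substrate = NA_character_) {
  treatment <- match.arg(treatment)
  stopifnot(inherits(community, "sim_community"), nrow(community) >= 1L)
  set.seed(.gradient_seed(cfg$seed, gradient_id))
  n <- cfg$n_fractions
  edges <- seq(cfg$density_max, cfg$density_min, length.out = n + 1L)
  upper <- edges[-(n + 1L)]
  lower <- edges[-1L]
  mid <- (upper + lower) / 2

  n_otu <- nrow(community)
  M <- matrix(0, n_otu, n)           # expected band mass, otu x fraction
  centers <- NULL
  for (i in seq_len(n_otu)) {
    sp <- .otu_components(community, i, treatment)
    ctr <- buoyant_density(community$gc[i], sp$atom_fraction_excess, cfg)
    if (any(ctr - 3 * cfg$band_sd < cfg$density_min |
            ctr + 3 * cfg$band_sd > cfg$density_max))
      warning(sprintf("band truncated: OTU %s center outside +/-3 SD window of the gradient",
                      community$otu_id[i]))
    for (k in seq_along(ctr)) {
      mass <- stats::pnorm(upper, ctr[k], cfg$band_sd) -
        stats::pnorm(lower, ctr[k], cfg$band_sd)
      M[i, ] <- M[i, ] + sp$weight[k] * mass
    }
    centers <- rbind(centers, data.frame(
      otu_id = community$otu_id[i], component = seq_along(ctr),
      weight = sp$weight, center = ctr, stringsAsFactors = FALSE))
  }
  M <- M * community$rel_abundance

  dna_total <- colSums(M)
  dna <- round(cfg$dna_scale * dna_total / sum(dna_total) *
                 stats::rlnorm(n, 0, cfg$dna_noise_sd), 3)
  run <- gradient_run(gradient_id,
                      data.frame(fraction_index = seq_len(n),
                                 density = round(mid, 4),
                                 dna_quantity = dna, sequenced = TRUE),
                      treatment = treatment, substrate = substrate)
  run <- select_fractions(run, cfg$n_select)
  sel <- which(run$fractions$sequenced)

  P <- M[, sel, drop = FALSE]
  p <- as.vector(P)
  reads <- stats::rmultinom(1L, cfg$reads_per_gradient, p / sum(p))
  counts <- matrix(as.integer(reads), n_otu, length(sel),
                   dimnames = list(community$otu_id, NULL))
  list(run = run, counts = counts, fraction_index = sel, centers = centers)
}

# Null-treatment excess draw: half-normal, scaled so imposed shifts sit well
# below one fraction spacing (sd 0.0002 g/ml) and truncated below the
# detectable range (< 0.002 g/ml).
.null_excess <- function(n, cfg) {
  sd_excess <- 0.0002 / cfg$delta_max_15N
  pmin(abs(stats::rnorm(n, 0, sd_excess)), 0.002 / cfg$delta_max_15N * 0.99)
}

#' Generate a complete paired Tag-SIP experiment
#'
#' Simulates, for each treatment, a control gradient (isotope term zeroed)
#' and a labeled gradient, and writes the full gradient_io input set --
#' fraction metadata, OTU count table, taxonomy, pairing manifest -- plus a
#' `truth.tsv` of imposed band centers and shifts.
#'
#' Each treatment is a list with elements `substrate` and `excess`, where
#' `excess` is one of: `"community"` (use the community's per-OTU excess and
#' any subpopulations), `"null"` (draw small excess emulating an undetectable
#' null treatment: half-normal imposed shifts of SD 0.0002 g/ml truncated
#' below 0.002 g/ml), or a numeric vector recycled over OTUs. A treatment
#' may set `is_null = TRUE` to be named the manifest's null treatment
#' (implied by `excess = "null"`).
#'
#' @param community A [sim_community()].
#' @param treatments Named list of treatment descriptions (see Details).
#' @param cfg A [sim_config()]; all randomness derives from `cfg$seed`.
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @return Invisibly, a list with the simulated `runs`, `counts`
#'   ([otu_table()]), `taxonomy`, `manifest`, `truth` data.frame and, when
#'   written, the file `paths`.
#' @export
generate_paired_experiment <- function(community, treatments,
                                       cfg = sim_config(), dir = NULL) {
  stopifnot(inherits(community, "sim_community"), length(treatments) >= 1L,
            !is.null(names(treatments)), all(nzchar(names(treatments))))
  runs <- list()
  blocks <- list()
  fidx <- list()
  pairs <- NULL
  truth <- NULL
  null_name <- NA_character_

  for (tn in names(treatments)) {
    tr <- treatments[[tn]]
    comm_t <- community
    is_null <- isTRUE(tr$is_null)
    ex <- tr$excess
    if (is.character(ex) && length(ex) == 1L) {
      if (ex == "null") {
        set.seed(.gradient_seed(cfg$seed, paste0(tn, "/excess")))
        comm_t$atom_fraction_excess <- .null_excess(nrow(comm_t), cfg)
        comm_t$subpops <- vector("list", nrow(comm_t))
        is_null <- TRUE
      } else if (ex != "community") {
        stop("treatment excess must be 'community', 'null' or numeric")
      }
    } else if (is.numeric(ex)) {
      comm_t$atom_fraction_excess <- rep_len(ex, nrow(comm_t))
    } else if (!is.null(ex)) {
      stop("treatment excess must be 'community', 'null' or numeric")
    }
    if (is_null) {
      if (!is.na(null_name))
        stop("more than one null treatment specified")
      null_name <- tn
    }

    cid <- paste0(tn, "_control")
    lid <- paste0(tn, "_labeled")
    sub <- if (is.null(tr$substrate)) "other" else tr$substrate
    g_c <- simulate_gradient(comm_t, "control", cid, cfg, substrate = sub)
    g_l <- simulate_gradient(comm_t, "labeled", lid, cfg, substrate = sub)
    runs[[cid]] <- g_c$run
    runs[[lid]] <- g_l$run
    blocks[[cid]] <- g_c$counts
    blocks[[lid]] <- g_l$counts
    fidx[[cid]] <- g_c$fraction_index
    fidx[[lid]] <- g_l$fraction_index
    pairs <- rbind(pairs, data.frame(labeled = lid, control = cid,
                                     treatment = tn,
                                     stringsAsFactors = FALSE))

    ctr_c <- g_c$centers
    ctr_l <- g_l$centers
    tt <- do.call(rbind, lapply(unique(ctr_l$otu_id), function(o) {
      lc <- ctr_l[ctr_l$otu_id == o, , drop = FALSE]
      dom <- which.max(lc$weight)
      sec <- if (nrow(lc) > 1L) lc$center[-dom][1L] else NA_real_
      cc <- ctr_c$center[ctr_c$otu_id == o][1L]
      data.frame(otu_id = o, treatment = tn,
                 true_center_control = cc,
                 true_center_labeled = lc$center[dom],
                 true_center_secondary = sec,
                 true_shift = lc$center[dom] - cc,
                 stringsAsFactors = FALSE)
    }))
    truth <- rbind(truth, tt)
  }

  gid_vec <- unlist(lapply(names(runs), function(g)
    rep(g, length(fidx[[g]]))))
  fr_vec <- unlist(fidx[names(runs)])
  counts <- otu_table(do.call(cbind, blocks[names(runs)]), gid_vec, fr_vec)
  taxonomy <- data.frame(otu_id = community$otu_id,
                         lineage = community$lineage,
                         stringsAsFactors = FALSE)
  man <- manifest(pairs, null_treatment = null_name)

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(metadata = file.path(dir, "fractions.tsv"),
               counts = file.path(dir, "otu_counts.tsv"),
               taxonomy = file.path(dir, "taxonomy.tsv"),
               manifest = file.path(dir, "manifest.yml"),
               truth = file.path(dir, "truth.tsv"))
    hdr <- sprintf("tagsip simulator\tseed=%d", cfg$seed)
    write_fraction_metadata(runs, paths[["metadata"]], header = hdr)
    write_otu_table(counts, paths[["counts"]], header = hdr)
    write_taxonomy(taxonomy, paths[["taxonomy"]])
    write_manifest(man, paths[["manifest"]])
    tout <- truth
    for (k in c("true_center_control", "true_center_labeled",
                "true_center_secondary", "true_shift"))
      tout[[k]] <- .num_fmt(tout[[k]])
    utils::write.table(tout, paths[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(runs = runs, counts = counts, taxonomy = taxonomy,
                 manifest = man, truth = truth, paths = paths))
}
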