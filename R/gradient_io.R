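#' Construct a gradient run
#'
#' A `gradient_run` holds the fraction-level record of one CsCl gradient:
#' fraction index, buoyant density, DNA quantity and whether the fraction was
#' (or is to be) sequenced. Fraction index 1 is the first fraction collected,
#' i.e. the densest material displaced from the bottom of the tube, so density
#' must decrease strictly with increasing index; this is validated, not
#' assumed.
#'
#' @param gradient_id Single string identifying the gradient. Must not
#'   contain `":"` (reserved as the separator in OTU-table column names).
#' @param fractions data.frame with columns `fraction_index` (integer, >= 1),
#'   `density` (g/ml), `dna_quantity` (ng, or any quantity proportional to
#'   recovered DNA) and `sequenced` (logical).
#' @param treatment Optional treatment label (`"control"` or `"labeled"`).
#' @param substrate Optional substrate label (e.g. `"ammonium"`, `"nitrate"`).
#'
#' @return An object of class `gradient_run`.
#' @examples
#' fr <- data.frame(fraction_index = 1:5, density = seq(1.74, 1.70, by = -0.01),
#'                  dna_quantity = c(1, 5, 9, 4, 1), sequenced = TRUE)
#' gradient_run("G1", fr)
#' @export
gradient_run <- function(gradient_id, fractions,
                         treatment = NA_character_, substrate = NA_character_) {
  stopifnot(is.character(gradient_id), length(gradient_id) == 1L,
            is.data.frame(fractions))
  if (grepl(":", gradient_id, fixed = TRUE))
    stop("gradient_id must not contain ':'")
  need <- c("fraction_index", "density", "dna_quantity", "sequenced")
  miss <- setdiff(need, names(fractions))
  if (length(miss))
    stop("fractions is missing column(s): ", paste(miss, collapse = ", "))
  fr <- fractions[order(fractions$fraction_index), need, drop = FALSE]
  rownames(fr) <- NULL
  fr$fraction_index <- as.integer(fr$fraction_index)
  fr$sequenced <- as.logical(fr$sequenced)
  if (any(fr$fraction_index < 1L))
    stop(sprintf("gradient '%s': fraction_index must be >= 1", gradient_id))
  if (anyDuplicated(fr$fraction_index))
    stop(sprintf("gradient '%s': duplicate fraction_index", gradient_id))
  if (nrow(fr) < 3L)
    stop(sprintf("gradient '%s': a gradient needs at least 3 fractions",
                 gradient_id))
  dd <- diff(fr$density)
  if (any(dd >= 0)) {
    at <- fr$fraction_index[which(dd >= 0)[1L] + 1L]
    stop(sprintf(paste0(
      "gradient '%s': density must decrease strictly with fraction_index ",
      "(fraction 1 is displaced first from the dense bottom of the tube); ",
      "inversion at fraction_index %d"), gradient_id, at))
  }
  out <- fr$density < 1.60 | fr$density > 1.80
  if (any(out))
    warning(sprintf(
      "gradient '%s': %d fraction(s) with density outside [1.60, 1.80] g/ml",
      gradient_id, sum(out)))
  structure(list(gradient_id = gradient_id, treatment = treatment,
                 substrate = substrate, fractions = fr),
            class = "gradient_run")
}

#' @export
print.gradient_run <- function(x, ...) {
  fr <- x$fractions
  cat(sprintf("Gradient '%s'%s: %d fractions, %.4f-%.4f g/ml, %d sequenced\n",
              x$gradient_id,
              if (is.na(x$treatment)) "" else paste0(" (", x$treatment, ")"),
              nrow(fr), max(fr$density), min(fr$density), sum(fr$sequenced)))
  invisible(x)
}

# Sniff the field separator of a text table (tab wins over comma).
.read_table_auto <- function(path) {
  l1 <- readLines(path, n = 1L)
  sep <- if (grepl("\t", l1, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

.num_fmt <- function(x) {
  # enough significant digits to round-trip the values we write
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

#' Read fraction metadata into gradient runs
#'
#' Reads a CSV/TSV file with columns `gradient_id`, `fraction_index`,
#' `density_g_ml`, `dna_quantity` and `sequenced` (0/1), groups rows into one
#' [gradient_run()] per gradient, and validates monotonicity of density and
#' uniqueness of fraction indices.
#'
#' @param path Path to the metadata file (separator is sniffed: tab or comma).
#' @return Named list of `gradient_run` objects, in order of first appearance.
#' @seealso [write_fraction_metadata()]
#' @export
read_fraction_metadata <- function(path) {
  tab <- .read_table_auto(path)
  need <- c("gradient_id", "fraction_index", "density_g_ml", "dna_quantity",
            "sequenced")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("fraction metadata is missing column(s): ",
         paste(miss, collapse = ", "))
  key <- paste(tab$gradient_id, tab$fraction_index)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (gradient_id, fraction_index) row: ", d)
  }
  ids <- unique(as.character(tab$gradient_id))
  runs <- lapply(ids, function(g) {
    rows <- tab[tab$gradient_id == g, , drop = FALSE]
    gradient_run(g, data.frame(fraction_index = rows$fraction_index,
                               density = rows$density_g_ml,
                               dna_quantity = rows$dna_quantity,
                               sequenced = rows$sequenced != 0))
  })
  names(runs) <- ids
  runs
}

#' Write fraction metadata
#'
#' Inverse of [read_fraction_metadata()]; a read/write cycle is the identity
#' on the parsed objects.
#'
#' @param runs A `gradient_run` or list of them.
#' @param path Output path; written tab-separated with a `sequenced` 0/1
#'   column.
#' @param header Optional comment line(s) written before the table (each
#'   prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_fraction_metadata <- function(runs, path, header = NULL) {
  if (inherits(runs, "gradient_run")) runs <- list(runs)
  rows <- do.call(rbind, lapply(runs, function(r) {
    fr <- r$fractions
    data.frame(gradient_id = r$gradient_id,
               fraction_index = fr$fraction_index,
               density_g_ml = .num_fmt(fr$density),
               dna_quantity = .num_fmt(fr$dna_quantity),
               sequenced = as.integer(fr$sequenced),
               stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an OTU count table
#'
#' Counts of reads per OTU per sequenced gradient fraction. Columns are
#' addressed by (gradient id, fraction index) pairs.
#'
#' @param counts Integer matrix, rows named by OTU id.
#' @param gradient_id Character vector, one gradient id per column.
#' @param fraction_index Integer vector, one fraction index per column.
#' @return Object of class `otu_table`.
#' @export
otu_table <- function(counts, gradient_id, fraction_index) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0L) stop("counts must have OTU ids as row names")
    rownames(counts) <- character(0)
  }
  stopifnot(length(gradient_id) == ncol(counts),
            length(fraction_index) == ncol(counts))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "double"
  colnames(counts) <- paste0(gradient_id, ":", fraction_index)
  structure(list(counts = counts,
                 gradient_id = as.character(gradient_id),
                 fraction_index = as.integer(fraction_index)),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU count table: %d OTUs x %d fraction samples (%d gradients), %s reads\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$gradient_id)),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Read an OTU count table
#'
#' Tab-separated file whose first column is `otu_id` and whose remaining
#' columns are named `<gradient_id>:<fraction_index>`.
#'
#' @param path Path to the TSV file.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (names(tab)[1L] != "otu_id")
    stop("first column of an OTU table must be 'otu_id'")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicate otu_id in OTU table")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  mode(m) <- "double"
  rownames(m) <- ids
  parts <- strsplit(colnames(m), ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("malformed OTU table column name(s): ",
         paste(colnames(m)[bad], collapse = ", "),
         " (expected '<gradient_id>:<fraction_index>')")
  otu_table(m,
            gradient_id = vapply(parts, `[`, "", 1L),
            fraction_index = as.integer(vapply(parts, `[`, "", 2L)))
}

#' Write an OTU count table
#'
#' @param table An [otu_table()].
#' @param path Output path (tab-separated).
#' @param header Optional comment line(s), `#`-prefixed.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, header = NULL) {
  stopifnot(inherits(table, "otu_table"))
  df <- data.frame(otu_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Tab-separated file with columns `otu_id` and `lineage`, the latter a
#' semicolon-delimited rank string (domain;phylum;class;order;family;genus).
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `otu_id`, `lineage`.
#' @export
read_taxonomy <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  miss <- setdiff(c("otu_id", "lineage"), names(tab))
  if (length(miss))
    stop("taxonomy table is missing column(s): ", paste(miss, collapse = ", "))
  tab[, c("otu_id", "lineage")]
}

#' Write a taxonomy table
#'
#' @param taxonomy data.frame with columns `otu_id`, `lineage`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy[, c("otu_id", "lineage")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the clade name at a taxonomic rank
#'
#' @param lineage Character vector of semicolon-delimited lineages.
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return Character vector of clade names; missing or empty ranks become
#'   `"unclassified"`.
#' @export
lineage_at_rank <- function(lineage,
                            rank = c("domain", "phylum", "class", "order",
                                     "family", "genus")) {
  rank <- match.arg(rank)
  pos <- match(rank, c("domain", "phylum", "class", "order", "family",
                       "genus"))
  vapply(strsplit(as.character(lineage), ";", fixed = TRUE), function(p) {
    p <- trimws(p)
    if (length(p) >= pos && nzchar(p[pos])) p[pos] else "unclassified"
  }, "")
}

#' Construct a pairing manifest
#'
#' Links each isotopically labeled gradient to its unlabeled control and names
#' the treatment; optionally names the null treatment used for limit of
#' detection calibration.
#'
#' @param pairs data.frame with columns `labeled`, `control`, `treatment`.
#' @param null_treatment Name of the treatment whose labeling is expected to
#'   be undetectable (the empirical null), or `NA`.
#' @return Object of class `tagsip_manifest`.
#' @export
manifest <- function(pairs, null_treatment = NA_character_) {
  need <- c("labeled", "control", "treatment")
  miss <- setdiff(need, names(pairs))
  if (length(miss))
    stop("manifest pairs need column(s): ", paste(miss, collapse = ", "))
  pairs <- as.data.frame(pairs)[, need]
  for (k in need) pairs[[k]] <- as.character(pairs[[k]])
  if (anyDuplicated(pairs$labeled))
    stop("each labeled gradient must map to exactly one control")
  if (!is.na(null_treatment) && !null_treatment %in% pairs$treatment)
    stop(sprintf("null treatment '%s' has no pair in the manifest",
                 null_treatment))
  structure(list(pairs = pairs,
                 null_treatment = as.character(null_treatment)),
            class = "tagsip_manifest")
}

#' @export
print.tagsip_manifest <- function(x, ...) {
  cat(sprintf("Pairing manifest: %d pair(s); null treatment: %s\n",
              nrow(x$pairs),
              if (is.na(x$null_treatment)) "<none>" else x$null_treatment))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Read a pairing manifest
#'
#' YAML file of the form
#' ```
#' null_treatment: LNT
#' pairs:
#' - labeled: LNT_labeled
#'   control: LNT_control
#'   treatment: LNT
#' ```
#'
#' @param path Path to the YAML file.
#' @return A [manifest()].
#' @export
read_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$pairs) || !length(y$pairs))
    stop("manifest has no 'pairs' entries")
  pairs <- do.call(rbind, lapply(y$pairs, function(p) {
    data.frame(labeled = p$labeled, control = p$control,
               treatment = p$treatment, stringsAsFactors = FALSE)
  }))
  manifest(pairs, null_treatment = if (is.null(y$null_treatment))
    NA_character_ else y$null_treatment)
}

#' Write a pairing manifest
#'
#' @param m A [manifest()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(m, path) {
  stopifnot(inherits(m, "tagsip_manifest"))
  y <- list(null_treatment = if (is.na(m$null_treatment)) NULL
            else m$null_treatment,
            pairs = lapply(seq_len(nrow(m$pairs)), function(i)
              as.list(m$pairs[i, ])))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Select the sequencing window of a gradient
#'
#' Picks the contiguous window of `n` fractions maximizing the summed DNA
#' quantity -- the DNA band region that would be carried forward to PCR and
#' sequencing -- and flags those fractions `sequenced = TRUE` (all others
#' `FALSE`). Ties are broken toward the lowest starting index (densest
#' window). The choice is invariant to uniform rescaling of `dna_quantity`.
#'
#' @param run A [gradient_run()] with `dna_quantity` recorded for every
#'   fraction.
#' @param n Number of fractions to select (default 20).
#' @return The run with its `sequenced` flags replaced.
#' @export
select_fractions <- function(run, n = 20L) {
  stopifnot(inherits(run, "gradient_run"))
  n <- as.integer(n)
  dna <- run$fractions$dna_quantity
  m <- length(dna)
  if (anyNA(dna))
    stop(sprintf("gradient '%s': dna_quantity must be recorded for every fraction",
                 run$gradient_id))
  if (m < n)
    stop(sprintf("gradient '%s' has %d fractions; cannot select %d",
                 run$gradient_id, m, n))
  ws <- vapply(seq_len(m - n + 1L),
               function(s) sum(dna[s:(s + n - 1L)]), numeric(1))
  s <- which.max(ws)   # first maximum = lowest starting index on ties
  run$fractions$sequenced <- seq_len(m) %in% s:(s + n - 1L)
  run
}

#' Align an OTU table to the sequenced fractions of a set of runs
#'
#' Restricts the table to columns belonging to `runs`, checks every retained
#' column resolves to a known, sequenced fraction, and orders columns by run
#' and ascending fraction index.
#'
#' @param table An [otu_table()].
#' @param runs Named list of [gradient_run()] objects.
#' @param drop_unsequenced Drop columns for known fractions that are not
#'   flagged sequenced (default `TRUE`; with `FALSE` such columns are an
#'   error).
#' @return The aligned `otu_table`.
#' @export
align_otu_table <- function(table, runs, drop_unsequenced = TRUE) {
  stopifnot(inherits(table, "otu_table"))
  if (inherits(runs, "gradient_run")) runs <- list(runs)
  if (is.null(names(runs)))
    names(runs) <- vapply(runs, `[[`, "", "gradient_id")
  keep <- integer(0)
  for (g in names(runs)) {
    fr <- runs[[g]]$fractions
    idx <- which(table$gradient_id == g)
    known <- table$fraction_index[idx] %in% fr$fraction_index
    if (any(!known))
      stop(sprintf("OTU table column(s) reference unknown fractions of gradient '%s': %s",
                   g, paste(table$fraction_index[idx][!known], collapse = ", ")))
    seqd <- fr$fraction_index[fr$sequenced]
    sel <- idx[table$fraction_index[idx] %in% seqd]
    if (!drop_unsequenced && length(sel) < length(idx))
      stop(sprintf("gradient '%s': OTU table has columns for unsequenced fractions",
                   g))
    miss <- setdiff(seqd, table$fraction_index[idx])
    if (length(miss))
      stop(sprintf("gradient '%s': sequenced fraction(s) missing from OTU table: %s",
                   g, paste(miss, collapse = ", ")))
    keep <- c(keep, sel[order(table$fraction_index[sel])])
  }
  otu_table(table$counts[, keep, drop = FALSE],
            table$gradient_id[keep], table$fraction_index[keep])
}

#' Filter OTUs by abundance rank and per-fraction read support
#'
#' Keeps OTUs that (a) rank within the global top `top_n` by total reads
#' (ties broken by lexicographic OTU id) and (b) carry at least
#' `min_mean_reads` reads per sequenced fraction (by default the mean over a
#' gradient's sequenced fractions) in at least one gradient of every analyzed
#' pair. The read-support rule suppresses artifacts from random banding of
#' very low abundance organisms. The operation is idempotent.
#'
#' @param table An [otu_table()] whose columns are sequenced fractions.
#' @param runs Optional named list of [gradient_run()]s; when given, the
#'   table is validated against their sequenced fractions first.
#' @param pairs Optional pairing as a [manifest()] or data.frame with columns
#'   `labeled` and `control`; when given, the read-support rule must hold in
#'   at least one gradient of *every* pair. When absent, in at least one
#'   gradient overall.
#' @param min_mean_reads Read-support threshold (default 400, inclusive).
#' @param top_n Abundance rank cut (default 100).
#' @param stat Per-gradient support statistic: `"mean"` reads per sequenced
#'   fraction (default; equals total reads divided by the number of sequenced
#'   fractions) or `"min"`.
#' @return The filtered `otu_table` (possibly with zero rows, with a
#'   warning).
#' @export
filter_otus <- function(table, runs = NULL, pairs = NULL,
                        min_mean_reads = 400, top_n = 100L,
                        stat = c("mean", "min")) {
  stopifnot(inherits(table, "otu_table"))
  stat <- match.arg(stat)
  if (!is.null(runs)) table <- align_otu_table(table, runs)
  counts <- table$counts
  ids <- rownames(counts)
  totals <- rowSums(counts)
  ord <- order(-totals, ids)
  top_ids <- ids[ord][seq_len(min(as.integer(top_n), length(ids)))]

  gids <- unique(table$gradient_id)
  statm <- vapply(gids, function(g) {
    cc <- counts[, table$gradient_id == g, drop = FALSE]
    if (stat == "mean") rowMeans(cc) else apply(cc, 1L, min)
  }, numeric(nrow(counts)))
  if (is.null(dim(statm))) statm <- matrix(statm, nrow = nrow(counts),
                                           dimnames = list(ids, gids))
  ok <- statm >= min_mean_reads

  if (!is.null(pairs)) {
    if (inherits(pairs, "tagsip_manifest")) pairs <- pairs$pairs
    miss <- setdiff(c(pairs$labeled, pairs$control), gids)
    if (length(miss))
      stop("pair gradient(s) absent from OTU table: ",
           paste(miss, collapse = ", "))
    per_pair <- vapply(seq_len(nrow(pairs)), function(i)
      ok[, pairs$labeled[i]] | ok[, pairs$control[i]],
      logical(nrow(counts)))
    if (is.null(dim(per_pair))) per_pair <- matrix(per_pair, nrow = nrow(counts))
    abundant <- apply(per_pair, 1L, all)
  } else {
    abundant <- apply(ok, 1L, any)
  }

  keep <- ids %in% top_ids & abundant
  if (!any(keep))
    warning("no OTUs pass the abundance filters; returning an empty table")
  otu_table(counts[keep, , drop = FALSE],
            table$gradient_id, table$fraction_index)
}
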