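test_that("fraction metadata round-trips through write/read and preserves counts", {
  runs <- list(A = make_run("A", dna = round(dnorm(1:50, 25, 8), 6)),
               B = make_run("B", dna = round(runif(50), 6)))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_fraction_metadata(runs, p)
  back <- read_fraction_metadata(p)
  expect_named(back, c("A", "B"))
  expect_equal(vapply(back, function(r) nrow(r$fractions), 0L),
               c(A = 50L, B = 50L))
  # read(write(x)) is the identity up to the unset treatment/substrate labels
  for (g in names(runs)) {
    expect_equal(back[[g]]$fractions, runs[[g]]$fractions)
    expect_equal(back[[g]]$gradient_id, g)
  }
  # write(read(write(x))) is byte-identical to write(x)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_fraction_metadata(back, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("metadata validation catches inversions, duplicates and odd densities", {
  fr <- data.frame(gradient_id = "G", fraction_index = 1:5,
                   density_g_ml = c(1.74, 1.73, 1.735, 1.71, 1.70),
                   dna_quantity = 1, sequenced = 1)
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(fr, p, row.names = FALSE, quote = FALSE)
  expect_error(read_fraction_metadata(p), "fraction_index 3")

  fr2 <- data.frame(fraction_index = c(1, 2, 2),
                    density = c(1.74, 1.73, 1.72),
                    dna_quantity = 1, sequenced = TRUE)
  expect_error(gradient_run("G", fr2), "duplicate")

  fr3 <- data.frame(fraction_index = 1:3, density = c(1.95, 1.90, 1.85),
                    dna_quantity = 1, sequenced = TRUE)
  expect_warning(gradient_run("G", fr3), "outside")
})

test_that("select_fractions matches the brute-force contiguous-window oracle", {
  brute <- function(dna, n) {
    ws <- sapply(seq_len(length(dna) - n + 1),
                 function(s) sum(dna[s:(s + n - 1)]))
    s <- which(ws == max(ws))[1]   # lowest starting index on ties
    s:(s + n - 1)
  }
  set.seed(4)
  for (rep in 1:5) {
    dna <- rgamma(50, 2, 1)
    run <- select_fractions(make_run(dna = dna), 20)
    expect_equal(which(run$fractions$sequenced), brute(dna, 20))
  }
  # single DNA hump centred between fractions 25 and 26 -> window 16..35
  hump <- dnorm(1:50, 25.5, 6)
  run <- select_fractions(make_run(dna = hump), 20)
  expect_equal(which(run$fractions$sequenced), 16:35)
})

test_that("select_fractions handles ties, identity and rescaling", {
  run <- select_fractions(make_run(n = 30, dna = rep(2, 30)), 10)
  expect_equal(which(run$fractions$sequenced), 1:10)  # tie -> lowest start

  run <- select_fractions(make_run(n = 20), 20)
  expect_true(all(run$fractions$sequenced))           # n = m -> identity

  dna <- rgamma(50, 2, 1)
  a <- select_fractions(make_run(dna = dna), 20)
  b <- select_fractions(make_run(dna = dna * 137.5), 20)
  expect_equal(a$fractions$sequenced, b$fractions$sequenced)

  expect_error(select_fractions(make_run(n = 10), 20), "cannot select")
})

test_that("filter_otus equals an independent sort-and-threshold oracle", {
  set.seed(7)
  n_otu <- 150; nf <- 20
  ids <- sprintf("OTU%03d", sample(n_otu))  # scrambled ids to exercise ties
  mu <- rexp(n_otu, 1 / 300)
  cnt <- cbind(matrix(rpois(n_otu * nf, mu), n_otu),
               matrix(rpois(n_otu * nf, mu * 0.6), n_otu))
  rownames(cnt) <- ids
  tab <- otu_table(cnt, rep(c("L", "C"), each = nf), rep(1:nf, 2))
  pairs <- data.frame(labeled = "L", control = "C")

  got <- filter_otus(tab, pairs = pairs, min_mean_reads = 400, top_n = 100)

  totals <- rowSums(cnt)
  top <- ids[order(-totals, ids)][1:100]
  okL <- rowMeans(cnt[, 1:nf]) >= 400
  okC <- rowMeans(cnt[, nf + 1:nf]) >= 400
  want <- ids[ids %in% top & (okL | okC)]
  expect_setequal(rownames(got$counts), want)

  # idempotence
  again <- filter_otus(got, pairs = pairs, min_mean_reads = 400, top_n = 100)
  expect_identical(again$counts, got$counts)
})

test_that("filter_otus thresholds are inclusive and rank-limited", {
  nf <- 20
  cnt <- rbind(boundary = rep(c(400L, 10L), each = nf),
               rich = rep(1000L, 2 * nf),
               poor = rep(c(399L, 399L), each = nf))
  tab <- otu_table(cnt, rep(c("L", "C"), each = nf), rep(1:nf, 2))
  pairs <- data.frame(labeled = "L", control = "C")
  got <- filter_otus(tab, pairs = pairs, min_mean_reads = 400, top_n = 100)
  expect_setequal(rownames(got$counts), c("boundary", "rich"))

  # an OTU ranked below top_n is dropped regardless of per-fraction support:
  # totals are rich 40000 > poor 15960 > boundary 8200, so top_n = 2 excludes
  # "boundary" even though its labeled-gradient mean passes the threshold
  got2 <- filter_otus(tab, pairs = pairs, min_mean_reads = 400, top_n = 2)
  expect_setequal(rownames(got2$counts), "rich")
  got3 <- filter_otus(tab, pairs = pairs, min_mean_reads = 0, top_n = 2)
  expect_false("boundary" %in% rownames(got3$counts))

  expect_warning(
    empty <- filter_otus(tab, pairs = pairs, min_mean_reads = 1e6),
    "no OTUs")
  expect_equal(nrow(empty$counts), 0L)
})

test_that("OTU table, taxonomy and manifest round-trip through their formats", {
  cnt <- matrix(rpois(12, 50), 3, dimnames = list(c("a", "b", "c"), NULL))
  tab <- otu_table(cnt, rep("G1", 4), 1:4)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, p)
  back <- read_otu_table(p)
  expect_equal(back$counts, tab$counts)
  expect_equal(back$gradient_id, tab$gradient_id)
  expect_equal(back$fraction_index, tab$fraction_index)

  tax <- data.frame(otu_id = c("a", "b"),
                    lineage = c("Bacteria;Proteobacteria;Alpha;R;F;G",
                                "Archaea;Euryarchaeota"))
  pt <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy(tax, pt)
  expect_equal(read_taxonomy(pt), tax)
  expect_equal(lineage_at_rank(tax$lineage, "family"),
               c("F", "unclassified"))

  m <- manifest(data.frame(labeled = c("L1", "L2"), control = c("C1", "C2"),
                           treatment = c("Nitrate", "LNT")),
                null_treatment = "LNT")
  pm <- withr::local_tempfile(fileext = ".yml")
  write_manifest(m, pm)
  back <- read_manifest(pm)
  expect_equal(back$pairs, m$pairs)
  expect_equal(back$null_treatment, "LNT")

  expect_error(manifest(data.frame(labeled = c("L", "L"),
                                   control = c("C1", "C2"),
                                   treatment = "T")),
               "exactly one control")
})

test_that("align_otu_table enforces column resolution to sequenced fractions", {
  run <- select_fractions(make_run("G", n = 10, dna = c(1:6, 5:2)), 4)
  sel <- which(run$fractions$sequenced)
  cnt <- matrix(1L, 2, 10, dimnames = list(c("a", "b"), NULL))
  tab <- otu_table(cnt, rep("G", 10), 1:10)
  al <- align_otu_table(tab, list(G = run))
  expect_equal(al$fraction_index, sel)
  expect_error(align_otu_table(otu_table(cnt, rep("G", 10), 3:12),
                               list(G = run)), "unknown fraction")
})
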