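test_that("blacklist filtering uses half-open overlap of at least one base", {
  pk <- gr_from_bed0("c1", 100, 200, name = "p", score = 1)
  ## 1 bp overlap removes
  expect_length(
    load_and_filter_peaks(pk, gr_from_bed0("c1", 199, 300)), 0)
  ## touching intervals do not overlap
  expect_length(
    load_and_filter_peaks(pk, gr_from_bed0("c1", 200, 300)), 1)
  ## empty blacklist is the identity
  expect_equal(length(load_and_filter_peaks(pk, NULL)), 1)
  ## blacklist chromosome absent from the peak set warns and is ignored
  expect_warning(out <- load_and_filter_peaks(
    pk, gr_from_bed0("cX", 0, 1e6)), "cX")
  expect_length(out, 1)
})

test_that("stitching merges at gap <= D and splits beyond, per chromosome", {
  pk <- gr_from_bed0(c("c1", "c1"), c(0, 40100), c(100, 40200),
                     name = c("a", "b"))
  r <- stitch_peaks(pk, 40000L)  # gap exactly 40000 merges
  expect_length(r, 1)
  expect_equal(bed0_from_gr(r)[1, c("start", "end")],
               data.frame(start = 0L, end = 40200L), ignore_attr = TRUE)
  pk2 <- gr_from_bed0(c("c1", "c1"), c(0, 40101), c(100, 40200))
  expect_length(stitch_peaks(pk2, 40000L), 2)  # gap 40001 splits
  ## chromosomes never merge
  pk3 <- gr_from_bed0(c("c1", "c2"), c(0, 50), c(100, 150))
  expect_length(stitch_peaks(pk3, 40000L), 2)
})

test_that("stitching matches the transitive-closure oracle and is idempotent", {
  set.seed(42)
  for (trial in 1:50) {
    inst <- random_peak_instance(sample(2:80, 1))
    D <- sample(c(0, 100, 5000, 40000), 1)
    pk <- gr_from_bed0(inst$chrom, inst$start, inst$end)
    r <- stitch_peaks(pk, D)
    got <- integer(length(pk))
    for (i in seq_along(r))
      got[S4Vectors::mcols(r)$constituents[[i]]] <- i
    want <- oracle_stitch(inst$chrom, inst$start, inst$end, D)
    ## same partition up to labels
    norm <- function(x) as.integer(factor(x, levels = unique(x)))
    expect_equal(norm(got), norm(want), label = sprintf("trial %d", trial))
    ## idempotent: stitching the regions again changes nothing
    r2 <- stitch_peaks(GenomicRanges::granges(r), D)
    expect_equal(bed0_from_gr(r2)[c("chrom", "start", "end")],
                 bed0_from_gr(r)[c("chrom", "start", "end")])
  }
})

test_that("region density is the input-subtracted per-bp signal over constituents only", {
  ## widths 100 + 300, uniform chip 2.0, input 0.5: (800-200)/400 = 1.5
  pk <- gr_from_bed0(c("c1", "c1"), c(0, 1000), c(100, 1300))
  r <- stitch_peaks(pk, 40000L)
  chip <- uniform_track("c1", 10000, 2.0)
  input <- uniform_track("c1", 10000, 0.5)
  d <- region_density(r, pk, chip, input)
  expect_equal(S4Vectors::mcols(d)$density, 1.5)
  ## chip identical to input gives zero
  d0 <- region_density(r, pk, chip, chip)
  expect_equal(S4Vectors::mcols(d0)$density, 0)
  ## changing coverage in the inter-peak gap never changes density
  bump <- gr_from_bed0("c1", c(0, 100, 1000), c(100, 1000, 1300),
                       score = c(2, 50, 2))
  flat <- uniform_track("c1", 10000, 2)
  expect_equal(S4Vectors::mcols(region_density(r, pk, bump, input))$density,
               S4Vectors::mcols(region_density(r, pk, flat, input))$density)
})

test_that("region density equals the base-by-base oracle on random step tracks", {
  set.seed(7)
  for (trial in 1:5) {
    ## two constituent peaks within one region on a 600 bp toy chromosome
    pk <- gr_from_bed0(c("c1", "c1"), c(10, 250), c(120, 430))
    edges <- sort(sample(0:600, 7))
    mk <- function() {
      keep <- edges[-length(edges)] < edges[-1]
      gr_from_bed0("c1", edges[-length(edges)][keep], edges[-1][keep],
                   score = round(runif(sum(keep), 0, 5), 2))
    }
    chip <- mk(); input <- mk()
    r <- stitch_peaks(pk, 40000L)
    got <- S4Vectors::mcols(region_density(r, pk, chip, input))$density
    osum <- function(tr, s, e) {
      df <- bed0_from_gr(tr)
      oracle_base_sum(df$start, df$end, df$score, s, e)
    }
    want <- (osum(chip, 10, 120) + osum(chip, 250, 430) -
               osum(input, 10, 120) - osum(input, 250, 430)) / (110 + 180)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("the slope-1 threshold sits at the analytic inflection of a quadratic curve", {
  n <- 1000
  pk <- gr_from_bed0(rep("c1", n), (0:(n - 1)) * 1e5,
                     (0:(n - 1)) * 1e5 + 100)
  r <- stitch_peaks(pk, 1000L)
  expect_length(r, n)
  S4Vectors::mcols(r)$density <- ((1:n) / n)^2
  for (method in c("tangent", "secant")) {
    res <- rank_threshold_call(
      r, caller_config(threshold_method = method))
    expect_lt(abs(res$threshold_rank - 0.5), 0.02)
    expect_lt(abs(res$threshold - 0.25), 0.02)
    expect_equal(res$n_flagged, n / 2)
    expect_false(res$warning)
  }
})

test_that("flat and linear rank curves trigger the documented fallbacks", {
  n <- 100
  pk <- gr_from_bed0(rep("c1", n), (0:(n - 1)) * 1e5,
                     (0:(n - 1)) * 1e5 + 100)
  r <- stitch_peaks(pk, 1000L)
  ## all equal: derivative 0 everywhere, nothing flagged, warning set
  S4Vectors::mcols(r)$density <- rep(3, n)
  expect_warning(res <- rank_threshold_call(r, caller_config()),
                 "no region flagged")
  expect_equal(res$n_flagged, 0L)
  expect_true(res$warning)
  ## linear: derivative 1 everywhere, everything flagged
  S4Vectors::mcols(r)$density <- (1:n) / n
  res2 <- rank_threshold_call(r, caller_config())
  expect_equal(res2$n_flagged, n)
  expect_false(res2$warning)
})

test_that("the flagged set is invariant to positive rescaling of densities", {
  set.seed(13)
  n <- 300
  pk <- gr_from_bed0(rep("c1", n), (0:(n - 1)) * 1e5,
                     (0:(n - 1)) * 1e5 + 100)
  r <- stitch_peaks(pk, 1000L)
  dens <- c(abs(rnorm(n - 20, 0, 0.1)), runif(20, 2, 6))
  S4Vectors::mcols(r)$density <- dens
  res1 <- rank_threshold_call(r, caller_config())
  S4Vectors::mcols(r)$density <- dens * 37.5
  res2 <- rank_threshold_call(r, caller_config())
  f1 <- names(res1$regions)[S4Vectors::mcols(res1$regions)$is_highly_enriched]
  f2 <- names(res2$regions)[S4Vectors::mcols(res2$regions)$is_highly_enriched]
  expect_setequal(f1, f2)
})

test_that("degenerate density inputs are rejected", {
  pk <- gr_from_bed0("c1", 0, 100)
  r <- stitch_peaks(pk, 1000L)
  S4Vectors::mcols(r)$density <- 1
  expect_error(rank_threshold_call(r), "at least 2")
  pk2 <- gr_from_bed0(c("c1", "c1"), c(0, 1e6), c(100, 1e6 + 100))
  r2 <- stitch_peaks(pk2, 1000L)
  S4Vectors::mcols(r2)$density <- c(-2, -1)
  expect_error(rank_threshold_call(r2), "cannot normalize")
})

test_that("nearest-gene annotation uses peak midpoints with ties to the lower TSS", {
  genes <- data.frame(gene_id = c("g900", "g1200"), chrom = "c1",
                      tss = c(900L, 1200L), strand = "+")
  ## midpoint 1000: distance 100 vs 200
  pk <- gr_from_bed0("c1", 950, 1050)
  expect_equal(annotate_nearest_genes(pk, genes)$peak_gene, "g900")
  ## midpoint 1000 equidistant from 900 and 1100: lower coordinate wins
  genes2 <- data.frame(gene_id = c("hi", "lo"), chrom = "c1",
                       tss = c(1100L, 900L), strand = "+")
  expect_equal(annotate_nearest_genes(pk, genes2)$peak_gene, "lo")
  ## a region's gene set is the union over constituents
  pk3 <- gr_from_bed0(rep("c1", 3), c(880, 920, 1190), c(920, 960, 1230))
  r3 <- stitch_peaks(pk3, 40000L)
  ann <- annotate_nearest_genes(pk3, genes, r3)
  expect_setequal(ann$region_genes[[1]], c("g900", "g1200"))
  ## chromosome without genes warns and leaves NA
  pk4 <- gr_from_bed0("cEmpty", 0, 100)
  expect_warning(a4 <- annotate_nearest_genes(pk4, genes), "cEmpty")
  expect_true(is.na(a4$peak_gene))
})

test_that("highly enriched regions recover planted clusters with precision and recall >= 0.9", {
  for (s in 1:3) {
    sim_cfg <- sim_config()  # signal_fold 4, 5 peaks per cluster
    gp <- simulate_genome_and_peaks(sim_cfg, seed = s)
    tracks <- simulate_tracks(gp$genome, gp$peaks, sim_cfg, seed = s)
    res <- call_regions(gp$peaks$at3, tracks$at3, tracks$input,
                        gp$genome$genes)
    fl <- res$regions[S4Vectors::mcols(res$regions)$is_highly_enriched]
    pr <- region_precision_recall(fl, gp$truth$true_region_intervals)
    expect_gte(pr[["precision"]], 0.9)
    expect_gte(pr[["recall"]], 0.9)
    ## flagged regions annotate their planted target genes
    ann <- res$annotation
    genes_fl <- unique(unlist(ann$region_genes[names(fl)]))
    expect_true(all(gp$truth$true_region_intervals$gene_id %in% genes_fl))
  }
})
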