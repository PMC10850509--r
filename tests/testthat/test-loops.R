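toy_loops <- function() {
  make_loops("c1", c(100, 100, 100), c(600, 600, 600),
             "c1", c(9000, 9000, 9000), c(9500, 9500, 9500),
             pet = c(4L, 3L, 10L), fdr = c(0.009, 0.001, 0.01))
}

test_that("loop filtering keeps PET >= 4 (inclusive) and FDR < 0.01 (strict)", {
  got <- suppressMessages(load_filter_loops(toy_loops(), loop_config()))
  ## PET 4 / FDR 0.009 kept; PET 3 dropped; FDR exactly 0.01 dropped
  expect_equal(got$name, "L001")
  ## idempotent and order-independent
  again <- suppressMessages(load_filter_loops(got, loop_config()))
  expect_equal(again, got)
  rev_in <- toy_loops()[3:1, ]
  got2 <- suppressMessages(load_filter_loops(rev_in, loop_config()))
  expect_equal(got2$name, "L001")
})

test_that("anchor and loop classes follow VCP-peak overlap with mixed loops as vcp", {
  loops <- make_loops("c1", c(0, 0, 0), c(1000, 1000, 1000),
                      "c1", c(5000, 5000, 5000), c(6000, 6000, 6000),
                      pet = 5L, fdr = 0.001)
  ## peaks overlapping: both anchors / neither / anchor1 only
  vcp <- gr_from_bed0(c("c1", "c1"), c(500, 5500), c(600, 5600))
  both <- classify_anchors_and_loops(loops[1, ], vcp)
  expect_equal(both$class, "vcp")
  neither <- classify_anchors_and_loops(
    loops[2, ], gr_from_bed0("c1", 20000, 21000))
  expect_equal(neither$class, "control")
  one <- classify_anchors_and_loops(
    loops[3, ], gr_from_bed0("c1", 500, 600))
  expect_equal(one$class, "vcp")
  expect_true(one$vcp_anchor1)
  expect_false(one$vcp_anchor2)
  ## restricting VCP peaks to a region empties the class
  none <- classify_anchors_and_loops(loops[1, ], vcp,
                                     restrict_to = gr_from_bed0("c2", 0, 10))
  expect_equal(none$class, "control")
})

test_that("normalized loop scores have unit mean and are depth-invariant", {
  loops <- make_loops("c1", c(0, 0, 0), c(10, 10, 10),
                      "c1", c(100, 100, 100), c(110, 110, 110),
                      pet = c(4L, 6L, 10L), fdr = 0.001)
  out <- normalized_loop_score(loops, loop_config())
  expect_equal(out$nls, c(0.6, 0.9, 1.5))
  expect_equal(mean(out$nls), 1)
  ## all equal PETs give NLS 1
  eq <- loops; eq$pet <- 7L
  expect_equal(normalized_loop_score(eq)$nls, c(1, 1, 1))
  ## doubling every PET (library depth) leaves NLS unchanged
  dbl <- loops; dbl$pet <- loops$pet * 2L
  expect_equal(normalized_loop_score(dbl)$nls, out$nls)
  expect_error(normalized_loop_score(loops[0, ]), "empty")
})

test_that("peak contexts follow promoter windows and loop anchors", {
  genes <- data.frame(gene_id = "g1", chrom = "c1", tss = 50000L,
                      strand = "+")
  cfg <- loop_config()  # promoter window 2500
  loops <- normalized_loop_score(make_loops(
    "c1", 10000, 11000, "c1", 49000, 51000, pet = 5L, fdr = 0.001))
  ## center at tss + 2499 is still promoter context
  pk_prom <- gr_from_bed0("c1", 52449, 52549, name = "pp")  # center 52499
  ctx <- assign_peak_context(pk_prom, genes, loops[0, ], cfg)
  expect_equal(ctx$context, "promoter")
  expect_equal(ctx$gene_id, "g1")
  ## center at tss + 2500 is not
  pk_out <- gr_from_bed0("c1", 52450, 52550, name = "po")  # center 52500
  expect_equal(nrow(assign_peak_context(pk_out, genes, loops[0, ], cfg)), 0)
  ## peak inside anchor1 whose partner anchor covers the promoter window
  pk_enh <- gr_from_bed0("c1", 10400, 10600, name = "pe")
  ctx2 <- assign_peak_context(pk_enh, genes, loops, cfg)
  expect_equal(ctx2$context, "looped_enhancer")
  expect_equal(ctx2$nls, 1)
  ## peak in an anchor with no partner promoter, outside promoter windows
  lonely <- normalized_loop_score(make_loops(
    "c1", 10000, 11000, "c1", 30000, 31000, pet = 5L, fdr = 0.001))
  expect_equal(nrow(assign_peak_context(pk_enh, genes, lonely, cfg)), 0)
})

test_that("the aggregate score reproduces the worked example 3 + 2 x 1.5 = 6", {
  genes <- data.frame(gene_id = "g1", chrom = "c1", tss = 50000L,
                      strand = "+")
  ## one promoter peak under uniform coverage 3, one looped enhancer peak
  ## under coverage 2 connected by a loop with NLS 1.5
  pks <- gr_from_bed0(c("c1", "c1"), c(49950, 10450), c(50050, 10550),
                      name = c("prom", "enh"))
  loops <- make_loops("c1", c(10000, 20000), c(11000, 21000),
                      "c1", c(49000, 60000), c(51000, 61000),
                      pet = c(6L, 2L), fdr = 0.001)
  loops <- normalized_loop_score(loops)  # NLS 1.5 and 0.5
  loops$class <- c("vcp", "control")
  track <- gr_from_bed0(c("c1", "c1"), c(0, 40000), c(40000, 100000),
                        score = c(2, 3))
  ctx <- assign_peak_context(pks, genes, loops)
  prof <- gene_aggregate_score(genes, ctx, pks, list(f = track), loops)
  expect_equal(prof$score_f, 3 + 2 * 1.5)
  expect_equal(prof$class, "looped_enhancer")
  expect_equal(prof$n_promoter_peaks, 1L)
  expect_equal(prof$n_enhancer_pairs, 1L)
  ## nls per promoter counts vcp loops with an anchor over the window
  expect_equal(prof$nls_per_promoter, 1.5)
  ## removing the loop removes exactly its E x NLS term
  ctx_prom <- ctx[ctx$context == "promoter", ]
  prof2 <- gene_aggregate_score(genes, ctx_prom, pks, list(f = track),
                                loops[0, ])
  expect_equal(prof2$score_f, 3)
  expect_equal(prof2$class, "promoter_only")
  ## a gene with no contextual peaks is untargeted with zero scores
  genes2 <- rbind(genes, data.frame(gene_id = "g2", chrom = "c1",
                                    tss = 90000L, strand = "+"))
  prof3 <- gene_aggregate_score(genes2, ctx, pks, list(f = track), loops)
  expect_equal(prof3$score_f[prof3$gene_id == "g2"], 0)
  expect_equal(prof3$class[prof3$gene_id == "g2"], "untargeted")
})

test_that("aggregate scores equal the brute-force oracle on random fixtures", {
  set.seed(21)
  for (trial in 1:5) {
    cfg <- sim_config(n_singleton_peaks = 20L, n_clusters = 6L,
                      n_control_genes = 8L, n_background_genes = 5L,
                      n_loops = 30L, n_loops_pass = 20L)
    gp <- simulate_genome_and_peaks(cfg, seed = trial)
    tracks <- simulate_tracks(gp$genome, gp$peaks, cfg, seed = trial)
    lp <- simulate_loops(gp$genome, gp$peaks, cfg, seed = trial)
    loops <- suppressMessages(load_filter_loops(lp$baseline))
    loops <- normalized_loop_score(
      classify_anchors_and_loops(loops, gp$peaks$vcp))
    ctx <- assign_peak_context(gp$peaks$vcp, gp$genome$genes, loops)
    prof <- gene_aggregate_score(gp$genome$genes, ctx, gp$peaks$vcp,
                                 list(at3 = tracks$at3), loops)
    ## oracle: recompute E per peak and walk the assignments one by one
    centers0 <- floor((GenomicRanges::start(gp$peaks$vcp) - 1L +
                         GenomicRanges::end(gp$peaks$vcp)) / 2)
    win <- gr_from_bed0(
      as.character(GenomicRanges::seqnames(gp$peaks$vcp)),
      centers0 - 500L, centers0 + 500L)
    E <- track_mean(tracks$at3, win)
    want <- oracle_gene_score(gp$genome$genes, ctx, E)
    expect_equal(prof$score_at3, unname(want[prof$gene_id]),
                 tolerance = 1e-9)
  }
})

test_that("the depletion contrast reproduces closed-form ratios and the null", {
  ## equal depths, PET 10 -> 5: log2 ratio -1 in the small-pseudocount limit
  base <- make_loops("c1", c(0, 100), c(10, 110),
                     "c1", c(1000, 2000), c(1010, 2010),
                     pet = c(10L, 10L), fdr = 0.001)
  base$class <- c("vcp", "control")
  dep <- base
  dep$pet <- c(5L, 15L)  # total PETs equal across conditions
  con <- loop_class_contrast(base, dep, eps = 1e-9)
  expect_equal(con$loops$log2_ratio[1], -1, tolerance = 1e-6)
  ## identical conditions: ratios all zero, rank-sum p near 1
  base2 <- make_loops("c1", rep(0, 6), rep(10, 6),
                      "c1", 1000 * (1:6), 1000 * (1:6) + 10,
                      pet = c(4L, 8L, 9L, 5L, 7L, 12L), fdr = 0.001)
  base2$class <- rep(c("vcp", "control"), 3)
  con2 <- loop_class_contrast(base2, base2)
  expect_true(all(con2$loops$log2_ratio == 0))
  expect_gt(con2$p_value, 0.9)
  ## unmatched loops are reported, disjoint sets are an error
  shifted <- base2
  shifted$start2 <- shifted$start2 + 1L
  expect_error(loop_class_contrast(base2, shifted), "no loops matched")
})

test_that("locus partition separates VCP-coincident top loci from VCP-free bottom loci", {
  k27 <- gr_from_bed0(rep("c1", 4), c(0, 2000, 4000, 90000) + 0,
                      c(0, 2000, 4000, 90000) + 1000,
                      name = sprintf("k%d", 1:4))
  vcp <- gr_from_bed0("c1", 100, 300)
  loops <- make_loops("c1", 0, 5000, "c1", 8000, 9000, pet = 5L,
                      fdr = 0.001)
  enrich <- c(10, 1, 5, 100)
  part <- partition_loci_for_differential(k27, vcp, enrich, loops,
                                          top_k = 1, bottom_k = 1)
  ## k1: VCP-coincident, in anchor, top AT3 rank -> set 1
  expect_equal(part$vcp_top, 1L)
  ## k2: in anchor, no VCP, lowest enrichment -> set 2
  expect_equal(part$non_vcp_bottom, 2L)
  ## k4 is outside all anchors: in neither set even with top enrichment
  expect_false(4L %in% c(part$vcp_top, part$non_vcp_bottom))
  expect_warning(
    partition_loci_for_differential(k27, vcp, enrich, loops,
                                    top_k = 5, bottom_k = 1),
    "truncated")
})
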