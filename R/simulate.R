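## Synthetic-fixture generator. Plants clustered vs singleton ChIP-seq peaks
## for two co-distributed factors on a small genome, Poisson coverage
## tracks, negative-binomial HiChIP loops joining enhancer anchors to
## promoters, knockdown expression tables whose effects scale with the true
## target propensity, and spiked-interactor proteomics tables -- all with
## ground truth recorded so every downstream stage can be checked.
##
## Every output family draws from its own RNG stream, seeded at the base
## seed plus a fixed offset (peaks +0, tracks +101, loops +211,
## expression/proteomics +307), so adding one output never perturbs others.

SEED_OFFSETS <- c(peaks = 0L, tracks = 101L, loops = 211L, omics = 307L)

#' Simulation configuration
#'
#' Defaults define the study conditions used throughout the test-suite:
#' 20 clusters of 5 peaks (4-fold coverage enrichment over a unit Poisson
#' background), 200 singleton peaks, 120 loops of which 75 pass the
#' PET >= 4 / FDR < 0.01 filter, half the loops VCP-anchored, 2-fold PET
#' depletion of true VCP loops, and a knockdown effect of -2 log2 units at
#' the strongest target with sd-0.5 noise correlated 0.8 across the two
#' perturbations.
#'
#' @param n_singleton_peaks isolated peaks with background-level coverage.
#' @param n_clusters number of planted high-signal peak clusters.
#' @param peaks_per_cluster peaks per cluster (first is the promoter peak).
#' @param cluster_span bp from the cluster TSS to the last enhancer center.
#' @param signal_fold mean cluster-peak coverage over the singleton mean.
#'   Individual clusters draw a strength multiplier uniform on
#'   `signal_fold * (0.5, 1.5)` so the rank curve has the spread real
#'   superenhancer signal shows; the across-cluster mean is `signal_fold`.
#' @param background_mean,singleton_mean expected per-bp read depth of the
#'   input/background and of singleton-peak coverage.
#' @param bin_size coverage bin width in bp.
#' @param noise `"poisson"` or `"none"` (exact means, for arithmetic tests).
#' @param n_loops,n_loops_pass loops planted / loops constructed to satisfy
#'   PET >= `min_pets` and FDR < 0.01.
#' @param loop_pet_mean,loop_pet_dispersion negative-binomial PET model
#'   (`mu`, `size`).
#' @param frac_loops_vcp fraction of loops whose enhancer anchor carries a
#'   VCP peak.
#' @param depletion_factor delta in (0, 1]: multiplier on the expected PET
#'   of true VCP loops in the depleted condition.
#' @param knockdown_beta,knockdown_sigma effect size and noise sd of the
#'   knockdown log2 fold changes.
#' @param factor_correlation rho between -1 and 1: target-effect
#'   correlation between the two perturbations.
#' @param n_control_genes genes with H3K27ac promoter/enhancer anchors but
#'   no VCP occupancy (control loops attach here).
#' @param n_background_genes genes with no peaks at all.
#' @param n_proteins,n_interactors,interactor_fc_range proteomics table
#'   sizes and the planted interactor fold-enrichment range.
#' @param n_chromosomes chromosomes the layout is spread over.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_singleton_peaks = 200L, n_clusters = 20L,
                       peaks_per_cluster = 5L, cluster_span = 8000L,
                       signal_fold = 4, background_mean = 4,
                       singleton_mean = 4, bin_size = 50L,
                       noise = c("poisson", "none"),
                       n_loops = 120L, n_loops_pass = 75L,
                       loop_pet_mean = 10, loop_pet_dispersion = 4,
                       frac_loops_vcp = 0.5, depletion_factor = 0.5,
                       knockdown_beta = 2, knockdown_sigma = 0.5,
                       factor_correlation = 0.8,
                       n_control_genes = 60L, n_background_genes = 100L,
                       n_proteins = 400L, n_interactors = 12L,
                       interactor_fc_range = c(3, 8),
                       n_chromosomes = 2L) {
  noise <- match.arg(noise)
  stopifnot(n_singleton_peaks >= 0, n_clusters >= 0,
            peaks_per_cluster >= 1, cluster_span > 0,
            signal_fold > 0, background_mean >= 0, singleton_mean >= 0,
            bin_size >= 1,
            n_loops >= 0, n_loops_pass >= 0, n_loops_pass <= n_loops,
            loop_pet_mean > 0, loop_pet_dispersion > 0,
            frac_loops_vcp >= 0, frac_loops_vcp <= 1,
            depletion_factor > 0, depletion_factor <= 1,
            knockdown_beta >= 0, knockdown_sigma > 0,
            factor_correlation >= -1, factor_correlation <= 1,
            n_control_genes >= 0, n_background_genes >= 0,
            n_proteins >= 1, n_interactors >= 0,
            n_interactors <= n_proteins,
            length(interactor_fc_range) == 2,
            interactor_fc_range[1] > 0,
            interactor_fc_range[1] <= interactor_fc_range[2],
            n_chromosomes >= 1)
  structure(as.list(environment()), class = "sim_config")
}

SLOT_WIDTH <- 60000L  # one genomic slot per planted feature; > 40 kb so
                      # independent slots never stitch together

#' Simulate the genome, gene annotation and peak sets
#'
#' Lays out cluster, singleton, control-gene and background-gene slots over
#' `n_chromosomes` chromosomes (slots are 60 kb, so features in different
#' slots never stitch at the default 40 kb distance). Factor A (AT3) peaks
#' occupy every site; factor B (VCP) peaks sit at the same sites jittered by
#' at most 50 bp; H3K27ac peaks cover promoters, enhancer flanks and
#' VCP-free control enhancers.
#'
#' @param config [sim_config()].
#' @param seed integer; the peak stream uses `seed + 0`.
#' @return list with `genome` (list of `chromosomes` and `genes`
#'   data.frames), `peaks` (list of `GRanges`: `at3`, `vcp`, `h3k27ac`) and
#'   `truth` (true region intervals, 0-based half-open).
#' @export
simulate_genome_and_peaks <- function(config = sim_config(), seed = 1L) {
  set.seed(seed + SEED_OFFSETS[["peaks"]])
  cfg <- config
  if (cfg$cluster_span + 10000L > SLOT_WIDTH ||
      (cfg$peaks_per_cluster > 1L && cfg$cluster_span < 3500L))
    stop("cluster_span ", cfg$cluster_span,
         " incompatible with the chromosome layout (slot width ",
         SLOT_WIDTH, " bp; enhancers start 3 kb past the TSS)")
  n_slots <- cfg$n_clusters + cfg$n_singleton_peaks +
    cfg$n_control_genes + cfg$n_background_genes
  if (n_slots == 0L) stop("empty simulation: no slots to place")
  per_chrom <- ceiling(n_slots / cfg$n_chromosomes)
  chrom_names <- sprintf("chrS%d", seq_len(cfg$n_chromosomes))
  chrom_len <- per_chrom * SLOT_WIDTH + SLOT_WIDTH
  chromosomes <- data.frame(name = chrom_names,
                            length = rep(chrom_len, cfg$n_chromosomes),
                            stringsAsFactors = FALSE)
  types <- sample(c(rep("cluster", cfg$n_clusters),
                    rep("singleton", cfg$n_singleton_peaks),
                    rep("control", cfg$n_control_genes),
                    rep("background", cfg$n_background_genes)))
  slot_chrom <- chrom_names[(seq_len(n_slots) - 1L) %/% per_chrom + 1L]
  slot_base <- ((seq_len(n_slots) - 1L) %% per_chrom) * SLOT_WIDTH + 5000L

  genes <- list(); a <- list(); k27 <- list()
  cl_id <- 0L; ctl_id <- 0L; bg_id <- 0L
  for (i in seq_len(n_slots)) {
    ch <- slot_chrom[i]; S <- slot_base[i]
    if (types[i] == "cluster") {
      cl_id <- cl_id + 1L
      gid <- sprintf("TG%03d", cl_id)
      fold <- cfg$signal_fold * stats::runif(1, 0.5, 1.5)
      tss <- S + 2000L
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, chrom = ch, tss = tss,
        strand = sample(c("+", "-"), 1), type = "target")
      n_enh <- cfg$peaks_per_cluster - 1L
      centers <- tss
      if (n_enh > 0L)
        centers <- c(tss, round(seq(tss + 3000L, tss + cfg$cluster_span,
                                    length.out = n_enh)))
      w <- round(stats::runif(length(centers), 300, 700))
      a[[length(a) + 1L]] <- data.frame(
        chrom = ch, center = centers, width = w,
        site_type = "cluster", cluster_id = cl_id, gene_id = gid,
        fold = fold)
      ## H3K27ac: promoter anchor plus one anchor per enhancer
      k27[[length(k27) + 1L]] <- data.frame(
        chrom = ch,
        start = c(tss - 1000L, centers[-1] - 750L),
        end = c(tss + 1000L, centers[-1] + 750L),
        role = c("promoter", rep("enhancer", n_enh)),
        slot_type = "cluster", cluster_id = cl_id, gene_id = gid)
    } else if (types[i] == "singleton") {
      c0 <- S + 2000L
      a[[length(a) + 1L]] <- data.frame(
        chrom = ch, center = c0,
        width = round(stats::runif(1, 300, 700)),
        site_type = "singleton", cluster_id = NA_integer_,
        gene_id = NA_character_, fold = 1)
    } else if (types[i] == "control") {
      ctl_id <- ctl_id + 1L
      gid <- sprintf("CG%03d", ctl_id)
      tss <- S + 2000L
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, chrom = ch, tss = tss,
        strand = sample(c("+", "-"), 1), type = "control")
      k27[[length(k27) + 1L]] <- data.frame(
        chrom = ch,
        start = c(tss - 1000L, S + 20000L - 750L),
        end = c(tss + 1000L, S + 20000L + 750L),
        role = c("promoter", "control_enhancer"),
        slot_type = "control", cluster_id = NA_integer_, gene_id = gid)
    } else {
      bg_id <- bg_id + 1L
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = sprintf("BG%03d", bg_id), chrom = ch, tss = S + 2000L,
        strand = sample(c("+", "-"), 1), type = "background")
    }
  }
  genes <- do.call(rbind, genes)
  adf <- do.call(rbind, a)
  k27df <- do.call(rbind, k27)

  half <- adf$width %/% 2L
  at3 <- gr_from_bed0(adf$chrom, adf$center - half,
                      adf$center - half + adf$width,
                      name = sprintf("A_p%04d", seq_len(nrow(adf))),
                      site_type = adf$site_type,
                      cluster_id = adf$cluster_id, gene_id = adf$gene_id,
                      fold = adf$fold)
  jit <- sample(-50:50, nrow(adf), replace = TRUE)
  vcp <- gr_from_bed0(adf$chrom, adf$center - half + jit,
                      adf$center - half + adf$width + jit,
                      name = sprintf("B_p%04d", seq_len(nrow(adf))),
                      site_type = adf$site_type,
                      cluster_id = adf$cluster_id, gene_id = adf$gene_id,
                      fold = adf$fold)
  h3k27ac <- if (nrow(k27df))
    gr_from_bed0(k27df$chrom, k27df$start, k27df$end,
                 name = sprintf("K27_%04d", seq_len(nrow(k27df))),
                 role = k27df$role, slot_type = k27df$slot_type,
                 cluster_id = k27df$cluster_id, gene_id = k27df$gene_id)
  else GenomicRanges::GRanges()

  true_regions <- if (cfg$n_clusters > 0L) {
    do.call(rbind, lapply(seq_len(cfg$n_clusters), function(k) {
      sel <- adf$site_type == "cluster" & adf$cluster_id == k
      data.frame(chrom = adf$chrom[sel][1],
                 start = min(adf$center[sel] - half[sel]),
                 end = max(adf$center[sel] - half[sel] + adf$width[sel]),
                 cluster_id = k, gene_id = adf$gene_id[sel][1],
                 fold = adf$fold[sel][1], stringsAsFactors = FALSE)
    }))
  } else data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), cluster_id = integer(0),
                    gene_id = character(0), fold = numeric(0))

  list(genome = list(chromosomes = chromosomes, genes = genes),
       peaks = list(at3 = at3, vcp = vcp, h3k27ac = h3k27ac),
       truth = list(true_region_intervals = true_regions,
                    rng_seed = seed))
}

#' Simulate coverage tracks
#'
#' Fixed-width bins tile each chromosome; each bin's value is the per-bp
#' read depth over that bin. The expected depth is `background_mean` away
#' from peaks, `singleton_mean` over singleton peaks, and the cluster's
#' strength multiplier times `singleton_mean` over cluster peaks (mean
#' `signal_fold * singleton_mean` across clusters). With
#' `noise = "poisson"` the read count over a bin draws from a Poisson at
#' `mean * bin_width` and is divided by the bin width; with `"none"` the
#' bin equals its mean exactly. The input track is background everywhere.
#'
#' @param genome genome list from [simulate_genome_and_peaks()].
#' @param peaks peak list from the same call (cluster strengths are read
#'   from the peak metadata, so track means are reproducible for any track
#'   seed).
#' @param config [sim_config()].
#' @param seed integer; the track stream uses `seed + 101`.
#' @return list of coverage `GRanges`: `at3`, `vcp`, `input`.
#' @export
simulate_tracks <- function(genome, peaks, config = sim_config(),
                            seed = 1L) {
  set.seed(seed + SEED_OFFSETS[["tracks"]])
  cfg <- config
  bin_chrom <- character(0); bin_start <- integer(0); bin_end <- integer(0)
  for (i in seq_len(nrow(genome$chromosomes))) {
    len <- genome$chromosomes$length[i]
    starts <- seq(0L, len - 1L, by = cfg$bin_size)
    bin_chrom <- c(bin_chrom, rep(genome$chromosomes$name[i],
                                  length(starts)))
    bin_start <- c(bin_start, starts)
    bin_end <- c(bin_end, pmin(starts + cfg$bin_size, len))
  }
  bins <- gr_from_bed0(bin_chrom, bin_start, bin_end)
  bw <- GenomicRanges::width(bins)
  draw <- function(mu) if (cfg$noise == "poisson")
    stats::rpois(length(mu), mu * bw) / bw else mu
  track_for <- function(pk) {
    mu <- rep(cfg$background_mean, length(bins))
    single <- pk[S4Vectors::mcols(pk)$site_type == "singleton"]
    mu[GenomicRanges::countOverlaps(bins, single,
                                    ignore.strand = TRUE) > 0L] <-
      cfg$singleton_mean
    clust <- pk[S4Vectors::mcols(pk)$site_type == "cluster"]
    hits <- GenomicRanges::findOverlaps(bins, clust, ignore.strand = TRUE)
    mu[S4Vectors::queryHits(hits)] <-
      S4Vectors::mcols(clust)$fold[S4Vectors::subjectHits(hits)] *
      cfg$singleton_mean
    out <- bins
    S4Vectors::mcols(out)$score <- draw(mu)
    out
  }
  at3 <- track_for(peaks$at3)
  vcp <- track_for(peaks$vcp)
  input <- bins
  S4Vectors::mcols(input)$score <- draw(rep(cfg$background_mean,
                                            length(bins)))
  list(at3 = at3, vcp = vcp, input = input)
}

#' @noRd
rnbinom_min <- function(n, mu, size, min_val) {
  x <- stats::rnbinom(n, mu = mu, size = size)
  for (it in 1:1000) {
    low <- x < min_val
    if (!any(low)) return(x)
    x[low] <- stats::rnbinom(sum(low), mu = if (length(mu) > 1)
      mu[low] else mu, size = size)
  }
  x[x < min_val] <- min_val
  x
}

#' Simulate HiChIP loops, baseline and depleted
#'
#' Each loop joins an H3K27ac enhancer anchor to an H3K27ac promoter anchor
#' on the same chromosome (same-locus pairs used first, then cross-locus).
#' A fraction `frac_loops_vcp` of loops use VCP-occupied enhancer anchors;
#' the rest use control enhancers and control promoters. PET counts are
#' negative-binomial; exactly `n_loops_pass` loops are constructed to
#' satisfy PET >= 4 and FDR < 0.01. The depleted condition resamples every
#' loop's PET from a negative binomial whose mean is the baseline count,
#' multiplied by `depletion_factor` for true VCP loops.
#'
#' @param genome,peaks from [simulate_genome_and_peaks()].
#' @param config [sim_config()].
#' @param seed integer; the loop stream uses `seed + 211`.
#' @return list with `baseline` and `depleted` loop data.frames (BEDPE
#'   columns plus `target_gene`) and `truth` (passing `true_vcp_loops` /
#'   `true_control_loops` names and `true_target_genes`, the per-gene
#'   aggregate propensity).
#' @export
simulate_loops <- function(genome, peaks, config = sim_config(),
                           seed = 1L) {
  set.seed(seed + SEED_OFFSETS[["loops"]])
  cfg <- config
  k27 <- peaks$h3k27ac
  mc <- S4Vectors::mcols(k27)
  pairs_from <- function(enh_idx, prom_idx) {
    if (!length(enh_idx) || !length(prom_idx))
      return(data.frame(enh = integer(0), prom = integer(0)))
    cand <- expand.grid(enh = enh_idx, prom = prom_idx)
    same_chrom <- as.character(GenomicRanges::seqnames(k27))[cand$enh] ==
      as.character(GenomicRanges::seqnames(k27))[cand$prom]
    cand <- cand[same_chrom, , drop = FALSE]
    same_locus <- !is.na(mc$gene_id[cand$enh]) &
      mc$gene_id[cand$enh] == mc$gene_id[cand$prom]
    rbind(cand[same_locus, ][sample(sum(same_locus)), , drop = FALSE],
          cand[!same_locus, ][sample(sum(!same_locus)), , drop = FALSE])
  }
  n_vcp <- round(cfg$n_loops * cfg$frac_loops_vcp)
  n_ctl <- cfg$n_loops - n_vcp
  vcp_cand <- pairs_from(which(mc$role == "enhancer"),
                         which(mc$role == "promoter" &
                                 mc$slot_type == "cluster"))
  ctl_cand <- pairs_from(which(mc$role == "control_enhancer"),
                         which(mc$role == "promoter" &
                                 mc$slot_type == "control"))
  if (nrow(vcp_cand) < n_vcp)
    stop("cannot place ", n_vcp, " VCP loops: only ", nrow(vcp_cand),
         " distinct enhancer-promoter anchor pairs available")
  if (nrow(ctl_cand) < n_ctl)
    stop("cannot place ", n_ctl, " control loops: only ", nrow(ctl_cand),
         " distinct control anchor pairs available")
  sel <- rbind(cbind(vcp_cand[seq_len(n_vcp), , drop = FALSE],
                     planted_class = "vcp"),
               cbind(ctl_cand[seq_len(n_ctl), , drop = FALSE],
                     planted_class = "control"))
  n <- nrow(sel)
  if (n == 0L)
    return(list(baseline = NULL, depleted = NULL,
                truth = list(true_vcp_loops = character(0),
                             true_control_loops = character(0),
                             true_target_genes = numeric(0))))
  e <- bed0_from_gr(k27[sel$enh]); p <- bed0_from_gr(k27[sel$prom])
  first_is_e <- e$chrom < p$chrom | (e$chrom == p$chrom & e$start <= p$start)
  loops <- data.frame(
    chrom1 = ifelse(first_is_e, e$chrom, p$chrom),
    start1 = ifelse(first_is_e, e$start, p$start),
    end1 = ifelse(first_is_e, e$end, p$end),
    chrom2 = ifelse(first_is_e, p$chrom, e$chrom),
    start2 = ifelse(first_is_e, p$start, e$start),
    end2 = ifelse(first_is_e, p$end, e$end),
    name = sprintf("loop_%04d", seq_len(n)),
    pet = 0L, fdr = 0.5,
    target_gene = p$gene_id,
    planted_class = sel$planted_class,
    stringsAsFactors = FALSE)
  pass <- rep(FALSE, n)
  pass[sample(n, min(cfg$n_loops_pass, n))] <- TRUE
  loops$pet[pass] <- rnbinom_min(sum(pass), cfg$loop_pet_mean,
                                 cfg$loop_pet_dispersion, 4L)
  loops$fdr[pass] <- stats::runif(sum(pass), 0, 0.0099)
  fail_on_pet <- !pass & sample(c(TRUE, FALSE), n, replace = TRUE)
  fail_on_fdr <- !pass & !fail_on_pet
  loops$pet[fail_on_pet] <- sample(0:3, sum(fail_on_pet), replace = TRUE)
  loops$fdr[fail_on_pet] <- stats::runif(sum(fail_on_pet), 0, 1)
  loops$pet[fail_on_fdr] <- rnbinom_min(sum(fail_on_fdr),
                                        cfg$loop_pet_mean,
                                        cfg$loop_pet_dispersion, 4L)
  loops$fdr[fail_on_fdr] <- stats::runif(sum(fail_on_fdr), 0.02, 0.6)

  true_vcp <- loops$name[pass & loops$planted_class == "vcp"]
  true_ctl <- loops$name[pass & loops$planted_class == "control"]

  depleted <- loops
  mu <- loops$pet * ifelse(loops$name %in% true_vcp,
                           cfg$depletion_factor, 1)
  depleted$pet <- stats::rnbinom(n, mu = mu,
                                 size = cfg$loop_pet_dispersion)

  ## per-gene aggregate propensity: the cluster's planted strength times
  ## (promoter term + loop-weighted enhancer terms), mirroring what the
  ## scorer measures
  target_ids <- genome$genes$gene_id[genome$genes$type == "target"]
  amc <- S4Vectors::mcols(peaks$at3)
  fold_of <- tapply(amc$fold, amc$gene_id, function(x) x[1])
  gene_fold <- as.numeric(fold_of[target_ids])
  gene_fold[is.na(gene_fold)] <- cfg$signal_fold
  loopsum <- stats::setNames(rep(0, length(target_ids)), target_ids)
  pv <- pass & loops$planted_class == "vcp"
  if (any(pv)) {
    nls_true <- loops$pet[pv] / mean(loops$pet[pass])
    add <- tapply(nls_true,
                  factor(loops$target_gene[pv], levels = target_ids), sum)
    loopsum <- ifelse(is.na(add), 0, add)
  }
  prop <- stats::setNames(gene_fold * (1 + loopsum), target_ids)
  list(baseline = loops, depleted = depleted,
       truth = list(true_vcp_loops = true_vcp,
                    true_control_loops = true_ctl,
                    true_target_genes = as.list(prop)))
}

#' Simulate knockdown expression tables and IP-MS proteomics tables
#'
#' Target genes receive log2 fold changes of
#' `-knockdown_beta * propensity / max(propensity)` plus Gaussian noise
#' whose correlation across the two perturbations is chosen so that the
#' total effect correlation equals `factor_correlation`; non-targets are
#' pure noise. Adjusted p-values derive from the simulated effects (normal
#' test at n = 3, BH-adjusted). Proteomics: `n_interactors` proteins carry
#' fold-enrichments drawn from `interactor_fc_range` with small planted
#' q-values (recorded verbatim in the protein table); PSM-level reporter
#' intensities embed the same fold changes so the peptide pipeline can be
#' run end to end. A few peptide sequences are planted in two proteins to
#' exercise unique-master-protein filtering.
#'
#' @param genome genome list.
#' @param truth truth list containing `true_target_genes`.
#' @param config [sim_config()].
#' @param seed integer; this stream uses `seed + 307`.
#' @return list with `expression` (named list `siA`, `siB` of contrast
#'   data.frames), `expr_matrix` (genes x samples, log2 scale),
#'   `psm`, `proteins` data.frames, and `truth` (interactor table).
#' @export
simulate_expression_and_proteomics <- function(genome, truth,
                                               config = sim_config(),
                                               seed = 1L) {
  set.seed(seed + SEED_OFFSETS[["omics"]])
  cfg <- config
  genes <- genome$genes
  prop <- unlist(truth$true_target_genes)
  eff <- stats::setNames(rep(0, nrow(genes)), genes$gene_id)
  if (length(prop) && max(prop) > 0)
    eff[names(prop)] <- -cfg$knockdown_beta * prop / max(prop)
  n <- nrow(genes)
  is_target <- genes$gene_id %in% names(prop)
  v_s <- if (sum(is_target) > 1) stats::var(eff[is_target]) else 0
  s2 <- cfg$knockdown_sigma^2
  c_noise <- (cfg$factor_correlation * (v_s + s2) - v_s) / s2
  c_noise <- max(-1, min(1, c_noise))
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  eA <- cfg$knockdown_sigma * z1
  eB <- cfg$knockdown_sigma * (c_noise * z1 + sqrt(1 - c_noise^2) * z2)
  fcA <- eff + eA
  fcB <- eff + eB
  padj_of <- function(fc) {
    p <- 2 * stats::pnorm(-abs(fc) / (cfg$knockdown_sigma / sqrt(3)))
    stats::p.adjust(p, method = "BH")
  }
  expression <- list(
    siA = data.frame(gene_id = genes$gene_id, log2fc = fcA,
                     adjusted_p = padj_of(fcA), stringsAsFactors = FALSE),
    siB = data.frame(gene_id = genes$gene_id, log2fc = fcB,
                     adjusted_p = padj_of(fcB), stringsAsFactors = FALSE))
  base_expr <- stats::runif(n, 5, 12)
  mknoise <- function() stats::rnorm(n, 0, 0.2)
  expr_matrix <- cbind(
    siSCR_1 = base_expr + mknoise(), siSCR_2 = base_expr + mknoise(),
    siA_1 = base_expr + fcA + mknoise(), siA_2 = base_expr + fcA + mknoise(),
    siB_1 = base_expr + fcB + mknoise(), siB_2 = base_expr + fcB + mknoise())
  rownames(expr_matrix) <- genes$gene_id

  ## proteomics
  n_int <- cfg$n_interactors
  prot_id <- c(sprintf("INT%03d", seq_len(n_int)),
               sprintf("NUL%04d", seq_len(cfg$n_proteins - n_int)))
  fc_true <- c(stats::runif(n_int, cfg$interactor_fc_range[1],
                            cfg$interactor_fc_range[2]),
               rep(1, cfg$n_proteins - n_int))
  q_planted <- c(10^(-stats::runif(n_int, 3, 6)),
                 stats::runif(cfg$n_proteins - n_int, 0.2, 1))
  proteins <- data.frame(protein_id = prot_id, fold_enrichment = fc_true,
                         q_value = q_planted, stringsAsFactors = FALSE)
  n_pept <- sample(2:5, cfg$n_proteins, replace = TRUE)
  pep_protein <- rep(prot_id, n_pept)
  pep_fc <- rep(fc_true, n_pept)
  n_pep_total <- length(pep_protein)
  pep_seq <- sprintf("PEP%05d", seq_len(n_pep_total))
  pep_base <- stats::runif(n_pep_total, 18, 24)
  n_psm <- sample(1:3, n_pep_total, replace = TRUE)
  idx <- rep(seq_len(n_pep_total), n_psm)
  psm_log2 <- function(group_fc) {
    pep_base[idx] + log2(group_fc[idx]) + stats::rnorm(length(idx), 0, 0.2)
  }
  one <- rep(1, n_pep_total)
  psm <- data.frame(protein_id = pep_protein[idx], peptide = pep_seq[idx],
                    ip_1 = 2^psm_log2(pep_fc), ip_2 = 2^psm_log2(pep_fc),
                    ip_3 = 2^psm_log2(pep_fc),
                    ctrl_1 = 2^psm_log2(one), ctrl_2 = 2^psm_log2(one),
                    ctrl_3 = 2^psm_log2(one), stringsAsFactors = FALSE)
  ## plant shared (non-unique) peptides: re-emit a few null peptides under
  ## a second protein id
  nulls <- which(psm$protein_id %in%
                   prot_id[seq(n_int + 1L, cfg$n_proteins)])
  if (length(nulls) >= 6L && cfg$n_proteins > n_int + 1L) {
    shared <- psm[nulls[1:3], , drop = FALSE]
    shared$protein_id <- prot_id[cfg$n_proteins]
    psm <- rbind(psm, shared)
  }
  list(expression = expression, expr_matrix = expr_matrix, psm = psm,
       proteins = proteins,
       truth = list(interactor_proteins = proteins[seq_len(n_int), ,
                                                   drop = FALSE]))
}

#' Run the whole generator, optionally writing fixture files
#'
#' Output files (all plain text, 0-based half-open coordinates):
#' `peaks_<factor>.narrowPeak`, `coverage_<factor>.bedGraph`,
#' `input.bedGraph`, `loops_baseline.bedpe`, `loops_depleted.bedpe`,
#' `tss.tsv`, `expression_<perturbation>.tsv`, `expression_matrix.tsv`,
#' `psm.tsv`, `proteins.tsv`, `truth.json`. Generation is a pure function
#' of `(config, seed)`.
#'
#' @param config [sim_config()].
#' @param seed integer base seed.
#' @param out_dir optional directory to write the fixture files into.
#' @return list with `genome`, `peaks`, `tracks`, `loops`, `expression`,
#'   `expr_matrix`, `psm`, `proteins`, `truth`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L,
                             out_dir = NULL) {
  gp <- simulate_genome_and_peaks(config, seed)
  tracks <- simulate_tracks(gp$genome, gp$peaks, config, seed)
  lp <- simulate_loops(gp$genome, gp$peaks, config, seed)
  truth <- c(gp$truth, lp$truth,
             list(depletion_factor = config$depletion_factor))
  ep <- simulate_expression_and_proteomics(gp$genome, truth, config, seed)
  truth$interactor_proteins <- ep$truth$interactor_proteins
  out <- list(genome = gp$genome, peaks = gp$peaks, tracks = tracks,
              loops = lp[c("baseline", "depleted")],
              expression = ep$expression, expr_matrix = ep$expr_matrix,
              psm = ep$psm, proteins = ep$proteins, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wp <- function(x, f) file.path(out_dir, f)
    write_narrowpeak(gp$peaks$at3, file.path(out_dir, "peaks_at3.narrowPeak"))
    write_narrowpeak(gp$peaks$vcp, file.path(out_dir, "peaks_vcp.narrowPeak"))
    write_narrowpeak(gp$peaks$h3k27ac,
                     file.path(out_dir, "peaks_h3k27ac.narrowPeak"))
    write_bedgraph(tracks$at3, file.path(out_dir, "coverage_at3.bedGraph"))
    write_bedgraph(tracks$vcp, file.path(out_dir, "coverage_vcp.bedGraph"))
    write_bedgraph(tracks$input, file.path(out_dir, "input.bedGraph"))
    if (!is.null(lp$baseline)) {
      write_bedpe(lp$baseline, file.path(out_dir, "loops_baseline.bedpe"))
      write_bedpe(lp$depleted, file.path(out_dir, "loops_depleted.bedpe"))
    }
    write_tsv(gp$genome$genes[c("gene_id", "chrom", "tss", "strand")],
              file.path(out_dir, "tss.tsv"))
    write_tsv(ep$expression$siA, file.path(out_dir, "expression_siA.tsv"))
    write_tsv(ep$expression$siB, file.path(out_dir, "expression_siB.tsv"))
    write_tsv(data.frame(gene_id = rownames(ep$expr_matrix),
                         ep$expr_matrix, check.names = FALSE),
              file.path(out_dir, "expression_matrix.tsv"))
    write_tsv(ep$psm, file.path(out_dir, "psm.tsv"))
    write_tsv(ep$proteins, file.path(out_dir, "proteins.tsv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Chromosome lengths of a simulated genome as a named vector
#' @param genome genome list from [simulate_genome_and_peaks()].
#' @return named numeric vector.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
}
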