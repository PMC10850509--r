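## HiChIP loop filtering, VCP/control anchor classification, normalized loop
## scores, and the loop-weighted per-gene aggregate enrichment score.

#' Loop filter and scoring configuration
#'
#' @param min_pets minimum PET count (kept when `pet >= min_pets`);
#'   default 4.
#' @param max_fdr FDR cutoff, strict (`fdr < max_fdr`); default 0.01.
#' @param promoter_window half-width in bp of the promoter window around the
#'   TSS (`[tss - W, tss + W)`); default 2500.
#' @param enrichment_window full width in bp of the window around a peak
#'   center over which factor enrichment is averaged; default 1000.
#' @param nls_scale normalization for the loop score: `"mean"` (PET divided
#'   by mean retained PET, unit mean; default), `"median"`, or
#'   `"per_million"` (PET per million total PETs).
#' @return list of class `loop_config`.
#' @export
loop_config <- function(min_pets = 4L, max_fdr = 0.01,
                        promoter_window = 2500L, enrichment_window = 1000L,
                        nls_scale = c("mean", "median", "per_million")) {
  stopifnot(min_pets >= 0, max_fdr > 0, max_fdr <= 1,
            promoter_window > 0, enrichment_window > 0)
  structure(list(min_pets = as.integer(min_pets), max_fdr = max_fdr,
                 promoter_window = as.integer(promoter_window),
                 enrichment_window = as.integer(enrichment_window),
                 nls_scale = match.arg(nls_scale)),
            class = "loop_config")
}

#' @noRd
anchor_gr <- function(loops, which = 1L) {
  gr_from_bed0(loops[[paste0("chrom", which)]],
               loops[[paste0("start", which)]],
               loops[[paste0("end", which)]])
}

#' Load and filter HiChIP loops
#'
#' Retains high-confidence loops with `pet >= min_pets` and
#' `fdr < max_fdr` (strict). The number dropped is reported via `message()`.
#' Loops whose two anchors overlap each other are retained with a warning.
#'
#' @param path BEDPE file path, or a loop data.frame from [read_bedpe()].
#' @param config [loop_config()].
#' @return filtered loop data.frame.
#' @export
load_filter_loops <- function(path, config = loop_config()) {
  loops <- if (is.data.frame(path)) path else read_bedpe(path)
  keep <- loops$pet >= config$min_pets & loops$fdr < config$max_fdr
  message(sprintf("retained %d of %d loops (PET >= %d, FDR < %g)",
                  sum(keep), length(keep), config$min_pets, config$max_fdr))
  out <- loops[keep, , drop = FALSE]
  self_ov <- out$chrom1 == out$chrom2 &
    out$start1 < out$end2 & out$start2 < out$end1
  if (any(self_ov))
    warning(sum(self_ov), " loop(s) have overlapping anchors; retained")
  rownames(out) <- NULL
  out
}

#' Classify anchors and loops by VCP-peak occupancy
#'
#' An H3K27ac anchor is a `vcp_anchor` when it overlaps at least one VCP
#' peak by one base or more, otherwise a `control_anchor`. A loop is class
#' `vcp` when at least one of its anchors is a vcp_anchor, else `control`.
#' Passing `restrict_to` (e.g. highly enriched regions) limits the VCP peaks
#' considered to those overlapping it, which yields SE-loop style classes.
#'
#' @param loops filtered loop data.frame.
#' @param vcp_peaks `GRanges` of VCP peaks.
#' @param restrict_to optional `GRanges`; only VCP peaks overlapping it are
#'   used.
#' @return `loops` with added logical columns `vcp_anchor1`, `vcp_anchor2`
#'   and a `class` column (`"vcp"`/`"control"`).
#' @export
classify_anchors_and_loops <- function(loops, vcp_peaks,
                                       restrict_to = NULL) {
  if (!is.null(restrict_to))
    vcp_peaks <- vcp_peaks[suppressWarnings(GenomicRanges::countOverlaps(
      vcp_peaks, restrict_to, ignore.strand = TRUE)) > 0L]
  if (!nrow(loops)) {
    loops$vcp_anchor1 <- logical(0)
    loops$vcp_anchor2 <- logical(0)
    loops$class <- character(0)
    return(loops)
  }
  a1 <- suppressWarnings(
    GenomicRanges::countOverlaps(anchor_gr(loops, 1L), vcp_peaks,
                                 ignore.strand = TRUE)) > 0L
  a2 <- suppressWarnings(
    GenomicRanges::countOverlaps(anchor_gr(loops, 2L), vcp_peaks,
                                 ignore.strand = TRUE)) > 0L
  loops$vcp_anchor1 <- a1
  loops$vcp_anchor2 <- a2
  loops$class <- ifelse(a1 | a2, "vcp", "control")
  loops
}

#' Normalized loop score (NLS)
#'
#' Depth-normalized per-loop strength. With the default `"mean"` scale,
#' `nls = pet / mean(pet)` over the retained loops, so the scores have unit
#' mean and are invariant to uniform PET scaling (library depth).
#'
#' @param loops filtered loop data.frame.
#' @param config [loop_config()] (`nls_scale` selects the normalization).
#' @return `loops` with a numeric `nls` column.
#' @export
normalized_loop_score <- function(loops, config = loop_config()) {
  if (!nrow(loops)) stop("empty loop set")
  if (sum(loops$pet) <= 0) stop("total PET count must be positive")
  loops$nls <- switch(config$nls_scale,
    mean = loops$pet / mean(loops$pet),
    median = loops$pet / stats::median(loops$pet),
    per_million = loops$pet / sum(loops$pet) * 1e6
  )
  loops
}

#' Assign promoter / looped-enhancer context to VCP peaks
#'
#' A peak is promoter-context for gene `g` when its center
#' (`floor((start0 + end0) / 2)`) lies in `[tss - W, tss + W)`. A peak is
#' looped-enhancer-context for `g` via loop `l` when the peak center lies
#' inside one anchor of `l` and the partner anchor intersects `g`'s promoter
#' window. A peak may carry several contexts across genes.
#'
#' @param vcp_peaks `GRanges` of VCP peaks (with a `name` column).
#' @param genes gene table (`gene_id`, `chrom`, `tss`).
#' @param loops classified loop data.frame with `nls` set.
#' @param config [loop_config()].
#' @return data.frame with one row per (peak, gene, context) assignment:
#'   columns `peak` (index into `vcp_peaks`), `peak_name`, `gene_id`,
#'   `context` (`"promoter"`/`"looped_enhancer"`), `loop_name` and `nls`
#'   (NA for promoter contexts).
#' @export
assign_peak_context <- function(vcp_peaks, genes, loops,
                                config = loop_config()) {
  W <- config$promoter_window
  centers0 <- floor((GenomicRanges::start(vcp_peaks) - 1L +
                       GenomicRanges::end(vcp_peaks)) / 2)
  center_gr <- gr_from_bed0(
    as.character(GenomicRanges::seqnames(vcp_peaks)), centers0, centers0 + 1L)
  prom_gr <- gr_from_bed0(genes$chrom, pmax(genes$tss - W, 0L),
                          genes$tss + W)
  peak_names <- S4Vectors::mcols(vcp_peaks)$name
  if (is.null(peak_names)) peak_names <- sprintf("peak_%d",
                                                 seq_along(vcp_peaks))
  rows <- list()
  ## promoter contexts: peak center inside the promoter window
  hits <- GenomicRanges::findOverlaps(center_gr, prom_gr,
                                      ignore.strand = TRUE)
  if (length(hits))
    rows[[length(rows) + 1L]] <- data.frame(
      peak = S4Vectors::queryHits(hits),
      peak_name = peak_names[S4Vectors::queryHits(hits)],
      gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
      context = "promoter", loop_name = NA_character_, nls = NA_real_,
      stringsAsFactors = FALSE)
  ## looped-enhancer contexts: center in one anchor, partner anchor
  ## intersects the gene's promoter window
  if (nrow(loops)) {
    for (side in 1:2) {
      partner <- 3L - side
      in_anchor <- GenomicRanges::findOverlaps(center_gr,
                                               anchor_gr(loops, side),
                                               ignore.strand = TRUE)
      if (!length(in_anchor)) next
      part_prom <- GenomicRanges::findOverlaps(anchor_gr(loops, partner),
                                               prom_gr,
                                               ignore.strand = TRUE)
      if (!length(part_prom)) next
      pp <- data.frame(loop = S4Vectors::queryHits(part_prom),
                       gene = S4Vectors::subjectHits(part_prom))
      ia <- data.frame(peak = S4Vectors::queryHits(in_anchor),
                       loop = S4Vectors::subjectHits(in_anchor))
      m <- merge(ia, pp, by = "loop")
      if (!nrow(m)) next
      rows[[length(rows) + 1L]] <- data.frame(
        peak = m$peak, peak_name = peak_names[m$peak],
        gene_id = genes$gene_id[m$gene],
        context = "looped_enhancer",
        loop_name = loops$name[m$loop], nls = loops$nls[m$loop],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(peak = integer(0), peak_name = character(0),
                      gene_id = character(0), context = character(0),
                      loop_name = character(0), nls = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("peak", "gene_id", "context", "loop_name")]),
             , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Loop-weighted aggregate target-gene enrichment scores
#'
#' For each gene and each factor track `f`,
#' `score_f(g) = sum over promoter peaks p of E_f(p) +
#'  sum over looped-enhancer (p, l) pairs of E_f(p) * nls_l`,
#' where `E_f(p)` is the mean track value over the `enrichment_window`
#' centered on the peak center (window clipped at chromosome ends with a
#' warning). Gene class is `looped_enhancer` when at least one enhancer pair
#' exists, else `promoter_only` when a promoter peak exists, else
#' `untargeted`. `nls_per_promoter` sums the NLS of class-`vcp` loops with
#' an anchor intersecting the gene's promoter window.
#'
#' @param genes gene table.
#' @param contexts assignments from [assign_peak_context()].
#' @param vcp_peaks the peak `GRanges` the contexts index into.
#' @param tracks named list of coverage `GRanges`, one per factor.
#' @param loops classified loop data.frame with `nls`.
#' @param config [loop_config()].
#' @param chrom_lengths optional named vector for window clipping.
#' @return data.frame with one row per gene: `gene_id`, `class`,
#'   `score_<factor>` per track, `nls_per_promoter`, `n_promoter_peaks`,
#'   `n_enhancer_pairs`.
#' @export
gene_aggregate_score <- function(genes, contexts, vcp_peaks, tracks, loops,
                                 config = loop_config(),
                                 chrom_lengths = NULL) {
  stopifnot(is.list(tracks), length(tracks) >= 1L,
            !is.null(names(tracks)))
  W <- config$promoter_window
  half <- config$enrichment_window %/% 2L
  centers0 <- floor((GenomicRanges::start(vcp_peaks) - 1L +
                       GenomicRanges::end(vcp_peaks)) / 2)
  ws <- centers0 - half
  we <- centers0 + (config$enrichment_window - half)
  if (any(ws < 0)) {
    warning("enrichment window clipped at chromosome start for ",
            sum(ws < 0), " peak(s)")
    ws <- pmax(ws, 0L)
  }
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[as.character(GenomicRanges::seqnames(vcp_peaks))]
    if (any(we > lim)) {
      warning("enrichment window clipped at chromosome end for ",
              sum(we > lim), " peak(s)")
      we <- pmin(we, lim)
    }
  }
  win <- gr_from_bed0(as.character(GenomicRanges::seqnames(vcp_peaks)),
                      ws, we)
  E <- lapply(tracks, function(t) track_mean(t, win))

  prof <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  is_prom <- contexts$context == "promoter"
  is_enh <- contexts$context == "looped_enhancer"
  prof$n_promoter_peaks <- as.integer(
    table(factor(contexts$gene_id[is_prom], levels = genes$gene_id)))
  prof$n_enhancer_pairs <- as.integer(
    table(factor(contexts$gene_id[is_enh], levels = genes$gene_id)))
  for (f in names(tracks)) {
    contrib <- ifelse(is_prom, E[[f]][contexts$peak],
                      E[[f]][contexts$peak] * contexts$nls)
    v <- tapply(contrib, factor(contexts$gene_id, levels = genes$gene_id),
                sum)
    sc <- as.numeric(v)
    sc[is.na(sc)] <- 0
    prof[[paste0("score_", f)]] <- sc
  }
  prof$class <- ifelse(prof$n_enhancer_pairs > 0L, "looped_enhancer",
                       ifelse(prof$n_promoter_peaks > 0L, "promoter_only",
                              "untargeted"))
  ## NLS aggregated per promoter over class-vcp loops
  npp <- numeric(nrow(genes))
  vcp_loops <- loops[!is.null(loops$class) & loops$class == "vcp", ,
                     drop = FALSE]
  if (nrow(vcp_loops)) {
    prom_gr <- gr_from_bed0(genes$chrom, pmax(genes$tss - W, 0L),
                            genes$tss + W)
    both <- unique(do.call(rbind, lapply(1:2, function(side) {
      hits <- GenomicRanges::findOverlaps(anchor_gr(vcp_loops, side),
                                          prom_gr, ignore.strand = TRUE)
      data.frame(loop = S4Vectors::queryHits(hits),
                 gene = S4Vectors::subjectHits(hits))
    })))
    if (nrow(both)) {
      v <- tapply(vcp_loops$nls[both$loop],
                  factor(both$gene, levels = seq_len(nrow(genes))), sum)
      v <- as.numeric(v)
      v[is.na(v)] <- 0
      npp <- v
    }
  }
  prof$nls_per_promoter <- npp
  prof[c("gene_id", "class", paste0("score_", names(tracks)),
         "nls_per_promoter", "n_promoter_peaks", "n_enhancer_pairs")]
}

#' Baseline-versus-depletion loop contrast
#'
#' Loops are matched across conditions by identical anchor coordinate pairs
#' (unmatched loops are reported as gained/lost). For each matched loop the
#' depth-corrected log2 ratio is
#' `log2((pet_depleted + eps) / (pet_baseline + eps)) + log2(M_b / M_d)`
#' with `M` the total PET count per condition and `eps = 0.5` a pseudocount.
#' The `vcp` and `control` classes are compared by a two-sided Wilcoxon
#' rank-sum test on the per-loop ratios.
#'
#' @param baseline,depleted classified loop data.frames (same peak set, so
#'   anchors are comparable exactly).
#' @param eps pseudocount on PET counts; default 0.5.
#' @return list with `loops` (matched loops, their classes and `log2_ratio`),
#'   `gained`, `lost` (unmatched names), `median_ratio` per class,
#'   `statistic` and `p_value` from the rank-sum test.
#' @export
loop_class_contrast <- function(baseline, depleted, eps = 0.5) {
  kb <- loop_key(baseline)
  kd <- loop_key(depleted)
  common <- intersect(kb, kd)
  if (!length(common)) stop("no loops matched across conditions")
  b <- baseline[match(common, kb), , drop = FALSE]
  d <- depleted[match(common, kd), , drop = FALSE]
  ## library sizes over the matched universe, so the depth factor is
  ## insensitive to loops present in only one condition's input table
  Mb <- sum(b$pet)
  Md <- sum(d$pet)
  ratio <- log2((d$pet + eps) / (b$pet + eps)) + log2(Mb / Md)
  out <- data.frame(name = b$name, class = b$class,
                    pet_baseline = b$pet, pet_depleted = d$pet,
                    log2_ratio = ratio, stringsAsFactors = FALSE)
  med <- tapply(out$log2_ratio, out$class, stats::median)
  v <- out$log2_ratio[out$class == "vcp"]
  ctl <- out$log2_ratio[out$class == "control"]
  if (length(v) && length(ctl)) {
    wt <- suppressWarnings(
      stats::wilcox.test(v, ctl, alternative = "two.sided",
                         exact = FALSE, correct = FALSE))
    stat <- unname(wt$statistic)
    p <- wt$p.value
    if (is.na(p)) p <- 1  # fully tied ratios carry no evidence
  } else {
    stat <- NA_real_
    p <- NA_real_
  }
  list(loops = out,
       gained = depleted$name[!(kd %in% kb)],
       lost = baseline$name[!(kb %in% kd)],
       median_ratio = med, statistic = stat, p_value = p)
}

#' Partition H3K27ac loci for differential analysis
#'
#' Set 1: H3K27ac peaks that coincide with a VCP peak, lie inside a loop
#' anchor, and rank in the `top_k` by AT3 enrichment. Set 2: H3K27ac peaks
#' inside loop anchors, not coincident with any VCP peak, ranking in the
#' `bottom_k` by AT3 enrichment. The two sets are disjoint by construction.
#'
#' @param h3k27ac_peaks `GRanges` with a `name` column.
#' @param vcp_peaks `GRanges`.
#' @param at3_enrichment numeric vector, one value per H3K27ac peak.
#' @param loops classified loop data.frame.
#' @param top_k,bottom_k set sizes (truncated with a warning when fewer
#'   candidates exist).
#' @return list with `vcp_top` and `non_vcp_bottom`, each an integer vector
#'   of indices into `h3k27ac_peaks`.
#' @export
partition_loci_for_differential <- function(h3k27ac_peaks, vcp_peaks,
                                            at3_enrichment, loops,
                                            top_k, bottom_k) {
  stopifnot(length(at3_enrichment) == length(h3k27ac_peaks))
  anchors <- suppressWarnings(c(anchor_gr(loops, 1L), anchor_gr(loops, 2L)))
  in_anchor <- suppressWarnings(
    GenomicRanges::countOverlaps(h3k27ac_peaks, anchors,
                                 ignore.strand = TRUE)) > 0L
  with_vcp <- suppressWarnings(
    GenomicRanges::countOverlaps(h3k27ac_peaks, vcp_peaks,
                                 ignore.strand = TRUE)) > 0L
  cand1 <- which(in_anchor & with_vcp)
  cand2 <- which(in_anchor & !with_vcp)
  if (top_k > length(cand1)) {
    warning("top_k exceeds available loci; truncated to ", length(cand1))
    top_k <- length(cand1)
  }
  if (bottom_k > length(cand2)) {
    warning("bottom_k exceeds available loci; truncated to ", length(cand2))
    bottom_k <- length(cand2)
  }
  set1 <- cand1[order(-at3_enrichment[cand1])][seq_len(top_k)]
  set2 <- cand2[order(at3_enrichment[cand2])][seq_len(bottom_k)]
  list(vcp_top = set1, non_vcp_bottom = set2)
}
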