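## Highly-enriched-region ("superenhancer-like") calling from stitched
## ChIP-seq peaks: blacklist filtering, gap-based stitching, input-subtracted
## density over constituent peaks only, rank-normalized signal curve, and a
## slope-1 inflection cutoff.

#' Caller configuration
#'
#' @param stitch_distance maximum edge-to-edge gap (bp) merged into one
#'   region; default 40000.
#' @param derivative_window number of rank points spanned by the centered
#'   secant used to estimate the curve slope. Default `NULL` means 1% of the
#'   number of regions, floored at 3.
#' @param threshold_method `"tangent"` (default) places the cutoff where
#'   the slope-1 tangent touches the normalized curve, i.e. at the point
#'   minimizing `signal - rank`, which is where the slope crosses 1 for a
#'   convex curve and is stable on noisy ones; `"secant"` takes the largest
#'   rank at which the estimated slope transitions from below 1 to at
#'   least 1.
#' @param blacklist optional `GRanges` of regions whose overlapping peaks
#'   are discarded.
#' @return list of class `caller_config`.
#' @export
caller_config <- function(stitch_distance = 40000L, derivative_window = NULL,
                          threshold_method = c("tangent", "secant"),
                          blacklist = NULL) {
  stopifnot(stitch_distance >= 0,
            is.null(derivative_window) || derivative_window >= 2)
  structure(list(stitch_distance = as.integer(stitch_distance),
                 derivative_window = derivative_window,
                 threshold_method = match.arg(threshold_method),
                 blacklist = blacklist),
            class = "caller_config")
}

#' Load peaks and remove blacklist overlaps
#'
#' A peak is dropped when it overlaps any blacklist interval by at least one
#' base. Blacklist intervals on chromosomes absent from the peak set are
#' ignored with a warning.
#'
#' @param path peak file (BED3/BED6/narrowPeak), or a `GRanges` already in
#'   memory.
#' @param blacklist optional `GRanges`.
#' @return filtered `GRanges`, sorted by (chromosome, start).
#' @export
load_and_filter_peaks <- function(path, blacklist = NULL) {
  peaks <- if (methods::is(path, "GRanges"))
    GenomicRanges::sort(path, ignore.strand = TRUE) else read_peaks(path)
  if (is.null(blacklist) || !length(blacklist)) return(peaks)
  unknown <- setdiff(unique(as.character(GenomicRanges::seqnames(blacklist))),
                     unique(as.character(GenomicRanges::seqnames(peaks))))
  if (length(unknown))
    warning("blacklist chromosomes not in peak set ignored: ",
            paste(unknown, collapse = ", "))
  drop <- suppressWarnings(
    GenomicRanges::countOverlaps(peaks, blacklist,
                                 ignore.strand = TRUE)) > 0L
  peaks[!drop]
}

#' Stitch peaks into regions
#'
#' Within a chromosome, consecutive peaks whose edge-to-edge gap is at most
#' `stitch_distance` are merged transitively into one region spanning the
#' minimum start to the maximum end of its constituents. Peaks on different
#' chromosomes never merge.
#'
#' @param peaks `GRanges` sorted by (chromosome, start), as returned by
#'   [load_and_filter_peaks()].
#' @param stitch_distance maximum merged gap in bp (default 40000).
#' @return `GRanges` of stitched regions with metadata columns
#'   `constituents` (IntegerList of peak indices into `peaks`),
#'   `n_peaks` and `constituent_width` (sum of constituent peak widths, bp;
#'   overlapping constituents counted once).
#' @export
stitch_peaks <- function(peaks, stitch_distance = 40000L) {
  if (!length(peaks)) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$constituents <- IRanges::IntegerList()
    return(out)
  }
  o <- order(as.character(GenomicRanges::seqnames(peaks)),
             GenomicRanges::start(peaks), GenomicRanges::end(peaks))
  if (!identical(o, seq_along(peaks)))
    stop("peaks must be sorted by (chromosome, start)")
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  s <- GenomicRanges::start(peaks)
  e <- GenomicRanges::end(peaks)
  n <- length(peaks)
  grp <- integer(n)
  grp[1] <- 1L
  run_end <- e[1]
  for (i in seq_len(n)[-1]) {
    ## 0-based gap between region so far and next peak = s0_next - e0_prev
    ## = (s[i] - 1) - run_end
    new_region <- chrom[i] != chrom[i - 1] ||
      (s[i] - 1L - run_end) > stitch_distance
    grp[i] <- grp[i - 1] + as.integer(new_region)
    run_end <- if (new_region) e[i] else max(run_end, e[i])
  }
  idx <- split(seq_len(n), grp)
  reg_chrom <- vapply(idx, function(j) chrom[j[1]], "")
  reg_start <- vapply(idx, function(j) min(s[j]), 0)
  reg_end <- vapply(idx, function(j) max(e[j]), 0)
  cw <- vapply(idx, function(j)
    sum(GenomicRanges::width(GenomicRanges::reduce(peaks[j],
                                                   ignore.strand = TRUE))),
    0)
  out <- GenomicRanges::GRanges(reg_chrom,
                                IRanges::IRanges(reg_start, reg_end))
  S4Vectors::mcols(out)$constituents <- IRanges::IntegerList(unname(idx))
  S4Vectors::mcols(out)$n_peaks <- lengths(idx)
  S4Vectors::mcols(out)$constituent_width <- as.integer(cw)
  names(out) <- sprintf("region_%d", seq_along(out))
  out
}

#' Input-subtracted signal density of stitched regions
#'
#' density = (sum of ChIP track over constituent-peak bases minus the same
#' sum of the input track) divided by the constituent width. Inter-peak gaps
#' contribute nothing; the value may be negative when input exceeds ChIP.
#'
#' @param regions stitched regions from [stitch_peaks()].
#' @param peaks the peak `GRanges` the regions were built from.
#' @param chip,input coverage `GRanges` tracks.
#' @return `regions` with a numeric `density` metadata column (signal per bp).
#' @export
region_density <- function(regions, peaks, chip, input) {
  if (!length(regions)) {
    S4Vectors::mcols(regions)$density <- numeric(0)
    return(regions)
  }
  cons <- S4Vectors::mcols(regions)$constituents
  red <- lapply(seq_along(regions), function(i)
    GenomicRanges::reduce(peaks[cons[[i]]], ignore.strand = TRUE))
  reg_idx <- rep(seq_along(regions), lengths(red))
  all_const <- unlist(methods::as(red, "GRangesList"))
  net <- track_sum(chip, all_const) - track_sum(input, all_const)
  f <- factor(reg_idx, levels = seq_along(regions))
  dens <- as.numeric(tapply(net, f, sum)) /
    as.numeric(tapply(GenomicRanges::width(all_const), f, sum))
  S4Vectors::mcols(regions)$density <- dens
  regions
}

#' Flag highly enriched regions by the slope-1 inflection of the rank curve
#'
#' Regions are sorted ascending by density; the signal is normalized so the
#' highest region is 1 and plotted against the fractional rank (highest rank
#' = 1). The curve's slope is estimated by a centered secant over
#' `derivative_window` rank points. With the default `"tangent"` method the
#' threshold is the normalized signal at the point minimizing
#' `signal - rank` (the slope-1 tangent point; the latest such point on
#' ties); with `"secant"` it is the signal at the largest rank where the
#' estimated slope transitions from below 1 to at least 1. Regions strictly
#' above the threshold are flagged. If the estimated slope is >= 1
#' everywhere all regions are flagged; if it is < 1 everywhere none are and
#' the result carries a warning flag.
#'
#' @param regions regions with a `density` column ([region_density()]).
#' @param config [caller_config()].
#' @return list with elements `regions` (input plus `fractional_rank`,
#'   `normalized_signal`, `is_highly_enriched`, in ascending density order),
#'   `threshold` (normalized-signal cutoff, `NA` when a fallback fired),
#'   `threshold_rank`, `n_flagged` and `warning` (`TRUE` when no region
#'   could be flagged).
#' @export
rank_threshold_call <- function(regions, config = caller_config()) {
  dens <- S4Vectors::mcols(regions)$density
  if (is.null(dens)) stop("regions carry no density; run region_density()")
  n <- length(regions)
  if (n < 2L) stop("need at least 2 regions with finite density")
  if (any(!is.finite(dens))) stop("non-finite densities")
  if (max(dens) <= 0) stop("maximum density <= 0; cannot normalize")
  ord <- order(dens)
  regions <- regions[ord]
  dens <- dens[ord]
  x <- seq_len(n) / n
  y <- dens / max(dens)
  w <- config$derivative_window
  if (is.null(w)) w <- max(3L, round(0.01 * n))
  h <- max(1L, floor(w / 2))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  slope <- (y[hi] - y[lo]) / (x[hi] - x[lo])
  above <- slope >= 1
  warn <- FALSE
  if (all(above)) {
    flagged <- rep(TRUE, n)
    threshold <- NA_real_
    thr_rank <- NA_real_
  } else if (!any(above)) {
    flagged <- rep(FALSE, n)
    threshold <- NA_real_
    thr_rank <- NA_real_
    warn <- TRUE
    warning("derivative below 1 everywhere; no region flagged")
  } else {
    i_star <- if (config$threshold_method == "secant") {
      max(which(!above[-n] & above[-1]) + 1L)  # below -> at/above
    } else {
      d <- y - x
      max(which(d == min(d)))  # slope-1 tangent point, latest on ties
    }
    threshold <- y[i_star]
    thr_rank <- x[i_star]
    flagged <- y > threshold
  }
  S4Vectors::mcols(regions)$fractional_rank <- x
  S4Vectors::mcols(regions)$normalized_signal <- y
  S4Vectors::mcols(regions)$is_highly_enriched <- flagged
  list(regions = regions, threshold = threshold, threshold_rank = thr_rank,
       n_flagged = sum(flagged), warning = warn)
}

#' Annotate peaks or regions with their nearest genes
#'
#' Each peak maps to the gene whose TSS is nearest to the peak midpoint
#' (`floor((start0 + end0) / 2)`); ties break toward the lower TSS
#' coordinate. A region's gene set is the union over its constituent peaks.
#' Items on chromosomes without genes are reported unannotated with a
#' warning.
#'
#' @param peaks peak `GRanges`.
#' @param genes gene table (`gene_id`, `chrom`, `tss` 0-based, `strand`).
#' @param regions optional stitched regions over `peaks`; when given, the
#'   result includes per-region gene sets.
#' @return list with `peak_gene` (character vector, one gene_id or NA per
#'   peak) and, when `regions` is given, `region_genes` (named list of
#'   gene_id vectors) and `gene_regions` (gene_id to region-name list).
#' @export
annotate_nearest_genes <- function(peaks, genes, regions = NULL) {
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  mid0 <- floor((GenomicRanges::start(peaks) - 1L +
                   GenomicRanges::end(peaks)) / 2)
  peak_gene <- rep(NA_character_, length(peaks))
  for (ch in unique(chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    sel <- which(chrom == ch)
    if (!nrow(g)) {
      warning("no genes on chromosome ", ch, "; peaks left unannotated")
      next
    }
    o <- order(g$tss, g$gene_id)
    tss <- g$tss[o]
    ids <- g$gene_id[o]
    pos <- findInterval(mid0[sel], tss)
    cand_lo <- pmax(pos, 1L)
    cand_hi <- pmin(pos + 1L, length(tss))
    d_lo <- abs(mid0[sel] - tss[cand_lo])
    d_hi <- abs(mid0[sel] - tss[cand_hi])
    ## ties (d_lo == d_hi) go to the lower TSS coordinate, i.e. cand_lo
    pick <- ifelse(d_hi < d_lo, cand_hi, cand_lo)
    peak_gene[sel] <- ids[pick]
  }
  out <- list(peak_gene = peak_gene)
  if (!is.null(regions)) {
    region_genes <- lapply(seq_along(regions), function(i) {
      j <- S4Vectors::mcols(regions)$constituents[[i]]
      sort(unique(peak_gene[j][!is.na(peak_gene[j])]))
    })
    names(region_genes) <- names(regions)
    gene_regions <- split(
      rep(names(region_genes), lengths(region_genes)),
      unlist(region_genes, use.names = FALSE)
    )
    out$region_genes <- region_genes
    out$gene_regions <- gene_regions
  }
  out
}

#' Full highly-enriched-region calling pipeline
#'
#' Blacklist-filters peaks, stitches them, computes input-subtracted
#' densities, applies the slope-1 inflection cutoff and annotates nearest
#' genes.
#'
#' @param peaks peak file path or `GRanges`.
#' @param chip,input coverage tracks.
#' @param genes gene/TSS table.
#' @param config [caller_config()].
#' @return list as [rank_threshold_call()] plus `annotation`.
#' @export
call_regions <- function(peaks, chip, input, genes,
                         config = caller_config()) {
  pk <- load_and_filter_peaks(peaks, config$blacklist)
  if (!length(pk)) stop("no peaks after blacklist filtering")
  regions <- stitch_peaks(pk, config$stitch_distance)
  regions <- region_density(regions, pk, chip, input)
  res <- rank_threshold_call(regions, config)
  res$annotation <- annotate_nearest_genes(pk, genes, res$regions)
  res$peaks <- pk
  res
}
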