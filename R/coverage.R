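## Coverage tracks are GRanges with a numeric `score` column, sorted and
## non-overlapping (bedGraph semantics). Positions not covered by any
## interval read as 0.

#' Sum of track values over intervals, base by base
#'
#' For each query interval, returns sum over its bases of the track value at
#' that base (uncovered bases contribute 0). Equivalent to integrating the
#' piecewise-constant track over the interval.
#'
#' @param track coverage `GRanges` with `score`.
#' @param gr query `GRanges`.
#' @return numeric vector, one sum per query interval.
#' @export
track_sum <- function(track, gr) {
  out <- numeric(length(gr))
  if (!length(track) || !length(gr)) return(out)
  hits <- GenomicRanges::findOverlaps(gr, track, ignore.strand = TRUE)
  if (!length(hits)) return(out)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- pmin(GenomicRanges::end(gr)[q], GenomicRanges::end(track)[s]) -
    pmax(GenomicRanges::start(gr)[q], GenomicRanges::start(track)[s]) + 1L
  contrib <- ov * S4Vectors::mcols(track)$score[s]
  v <- tapply(contrib, q, sum)
  out[as.integer(names(v))] <- as.numeric(v)
  out
}

#' Mean track value per base over intervals
#'
#' The denominator is the full interval width, so uncovered bases count as
#' zeros (not missing).
#'
#' @inheritParams track_sum
#' @return numeric vector of per-base means.
#' @export
track_mean <- function(track, gr) {
  track_sum(track, gr) / GenomicRanges::width(gr)
}

#' Depth-normalize and average coverage tracks
#'
#' Each track is scaled to reads-per-million by its library depth
#' (`score * 1e6 / depth`), then the tracks are averaged position-wise over
#' the union of their covered intervals; a chromosome or interval missing
#' from one track contributes 0 there (with a warning when chromosome sets
#' differ).
#'
#' @param tracks list of coverage `GRanges`.
#' @param depths numeric vector of total read counts, one per track, > 0.
#' @return coverage `GRanges` of the averaged RPM signal.
#' @export
average_tracks <- function(tracks, depths) {
  stopifnot(length(tracks) >= 1L, length(depths) == length(tracks),
            all(depths > 0))
  chrom_sets <- lapply(tracks, function(t)
    unique(as.character(GenomicRanges::seqnames(t))))
  if (length(unique(vapply(chrom_sets, function(x)
    paste(sort(x), collapse = ","), ""))) > 1L)
    warning("tracks cover different chromosomes; missing coverage read as 0")
  scaled <- mapply(function(t, d) {
    S4Vectors::mcols(t)$score <- S4Vectors::mcols(t)$score * 1e6 / d
    t
  }, tracks, depths, SIMPLIFY = FALSE)
  all_gr <- suppressWarnings(do.call(c, lapply(scaled, function(t) {
    S4Vectors::mcols(t) <- NULL
    t
  })))
  pieces <- GenomicRanges::disjoin(all_gr, ignore.strand = TRUE)
  acc <- numeric(length(pieces))
  for (t in scaled) {
    hits <- GenomicRanges::findOverlaps(pieces, t, ignore.strand = TRUE)
    acc[S4Vectors::queryHits(hits)] <- acc[S4Vectors::queryHits(hits)] +
      S4Vectors::mcols(t)$score[S4Vectors::subjectHits(hits)]
  }
  S4Vectors::mcols(pieces)$score <- acc / length(scaled)
  GenomicRanges::sort(pieces, ignore.strand = TRUE)
}
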