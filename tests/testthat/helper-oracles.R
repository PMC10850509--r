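## Independent oracles used across test files. These deliberately share no
## code with the implementation they check.

## Transitive closure of "edge-to-edge gap <= D" over all peak pairs
## (coordinates 0-based half-open): build the full pairwise adjacency and
## take graph connected components.
oracle_stitch <- function(chrom, start0, end0, D) {
  adj <- (outer(start0, start0, pmax) - outer(end0, end0, pmin) <= D) &
    outer(chrom, chrom, "==")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  m <- igraph::components(g)$membership
  match(m, unique(m))
}

## Random peak instance on a couple of chromosomes; returns sorted 0-based
## coordinates.
random_peak_instance <- function(n, max_pos = 1e6) {
  chrom <- sample(c("c1", "c2"), n, replace = TRUE)
  s <- floor(runif(n, 0, max_pos))
  w <- floor(runif(n, 1, 5000))
  o <- order(chrom, s, s + w)
  list(chrom = chrom[o], start = s[o], end = (s + w)[o])
}

## Per-base sum of a piecewise-constant track (0-based half-open pieces)
## over one interval, by literal base-by-base accumulation.
oracle_base_sum <- function(piece_start0, piece_end0, values, s0, e0) {
  total <- 0
  for (b in seq(s0, e0 - 1)) {
    k <- which(piece_start0 <= b & b < piece_end0)
    if (length(k)) total <- total + values[k[1]]
  }
  total
}

## Brute-force double-loop gene aggregate score: for each gene, walk every
## (peak, context) assignment and accumulate E (or E * nls) terms.
oracle_gene_score <- function(genes, contexts, E) {
  out <- stats::setNames(rep(0, nrow(genes)), genes$gene_id)
  if (!nrow(contexts)) return(out)
  for (r in seq_len(nrow(contexts))) {
    g <- contexts$gene_id[r]
    term <- if (contexts$context[r] == "promoter") E[contexts$peak[r]]
    else E[contexts$peak[r]] * contexts$nls[r]
    out[g] <- out[g] + term
  }
  out
}

## Precision/recall of flagged regions against truth intervals at >= 50%
## reciprocal overlap.
region_precision_recall <- function(flagged_gr, truth_df) {
  tr <- GenomicRanges::GRanges(
    truth_df$chrom, IRanges::IRanges(truth_df$start + 1, truth_df$end))
  if (!length(flagged_gr)) return(c(precision = NaN, recall = 0))
  hits <- GenomicRanges::findOverlaps(flagged_gr, tr, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ovw <- GenomicRanges::width(GenomicRanges::pintersect(
    flagged_gr[q], tr[s], ignore.strand = TRUE))
  ok <- ovw >= 0.5 * GenomicRanges::width(flagged_gr[q]) &
    ovw >= 0.5 * GenomicRanges::width(tr[s])
  c(precision = length(unique(q[ok])) / length(flagged_gr),
    recall = length(unique(s[ok])) / length(tr))
}

## Rank-sum AUC of scores for positives vs negatives.
auc_of <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

## Uniform coverage track over one chromosome (0-based half-open).
uniform_track <- function(chrom, len, value) {
  gr_from_bed0(chrom, 0, len, score = value)
}

## Small loop table builder.
make_loops <- function(chrom1, s1, e1, chrom2, s2, e2, pet, fdr,
                       name = NULL) {
  n <- length(s1)
  data.frame(chrom1 = rep_len(chrom1, n), start1 = s1, end1 = e1,
             chrom2 = rep_len(chrom2, n), start2 = s2, end2 = e2,
             name = if (is.null(name)) sprintf("L%03d", seq_len(n)) else name,
             pet = pet, fdr = fdr, stringsAsFactors = FALSE)
}
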