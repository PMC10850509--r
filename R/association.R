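## Target-gene association statistics: peak-count expression bins, overlap
## chi-square versus random placement, fold-change correlations between
## perturbations, responsive-gene selection, and top-percent / PC1
## contributor selection.

#' Selection configuration
#'
#' @param min_fold minimum linear fold change (inclusive); default 8.
#' @param max_padj adjusted-p cutoff, strict; default 0.01.
#' @param top_percent percentage of genes kept by aggregate score; default 1.
#' @param pc1_coefficient_min minimum PC1 coefficient (strict) for
#'   contributor genes; default 0.05.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(min_fold = 8, max_padj = 0.01,
                             top_percent = 1, pc1_coefficient_min = 0.05) {
  stopifnot(min_fold > 0, max_padj > 0, max_padj <= 1,
            top_percent > 0, top_percent <= 100)
  structure(list(min_fold = min_fold, max_padj = max_padj,
                 top_percent = top_percent,
                 pc1_coefficient_min = pc1_coefficient_min),
            class = "selection_config")
}

#' Expression contrast by associated peak count
#'
#' Genes are binned by the number of ChIP-seq peaks annotated to them;
#' reports per-count summaries and a two-sided Welch (heteroscedastic)
#' t-test comparing the pooled 1-2-peak group against the 3-or-more group.
#'
#' @param gene_peak_counts data.frame with `gene_id` and `n_peaks` (>= 1).
#' @param expression data.frame with `gene_id` and `log2fc` for one
#'   contrast.
#' @return list with `bins` (per-count n, mean, quartiles), `group_means`
#'   (1-2 vs >= 3), `t_statistic`, `p_value` (NA when a group has < 2
#'   genes, with the bins still reported).
#' @export
peak_count_expression_contrast <- function(gene_peak_counts, expression) {
  stopifnot(all(gene_peak_counts$n_peaks >= 1))
  m <- merge(gene_peak_counts, expression[c("gene_id", "log2fc")],
             by = "gene_id")
  bins <- do.call(rbind, lapply(split(m$log2fc, m$n_peaks), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(v), mean = mean(v),
               q25 = q[1], median = q[2], q75 = q[3])
  }))
  bins <- cbind(n_peaks = as.integer(rownames(bins)), bins)
  rownames(bins) <- NULL
  lo <- m$log2fc[m$n_peaks <= 2]
  hi <- m$log2fc[m$n_peaks >= 3]
  gm <- c(`1-2` = mean(lo), `>=3` = mean(hi))
  if (length(lo) >= 2 && length(hi) >= 2 &&
      (stats::sd(lo) > 0 || stats::sd(hi) > 0)) {
    tt <- stats::t.test(hi, lo, var.equal = FALSE,
                        alternative = "two.sided")
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  } else if (length(lo) >= 2 && length(hi) >= 2) {
    ## both groups constant: no difference to detect
    t_stat <- 0
    p <- 1
  } else {
    warning("a peak-count group has fewer than 2 genes; test skipped")
    t_stat <- NA_real_
    p <- NA_real_
  }
  list(bins = bins, group_means = gm, t_statistic = t_stat, p_value = p)
}

#' Pearson chi-square statistic of a 2x2 table
#'
#' Closed form `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` for the table
#' `rbind(c(a, b), c(c, d))`, optionally with the Yates continuity
#' correction; p-value from the chi-square distribution with df = 1.
#' Degenerate margins give statistic 0, p 1.
#'
#' @param tab 2x2 numeric matrix of counts.
#' @param yates apply Yates continuity correction; default FALSE.
#' @return list with `chi2`, `df`, `p_value`.
#' @export
chi2_2x2 <- function(tab, yates = FALSE) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + cc + d
  denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
  if (denom == 0) return(list(chi2 = 0, df = 1L, p_value = 1))
  num <- abs(a * d - b * cc)
  if (yates) num <- max(0, num - n / 2)
  chi2 <- n * num^2 / denom
  list(chi2 = chi2, df = 1L,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Chi-square test of peak overlap against random placement
#'
#' Counts how many `peaks_a` overlap at least one feature peak by >= 1 bp,
#' then re-places each peak uniformly at random within its own chromosome
#' (width preserved) `n_draws` times and averages the same count (rounded
#' to the nearest integer). The 2x2 table
#' `[overlap, no overlap] x [observed, random]` is tested by Pearson's
#' chi-square without continuity correction (df = 1).
#'
#' @param peaks_a,feature_peaks `GRanges`.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param n_draws random re-placements averaged into the null count;
#'   default 1, which is the calibrated two-sample comparison.
#' @param seed integer seed for the placements.
#' @param yates apply Yates continuity correction; default FALSE.
#' @return list with `table` (2x2 counts), `chi2`, `df`, `p_value`,
#'   `n_random_draws`.
#' @export
overlap_chi2_vs_random <- function(peaks_a, feature_peaks, chrom_lengths,
                                   n_draws = 1L, seed = 1L,
                                   yates = FALSE) {
  n <- length(peaks_a)
  stopifnot(n > 0)
  chrom <- as.character(GenomicRanges::seqnames(peaks_a))
  w <- GenomicRanges::width(peaks_a)
  L <- chrom_lengths[chrom]
  if (any(is.na(L))) stop("chromosome length missing for: ",
                          paste(unique(chrom[is.na(L)]), collapse = ", "))
  if (any(w > L)) stop("peak wider than its chromosome")
  observed <- sum(GenomicRanges::countOverlaps(peaks_a, feature_peaks,
                                               ignore.strand = TRUE) > 0L)
  set.seed(seed)
  draws <- vapply(seq_len(n_draws), function(i) {
    start0 <- floor(stats::runif(n, 0, L - w + 1))
    rnd <- gr_from_bed0(chrom, start0, start0 + w)
    sum(GenomicRanges::countOverlaps(rnd, feature_peaks,
                                     ignore.strand = TRUE) > 0L)
  }, 0)
  random <- round(mean(draws))
  tab <- matrix(c(observed, n - observed, random, n - random), nrow = 2,
                byrow = TRUE,
                dimnames = list(c("observed", "random"),
                                c("overlap", "no_overlap")))
  ct <- chi2_2x2(tab, yates = yates)
  list(table = tab, chi2 = ct$chi2, df = 1L, p_value = ct$p_value,
       n_random_draws = n_draws)
}

#' Fold-change correlation between two perturbations
#'
#' Spearman (midranks for ties) and Pearson coefficients with p-values over
#' the genes shared by both contrasts, optionally restricted to a gene set.
#'
#' @param expr_a,expr_b data.frames with `gene_id` and `log2fc`.
#' @param gene_set optional character vector restricting the genes used.
#' @return list with `n`, `spearman_rho`, `spearman_p`, `pearson_r`,
#'   `pearson_p`.
#' @export
foldchange_correlation <- function(expr_a, expr_b, gene_set = NULL) {
  m <- merge(expr_a[c("gene_id", "log2fc")],
             expr_b[c("gene_id", "log2fc")],
             by = "gene_id", suffixes = c("_a", "_b"))
  if (!is.null(gene_set)) m <- m[m$gene_id %in% gene_set, , drop = FALSE]
  if (nrow(m) < 3L) stop("fewer than 3 shared genes")
  sp <- suppressWarnings(
    stats::cor.test(m$log2fc_a, m$log2fc_b, method = "spearman",
                    exact = FALSE))
  pe <- stats::cor.test(m$log2fc_a, m$log2fc_b, method = "pearson")
  list(n = nrow(m),
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       pearson_r = unname(pe$estimate), pearson_p = pe$p.value)
}

#' Select genes responsive in every contrast
#'
#' A gene is kept when it has linear fold change >= `min_fold`
#' (`log2fc >= log2(min_fold)`) and adjusted p < `max_padj` in every listed
#' contrast; a gene missing from a contrast fails that contrast.
#'
#' @param contrasts named list of data.frames with `gene_id`, `log2fc`,
#'   `adjusted_p`.
#' @param config [selection_config()].
#' @return character vector of gene ids, sorted.
#' @export
select_responsive_genes <- function(contrasts, config = selection_config()) {
  stopifnot(length(contrasts) >= 1L)
  lfc_min <- log2(config$min_fold)
  sets <- lapply(contrasts, function(df) {
    df$gene_id[df$log2fc >= lfc_min & df$adjusted_p < config$max_padj]
  })
  sort(Reduce(intersect, sets))
}

#' Top-percent and PC1-contributor gene selection
#'
#' The top set is the highest `ceiling(n * top_percent / 100)` genes by
#' aggregate score (ties broken by gene_id). Principal components are
#' computed by eigen-decomposition of the gene-wise covariance of the
#' expression matrix (genes as variables, samples as observations); PC1's
#' sign is oriented so that its gene coefficients correlate positively with
#' the mean control-minus-knockdown expression difference, and contributor
#' genes have PC1 coefficient > `pc1_coefficient_min`.
#'
#' @param scores data.frame with `gene_id` and `score`.
#' @param expr_matrix numeric matrix, genes (rows, named) x samples.
#' @param control_samples,knockdown_samples column names of `expr_matrix`
#'   used to orient PC1.
#' @param config [selection_config()].
#' @return list with `top_genes`, `pc1_genes`, `pc1_coefficients` (named,
#'   oriented), `variance_explained` (PC1 fraction).
#' @export
top_and_pc1_selection <- function(scores, expr_matrix, control_samples,
                                  knockdown_samples,
                                  config = selection_config()) {
  stopifnot(!is.null(rownames(expr_matrix)),
            all(c(control_samples, knockdown_samples) %in%
                  colnames(expr_matrix)))
  n <- nrow(scores)
  m <- ceiling(n * config$top_percent / 100)
  o <- order(-scores$score, scores$gene_id)
  top_genes <- scores$gene_id[o][seq_len(min(m, n))]

  if (stats::sd(as.vector(expr_matrix)) == 0)
    stop("constant expression matrix; principal components undefined")
  pc <- stats::prcomp(t(expr_matrix), center = TRUE, scale. = FALSE)
  coef1 <- pc$rotation[, 1]
  diff <- rowMeans(expr_matrix[, control_samples, drop = FALSE]) -
    rowMeans(expr_matrix[, knockdown_samples, drop = FALSE])
  if (stats::sd(diff) > 0 && stats::sd(coef1) > 0 &&
      stats::cor(coef1, diff) < 0)
    coef1 <- -coef1
  pc1_genes <- sort(names(coef1)[coef1 > config$pc1_coefficient_min])
  list(top_genes = sort(top_genes), pc1_genes = pc1_genes,
       pc1_coefficients = coef1,
       variance_explained = unname(pc$sdev[1]^2 / sum(pc$sdev^2)))
}
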