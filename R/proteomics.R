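## Co-IP TMT proteomics downstream computation: PSM -> peptide median
## aggregation, a peptide-level moderated-t differential statistic with a
## Beta order-statistic combination to the protein level (a surrogate
## following the published PECA outline), and the total-protein-enrichment
## score used to rank interactors.

#' Median-aggregate PSMs into unique peptides
#'
#' Within each (protein, peptide) group the peptide value per channel is the
#' median of its PSM values (mean-of-middle-two for even counts). Peptide
#' sequences assigned to more than one protein are excluded, keeping only
#' peptides with a unique master protein.
#'
#' @param psms data.frame with `protein_id`, `peptide`, and one numeric
#'   column per reporter channel.
#' @return data.frame with `protein_id`, `peptide` and the median-aggregated
#'   channel columns.
#' @export
aggregate_psm_to_peptide <- function(psms) {
  stopifnot(all(c("protein_id", "peptide") %in% names(psms)))
  channels <- setdiff(names(psms), c("protein_id", "peptide"))
  if (!length(channels)) stop("no channel columns in PSM table")
  pp <- unique(psms[c("protein_id", "peptide")])
  multi <- names(which(table(unique(pp)$peptide) > 1L))
  psms <- psms[!(psms$peptide %in% multi), , drop = FALSE]
  if (!nrow(psms))
    return(psms[c("protein_id", "peptide", channels)])
  key <- paste(psms$protein_id, psms$peptide, sep = "\r")
  first <- !duplicated(key)
  out <- psms[first, c("protein_id", "peptide"), drop = FALSE]
  for (ch in channels)
    out[[ch]] <- as.numeric(
      tapply(psms[[ch]], factor(key, levels = key[first]), stats::median))
  rownames(out) <- NULL
  out
}

#' Peptide-level differential enrichment rolled up to proteins
#'
#' Channel intensities are log2-transformed (zeros offset by half the
#' smallest nonzero value in their channel), each peptide is tested IP
#' versus control with limma's moderated t-statistic, and per protein the
#' fold enrichment is the median peptide-level linear ratio of group means
#' while the p-value combines the peptide p-values through the Beta
#' order-statistic null of the median peptide p (for `n` peptides the
#' `k`-th smallest p, `k = floor(n/2) + 1`, is Beta(k, n - k + 1) under the
#' null). Protein p-values are BH-adjusted into q-values.
#'
#' @param peptides peptide table from [aggregate_psm_to_peptide()].
#' @param ip_channels,control_channels character vectors of channel column
#'   names; at least one each, two for variance estimation (with fewer the
#'   moderated fit still proceeds on the pooled prior).
#' @return data.frame with `protein_id`, `n_peptides`, `fold_enrichment`,
#'   `p_value`, `q_value`, sorted by `protein_id`.
#' @export
protein_differential <- function(peptides, ip_channels, control_channels) {
  stopifnot(length(ip_channels) >= 1L, length(control_channels) >= 1L,
            all(c(ip_channels, control_channels) %in% names(peptides)))
  chans <- c(ip_channels, control_channels)
  if (length(chans) < 3L)
    stop("need at least 3 channels in total to estimate peptide variance")
  mat <- as.matrix(peptides[chans])
  all_zero <- rowSums(mat) == 0
  if (any(all_zero)) {
    warning(sum(all_zero), " peptide(s) with all-zero intensities excluded")
    peptides <- peptides[!all_zero, , drop = FALSE]
    mat <- mat[!all_zero, , drop = FALSE]
  }
  for (j in seq_len(ncol(mat))) {
    z <- mat[, j] == 0
    if (any(z)) {
      nz <- mat[, j][!z]
      if (!length(nz)) stop("channel ", chans[j], " is all zero")
      mat[z, j] <- min(nz) / 2
    }
  }
  lmat <- log2(mat)
  group <- factor(rep(c("ip", "control"),
                      c(length(ip_channels), length(control_channels))),
                  levels = c("control", "ip"))
  design <- stats::model.matrix(~group)
  fit <- limma::eBayes(limma::lmFit(lmat, design))
  pep_p <- fit$p.value[, "groupip"]
  pep_ratio <- rowMeans(mat[, ip_channels, drop = FALSE]) /
    rowMeans(mat[, control_channels, drop = FALSE])

  prot <- split(seq_len(nrow(peptides)), peptides$protein_id)
  res <- data.frame(protein_id = names(prot), stringsAsFactors = FALSE)
  res$n_peptides <- lengths(prot)
  res$fold_enrichment <- vapply(prot, function(i)
    stats::median(pep_ratio[i]), 0)
  res$p_value <- vapply(prot, function(i) {
    n <- length(i)
    k <- n %/% 2L + 1L
    stats::pbeta(sort(pep_p[i])[k], k, n - k + 1L)
  }, 0)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  rownames(res) <- NULL
  res[order(res$protein_id), , drop = FALSE]
}

#' Total-protein-enrichment score and interactor ranking
#'
#' `enrichment_score = -log10(q_value) * (2 * fold_enrichment)`. Zero
#' q-values are clamped to the smallest representable positive double with
#' a warning. The table is sorted descending by score, ties broken by
#' fold_enrichment then protein_id.
#'
#' @param table data.frame with `protein_id`, `fold_enrichment`, `q_value`
#'   (e.g. from [protein_differential()] or a precomputed upstream table).
#' @return the table with an `enrichment_score` column, ranked.
#' @export
enrichment_score_and_rank <- function(table) {
  stopifnot(all(c("protein_id", "fold_enrichment", "q_value") %in%
                  names(table)))
  q <- table$q_value
  if (any(q == 0)) {
    warning("q_value of 0 clamped to smallest positive double")
    q[q == 0] <- .Machine$double.xmin
  }
  stopifnot(all(q > 0 & q <= 1), all(table$fold_enrichment >= 0))
  table$enrichment_score <- -log10(q) * (2 * table$fold_enrichment)
  o <- order(-table$enrichment_score, -table$fold_enrichment,
             table$protein_id)
  out <- table[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
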