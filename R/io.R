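#' @importFrom GenomicRanges GRanges seqnames start end width mcols mcols<-
#'   findOverlaps countOverlaps reduce sort.GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

## Coordinate convention: every file read or written by this package is
## 0-based half-open (BED). GRanges are 1-based closed internally; these two
## helpers are the only place the conversion happens.

#' Build a GRanges from 0-based half-open coordinates
#'
#' @param chrom character vector of chromosome names.
#' @param start0,end0 integer vectors, 0-based half-open (`start0 < end0`).
#' @param ... further vectors stored as metadata columns.
#' @return A `GRanges` (1-based closed internally).
#' @export
gr_from_bed0 <- function(chrom, start0, end0, ...) {
  stopifnot(all(start0 < end0), all(start0 >= 0))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
  extra <- list(...)
  for (nm in names(extra)) S4Vectors::mcols(gr)[[nm]] <- extra[[nm]]
  gr
}

#' Extract 0-based half-open coordinates from a GRanges
#'
#' @param gr A `GRanges`.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) plus
#'   any metadata columns.
#' @export
bed0_from_gr <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  rownames(df) <- NULL
  df
}

#' Read peaks from a BED3/BED6/narrowPeak file
#'
#' Accepts 3-, 6- or 10-column tab-separated peak files (no header). The
#' narrowPeak summit offset (column 10), when present and non-negative, is
#' kept as `summit_offset`. Any line with `start >= end` is a parse error
#' naming the offending line.
#'
#' @param path file path.
#' @return `GRanges` sorted by (chromosome, start), with metadata columns
#'   `name`, `score` and (narrowPeak only) `summit_offset`.
#' @export
read_peaks <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3L) stop("peak file needs at least 3 columns: ", path)
  bad <- which(df[[2]] >= df[[3]])
  if (length(bad)) {
    stop(sprintf("invalid interval (start >= end) at line %d of %s",
                 bad[1], path))
  }
  name <- if (ncol(df) >= 4L) as.character(df[[4]]) else
    sprintf("peak_%d", seq_len(nrow(df)))
  score <- if (ncol(df) >= 5L) suppressWarnings(as.numeric(df[[5]])) else
    rep(NA_real_, nrow(df))
  gr <- gr_from_bed0(df[[1]], df[[2]], df[[3]], name = name, score = score)
  if (ncol(df) >= 10L) {
    so <- suppressWarnings(as.integer(df[[10]]))
    so[!is.na(so) & so < 0L] <- NA_integer_
    S4Vectors::mcols(gr)$summit_offset <- so
  }
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write peaks as narrowPeak
#'
#' Coordinates are written 0-based half-open. Missing scores become 0 and
#' missing summits -1, per the narrowPeak convention.
#'
#' @param peaks `GRanges` with optional `name`, `score`, `summit_offset`.
#' @param path output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- bed0_from_gr(peaks)
  n <- nrow(df)
  name <- if (!is.null(df$name)) df$name else sprintf("peak_%d", seq_len(n))
  score <- if (!is.null(df$score)) ifelse(is.na(df$score), 0, df$score) else 0
  summit <- if (!is.null(df$summit_offset))
    ifelse(is.na(df$summit_offset), -1L, df$summit_offset) else -1L
  out <- data.frame(df$chrom, df$start, df$end, name,
                    format(score, trim = TRUE, scientific = FALSE),
                    ".", 0, -1, -1, summit)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph file (0-based half-open).
#' @return `GRanges` with numeric `score`, the package's coverage-track
#'   container: sorted, non-overlapping; positions not covered read as 0.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write a coverage track as bedGraph (0-based half-open)
#'
#' @param track `GRanges` with `score`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  df <- bed0_from_gr(track)
  out <- data.frame(df$chrom, df$start, df$end,
                    format(df$score, trim = TRUE, scientific = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read HiChIP loops from a BEDPE file
#'
#' Expects the 11-column layout written by [simulate_dataset()]: columns 1-6
#' the two anchors (0-based half-open), 7 loop name, 8 PET count, 9-10 strand
#' placeholders, 11 FDR. Extra trailing columns (hichipper-style) are
#' tolerated and ignored. Column positions for PET and FDR can be overridden.
#'
#' @param path BEDPE file.
#' @param pet_col,fdr_col 1-based column indices of the PET count and FDR.
#' @return data.frame with columns `chrom1,start1,end1,chrom2,start2,end2,
#'   name,pet,fdr` (coordinates 0-based half-open).
#' @export
read_bedpe <- function(path, pet_col = 8L, fdr_col = 11L) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < pet_col) stop("BEDPE lacks PET column ", pet_col)
  if (ncol(df) < fdr_col) stop("BEDPE lacks FDR column ", fdr_col)
  out <- data.frame(
    chrom1 = as.character(df[[1]]), start1 = as.integer(df[[2]]),
    end1 = as.integer(df[[3]]),
    chrom2 = as.character(df[[4]]), start2 = as.integer(df[[5]]),
    end2 = as.integer(df[[6]]),
    name = if (ncol(df) >= 7L) as.character(df[[7]]) else
      sprintf("loop_%d", seq_len(nrow(df))),
    pet = as.integer(df[[pet_col]]),
    fdr = as.numeric(df[[fdr_col]]),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$pet)) stop("non-integer PET values in column ", pet_col)
  if (anyNA(out$fdr)) stop("non-numeric FDR values in column ", fdr_col)
  out
}

#' Write loops as BEDPE (11 columns, FDR in column 11)
#'
#' @param loops loop data.frame as returned by [read_bedpe()].
#' @param path output path.
#' @export
write_bedpe <- function(loops, path) {
  out <- data.frame(loops$chrom1, loops$start1, loops$end1,
                    loops$chrom2, loops$start2, loops$end2,
                    loops$name, loops$pet, ".", ".",
                    format(loops$fdr, trim = TRUE, digits = 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' @param path TSV with header `gene_id chrom tss strand` (tss 0-based).
#' @return data.frame of genes.
#' @export
read_tss <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(df)))
    stop("TSS table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_ids in TSS table")
  df
}

#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Key for matching loop anchor pairs across conditions
#' @noRd
loop_key <- function(loops) {
  paste0(loops$chrom1, ":", loops$start1, "-", loops$end1, "|",
         loops$chrom2, ":", loops$start2, "-", loops$end2)
}
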