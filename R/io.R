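# Readers and writers for the plain-text interchange formats.
# All genomic coordinates are 0-based half-open.

#' Write an interval set as BED6
#'
#' The BED score column is `1000 * mean ratio`, clamped to
#' `[0, 1000]`; exact scores survive in the optional sidecar TSV.
#'
#' @param intervals Data frame with `chrom`, `start`, `end`, `name`,
#'   and optionally `score`, `strand`.
#' @param path Output path.
#' @param sidecar Optional TSV path retaining exact scores.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, sidecar = NULL) {
  if (!nrow(intervals)) {
    file.create(path)
    if (!is.null(sidecar))
      utils::write.table(intervals, sidecar, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    return(invisible(path))
  }
  score <- if ("score" %in% names(intervals)) intervals$score else rep(0, nrow(intervals))
  strand <- if ("strand" %in% names(intervals)) intervals$strand else rep(".", nrow(intervals))
  bed <- data.frame(chrom = intervals$chrom,
                    start = format(intervals$start, scientific = FALSE, trim = TRUE),
                    end = format(intervals$end, scientific = FALSE, trim = TRUE),
                    name = intervals$name,
                    score = round(pmin(1000, pmax(0, 1000 * score))),
                    strand = strand, stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(sidecar))
    utils::write.table(intervals, sidecar, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read a BED file (3-6 columns)
#'
#' @param path File path.
#' @return Data frame `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(df))]
  df
}

#' Write a track as bedGraph
#'
#' @param track A `probe_track`.
#' @param path Output path.
#' @param column Which value column to write (default `"M_norm"`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, column = "M_norm") {
  stopifnot(inherits(track, "probe_track"), column %in% names(track))
  ok <- !is.na(track[[column]])
  df <- data.frame(track$chrom[ok],
                   format(track$start[ok], scientific = FALSE, trim = TRUE),
                   format(track$end[ok], scientific = FALSE, trim = TRUE),
                   track[[column]][ok])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s",
                     attr(track, "sample_id") %||% "track"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an expression matrix with its group sidecar
#'
#' @param mat Genes x samples matrix (row names = gene ids).
#' @param groups Group label per column.
#' @param path Output CSV (first column `gene_id`, header = sample
#'   ids).
#' @param groups_path Sidecar CSV mapping `sample` to `group`
#'   (default: `path` with `_groups` suffix).
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, groups, path,
                             groups_path = sub("(\\.[^.]*)?$", "_groups\\1", path)) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(sample = colnames(mat), group = groups),
                   groups_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expression matrix with its group sidecar
#'
#' @param path Expression CSV written by [write_expression()].
#' @param groups_path Group sidecar CSV.
#' @return A list: `matrix`, `groups`.
#' @export
read_expression <- function(path,
                            groups_path = sub("(\\.[^.]*)?$", "_groups\\1", path)) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  grp <- utils::read.csv(groups_path, stringsAsFactors = FALSE)
  if (!identical(grp$sample, colnames(mat)))
    stopf("group sidecar does not match expression columns")
  list(matrix = mat, groups = grp$group)
}

#' Read FASTA sequences
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write FASTA sequences
#'
#' @param seqs A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
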