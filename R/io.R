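# Shared readers and writers. All user-facing coordinates are 1-based
# inclusive (the R convention); BED output is converted to its native
# 0-based half-open dialect at the boundary. Writes go through a temporary
# file and an atomic rename so a failed run never leaves truncated output.

atomic_write <- function(lines, path) {
  tmp <- paste0(path, ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a single-record FASTA file
#' @param sequence Character scalar.
#' @param path Output path.
#' @param id Record identifier.
#' @export
write_locus_fasta <- function(sequence, path, id = "locus") {
  x <- Biostrings::DNAStringSet(sequence)
  names(x) <- id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read paired FASTQ files into a read data frame
#'
#' @param fastq1,fastq2 Paths to the mate-1 and mate-2 FASTQ files
#'   (gzip-aware). `fastq2` may be `NULL` for single-end input.
#' @return Read data frame with columns `id`, `mate`, `bases`, `quals` and,
#'   when read identifiers carry an `ind=<name>` token, `individual`.
#' @export
read_fastq_pairs <- function(fastq1, fastq2 = NULL) {
  one <- function(path, mate) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    ids <- sub("[/ ].*$", "", names(x))
    data.frame(id = ids, mate = mate,
               bases = as.character(x),
               quals = as.character(S4Vectors::mcols(x)$qualities),
               stringsAsFactors = FALSE)
  }
  out <- one(fastq1, 1L)
  if (!is.null(fastq2)) {
    r2 <- one(fastq2, 2L)
    if (nrow(r2) != nrow(out) || !setequal(out$id, r2$id))
      stop("mate files disagree: ", nrow(out), " vs ", nrow(r2),
           " reads or mismatching identifiers")
    out <- rbind(out, r2)
  }
  ind <- regmatches(out$id, regexpr("ind=[^_]+", out$id))
  if (length(ind) == nrow(out))
    out$individual <- sub("^ind=", "", ind)
  rownames(out) <- NULL
  out
}

#' Write a read data frame as paired FASTQ files
#' @param reads Read data frame (`id`, `mate`, `bases`, `quals`).
#' @param fastq1,fastq2 Output paths for mate 1 and mate 2.
#' @export
write_fastq_pairs <- function(reads, fastq1, fastq2) {
  one <- function(sub, path) {
    lines <- as.vector(rbind(paste0("@", sub$id), sub$bases, "+", sub$quals))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    writeLines(lines, con)
    close(con)
  }
  one(reads[reads$mate == 1L, , drop = FALSE], fastq1)
  one(reads[reads$mate == 2L, , drop = FALSE], fastq2)
  invisible(c(fastq1, fastq2))
}

#' Write intervals as BED (0-based half-open)
#' @param intervals Data frame with `start`, `end` (1-based inclusive) and
#'   optionally `name`.
#' @param path Output path.
#' @param chrom Chromosome/contig label for every record.
#' @export
write_bed <- function(intervals, path, chrom = "locus") {
  nm <- if ("name" %in% names(intervals)) intervals$name else "."
  atomic_write(sprintf("%s\t%d\t%d\t%s", chrom,
                       as.integer(intervals$start) - 1L,
                       as.integer(intervals$end), nm), path)
}

#' Read a BED file back into 1-based inclusive intervals
#' @param path BED path.
#' @return Data frame `name`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(name = if (ncol(tab) >= 4) tab[[4]] else ".",
             start = tab[[2]] + 1L, end = tab[[3]],
             stringsAsFactors = FALSE)
}

#' Write a methylation matrix as TSV
#'
#' One row per CpG site (1-based position) and one column per individual,
#' with `<ind>.meth`, `<ind>.unmeth` count columns followed by the fraction
#' columns.
#'
#' @param meth A `meth_matrix`.
#' @param path Output path.
#' @export
write_meth_tsv <- function(meth, path) {
  stopifnot(inherits(meth, "meth_matrix"))
  df <- data.frame(c_position = meth$sites$c_position,
                   status = meth$sites$status)
  for (i in seq_along(meth$individuals)) {
    id <- meth$individuals[i]
    df[[paste0(id, ".meth")]] <- meth$meth[, i]
    df[[paste0(id, ".unmeth")]] <- meth$unmeth[, i]
  }
  for (i in seq_along(meth$individuals))
    df[[paste0(meth$individuals[i], ".fraction")]] <- meth$fraction[, i]
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read an expression table
#' @param path TSV with columns `individual`, `expression`.
#' @return Named numeric vector.
#' @export
read_expression_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}
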