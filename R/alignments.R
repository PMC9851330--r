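#' Read a 12-column tabular protein alignment file
#'
#' Parses the standard blast/diamond tabular format (outfmt 6):
#' qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore. Plain or gzip-compressed files are accepted, as is a
#' data.frame that already carries the 12 columns (returned normalized).
#'
#' @param x Path to an alignment file, or a data.frame with 12 columns.
#' @return A data.frame with the canonical column names and types
#'   (identifiers as character, evalue/bitscore numeric).
#' @export
read_alignments <- function(x) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (is.data.frame(x)) {
    if (ncol(x) < 12L)
      stop("alignment table must have 12 columns, got ", ncol(x))
    x <- as.data.frame(x)[, seq_len(12L)]
    names(x) <- cols
  } else {
    if (!file.exists(x)) stop("alignment file not found: ", x)
    x <- tryCatch(
      as.data.frame(data.table::fread(
        x, header = FALSE, col.names = cols, sep = "\t",
        colClasses = list(character = 1:2))),
      error = function(e) stop("failed to parse alignment file: ",
                               conditionMessage(e)))
  }
  x$qseqid <- as.character(x$qseqid)
  x$sseqid <- as.character(x$sseqid)
  for (nm in cols[3:12]) x[[nm]] <- as.numeric(x[[nm]])
  bad <- which(!is.finite(x$evalue) | x$evalue < 0)
  if (length(bad))
    stop("malformed alignment rows (negative or non-numeric e-value) at line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  x
}

#' Write a 12-column tabular alignment file
#'
#' @param aln Data frame as returned by [read_alignments()].
#' @param path Output path (".gz" suffix gives gzip).
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path) {
  aln <- read_alignments(aln)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(aln, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
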