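#' Read a (multi-)FASTA file
#'
#' Accepts plain or gzipped FASTA with multi-line records; lowercase bases
#' are upcased.  Sequence names are the first whitespace-delimited token of
#' each header; duplicate names are rejected.
#'
#' @param path path to a FASTA file (optionally `.gz`).
#' @return Named character vector of upper-case sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  con <- gzfile(path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    stop(sprintf("empty FASTA file: %s", path))
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop(sprintf("malformed FASTA %s: expected '>' header at line %d",
                 path, nonblank[1L]))
  hdr <- which(startsWith(lines, ">"))
  nm <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  bad <- which(!nzchar(nm))
  if (length(bad))
    stop(sprintf("malformed FASTA %s: empty header name at line %d",
                 path, hdr[bad[1L]]))
  if (anyDuplicated(nm)) {
    d <- nm[duplicated(nm)][1L]
    stop(sprintf("duplicate sequence name '%s' in %s", d, path))
  }
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @param width line width for sequence wrapping.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

mapping_columns <- c("query_id", "query_length", "q_begin", "q_end",
                     "strand", "ref_id", "ref_length", "r_begin", "r_end",
                     "identity", "score")

#' Write mapping records
#'
#' `tab` is the native layout: query name, query length, query begin/end,
#' strand, reference name, reference length, reference begin/end, identity
#' (percent, 2 decimals) and score (integer bp-equivalents), one record per
#' line.  `paf` is standard 12-column PAF (0-based, half-open) with the
#' residue-match column set to `round(identity/100 * block length)`, mapping
#' quality 255 (unavailable) and the identity fraction in an `id:f:` tag.
#'
#' @param records segment data.frame from [map_all()] (needs the
#'   `query_length` and `ref_length` columns).
#' @param path output path.
#' @param format `"tab"` or `"paf"`.
#' @return The path, invisibly.
#' @export
write_mappings <- function(records, path, format = c("tab", "paf")) {
  format <- match.arg(format)
  if (NROW(records) == 0L) {
    cat("", file = path)
    return(invisible(path))
  }
  stopifnot(all(c("query_id", "query_length", "ref_length") %in%
                  names(records)),
            all(records$q_begin < records$q_end),
            all(records$r_begin < records$r_end))
  if (format == "tab") {
    out <- data.frame(records$query_id, records$query_length,
                      records$q_begin, records$q_end, records$strand,
                      records$ref_id, records$ref_length,
                      records$r_begin, records$r_end,
                      sprintf("%.2f", records$identity),
                      round(records$score))
  } else {
    blen <- records$q_end - records$q_begin
    out <- data.frame(records$query_id, records$query_length,
                      records$q_begin, records$q_end, records$strand,
                      records$ref_id, records$ref_length,
                      records$r_begin, records$r_end,
                      round(records$identity / 100 * blen), blen, 255L,
                      sprintf("id:f:%.4f", records$identity / 100))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read back mapping records written in `tab` format
#'
#' @param path path to a `tab`-format mapping file.
#' @return A data.frame with the same columns [write_mappings()] serialised.
#' @export
read_mappings <- function(path) {
  if (file.size(path) == 0L) {
    out <- data.frame(matrix(nrow = 0, ncol = length(mapping_columns)))
    names(out) <- mapping_columns
    return(out)
  }
  out <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = c("character", "integer", "integer",
                                   "integer", "character", "character",
                                   "integer", "integer", "integer",
                                   "numeric", "numeric"))
  names(out) <- mapping_columns
  out
}
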