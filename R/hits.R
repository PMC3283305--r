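#' Parse an all-vs-all similarity hit table
#'
#' Reads BLAST tabular output (`-outfmt 6` dialect, no header) or accepts an
#' in-memory data frame, keeps the minimum columns needed for clustering
#' (query id, subject id, E-value, alignment length), drops self hits, and
#' deduplicates to one hit per ordered (query, subject) pair. When a pair is
#' reported several times (multiple local alignments), the row with the
#' lowest E-value is retained and its alignment length is the one used
#' downstream; ties on E-value keep the longer alignment.
#'
#' @param hits path to a tab-separated hit file, or a data frame.
#' @param manifest a [genome_manifest()]; every gene id in the table must
#'   resolve against it.
#' @param columns named integer vector locating the `qseqid`, `sseqid`,
#'   `evalue` and `length` columns in the file. The default matches standard
#'   BLAST `-outfmt 6` (12 columns: qseqid sseqid pident length ... evalue
#'   bitscore).
#' @return a `data.table` of class `similarity_hits` with columns
#'   `query_id`, `subject_id`, `e_value`, `aln_length`; one row per ordered
#'   pair, no self pairs.
#' @export
parse_hits <- function(hits, manifest,
                       columns = c(qseqid = 1L, sseqid = 2L,
                                   evalue = 11L, length = 4L)) {
  need <- c("qseqid", "sseqid", "evalue", "length")
  if (!all(need %in% names(columns))) {
    stop("columns must name positions for: ", paste(need, collapse = ", "))
  }
  if (is.character(hits) && length(hits) == 1L) {
    if (!file.exists(hits)) stop("no such hit file: ", hits)
    raw <- if (file.size(hits) == 0L) data.table::data.table() else
      data.table::fread(hits, sep = "\t", header = FALSE,
                        colClasses = "character", fill = TRUE)
    if (nrow(raw) > 0L && ncol(raw) < max(columns)) {
      stop("hit table has ", ncol(raw), " columns but column spec needs ",
           max(columns))
    }
    if (nrow(raw) == 0L) {
      h <- data.table::data.table(query_id = character(), subject_id = character(),
                                  e_value = numeric(), aln_length = integer())
    } else {
      h <- data.table::data.table(
        query_id = raw[[columns[["qseqid"]]]],
        subject_id = raw[[columns[["sseqid"]]]],
        e_value = suppressWarnings(as.numeric(raw[[columns[["evalue"]]]])),
        aln_length = suppressWarnings(as.integer(raw[[columns[["length"]]]])))
      bad <- which(is.na(h$e_value) | is.na(h$aln_length) | h$aln_length < 1L |
                     h$e_value < 0)
      if (length(bad)) {
        stop("malformed hit row(s) at line(s): ",
             paste(utils::head(bad, 5L), collapse = ", "))
      }
    }
  } else if (is.data.frame(hits)) {
    h <- data.table::as.data.table(hits)
    nm <- names(h)
    ren <- c(qseqid = "query_id", sseqid = "subject_id",
             evalue = "e_value", length = "aln_length")
    for (k in names(ren)) if (k %in% nm) data.table::setnames(h, k, ren[[k]])
    need2 <- c("query_id", "subject_id", "e_value", "aln_length")
    if (!all(need2 %in% names(h))) {
      stop("hit data frame must have columns: ", paste(need2, collapse = ", "))
    }
    h <- h[, c("query_id", "subject_id", "e_value", "aln_length"), with = FALSE]
    h[, `:=`(query_id = as.character(query_id),
             subject_id = as.character(subject_id),
             e_value = as.numeric(e_value),
             aln_length = as.integer(aln_length))]
    if (anyNA(h$e_value) || anyNA(h$aln_length) || any(h$e_value < 0) ||
        (nrow(h) && any(h$aln_length < 1L))) {
      stop("malformed hit rows: E-values must be >= 0 and alignment lengths >= 1")
    }
  } else {
    stop("hits must be a file path or a data frame")
  }

  ids <- unique(c(h$query_id, h$subject_id))
  unknown <- setdiff(ids, manifest$gene_id)
  if (length(unknown)) {
    stop("hit table references gene id(s) absent from the manifest: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }

  h <- h[query_id != subject_id]
  if (nrow(h)) {
    data.table::setorder(h, query_id, subject_id, e_value, -aln_length)
    h <- h[!duplicated(h, by = c("query_id", "subject_id"))]
  }
  data.table::setattr(h, "class", c("similarity_hits", class(h)))
  h[]
}

#' @export
print.similarity_hits <- function(x, ...) {
  cat(sprintf("similarity_hits: %d deduplicated ordered pairs\n", nrow(x)))
  NextMethod()
}

#' Write a hit table in BLAST outfmt-6 dialect
#'
#' Emits the standard 12 tab-separated columns with placeholder values for
#' the fields the pipeline does not use (percent identity, mismatches, gap
#' opens, coordinates, bit score), so the file round-trips through
#' [parse_hits()] with the default column spec.
#'
#' @param hits a `similarity_hits` table or data frame with columns
#'   `query_id`, `subject_id`, `e_value`, `aln_length`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  h <- data.table::as.data.table(hits)
  out <- data.table::data.table(
    qseqid = h$query_id, sseqid = h$subject_id, pident = "100.00",
    length = h$aln_length, mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = h$aln_length, sstart = 1L, send = h$aln_length,
    evalue = formatC(h$e_value, format = "e", digits = 16),
    bitscore = "0.0")
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
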