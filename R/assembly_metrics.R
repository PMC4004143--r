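# Transcriptome-assembly completeness from alignment hit tables.

#' Ortholog hit ratio
#'
#' Number of non-gap aligned characters in the query (assembled unigene)
#' divided by the full length of the subject (model-organism ortholog).
#' Values near 1 indicate a fully assembled transcript; the ratio is not
#' clamped, so queries longer than their subject exceed 1.
#'
#' @param query_aligned Non-gap aligned character count(s) in the query.
#' @param subject_length Full subject length(s); must be > 0.
#' @return Numeric ratio(s).
#' @examples
#' ortholog_hit_ratio(350, 500) # 0.7
#' @export
ortholog_hit_ratio <- function(query_aligned, subject_length) {
  if (any(subject_length <= 0)) stop("subject length must be > 0")
  if (any(query_aligned < 0)) stop("negative aligned character count")
  query_aligned / subject_length
}

#' Read a 12-column tabular alignment file
#'
#' Standard 12-column tabular hit format (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore), optionally
#' with a 13th `slen` column. Subject lengths may instead be supplied as a
#' named vector. Query non-gap aligned characters are `qend - qstart + 1`.
#'
#' @param path Tab-separated hit file.
#' @param subject_lengths Optional named vector of subject lengths; needed
#'   when the file has no 13th column.
#' @return data.table of hits with `query_aligned`, `subject_length` and
#'   `hit_ratio` columns appended.
#' @export
read_hit_table <- function(path, subject_lengths = NULL) {
  dt <- fread(path, header = FALSE)
  if (ncol(dt) < 12) stop("expected at least 12 tab-separated columns")
  setnames(dt, 1:12, c("query", "subject", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore"))
  if (ncol(dt) >= 13) {
    setnames(dt, 13, "subject_length")
  } else {
    if (is.null(subject_lengths))
      stop("no slen column; supply subject_lengths")
    dt[, subject_length := subject_lengths[subject]]
    if (anyNA(dt$subject_length)) stop("missing subject length(s)")
  }
  dt[, query_aligned := abs(qend - qstart) + 1L]
  dt[, hit_ratio := ortholog_hit_ratio(query_aligned, subject_length)]
  dt[]
}

#' Best hit per query
#'
#' One hit per query: lowest e-value, ties broken by highest bit score.
#'
#' @param hits A [read_hit_table()] table.
#' @return data.table with one row per query.
#' @export
best_hits <- function(hits) {
  dt <- as.data.table(hits)
  setorder(dt, query, evalue, -bitscore)
  dt[, .SD[1], by = query]
}
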