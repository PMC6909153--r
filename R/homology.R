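# homology: deterministic local-alignment search across translated datasets
# (a stand-in for a TBLASTN step; no E-value statistics, a raw-score
# threshold plus identity report suffices for cross-annotation).

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman local alignment with affine gaps (a gap of length L costs
#' `gap_open + gap_extend * L`), computed through
#' [Biostrings::pairwiseAlignment()]. Default scoring: BLOSUM62, gap open
#' 11, gap extend 1.
#'
#' @param query,subject Protein residue strings or single-row records.
#' @param matrix Substitution-matrix name shipped with Biostrings (or a
#'   matrix).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return An object of class `homology_hit`: `query_id`, `subject_id`,
#'   `score`, `identity` (matches over alignment columns), aligned strings
#'   and 1-based `q_start`, `q_end`, `s_start`, `s_end`.
#' @export
local_align <- function(query, subject, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  qid <- if (is.data.frame(query)) query$id else "query"
  sid <- if (is.data.frame(subject)) subject$id else "subject"
  qs <- if (is.data.frame(query)) query$seq else query
  ss <- if (is.data.frame(subject)) subject$seq else subject
  stopifnot(nzchar(qs), nzchar(ss))
  subm <- get_submat(matrix)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(qs), subject = Biostrings::AAString(ss),
    type = "local", substitutionMatrix = subm,
    gapOpening = gap_open, gapExtension = gap_extend)
  len <- Biostrings::nchar(pa)
  structure(list(
    query_id = qid, subject_id = sid,
    score = as.numeric(Biostrings::score(pa)),
    identity = if (len > 0) Biostrings::nmatch(pa) / len else 0,
    length = len,
    query_aligned = as.character(Biostrings::alignedPattern(pa)),
    subject_aligned = as.character(Biostrings::alignedSubject(pa)),
    q_start = pa@pattern@range@start,
    q_end = pa@pattern@range@start + pa@pattern@range@width - 1L,
    s_start = pa@subject@range@start,
    s_end = pa@subject@range@start + pa@subject@range@width - 1L),
    class = "homology_hit")
}

#' @export
print.homology_hit <- function(x, ...) {
  cat("<homology_hit> ", x$query_id, " vs ", x$subject_id, ": score ",
      x$score, ", identity ", round(x$identity, 3), ", length ", x$length,
      "\n", sep = "")
  invisible(x)
}

#' Search a translated nucleotide dataset with a protein query
#'
#' Six-frame translates the dataset, locally aligns the query against every
#' ORF, and reports hits at or above the score threshold, sorted by score
#' (descending) with ties broken by subject id.
#'
#' @param query Protein residue string or single-row record.
#' @param dataset Nucleotide record data frame.
#' @param min_score Raw-score report threshold (default 60).
#' @param min_orf_aa Minimum ORF length for the translation stage (default
#'   30; shorter than the detector's default so that short homologous
#'   fragments remain visible).
#' @param matrix,gap_open,gap_extend Passed to [local_align()].
#' @return A `data.frame` in tabular-hit layout: `qseqid`, `sseqid`,
#'   `parent_id`, `frame`, `pident`, `length`, `score`.
#' @export
search_translated <- function(query, dataset, min_score = 60,
                              min_orf_aa = 30L, matrix = "BLOSUM62",
                              gap_open = 11, gap_extend = 1) {
  empty <- data.frame(qseqid = character(), sseqid = character(),
                      parent_id = character(), frame = integer(),
                      pident = numeric(), length = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (nrow(dataset) == 0L) return(empty)
  orfs <- six_frame_translate(dataset, min_orf_aa = min_orf_aa)
  if (nrow(orfs) == 0L) return(empty)
  qid <- if (is.data.frame(query)) query$id else "query"
  subm <- get_submat(matrix)
  rows <- lapply(seq_len(nrow(orfs)), function(i) {
    hit <- local_align(query, orfs[i, , drop = FALSE], subm,
                       gap_open, gap_extend)
    if (hit$score < min_score) return(NULL)
    data.frame(qseqid = qid, sseqid = orfs$id[i],
               parent_id = sub("_F[+-][123]_[0-9]+$", "", orfs$id[i]),
               frame = orfs$frame[i], pident = 100 * hit$identity,
               length = hit$length, score = hit$score,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$sseqid), , drop = FALSE]
  rownames(out) <- NULL
  out
}
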