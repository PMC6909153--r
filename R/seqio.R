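# seqio: FASTA I/O and six-frame stop-to-stop translation.
#
# Sequence records are plain data frames with the columns
#   id, seq, alphabet ("nucleotide"/"protein"), source, frame, offset
# so that every downstream stage can subset, join and serialise them with
# ordinary data-frame tools. Coordinates are 0-based half-open; frames are
# +1..+3 on the forward strand and -1..-3 on the reverse complement; `offset`
# is the 0-based start of a translated ORF on the forward strand of its
# parent nucleotide sequence.

#' Construct a sequence-record data frame
#'
#' @param id Character vector of identifiers.
#' @param seq Character vector of residue strings (uppercased).
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param source Dataset label (recycled).
#' @param frame Integer frame in `-3..-1, 1..3`, or `NA` when the record is
#'   not derived from translation.
#' @param offset 0-based start of the ORF in the parent nucleotide sequence,
#'   or `NA`.
#' @return A `data.frame` with one row per record.
#' @export
seq_records <- function(id = character(), seq = character(),
                        alphabet = "protein", source = NA_character_,
                        frame = NA_integer_, offset = NA_integer_) {
  stopifnot(length(id) == length(seq))
  data.frame(id = as.character(id), seq = toupper(as.character(seq)),
             alphabet = rep_len(alphabet, length(id)),
             source = rep_len(as.character(source), length(id)),
             frame = rep_len(as.integer(frame), length(id)),
             offset = rep_len(as.integer(offset), length(id)),
             stringsAsFactors = FALSE)
}

#' Read a FASTA file into a record data frame
#'
#' Residues outside the declared alphabet (`A,C,G,T,N` for nucleotide, the
#' twenty amino acids plus `X` for protein) are replaced by `N`/`X` with a
#' warning, or rejected with an error in strict mode. Header text after the
#' first whitespace is dropped from the id.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` (default) or `"nucleotide"`.
#' @param source Dataset label stored on every record.
#' @param strict If `TRUE`, illegal residues raise an error instead of being
#'   masked.
#' @return A record data frame (see [seq_records()]); empty (with a warning)
#'   for an empty file.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide"),
                       source = basename(path), strict = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path)
    return(seq_records(alphabet = alphabet, source = source))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA (no header line) at line ", nonblank[1],
         " of ", path)
  }
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- toupper(as.character(x))
  legal <- if (alphabet == "nucleotide") "ACGTN" else paste0(paste(AA20, collapse = ""), "X")
  mask <- if (alphabet == "nucleotide") "N" else "X"
  bad <- grepl(sprintf("[^%s]", legal), seqs)
  if (any(bad)) {
    if (strict) {
      stop("illegal residue(s) in record(s): ",
           paste(ids[bad], collapse = ", "))
    }
    warning(sum(bad), " record(s) contained illegal residues; replaced by ",
            mask)
    seqs[bad] <- gsub(sprintf("[^%s]", legal), mask, seqs[bad])
  }
  seq_records(id = ids, seq = seqs, alphabet = alphabet, source = source)
}

#' Write records to FASTA
#'
#' @param records A record data frame.
#' @param path Output path.
#' @param width Line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  x <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

# Translate a character vector of in-frame nucleotide strings (lengths
# trimmed to whole codons) to protein strings with '*' stops; fuzzy codons
# (containing N) give X.
translate_frames <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  out <- character(length(nt))
  ok <- n >= 3L
  if (any(ok)) {
    x <- Biostrings::DNAStringSet(substr(nt[ok], 1L, n[ok]))
    out[ok] <- as.character(Biostrings::translate(x, if.fuzzy.codon = "X"))
  }
  out
}

#' Six-frame stop-to-stop translation
#'
#' Translates a nucleotide record in all six reading frames with the standard
#' genetic code and cuts each frame into stop-to-stop segments (assembled
#' transcripts are frequently 5'-truncated, so segments are not required to
#' start at ATG). Segments shorter than `min_orf_aa` are discarded. Resulting
#' ids are suffixed deterministically with the frame and a per-frame ordinal,
#' e.g. `tx1_F+2_1`.
#'
#' @param rec A single-row nucleotide record (or a record data frame, handled
#'   row-wise).
#' @param min_orf_aa Minimum ORF length in residues (default 60, about the
#'   shortest plausible precursor: signal peptide plus three cassettes).
#' @return A protein record data frame with `frame` set and `offset` giving
#'   the 0-based forward-strand start of each ORF in its parent sequence.
#' @export
six_frame_translate <- function(rec, min_orf_aa = 60L) {
  stopifnot(min_orf_aa >= 1L, all(rec$alphabet == "nucleotide"))
  n <- nrow(rec)
  if (n == 0L) return(seq_records())
  keep <- nchar(rec$seq) >= 3L
  rec <- rec[keep, , drop = FALSE]
  n <- nrow(rec)
  if (n == 0L) return(seq_records())
  L <- nchar(rec$seq)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rec$seq)))
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  # one translation call per frame over all records
  acc_id <- list(); acc_seq <- list(); acc_src <- list()
  acc_frame <- list(); acc_off <- list()
  for (fi in seq_along(frames)) {
    fr <- frames[fi]
    tmpl <- if (fr > 0L) rec$seq else rc
    sh <- abs(fr) - 1L
    aa <- translate_frames(substring(tmpl, sh + 1L))
    seg_list <- strsplit(aa, "*", fixed = TRUE)
    for (i in seq_len(n)) {
      segs <- seg_list[[i]]
      if (!length(segs)) next
      lens <- nchar(segs)
      # 0-based residue start of each stop-to-stop segment in this frame
      aa_start <- cumsum(c(0L, head(lens, -1L) + 1L))
      sel <- which(lens >= min_orf_aa)
      if (!length(sel)) next
      nt_start <- sh + 3L * aa_start[sel]        # on the template strand
      fwd_off <- if (fr > 0L) nt_start else
        L[i] - (nt_start + 3L * lens[sel])
      acc_id[[length(acc_id) + 1L]] <-
        sprintf("%s_F%+d_%d", rec$id[i], fr, seq_along(sel))
      acc_seq[[length(acc_seq) + 1L]] <- segs[sel]
      acc_src[[length(acc_src) + 1L]] <- rep(rec$source[i], length(sel))
      acc_frame[[length(acc_frame) + 1L]] <- rep(fr, length(sel))
      acc_off[[length(acc_off) + 1L]] <- fwd_off
    }
  }
  if (!length(acc_id)) return(seq_records())
  seq_records(id = unlist(acc_id), seq = unlist(acc_seq),
              alphabet = "protein", source = unlist(acc_src),
              frame = unlist(acc_frame), offset = unlist(acc_off))
}
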