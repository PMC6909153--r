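# curation: signal-peptide heuristic and the accept/review/reject rule.

#' Heuristic signal-peptide prediction
#'
#' A documented three-criterion stand-in for a neural-network predictor,
#' evaluating the classical tripartite signal-peptide architecture within the
#' first 36 residues:
#'
#' 1. an h-region: a hydrophobic window of at least 7 residues with mean
#'    Kyte-Doolittle hydropathy >= 1.6;
#' 2. an n-region: the residues before that window carry non-negative net
#'    charge (K/R = +1, D/E = -1);
#' 3. a signal-peptidase site within 8 residues after the window whose -3 and
#'    -1 residues are small (A, G, S, C, T, V); the first qualifying
#'    position is reported as the cleavage site.
#'
#' The score is the mean of three monotone sub-scores (logistic margins of
#' the hydropathy and charge criteria, and an indicator for the cleavage
#' motif). External predictions can be injected verbatim with
#' [read_signal_calls()].
#'
#' @param protein Protein residue string or single-row record.
#' @return A list of class `signal_call`: `present`, `cleavage_pos` (0-based
#'   index of the first mature residue, `NA` when absent), `score` in
#'   `[0, 1]`, `method = "heuristic"`.
#' @export
predict_signal_peptide <- function(protein) {
  seq <- if (is.data.frame(protein)) protein$seq else protein
  call0 <- structure(list(present = FALSE, cleavage_pos = NA_integer_,
                          score = 0, method = "heuristic"),
                     class = "signal_call")
  if (nchar(seq) < 20L) {
    warning("protein shorter than 20 aa; no signal-peptide call")
    return(call0)
  }
  head_aa <- chars(substr(seq, 1L, min(36L, nchar(seq))))
  kd <- unname(KD_HYDROPATHY[head_aa])
  kd[is.na(kd)] <- 0
  w <- 7L
  nwin <- length(kd) - w + 1L
  if (nwin < 1L) return(call0)
  means <- vapply(seq_len(nwin), function(s) mean(kd[s:(s + w - 1L)]), 0)
  s_best <- which.max(means)
  hydro <- means[s_best]
  nreg <- if (s_best > 1L) head_aa[seq_len(s_best - 1L)] else character()
  charge <- sum(nreg %in% c("K", "R")) - sum(nreg %in% c("D", "E"))
  win_end <- s_best + w - 1L                      # 1-based last h-region pos
  cleavage <- NA_integer_
  all_aa <- chars(seq)
  for (c1 in (win_end + 1L):min(win_end + 8L, nchar(seq))) {
    if (c1 - 2L < 1L) next
    if (all_aa[c1] %in% SMALL_RESIDUES && all_aa[c1 - 2L] %in% SMALL_RESIDUES) {
      cleavage <- c1                              # cleave after residue c1
      break
    }
  }
  present <- hydro >= 1.6 && charge >= 0 && !is.na(cleavage)
  s_h <- 1 / (1 + exp(-(hydro - 1.6)))
  s_c <- 1 / (1 + exp(-charge))
  s_cl <- as.numeric(!is.na(cleavage))
  structure(list(present = present,
                 cleavage_pos = if (present) cleavage else NA_integer_,
                 score = mean(c(s_h, s_c, s_cl)), method = "heuristic"),
            class = "signal_call")
}

#' @export
print.signal_call <- function(x, ...) {
  cat("<signal_call> present=", x$present,
      if (!is.na(x$cleavage_pos)) paste0(" cleavage_pos=", x$cleavage_pos),
      " score=", round(x$score, 3), " (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Read externally produced signal-peptide calls
#'
#' Exchange format: TSV with columns `protein_id`, `present` (0/1),
#' `cleavage_pos` (0-based, empty/NA when absent), `score`. Calls are passed
#' through verbatim with `method = "external"`.
#'
#' @param path Path to the TSV file.
#' @return Named list of `signal_call` objects keyed by protein id.
#' @export
read_signal_calls <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "present", "cleavage_pos", "score")
  if (!all(need %in% names(tab))) {
    stop("signal-call file must have columns: ", paste(need, collapse = ", "))
  }
  calls <- lapply(seq_len(nrow(tab)), function(i) {
    structure(list(present = as.logical(tab$present[i]),
                   cleavage_pos = suppressWarnings(as.integer(tab$cleavage_pos[i])),
                   score = as.numeric(tab$score[i]), method = "external"),
              class = "signal_call")
  })
  names(calls) <- tab$protein_id
  calls
}

#' Classify a screened protein as preprohormone / review / rejected
#'
#' Codifies the manual-curation rule: a protein is an `accepted`
#' preprohormone when the detector fired and a signal peptide is present;
#' `review` when the detector fired without a signal peptide (a plausible
#' 5'-truncated transcript); `rejected` otherwise. The fraction of the
#' protein spanned by the best cluster is reported as a descriptive
#' architecture metric but never gates the decision.
#'
#' @param detector_result A `cnido_screen` from [screen_protein()].
#' @param signal_call A `signal_call` for the same protein.
#' @param protein_id Optional id cross-check; an id mismatch is an error.
#' @return An object of class `cnido_annotation` with fields `protein_id`,
#'   `signal`, `detector`, `status`, `cluster_coverage`, and
#'   `mature_peptides` (`NULL` until [mature_all()] is applied).
#' @export
classify <- function(detector_result, signal_call, protein_id = NULL) {
  stopifnot(inherits(detector_result, "cnido_screen"),
            inherits(signal_call, "signal_call"))
  if (!is.null(protein_id) && !identical(protein_id,
                                         detector_result$protein_id)) {
    stop("protein id mismatch: ", protein_id, " vs ",
         detector_result$protein_id)
  }
  status <- if (detector_result$is_hit && signal_call$present) "accepted"
  else if (detector_result$is_hit) "review"
  else "rejected"
  cov <- NA_real_
  if (length(detector_result$clusters)) {
    sizes <- vapply(detector_result$clusters,
                    function(cl) nrow(cl$members), 0L)
    best <- detector_result$clusters[[which.max(sizes)]]
    span <- max(best$members$end) - min(best$members$start)
    cov <- span / nchar(detector_result$seq)
  }
  structure(list(protein_id = detector_result$protein_id,
                 signal = signal_call, detector = detector_result,
                 status = status, cluster_coverage = cov,
                 mature_peptides = NULL, copy_counts = NULL),
            class = "cnido_annotation")
}

#' @export
print.cnido_annotation <- function(x, ...) {
  cat("<cnido_annotation> ", x$protein_id, ": ", toupper(x$status),
      " (signal=", x$signal$present, ", hit=", x$detector$is_hit, ")\n",
      sep = "")
  if (!is.null(x$copy_counts) && length(x$copy_counts)) {
    cat("  mature peptides:\n")
    for (nm in names(x$copy_counts)) {
      cat("    ", nm, " x", x$copy_counts[[nm]], "\n", sep = "")
    }
  }
  invisible(x)
}
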