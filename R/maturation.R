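# maturation: convertase cleavage, C-terminal amidation, and N-terminal
# aminopeptidase trimming with pyroglutamate and proline stops.

#' N-terminal trimming policy
#'
#' The unspecific cnidarian aminopeptidase preferentially removes
#' E, D, S, T, N, G, A, L, V, Y and F, stops at Q (converted to an
#' N-terminal pyroglutamate, written pQ) and at P in position 1 or 2 (the
#' X-P bond is an imide and resists hydrolysis). K and R are never
#' trimmable, which is what preserves peptides such as RPRSamide and
#' KPRSamide.
#'
#' @param trimmable Residues the aminopeptidase may remove.
#' @param stop_on_Q,stop_on_P_pos1,stop_on_P_pos2 Stop-rule switches.
#' @param min_len Minimum residues a mature peptide must retain (default 3);
#'   shorter products are rejected.
#' @return An object of class `trim_policy`.
#' @export
trim_policy <- function(trimmable = TRIMMABLE_DEFAULT, stop_on_Q = TRUE,
                        stop_on_P_pos1 = TRUE, stop_on_P_pos2 = TRUE,
                        min_len = 3L) {
  if (any(trimmable %in% c("Q", "P", "K", "R"))) {
    stop("trimmable set must not contain Q, P, K or R")
  }
  structure(list(trimmable = trimmable, stop_on_Q = isTRUE(stop_on_Q),
                 stop_on_P_pos1 = isTRUE(stop_on_P_pos1),
                 stop_on_P_pos2 = isTRUE(stop_on_P_pos2),
                 min_len = as.integer(min_len)),
            class = "trim_policy")
}

#' Canonical peptide display string
#'
#' `pQ` prefix for an N-terminal pyroglutamate (the core itself starts with
#' Q) and an `amide` suffix for a C-terminally amidated peptide, e.g.
#' `pQWLRGRFamide`.
#'
#' @param core Residue string.
#' @param n_state `"free"`, `"pyroglutamate"` or `"proline_protected"`.
#' @param c_state `"amide"` or `"free_acid"`.
#' @return A display string that round-trips through [parse_display()].
#' @export
peptide_display <- function(core, n_state, c_state) {
  paste0(ifelse(n_state == "pyroglutamate", "p", ""), core,
         ifelse(c_state == "amide", "amide", ""))
}

#' Parse a peptide display string
#'
#' @param display String such as `"pQGRFamide"` or `"KQPPGVW"`.
#' @return List with `core`, `n_state`, `c_state`. The N-terminal state is
#'   inferred: `pQ` prefix means pyroglutamate; otherwise a P in position 1
#'   or 2 means proline-protected; otherwise free.
#' @export
parse_display <- function(display) {
  m <- regmatches(display, regexec("^(p?)([A-Z]+?)(amide)?$", display))[[1]]
  if (length(m) == 0L) stop("not a peptide display string: ", display)
  core <- m[3]
  n_state <- if (m[2] == "p") {
    if (substr(core, 1, 1) != "Q") stop("pQ display must start with Q: ",
                                        display)
    "pyroglutamate"
  } else if (substr(core, 1, 1) == "P" || substr(core, 2, 2) == "P") {
    "proline_protected"
  } else "free"
  list(core = core, n_state = n_state,
       c_state = if (m[4] == "amide") "amide" else "free_acid")
}

#' Cleave a precursor at its processing sites
#'
#' Cleavage occurs C-terminally of each basic tract; the tract residues are
#' removed, and a G immediately preceding the tract is removed as the amide
#' donor, marking the segment `amide` (otherwise `free_acid`). Segments are
#' returned raw (no length filter, no trimming).
#'
#' @param precursor Protein residue string or single-row record.
#' @param sites Site table from [find_processing_sites()] on the same
#'   precursor.
#' @return A `data.frame` with `start`, `end`, `seq`, `c_state`.
#' @export
cleave <- function(precursor, sites) {
  seq <- if (is.data.frame(precursor)) precursor$seq else precursor
  out <- data.frame(start = integer(), end = integer(), seq = character(),
                    c_state = character(), stringsAsFactors = FALSE)
  if (nrow(sites) == 0L) return(out)
  sites <- sites[order(sites$start), , drop = FALSE]
  prev_end <- 0L
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    seg_end <- if (sites$g_preceded[i]) sites$start[i] - 1L else sites$start[i]
    seg_end <- max(seg_end, prev_end)
    if (seg_end > prev_end) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = prev_end, end = seg_end,
        seq = substring(seq, prev_end + 1L, seg_end),
        c_state = if (sites$g_preceded[i]) "amide" else "free_acid",
        stringsAsFactors = FALSE)
    }
    prev_end <- sites$end[i]
  }
  if (length(rows)) out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Basic residues at a segment's N-terminus sit directly against the upstream
# tract and are removed as convertase remnants (they are never substrates of
# the aminopeptidase).
strip_remnants <- function(seq) sub("^[KR]+", "", seq)

#' Trim a cleaved segment to its mature N-terminus
#'
#' Iterates the aminopeptidase rules in fixed order: (1) N-terminal Q stops
#' trimming and cyclises to pyroglutamate; (2) N-terminal P stops trimming;
#' (3) P in position 2 stops trimming (X-P imide); (4) a trimmable residue is
#' removed and the rules are re-applied; (5) any other residue stops trimming
#' with a free N-terminus (reported as `trim_blocked`, since the printed
#' product could only be reached through a residue outside the preferred
#' set). Products retaining fewer than `policy$min_len` residues are
#' rejected (`NULL`).
#'
#' @param segment Residue string (a cleaved segment).
#' @param policy A [trim_policy()].
#' @param c_state `"amide"` or `"free_acid"` carried through from cleavage.
#' @return A list of class `mature_peptide` with `core`, `n_state`,
#'   `c_state`, `display`, `n_trimmed`, `trim_blocked`; or `NULL` when the
#'   product is shorter than `policy$min_len`.
#' @export
trim_n_terminus <- function(segment, policy = trim_policy(),
                            c_state = "amide") {
  stopifnot(nzchar(segment))
  s <- segment
  n_state <- "free"
  blocked <- FALSE
  repeat {
    if (!nzchar(s)) break
    a <- substr(s, 1L, 1L)
    b <- substr(s, 2L, 2L)
    if (policy$stop_on_Q && a == "Q") { n_state <- "pyroglutamate"; break }
    if (policy$stop_on_P_pos1 && a == "P") { n_state <- "proline_protected"; break }
    if (policy$stop_on_P_pos2 && b == "P") { n_state <- "proline_protected"; break }
    if (a %in% policy$trimmable) { s <- substr(s, 2L, nchar(s)); next }
    blocked <- TRUE
    break
  }
  if (nchar(s) < policy$min_len) return(NULL)
  structure(list(core = s, n_state = n_state, c_state = c_state,
                 display = peptide_display(s, n_state, c_state),
                 n_trimmed = nchar(segment) - nchar(s),
                 trim_blocked = blocked),
            class = "mature_peptide")
}

#' @export
print.mature_peptide <- function(x, ...) {
  cat("<mature_peptide> ", x$display, " (N: ", x$n_state, ", C: ",
      x$c_state, if (x$trim_blocked) ", trim-blocked", ")\n", sep = "")
  invisible(x)
}

# Process one candidate cassette: strip convertase remnants, then trim.
mature_segment <- function(seq, amide, policy, start = NA_integer_) {
  stripped <- strip_remnants(seq)
  if (!nzchar(stripped)) return(NULL)
  n_removed <- nchar(seq) - nchar(stripped)
  mp <- trim_n_terminus(stripped, policy,
                        c_state = if (amide) "amide" else "free_acid")
  if (is.null(mp)) return(NULL)
  mp$start <- if (is.na(start)) NA_integer_ else
    start + n_removed + mp$n_trimmed
  mp$end <- if (is.na(mp$start)) NA_integer_ else mp$start + nchar(mp$core)
  mp
}

#' Predict all mature peptides of an annotated precursor
#'
#' Applies cleavage chemistry and N-terminal trimming to every cassette of
#' every hit cluster of an accepted or review annotation. Copy counts are
#' the multiset of display strings with multiplicities, so amidated and
#' non-amidated variants of the same core are counted separately.
#'
#' @param annotation A `cnido_annotation` from [classify()].
#' @param policy A [trim_policy()].
#' @return The annotation, with `mature_peptides` (a `data.frame` with
#'   `display`, `core`, `n_state`, `c_state`, `start`, `end`,
#'   `trim_blocked`) and `copy_counts` (named integer vector) filled in.
#' @export
mature_all <- function(annotation, policy = trim_policy()) {
  stopifnot(inherits(annotation, "cnido_annotation"))
  det <- annotation$detector
  min_copies <- det$params$min_copies
  rows <- list()
  for (cl in det$clusters) {
    if (nrow(cl$members) < min_copies) next
    for (i in seq_len(nrow(cl$members))) {
      mem <- cl$members[i, ]
      mp <- mature_segment(mem$seq, mem$amidation_flag, policy, mem$start)
      if (is.null(mp)) next
      rows[[length(rows) + 1L]] <- data.frame(
        precursor_id = annotation$protein_id, display = mp$display,
        core = mp$core, n_state = mp$n_state, c_state = mp$c_state,
        start = mp$start, end = mp$end, trim_blocked = mp$trim_blocked,
        stringsAsFactors = FALSE)
    }
  }
  peptides <- if (length(rows)) do.call(rbind, rows) else
    data.frame(precursor_id = character(), display = character(),
               core = character(), n_state = character(),
               c_state = character(), start = integer(), end = integer(),
               trim_blocked = logical(), stringsAsFactors = FALSE)
  rownames(peptides) <- NULL
  counts <- table(peptides$display)
  annotation$mature_peptides <- peptides
  annotation$copy_counts <- setNames(as.integer(counts), names(counts))
  annotation
}
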