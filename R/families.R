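# families: cross-dataset peptide families, C-terminally anchored consensus
# motifs, and the class presence/absence overview.

# Normalise peptide input to a data frame with display/core/n_state/c_state
# plus optional dataset/class/arch columns.
as_peptide_table <- function(peptides) {
  if (is.character(peptides)) {
    parsed <- lapply(peptides, parse_display)
    peptides <- data.frame(
      display = peptides,
      core = vapply(parsed, `[[`, "", "core"),
      n_state = vapply(parsed, `[[`, "", "n_state"),
      c_state = vapply(parsed, `[[`, "", "c_state"),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(peptides), all(c("display", "core", "c_state") %in%
                                           names(peptides)))
  if (is.null(peptides$dataset)) peptides$dataset <- NA_character_
  if (is.null(peptides$class)) peptides$class <- NA_character_
  if (is.null(peptides$arch)) peptides$arch <- NA_character_
  peptides
}

# Predominant value of a character vector ignoring NA; NA if none.
modal_label <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  names(sort(table(x), decreasing = TRUE))[1]
}

#' Group mature peptides into cross-dataset families
#'
#' Peptides are first bucketed by their C-terminal anchor (the last
#' `anchor_len` residues of the core together with the amidation state);
#' non-amidated variants are merged with an amidated bucket sharing an
#' identical core. Buckets are then merged agglomeratively under complete
#' linkage: two buckets join when every cross-bucket pair of cores reaches
#' right-anchored identity `merge_identity`, most-similar pairs first.
#' (Single linkage at the same threshold chains unrelated short anchors --
#' a 4-residue core matches half of almost any C-terminus -- and would
#' collapse the two ubiquitous families; complete linkage reproduces the
#' published groupings.) When peptides carry a precursor-architecture label
#' (`arch` column, e.g. `"monobasic"` vs `"dibasic"` processing-site usage,
#' see [precursor_architecture()]), buckets with conflicting labels are
#' never merged: this is what keeps GPRRamide (exclusively monobasic R
#' sites, DEIT-type spacers) apart from the X1PRX2amide family despite the
#' sequence similarity. Family ids are assigned deterministically from the
#' sorted medoid display strings.
#'
#' @param peptides Character vector of display strings, or a `data.frame`
#'   with columns `display`, `core`, `c_state` and optionally `dataset`,
#'   `class`, `arch`.
#' @param anchor_len Anchor length (default 3, >= 2).
#' @param merge_identity Single-linkage merge threshold (default 0.5).
#' @return List of `peptide_family` objects: each has `id`, `members`
#'   (peptide rows), `anchor`, `consensus` (see [consensus()]), `medoid`.
#' @export
group_families <- function(peptides, anchor_len = 3L, merge_identity = 0.5) {
  stopifnot(anchor_len >= 2L)
  pep <- as_peptide_table(peptides)
  if (nrow(pep) == 0L) return(list())
  nc <- nchar(pep$core)
  anchor <- substring(pep$core, pmax(1L, nc - anchor_len + 1L), nc)
  key <- paste(anchor, pep$c_state, sep = "|")
  buckets <- split(seq_len(nrow(pep)), key)
  # merge free-acid buckets into amide buckets sharing an identical core
  bnames <- names(buckets)
  free <- grep("\\|free_acid$", bnames)
  for (fb in free) {
    fcores <- pep$core[buckets[[fb]]]
    for (ab in grep("\\|amide$", bnames)) {
      if (any(fcores %in% pep$core[buckets[[ab]]])) {
        buckets[[ab]] <- c(buckets[[ab]], buckets[[fb]])
        buckets[[fb]] <- integer()
        break
      }
    }
  }
  buckets <- buckets[vapply(buckets, length, 0L) > 0L]
  # agglomerative complete-linkage merging: bucket-level similarity is the
  # minimum right-anchored identity over all cross-bucket core pairs
  bucket_key <- function(ix) paste(sort(pep$display[ix]), collapse = "+")
  bucket_sim <- function(ia, ib) {
    aa <- modal_label(pep$arch[ia]); ab <- modal_label(pep$arch[ib])
    if (!is.na(aa) && !is.na(ab) && aa != ab) return(-1)
    min(vapply(ia, function(a) min(vapply(ib, function(b)
      ranchored_identity(pep$core[a], pep$core[b]), 0)), 0))
  }
  repeat {
    nb <- length(buckets)
    if (nb < 2L) break
    keys <- vapply(buckets, bucket_key, "")
    ord <- order(keys)
    buckets <- buckets[ord]
    keys <- keys[ord]
    best <- NULL; best_sim <- -Inf
    for (i in seq_len(nb - 1L)) for (j in (i + 1L):nb) {
      s <- bucket_sim(buckets[[i]], buckets[[j]])
      if (s > best_sim) { best_sim <- s; best <- c(i, j) }
    }
    if (best_sim < merge_identity) break
    buckets[[best[1]]] <- c(buckets[[best[1]]], buckets[[best[2]]])
    buckets[[best[2]]] <- NULL
  }
  fams <- lapply(unname(buckets), function(ix) {
    ix <- sort(ix)
    members <- pep[ix, , drop = FALSE]
    idm <- identity_matrix(members$core)
    med <- members$display[order(-rowSums(idm), members$display)][1]
    # family anchor: shared C-terminal run over all cores + amide state
    anc <- shared_anchor(members$core)
    anc_state <- if (all(members$c_state == "amide")) "amide"
    else if (all(members$c_state == "free_acid")) "" else "(amide)"
    structure(list(id = NA_character_, members = members,
                   anchor = paste0(anc, anc_state), medoid = med),
              class = "peptide_family")
  })
  fams <- fams[order(vapply(fams, `[[`, "", "medoid"))]
  for (i in seq_along(fams)) {
    fams[[i]]$id <- sprintf("FAM%02d", i)
    fams[[i]]$consensus <- consensus(fams[[i]])
  }
  fams
}

# Longest common C-terminal run of a set of cores.
shared_anchor <- function(cores) {
  n <- min(nchar(cores))
  k <- 0L
  while (k < n) {
    col <- substring(cores, nchar(cores) - k, nchar(cores) - k)
    if (length(unique(col)) > 1L) break
    k <- k + 1L
  }
  if (k == 0L) "" else substring(cores[1], nchar(cores[1]) - k + 1L,
                                 nchar(cores[1]))
}

#' C-terminally aligned consensus pattern of a family
#'
#' Members are right-aligned; each column emits the residue when all members
#' agree (and are present), otherwise a fresh numbered wildcard annotated
#' with the observed residue set. A shared amidation state is appended.
#'
#' @param family A `peptide_family` from [group_families()].
#' @return List of class `family_consensus`: `pattern` (e.g.
#'   `"X1PRX2amide"`) and `wildcards` (named list of residue sets, columns
#'   where some members are absent include `"-"`).
#' @export
consensus <- function(family) {
  members <- family$members
  stopifnot(nrow(members) >= 1L)
  cores <- members$core
  L <- max(nchar(cores))
  padded <- vapply(cores, function(s)
    paste0(strrep("-", L - nchar(s)), s), "")
  mat <- do.call(rbind, strsplit(padded, ""))
  cols <- character(L)
  wildcards <- list()
  k <- 0L
  for (j in seq_len(L)) {
    vals <- unique(mat[, j])
    if (length(vals) == 1L && vals != "-") {
      cols[j] <- vals
    } else {
      k <- k + 1L
      nm <- paste0("X", k)
      cols[j] <- nm
      wildcards[[nm]] <- sort(vals)
    }
  }
  amide <- if (all(members$c_state == "amide")) "amide" else ""
  structure(list(pattern = paste0(paste(cols, collapse = ""), amide),
                 wildcards = wildcards),
            class = "family_consensus")
}

#' @export
print.family_consensus <- function(x, ...) {
  cat(x$pattern, "\n")
  for (nm in names(x$wildcards)) {
    cat("  ", nm, " in {", paste(x$wildcards[[nm]], collapse = ","), "}\n",
        sep = "")
  }
  invisible(x)
}

#' @export
print.peptide_family <- function(x, ...) {
  cat("<peptide_family> ", x$id %||% "?", ": ", nrow(x$members),
      " peptide(s), anchor ", x$anchor, ", consensus ",
      x$consensus$pattern, "\n", sep = "")
  invisible(x)
}

#' Family-by-class presence/absence overview
#'
#' @param families List of `peptide_family` objects whose members carry a
#'   `dataset` column.
#' @param class_map Named character vector mapping dataset labels to
#'   class/subclass labels; every dataset occurring in the families must be
#'   mapped.
#' @return An object of class `family_overview`: a `data.frame` with one row
#'   per family (id, consensus, size, breadth, class_specific and one
#'   logical column per class), sorted by breadth then size, plus the
#'   logical `matrix` as an attribute.
#' @export
presence_matrix <- function(families, class_map) {
  classes <- sort(unique(unname(class_map)))
  rows <- lapply(families, function(f) {
    ds <- unique(f$members$dataset)
    ds <- ds[!is.na(ds)]
    unmapped <- setdiff(ds, names(class_map))
    if (length(unmapped)) {
      stop("dataset(s) not mapped to a class: ",
           paste(unmapped, collapse = ", "))
    }
    pres <- classes %in% unname(class_map[ds])
    c(list(family_id = f$id, consensus = f$consensus$pattern,
           size = nrow(f$members), breadth = sum(pres),
           class_specific = sum(pres) == 1L),
      setNames(as.list(pres), classes))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out <- out[order(-out$breadth, -out$size, out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  m <- as.matrix(out[, classes, drop = FALSE])
  rownames(m) <- out$family_id
  attr(out, "matrix") <- m
  class(out) <- c("family_overview", "data.frame")
  out
}

#' Processing-site architecture of a precursor
#'
#' Summarises how a precursor's cassette array is punctuated:
#' `"monobasic"` when cleavage uses exclusively single-basic tracts,
#' `"dibasic"` when at least half of the tracts have two or more basic
#' residues, `"mixed"` otherwise. Used as the merge guard in
#' [group_families()].
#'
#' @param sites Site table from [find_processing_sites()].
#' @return A character scalar, or `NA` for an empty site table.
#' @export
precursor_architecture <- function(sites) {
  if (nrow(sites) == 0L) return(NA_character_)
  multi <- nchar(sites$tract) >= 2L
  if (!any(multi)) "monobasic"
  else if (mean(multi) >= 0.5) "dibasic"
  else "mixed"
}

#' Cystine-loop ring size of a presumed cyclic peptide
#'
#' For a core containing exactly two cysteines, the inclusive residue span
#' from the first to the second cysteine: the size of the ring closed by the
#' cystine bridge (6 for both CKGQMCWFRamide and CTSPMCWFRPamide).
#'
#' @param peptide Core residue string or display string.
#' @return Integer span, or `NA` when the peptide does not contain exactly
#'   two cysteines (with a warning when it contains more than two).
#' @export
cystine_loop_size <- function(peptide) {
  core <- tryCatch(parse_display(peptide)$core, error = function(e) peptide)
  pos <- which(chars(core) == "C")
  if (length(pos) > 2L) {
    warning("more than two cysteines; no unique cystine loop")
    return(NA_integer_)
  }
  if (length(pos) != 2L) return(NA_integer_)
  pos[2] - pos[1] + 1L
}
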