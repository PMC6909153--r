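# detector: the screening rule — at least three similar peptide cassettes,
# each followed by a classical prohormone-convertase processing site.

#' Processing-site grammar
#'
#' Classical convertase sites are mono-, di- or tribasic K/R tracts
#' (R, RR, KR, RRR, RKR, RKK, ...), optionally preceded by a glycine that is
#' consumed as the C-terminal amide donor (GR, GKR, GRR, GKRR, ...). Bare
#' monobasic tracts are too frequent in ordinary proteins to be informative,
#' so by default a monobasic site (K or R) is only accepted with a G donor;
#' multibasic tracts count regardless. Set `mono_R_requires_G = FALSE` to
#' also accept plain monobasic R.
#'
#' @param max_tract Maximum basic-tract length (default 3).
#' @param mono_K_requires_G,mono_R_requires_G Whether a length-1 K (resp. R)
#'   tract requires a preceding G to count as a site.
#' @return An object of class `site_grammar`.
#' @export
site_grammar <- function(max_tract = 3L, mono_K_requires_G = TRUE,
                         mono_R_requires_G = TRUE) {
  stopifnot(max_tract >= 1L)
  structure(list(max_tract = as.integer(max_tract),
                 mono_K_requires_G = isTRUE(mono_K_requires_G),
                 mono_R_requires_G = isTRUE(mono_R_requires_G)),
            class = "site_grammar")
}

#' Locate convertase processing sites on a protein
#'
#' Scans left to right for maximal-munch basic tracts of length 1 to
#' `grammar$max_tract` (a longer K/R run is split greedily, so `GKRR` yields
#' the single tract `KRR` with a G donor). Coordinates are 0-based half-open
#' over the basic tract only.
#'
#' @param protein A protein residue string, or a single-row record data frame.
#' @param grammar A [site_grammar()].
#' @return A `data.frame` with columns `start`, `end`, `tract`, `g_preceded`,
#'   `site_string`; zero rows when no site is present.
#' @export
find_processing_sites <- function(protein, grammar = site_grammar()) {
  seq <- if (is.data.frame(protein)) protein$seq else protein
  stopifnot(length(seq) == 1L)
  pat <- sprintf("[KR]{1,%d}", grammar$max_tract)
  m <- gregexpr(pat, seq)[[1]]
  empty <- data.frame(start = integer(), end = integer(),
                      tract = character(), g_preceded = logical(),
                      site_string = character(), stringsAsFactors = FALSE)
  if (m[1] == -1L) return(empty)
  start0 <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  tract <- substring(seq, start0 + 1L, start0 + len)
  g_prev <- start0 > 0L & substring(seq, start0, start0) == "G"
  keep <- rep(TRUE, length(tract))
  mono <- len == 1L
  keep[mono & tract == "K" & !g_prev & grammar$mono_K_requires_G] <- FALSE
  keep[mono & tract == "R" & !g_prev & grammar$mono_R_requires_G] <- FALSE
  out <- data.frame(start = start0, end = start0 + len, tract = tract,
                    g_preceded = g_prev,
                    site_string = ifelse(g_prev, paste0("G", tract), tract),
                    stringsAsFactors = FALSE)
  out[keep, , drop = FALSE]
}

#' Extract candidate peptide cassettes between processing sites
#'
#' For each site, the raw segment runs from the previous site's tract end (or
#' the protein start) up to the site's donor G when present, otherwise to the
#' tract start. Segments outside `[min_len, max_len]` are dropped. The
#' amidation flag records whether a G donor is present on the segment's own
#' site.
#'
#' @param protein Protein residue string or single-row record.
#' @param sites Site table from [find_processing_sites()] (sorted by start).
#' @param min_len,max_len Length bounds for a plausible immature peptide
#'   (defaults 3 and 30; the shortest reported mature peptide is 4 residues
#'   and the longest families are well under 15).
#' @return A `data.frame` with `start`, `end` (0-based half-open raw-segment
#'   coordinates), `seq`, `amidation_flag`, `site_index`.
#' @export
extract_candidates <- function(protein, sites, min_len = 3L, max_len = 30L) {
  seq <- if (is.data.frame(protein)) protein$seq else protein
  out <- data.frame(start = integer(), end = integer(), seq = character(),
                    amidation_flag = logical(), site_index = integer(),
                    stringsAsFactors = FALSE)
  if (nrow(sites) == 0L) return(out)
  sites <- sites[order(sites$start), , drop = FALSE]
  prev_end <- 0L
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    seg_end <- if (sites$g_preceded[i]) sites$start[i] - 1L else sites$start[i]
    seg_end <- max(seg_end, prev_end)
    len <- seg_end - prev_end
    if (len >= min_len && len <= max_len) {
      rows[[i]] <- data.frame(
        start = prev_end, end = seg_end,
        seq = substring(seq, prev_end + 1L, seg_end),
        amidation_flag = sites$g_preceded[i], site_index = i,
        stringsAsFactors = FALSE)
    }
    prev_end <- sites$end[i]
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Right-anchored pairwise identity
#'
#' Identity between two peptides after right-aligning them (conserved
#' C-termini, variable N-termini): matches over the length of the shorter
#' sequence. `X` never matches any residue.
#'
#' @param a,b Residue strings.
#' @return Fraction in `[0, 1]`.
#' @export
ranchored_identity <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  n <- min(na, nb)
  if (n == 0L) return(0)
  va <- chars(substring(a, na - n + 1L, na))
  vb <- chars(substring(b, nb - n + 1L, nb))
  sum(va == vb & va != "X") / n
}

# Pairwise right-anchored identity matrix for a character vector.
identity_matrix <- function(seqs) {
  n <- length(seqs)
  m <- diag(1, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- ranchored_identity(seqs[i], seqs[j])
    }
  }
  m
}

#' Cluster candidate cassettes by right-anchored identity
#'
#' Single-linkage clustering of candidates whose pairwise right-anchored
#' identity reaches `identity_threshold`; singleton clusters are discarded.
#' The medoid is the member maximising summed identity to the rest, ties
#' broken by the smaller start coordinate.
#'
#' @param cands Candidate table from [extract_candidates()].
#' @param identity_threshold Fraction in `(0, 1]` (default 0.5).
#' @return A list of clusters, each a list with `members` (candidate rows),
#'   `medoid` (one row) and `mean_pairwise_identity`.
#' @export
cluster_candidates <- function(cands, identity_threshold = 0.5) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  n <- nrow(cands)
  if (n < 2L) return(list())
  idm <- identity_matrix(cands$seq)
  adj <- idm >= identity_threshold
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  out <- list()
  for (k in seq_len(cur)) {
    idx <- which(comp == k)
    if (length(idx) < 2L) next
    sub <- idm[idx, idx, drop = FALSE]
    sums <- rowSums(sub)
    best <- idx[order(-sums, cands$start[idx])][1]
    mpid <- mean(sub[upper.tri(sub)])
    out[[length(out) + 1L]] <- list(
      members = cands[idx, , drop = FALSE],
      medoid = cands[best, , drop = FALSE],
      mean_pairwise_identity = mpid)
  }
  # deterministic order: by first member coordinate
  if (length(out) > 1L) {
    out <- out[order(vapply(out, function(cl) min(cl$members$start), 0L))]
  }
  out
}

#' Detector parameters
#'
#' @param min_copies Minimum cluster size for a hit (default 3: "at least
#'   three similar peptide sequences").
#' @param identity Similarity threshold for [cluster_candidates()].
#' @param min_len,max_len Candidate length bounds.
#' @param grammar A [site_grammar()].
#' @param mode `"similarity"` (clusters of mutually similar candidates, the
#'   default) or `"site_count"` (a hit whenever at least `min_copies`
#'   processing sites are present, the permissive pre-curation reading).
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(min_copies = 3L, identity = 0.5, min_len = 3L,
                            max_len = 30L, grammar = site_grammar(),
                            mode = c("similarity", "site_count")) {
  structure(list(min_copies = as.integer(min_copies), identity = identity,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 grammar = grammar, mode = match.arg(mode)),
            class = "detector_params")
}

#' Screen one protein for a multi-copy peptide cassette array
#'
#' Composes [find_processing_sites()], [extract_candidates()] and
#' [cluster_candidates()]. A protein is a hit when some cluster has at least
#' `min_copies` members (or, in `"site_count"` mode, when at least
#' `min_copies` sites are present).
#'
#' @param protein Single-row protein record (or residue string; an id is then
#'   synthesised).
#' @param params A [detector_params()].
#' @return An object of class `cnido_screen`: list with `protein_id`, `seq`,
#'   `sites`, `candidates`, `clusters`, `is_hit`.
#' @export
screen_protein <- function(protein, params = detector_params()) {
  if (!is.data.frame(protein)) {
    protein <- seq_records(id = "protein", seq = protein)
  }
  stopifnot(nrow(protein) == 1L)
  sites <- find_processing_sites(protein$seq, params$grammar)
  cands <- extract_candidates(protein$seq, sites, params$min_len,
                              params$max_len)
  clusters <- cluster_candidates(cands, params$identity)
  is_hit <- if (params$mode == "site_count") {
    nrow(sites) >= params$min_copies
  } else {
    any(vapply(clusters, function(cl) nrow(cl$members), 0L) >=
          params$min_copies)
  }
  structure(list(protein_id = protein$id, seq = protein$seq, sites = sites,
                 candidates = cands, clusters = clusters, is_hit = is_hit,
                 params = params),
            class = "cnido_screen")
}

#' @export
print.cnido_screen <- function(x, ...) {
  cat("<cnido_screen> ", x$protein_id, ": ", nrow(x$sites),
      " processing site(s), ", length(x$clusters), " cluster(s), ",
      if (x$is_hit) "HIT" else "no hit", "\n", sep = "")
  for (cl in x$clusters) {
    cat("  cluster of ", nrow(cl$members), " (medoid ", cl$medoid$seq,
        ", mean identity ", round(cl$mean_pairwise_identity, 3), ")\n",
        sep = "")
  }
  invisible(x)
}

#' Screen every protein of a record data frame
#'
#' @param records Protein record data frame.
#' @param params A [detector_params()].
#' @return A list of `cnido_screen` objects, named by protein id.
#' @export
screen_proteins <- function(records, params = detector_params()) {
  res <- lapply(seq_len(nrow(records)), function(i)
    screen_protein(records[i, , drop = FALSE], params))
  names(res) <- records$id
  res
}
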