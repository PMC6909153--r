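# phylo: p-distance, Fitch parsimony (bitmask implementation, exhaustive
# and hill-climbing search), neighbor joining, canonical Newick.

#' p-distance matrix of an alignment
#'
#' Proportion of differing sites over compared sites for every pair of rows.
#' Under pairwise deletion (default) the columns where either row carries a
#' gap are excluded for that pair; under complete deletion any column with a
#' gap in any row is excluded for all pairs.
#'
#' @param alignment A `cnido_alignment` (character matrix, `-` for gaps).
#' @param deletion_mode `"pairwise"` (default) or `"complete"`.
#' @return A symmetric numeric matrix with zero diagonal, taxa as dimnames.
#'   A pair with zero comparable sites is an error naming the pair.
#' @export
p_distance <- function(alignment, deletion_mode = c("pairwise", "complete")) {
  deletion_mode <- match.arg(deletion_mode)
  stopifnot(nrow(alignment) >= 2L)
  mat <- unclass(alignment)
  if (deletion_mode == "complete") {
    keep <- colSums(mat == "-") == 0L
    mat <- mat[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  taxa <- rownames(mat)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(ok)) {
      stop("no comparable sites between ", taxa[i], " and ", taxa[j])
    }
    d[i, j] <- d[j, i] <- mean(mat[i, ok] != mat[j, ok])
  }
  d
}

# ---- Fitch parsimony on bitmask-encoded columns -------------------------

FITCH_STATES <- c(AA20, "-")   # 21 states; fits a 32-bit integer mask

# Encode alignment columns as a (taxa x columns) integer bitmask matrix.
# X (and any unknown symbol) is fully ambiguous; in gap_mode "missing" a
# gap is also fully ambiguous, in "state" it is a 21st character state.
encode_alignment <- function(alignment, gap_mode = c("state", "missing")) {
  gap_mode <- match.arg(gap_mode)
  bits <- setNames(bitwShiftL(1L, seq_along(FITCH_STATES) - 1L),
                   FITCH_STATES)
  all_aa <- sum(bits[AA20])
  mat <- unclass(alignment)
  enc <- matrix(0L, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (i in seq_len(nrow(mat))) {
    ch <- mat[i, ]
    v <- unname(bits[ch])
    v[is.na(v)] <- all_aa                          # X / unknown residue
    if (gap_mode == "missing") v[ch == "-"] <- all_aa
    enc[i, ] <- as.integer(v)
  }
  enc
}

# Collapse identical columns, returning the reduced matrix and weights.
compress_columns <- function(enc) {
  key <- apply(enc, 2, paste, collapse = "\r")
  ux <- !duplicated(key)
  list(enc = enc[, ux, drop = FALSE],
       weight = as.integer(table(key)[key[ux]]))
}

# Root an unrooted binary phylo on its first tip so that Fitch can run on a
# strictly binary rooted topology (the score is rooting-invariant).
as_rooted_binary <- function(tree) {
  if (!ape::is.rooted(tree)) {
    tree <- ape::root(tree, outgroup = tree$tip.label[1],
                      resolve.root = TRUE)
  }
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  tree
}

# Core Fitch pass: vector of per-column change counts for encoded leaves.
# Edges are walked in postorder, so every child set is complete when its
# edge is reached; the parent accumulates by intersection, falling back to
# union (one change) on empty intersections.
fitch_column_scores <- function(tree, enc) {
  tree <- as_rooted_binary(tree)
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  ncols <- ncol(enc)
  sets <- matrix(0L, ntip + tree$Nnode, ncols)
  sets[seq_len(ntip), ] <- enc[tree$tip.label, , drop = FALSE]
  seen <- logical(ntip + tree$Nnode)
  changes <- integer(ncols)
  edge <- tree$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    if (!seen[p]) {
      sets[p, ] <- sets[ch, ]
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(sets[p, ], sets[ch, ])
      zero <- inter == 0L
      changes <- changes + zero
      sets[p, ] <- ifelse(zero, bitwOr(sets[p, ], sets[ch, ]), inter)
    }
  }
  changes
}

#' Fitch small-parsimony score of a tree on an alignment
#'
#' Minimum number of state changes summed over columns, computed by the
#' Fitch dynamic program on bitmask-encoded states. Gaps are treated as a
#' 21st character state by default (`gap_mode = "state"`), or as missing
#' data (`gap_mode = "missing"`); `X` is always fully ambiguous. The score
#' is invariant under re-rooting.
#'
#' @param tree An `ape` `phylo` tree whose tip labels match the alignment
#'   taxa exactly.
#' @param alignment A `cnido_alignment`.
#' @param gap_mode `"state"` or `"missing"`.
#' @return Integer parsimony score.
#' @export
parsimony_score <- function(tree, alignment, gap_mode = "state") {
  if (!setequal(tree$tip.label, rownames(alignment)) ||
      length(tree$tip.label) != nrow(alignment)) {
    stop("tree tips and alignment taxa differ")
  }
  enc <- encode_alignment(alignment, gap_mode)
  cc <- compress_columns(enc)
  sum(fitch_column_scores(tree, cc$enc) * cc$weight)
}

# ---- canonical Newick ---------------------------------------------------

#' Canonical Newick string of a tree topology
#'
#' Serialises the topology deterministically: the tree is rooted on its
#' lexicographically smallest tip and children are ordered by their smallest
#' descendant label. Branch lengths are omitted; equal topologies yield
#' byte-identical strings, which is also the tie-break used by
#' [best_tree()].
#'
#' @param tree A `phylo` tree.
#' @return A Newick string ending in `;`.
#' @export
canonical_newick <- function(tree) {
  tree <- ape::root(ape::unroot(tree), outgroup = min(tree$tip.label),
                    resolve.root = TRUE)
  edge <- tree$edge
  kids <- split(edge[, 2], edge[, 1])
  ntip <- length(tree$tip.label)
  build <- function(node) {
    if (node <= ntip) {
      lab <- tree$tip.label[node]
      return(list(str = lab, min = lab))
    }
    parts <- lapply(kids[[as.character(node)]], build)
    ord <- order(vapply(parts, `[[`, "", "min"))
    parts <- parts[ord]
    list(str = paste0("(", paste(vapply(parts, `[[`, "", "str"),
                                 collapse = ","), ")"),
         min = parts[[1]]$min)
  }
  root <- ntip + 1L
  paste0(build(root)$str, ";")
}

#' Write / read Newick files
#'
#' Thin wrappers over [ape::write.tree()] and [ape::read.tree()].
#'
#' @param tree A `phylo` tree.
#' @param path File path.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`
#'   invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

# ---- tree search --------------------------------------------------------

# NNI hill climb to convergence under a score function (minimisation):
# steepest descent with a bounded number of sideways (equal-score) moves,
# since parsimony landscapes are rich in plateaus and crossing them is what
# lets the climb reach optima one step beyond a flat neighbourhood. Visited
# plateau topologies are tracked to avoid cycling. With `randomized = TRUE`
# ties and plateau steps are sampled from the caller's RNG (best_tree seeds
# it), so restarts explore different plateau exits instead of collapsing
# onto one deterministic walk.
nni_hill_climb <- function(tree, score_of, sideways = 15L,
                           randomized = FALSE) {
  cur <- ape::unroot(tree)
  cur$edge.length <- NULL
  cur_score <- score_of(cur)
  visited <- canonical_newick(cur)
  sw <- 0L
  pick <- function(cand_trees, keys) {
    if (randomized) sample.int(length(keys), 1L) else order(keys)[1]
  }
  repeat {
    nbs <- phangorn::nni(cur)
    scores <- vapply(nbs, score_of, 0)
    mn <- min(scores)
    if (mn < cur_score) {
      best <- which(scores == mn)
      keys <- vapply(nbs[best], canonical_newick, "")
      cur <- nbs[[best[pick(nbs[best], keys)]]]
      cur_score <- mn
      visited <- canonical_newick(cur)
      sw <- 0L
    } else if (mn == cur_score && sw < sideways) {
      cand <- which(scores == mn)
      keys <- vapply(nbs[cand], canonical_newick, "")
      fresh <- which(!(keys %in% visited))
      if (!length(fresh)) break
      j <- fresh[pick(nbs[cand][fresh], keys[fresh])]
      cur <- nbs[[cand[j]]]
      visited <- c(visited, keys[j])
      sw <- sw + 1L
    } else break
  }
  cur
}

#' Best tree under parsimony or neighbor joining
#'
#' `method = "parsimony"`: with `search = "exhaustive"` (the default for up
#' to 8 taxa; 3, 15, 105, 945 and 10395 unrooted topologies at 4-8 taxa)
#' every unrooted topology is scored and the minimum taken; with
#' `search = "hillclimb"` (the default beyond 8 taxa) a deterministic hill
#' climb is run from the neighbor-joining tree plus `restarts` seeded
#' random starting topologies, each NNI-rearranged to convergence with a
#' bounded number of plateau (equal-score) moves and followed by seeded
#' perturb-and-reclimb kicks (iterated local search). Score
#' ties are broken by the lexicographically smallest [canonical_newick()]
#' string. `method = "nj"`: neighbor joining ([ape::nj()]) on the
#' [p_distance()] matrix.
#'
#' @param alignment A `cnido_alignment` with >= 3 taxa (>= 4 for a
#'   non-trivial unrooted topology).
#' @param method `"parsimony"` or `"nj"`.
#' @param search `"auto"` (default), `"exhaustive"` or `"hillclimb"`
#'   (parsimony only).
#' @param gap_mode Gap handling for the parsimony score (see
#'   [parsimony_score()]).
#' @param restarts Number of random-restart hill climbs beyond the NJ start
#'   (default 10).
#' @param seed Seed for the restart topologies (default 1).
#' @param outgroup Optional tip label; the returned tree is rooted on it.
#' @return An object of class `cnido_tree`: list with `tree` (`phylo`),
#'   `method`, `score` (parsimony score, also reported for NJ trees),
#'   `newick` (canonical string), `search`.
#' @export
best_tree <- function(alignment, method = c("parsimony", "nj"),
                      search = c("auto", "exhaustive", "hillclimb"),
                      gap_mode = "state", restarts = 10L, seed = 1L,
                      outgroup = NULL) {
  method <- match.arg(method)
  search <- match.arg(search)
  taxa <- rownames(alignment)
  n <- length(taxa)
  if (n < 3L) stop("need at least 3 taxa")
  enc <- encode_alignment(alignment, gap_mode)
  cc <- compress_columns(enc)
  score_of <- function(tr) sum(fitch_column_scores(tr, cc$enc) * cc$weight)
  if (method == "nj") {
    tr <- ape::nj(as.dist(p_distance(alignment)))
    search <- "nj"
  } else {
    if (search == "auto") search <- if (n <= 8L) "exhaustive" else "hillclimb"
    if (search == "exhaustive") {
      cand <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
      scores <- vapply(cand, score_of, 0)
      best <- which(scores == min(scores))
      if (length(best) > 1L) {
        keys <- vapply(cand[best], canonical_newick, "")
        best <- best[order(keys)][1]
      }
      tr <- cand[[best]]
    } else {
      starts <- list(ape::nj(as.dist(p_distance(alignment))))
      starts <- c(starts, with_seed(seed, lapply(seq_len(restarts),
        function(i) ape::rtree(n, tip.label = sample(taxa)))))
      best_tr <- NULL; best_score <- Inf
      with_seed(seed + 1L, for (st in starts) {
        tr0 <- nni_hill_climb(st, score_of, randomized = TRUE)
        s0 <- score_of(tr0)
        # iterated local search: kick the local optimum with two random
        # NNI moves and re-climb, keeping the better tree
        for (kick in 1:3) {
          pert <- tr0
          for (k in 1:2) {
            nbs <- phangorn::nni(pert)
            pert <- nbs[[sample.int(length(nbs), 1L)]]
          }
          tr1 <- nni_hill_climb(pert, score_of, randomized = TRUE)
          s1 <- score_of(tr1)
          if (s1 < s0) { tr0 <- tr1; s0 <- s1 }
        }
        if (s0 < best_score ||
            (s0 == best_score &&
             canonical_newick(tr0) < canonical_newick(best_tr))) {
          best_tr <- tr0; best_score <- s0
        }
      })
      tr <- best_tr
    }
  }
  tr$edge.length <- NULL
  if (!is.null(outgroup)) {
    tr <- ape::root(ape::unroot(tr), outgroup = outgroup,
                    resolve.root = TRUE)
  }
  structure(list(tree = tr, method = method, score = score_of(tr),
                 newick = canonical_newick(tr), search = search),
            class = "cnido_tree")
}

#' @export
print.cnido_tree <- function(x, ...) {
  cat("<cnido_tree> ", x$method, " (", x$search, "), parsimony score ",
      x$score, "\n  ", x$newick, "\n", sep = "")
  invisible(x)
}
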