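# Independent oracles used by the tests. These deliberately re-derive the
# quantities through a different route than the package implementation:
# per-codon table lookup for translation, quadratic-space dynamic programs
# for alignment, and exhaustive internal-state enumeration for parsimony.

# Per-codon standard-genetic-code translation; codons containing anything
# other than A/C/G/T give X.
oracle_translate <- function(nt) {
  gc_table <- Biostrings::GENETIC_CODE
  n <- nchar(nt) - nchar(nt) %% 3
  if (n < 3) return("")
  starts <- seq(1, n - 2, by = 3)
  cods <- substring(nt, starts, starts + 2)
  aa <- unname(gc_table[cods])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

oracle_revcomp <- function(nt) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(nt, "")[[1]]])), collapse = "")
}

# Quadratic-space affine-gap local alignment score (Gotoh); a gap of length
# L costs open + ext * L.
oracle_local_score <- function(a, b, subm, open = 11, ext = 1) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
      M[i + 1, j + 1] <- max(0,
                             max(M[i, j], X[i, j], Y[i, j]) +
                               subm[va[i], vb[j]])
      best <- max(best, M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
    }
  }
  best
}

# Minimum change count of one alignment column on a rooted binary tree by
# brute-force enumeration of all internal-state assignments.
oracle_column_changes <- function(tree, tip_states) {
  tree <- stats::reorder(cnidopep:::as_rooted_binary(tree), "postorder")
  states <- sort(unique(tip_states))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tips <- tip_states[tree$tip.label]
  grid <- expand.grid(rep(list(states), nnode), stringsAsFactors = FALSE)
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign_all <- c(tips, setNames(unlist(grid[g, ]),
                                   as.character(ntip + seq_len(nnode))))
    node_state <- function(k) {
      if (k <= ntip) tips[k] else assign_all[[as.character(k)]]
    }
    changes <- sum(vapply(seq_len(nrow(tree$edge)), function(e) {
      node_state(tree$edge[e, 1]) != node_state(tree$edge[e, 2])
    }, TRUE))
    best <- min(best, changes)
  }
  best
}

oracle_parsimony <- function(tree, alignment) {
  sum(vapply(seq_len(ncol(alignment)), function(j) {
    oracle_column_changes(tree, setNames(alignment[, j],
                                         rownames(alignment)))
  }, 0))
}

# Random gap-free alignment over a small state alphabet.
random_alignment <- function(ntaxa, len, states = c("A", "C", "D", "E")) {
  m <- matrix(sample(states, ntaxa * len, replace = TRUE), nrow = ntaxa,
              dimnames = list(paste0("t", seq_len(ntaxa)), NULL))
  structure(m, class = c("cnido_alignment", "matrix", "array"))
}

# Unrooted Robinson-Foulds distance convenience.
rf_dist <- function(a, b) {
  as.numeric(ape::dist.topo(ape::unroot(a), ape::unroot(b)))
}
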