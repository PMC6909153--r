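# Progressive multiple alignment: k-mer distance guide tree followed by
# profile-profile global (Needleman-Wunsch) alignment with affine gaps.
# Deterministic for a fixed input order and parameter set.

# Fractional k-mer distance between two sequences: 1 - shared/min count.
kmer_distance <- function(a, b, k = 3L) {
  ka <- substring(a, seq_len(max(0L, nchar(a) - k + 1L)),
                  seq_len(max(0L, nchar(a) - k + 1L)) + k - 1L)
  kb <- substring(b, seq_len(max(0L, nchar(b) - k + 1L)),
                  seq_len(max(0L, nchar(b) - k + 1L)) + k - 1L)
  if (!length(ka) || !length(kb)) return(1)
  ta <- table(ka); tb <- table(kb)
  common <- intersect(names(ta), names(tb))
  shared <- sum(pmin(ta[common], tb[common]))
  1 - shared / min(length(ka), length(kb))
}

# Column frequency profile (rows: AA20 + X, normalised over non-gap mass).
profile_freq <- function(mat, residues) {
  L <- ncol(mat)
  f <- matrix(0, nrow = length(residues), ncol = L,
              dimnames = list(residues, NULL))
  for (j in seq_len(L)) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (length(col)) {
      tb <- table(factor(col, levels = residues))
      f[, j] <- as.numeric(tb) / length(col)
    }
  }
  f
}

# Global profile-profile alignment with affine gaps; returns the two index
# vectors (0 = gap) mapping merged columns to input columns. Traceback tie
# preference: diagonal, then gap in B (consume A), then gap in A -- which
# places indels leftmost in the first profile.
align_profiles <- function(A, B, subm, gap_open, gap_extend) {
  residues <- intersect(rownames(subm), c(AA20, "X"))
  fa <- profile_freq(A, residues)
  fb <- profile_freq(B, residues)
  S <- t(fa) %*% subm[residues, residues] %*% fb
  n <- ncol(A); m <- ncol(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)   # match/mismatch state
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in B (A column against gap)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in A
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -gap_open - gap_extend * i
  for (j in seq_len(m)) Y[1L, j + 1L] <- -gap_open - gap_extend * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + S[i, j]
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open - gap_extend,
                               X[i, j + 1L] - gap_extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open - gap_extend,
                               Y[i + 1L, j] - gap_extend)
    }
  }
  ia <- integer(0); ib <- integer(0)
  i <- n; j <- m
  state <- which.max(c(M[n + 1L, m + 1L], X[n + 1L, m + 1L],
                       Y[n + 1L, m + 1L]))
  while (i > 0L || j > 0L) {
    if (state == 1L && i > 0L && j > 0L) {
      ia <- c(i, ia); ib <- c(j, ib)
      prev <- c(M[i, j], X[i, j], Y[i, j])
      i <- i - 1L; j <- j - 1L
      state <- which.max(prev)
    } else if ((state == 2L && i > 0L) || j == 0L) {
      ia <- c(i, ia); ib <- c(0L, ib)
      if (i > 1L || j > 0L) {
        open <- M[i, j + 1L] - gap_open - gap_extend
        ext <- X[i, j + 1L] - gap_extend
        state <- if (open >= ext) 1L else 2L
      }
      i <- i - 1L
    } else {
      ia <- c(0L, ia); ib <- c(j, ib)
      if (j > 1L || i > 0L) {
        open <- M[i + 1L, j] - gap_open - gap_extend
        ext <- Y[i + 1L, j] - gap_extend
        state <- if (open >= ext) 1L else 3L
      }
      j <- j - 1L
    }
  }
  list(ia = ia, ib = ib)
}

expand_alignment <- function(mat, idx) {
  out <- matrix("-", nrow = nrow(mat), ncol = length(idx),
                dimnames = list(rownames(mat), NULL))
  nz <- idx != 0L
  out[, nz] <- mat[, idx[nz], drop = FALSE]
  out
}

#' Progressive multiple alignment
#'
#' Aligns two or more protein sequences: pairwise k-mer distances feed a
#' UPGMA guide tree, and profiles are merged bottom-up by global
#' profile-profile alignment with affine gap costs. Output is deterministic
#' for a fixed input order and parameter set. Already-aligned input (all
#' sequences the same length, possibly containing `-`) can be accepted
#' verbatim with `prealigned = TRUE`.
#'
#' @param seqs Named character vector of protein sequences (>= 2), or a
#'   record data frame.
#' @param matrix Substitution matrix name or matrix (default BLOSUM62).
#' @param gap_open,gap_extend Affine gap costs (defaults 10 and 1).
#' @param k k-mer length for the guide-tree distance (default 3).
#' @param prealigned Accept the input as an alignment without change.
#' @return An object of class `cnido_alignment`: a character matrix with one
#'   row per sequence (rownames are taxon ids).
#' @export
progressive_align <- function(seqs, matrix = "BLOSUM62", gap_open = 10,
                              gap_extend = 1, k = 3L, prealigned = FALSE) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  if (length(seqs) < 2L) stop("progressive_align needs at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must carry unique names")
  }
  if (prealigned) {
    if (length(unique(nchar(seqs))) != 1L) {
      stop("prealigned input must have equal lengths")
    }
    mat <- do.call(rbind, strsplit(seqs, ""))
    rownames(mat) <- names(seqs)
    return(structure(mat, class = c("cnido_alignment", "matrix", "array")))
  }
  subm <- get_submat(matrix)
  n <- length(seqs)
  profiles <- lapply(seqs, function(s) {
    m <- matrix(chars(s), nrow = 1L)
    rownames(m) <- NULL
    m
  })
  for (i in seq_len(n)) rownames(profiles[[i]]) <- names(seqs)[i]
  if (n == 2L) {
    merges <- matrix(c(-1L, -2L), nrow = 1L)
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- kmer_distance(seqs[i], seqs[j], k)
    }
    hc <- hclust(as.dist(d), method = "average")
    merges <- hc$merge
  }
  nodes <- vector("list", nrow(merges))
  getp <- function(x) if (x < 0L) profiles[[-x]] else nodes[[x]]
  for (r in seq_len(nrow(merges))) {
    A <- getp(merges[r, 1]); B <- getp(merges[r, 2])
    idx <- align_profiles(A, B, subm, gap_open, gap_extend)
    nodes[[r]] <- rbind(expand_alignment(A, idx$ia),
                        expand_alignment(B, idx$ib))
  }
  out <- nodes[[nrow(merges)]]
  out <- out[names(seqs), , drop = FALSE]   # restore input order
  structure(out, class = c("cnido_alignment", "matrix", "array"))
}

#' @export
print.cnido_alignment <- function(x, ...) {
  cat("<cnido_alignment> ", nrow(x), " sequences x ", ncol(x),
      " columns\n", sep = "")
  show <- apply(x[, seq_len(min(60L, ncol(x))), drop = FALSE], 1, paste,
                collapse = "")
  for (i in seq_along(show)) {
    cat(sprintf("  %-20s %s%s\n", rownames(x)[i], show[i],
                if (ncol(x) > 60L) "..." else ""))
  }
  invisible(x)
}

#' Recover the ungapped sequences of an alignment
#'
#' @param alignment A `cnido_alignment`.
#' @return Named character vector.
#' @export
ungap_alignment <- function(alignment) {
  vapply(seq_len(nrow(alignment)), function(i) {
    paste(alignment[i, alignment[i, ] != "-"], collapse = "")
  }, "", USE.NAMES = FALSE) |> setNames(rownames(alignment))
}
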