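# Shared residue-level constants.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte-Doolittle hydropathy scale.
KD_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3, X = 0)

# Background amino-acid frequencies (average over well-characterised
# proteomes, Swiss-Prot composition statistics); used by the decoy model.
AA_BACKGROUND <- c(
  A = 0.0826, C = 0.0139, D = 0.0546, E = 0.0672, F = 0.0387,
  G = 0.0707, H = 0.0228, I = 0.0591, K = 0.0580, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0475, Q = 0.0393, R = 0.0553,
  S = 0.0665, T = 0.0536, V = 0.0686, W = 0.0110, Y = 0.0292)

# Residues preferred by the unspecific N-terminal aminopeptidase.
TRIMMABLE_DEFAULT <- c("E", "D", "S", "T", "N", "G", "A", "L", "V", "Y", "F")

# Small residues accepted at the -3/-1 positions of a signal-peptidase site.
SMALL_RESIDUES <- c("A", "G", "S", "C", "T", "V")

#' Mature neuropeptides reported across the four studied cnidarian classes
#'
#' Display strings (see [peptide_display()]) of the mature peptides reported
#' for Scyphozoa, Staurozoa, Cubozoa and Octocorallia: the cross-class
#' X1PRX2amide and GRFamide families plus the class- or subclass-restricted
#' families (pQPPGVWamide-type, cyclic CX..CWFRamide, pQH(L/V)RYamide,
#' pQPLWSARFamide, pQLRGamide, P/pQPFHamide, RPFLamide and GPRRamide).
#' Used by the regression tests as trimming fixed points: each string must be
#' returned unchanged by [trim_n_terminus()], with its printed
#' pyroglutamate/proline/amide state reproduced.
#'
#' @format Character vector of 22 peptide display strings.
#' @export
published_peptides <- c(
  "RPRSamide", "LPRSamide", "RPRAamide", "GPRGamide", "KPRSamide",
  "pQGRFamide", "pQWLRGRFamide", "pQFLRGRFamide",
  "pQPPGVWamide", "pQPPGTWamide",
  "pQHLRYamide", "pQHVRYamide", "PHVRYamide", "PHLRYamide",
  "pQPLWSARFamide", "pQLRPamide", "pQLRGamide",
  "PPFHamide", "pQPFHamide", "RPFLamide", "GPRRamide",
  "CKGQMCWFRamide")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split a residue string into single characters.
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Retrieve a substitution matrix shipped with Biostrings by name.
get_submat <- function(name = "BLOSUM62") {
  if (is.matrix(name)) return(name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}
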