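# simdata: ground-truthed generator of synthetic preprohormones,
# transcriptomes and class-structured divergence. Every draw is reproducible
# bit-exactly from (spec, seed).

# Residue pools used by the generator. Spacers default to the
# aminopeptidase-preferred set plus K (all reported N-terminal flanking
# residues), so generated precursors exercise the trimming rules
# nontrivially; C and W are excluded to avoid spurious cystine/consensus
# motifs. A spacer's final residue avoids G and K, which would otherwise
# graft onto the downstream cassette's processing grammar (a trailing G
# becomes an amide donor for a core-initial basic residue; a trailing K can
# extend the next tract).
SPACER_POOL_DEFAULT <- c(TRIMMABLE_DEFAULT, "K")
SPACER_END_POOL <- setdiff(TRIMMABLE_DEFAULT, "G")
PRO_POOL <- c("E", "D", "S", "T", "N", "A", "V", "L")
CORE_SUB_POOL <- c("A", "S", "T", "N", "D", "E", "V", "L", "I", "F", "Y",
                   "H", "M")
SIGNAL_TEMPLATE <- "MKTLVLLALLAVALA"
SITE_INVENTORY <- c("GR", "GKR", "GRR", "GKRR", "RR", "KR", "RRR", "RKR",
                    "RKK")

#' Specification of one synthetic preprohormone
#'
#' Describes a precursor the way the studied genes are organised: a signal
#' peptide, an acidic pro-region closed by a processing site, then
#' `n_copies` cassettes (spacer + peptide core + convertase site) and a
#' C-terminal tail.
#'
#' @param id Precursor identifier.
#' @param core Immature peptide core (e.g. `"RPRS"`), >= 3 residues.
#' @param n_copies Number of cassette copies (1-32 in the studied genes).
#' @param class_label Taxonomic class/subclass label carried into the ground
#'   truth.
#' @param site_weights Named sampling weights over the classical site
#'   inventory `GR, GKR, GRR, GKRR, RR, KR, RRR, RKR, RKK` (default: GKR
#'   only, the commonest dibasic amidating site).
#' @param spacer_len Length range of inter-cassette spacers (default 1-4).
#' @param spacer_pool Residues for spacer positions (default: trimmable set
#'   plus K).
#' @param signal Signal-peptide template.
#' @param pro_len Length range of the pro-region (default 31-40; long
#'   enough that the signal-bearing leading segment falls outside the
#'   detector's candidate window).
#' @param tail_len Length range of the C-terminal tail (default 8-15).
#' @param noise Per-residue substitution probability applied independently
#'   to every cassette core copy (default 0: identical copies).
#' @param core_sub_pool Residues used for core substitutions.
#' @return An object of class `precursor_spec`.
#' @export
precursor_spec <- function(id, core, n_copies, class_label = NA_character_,
                           site_weights = c(GKR = 1), spacer_len = c(1L, 4L),
                           spacer_pool = SPACER_POOL_DEFAULT,
                           signal = SIGNAL_TEMPLATE, pro_len = c(31L, 40L),
                           tail_len = c(8L, 15L), noise = 0,
                           core_sub_pool = CORE_SUB_POOL) {
  stopifnot(nzchar(core), nchar(core) >= 3L, n_copies >= 0L,
            all(names(site_weights) %in% SITE_INVENTORY),
            noise >= 0, noise <= 1)
  structure(list(id = id, core = core, n_copies = as.integer(n_copies),
                 class_label = class_label, site_weights = site_weights,
                 spacer_len = as.integer(spacer_len),
                 spacer_pool = spacer_pool, signal = signal,
                 pro_len = as.integer(pro_len),
                 tail_len = as.integer(tail_len), noise = noise,
                 core_sub_pool = core_sub_pool),
            class = "precursor_spec")
}

sample_pool <- function(pool, n) {
  if (n <= 0L) return(character(0))
  sample(pool, n, replace = TRUE)
}

sample_spacer <- function(spec) {
  len <- sample(seq(spec$spacer_len[1], spec$spacer_len[2]), 1L)
  res <- sample_pool(spec$spacer_pool, len)
  res[len] <- sample(SPACER_END_POOL, 1L)
  # spacers must not embed processing sites: a K after a K would form a
  # dibasic tract and a K after a G a donor-bearing monobasic site, so
  # such draws are replaced
  if (len > 1L) {
    for (i in 2:len) {
      if (res[i] == "K" && res[i - 1L] %in% c("K", "G")) {
        res[i] <- sample(SPACER_END_POOL, 1L)
      }
    }
  }
  paste(res, collapse = "")
}

mutate_core <- function(core, noise, pool) {
  if (noise <= 0) return(core)
  v <- chars(core)
  hit <- runif(length(v)) < noise
  for (i in which(hit)) v[i] <- sample(setdiff(pool, v[i]), 1L)
  paste(v, collapse = "")
}

# Build the structured part list of a precursor (used by both
# generate_precursor and diverge).
build_parts <- function(spec) {
  pro_len <- sample(seq(spec$pro_len[1], spec$pro_len[2]), 1L)
  sites <- if (spec$n_copies > 0L) {
    sample(names(spec$site_weights), spec$n_copies, replace = TRUE,
           prob = spec$site_weights)
  } else character(0)
  list(signal = spec$signal,
       pro = paste(sample_pool(PRO_POOL, pro_len), collapse = ""),
       pro_site = "GKR",
       spacers = vapply(seq_len(spec$n_copies),
                        function(i) sample_spacer(spec), ""),
       cores = vapply(seq_len(spec$n_copies), function(i)
         mutate_core(spec$core, spec$noise, spec$core_sub_pool), ""),
       sites = sites,
       tail = paste(sample_pool(SPACER_END_POOL,
                                sample(seq(spec$tail_len[1],
                                           spec$tail_len[2]), 1L)),
                    collapse = ""))
}

assemble_parts <- function(parts) {
  paste0(parts$signal, parts$pro, parts$pro_site,
         paste(paste0(parts$spacers, parts$cores, parts$sites),
               collapse = ""), parts$tail)
}

# Ground truth for assembled parts: the intended mature product of each
# cassette, computed by the same remnant-stripping + trimming chemistry the
# pipeline applies, so truth and recovery agree by construction.
parts_truth <- function(parts, id, class_label, policy = trim_policy()) {
  n <- length(parts$cores)
  if (n == 0L) {
    return(data.frame(precursor_id = character(), cassette = integer(),
                      segment = character(), display = character(),
                      c_state = character(), stringsAsFactors = FALSE))
  }
  segs <- paste0(parts$spacers, parts$cores)
  amide <- startsWith(parts$sites, "G")
  disp <- character(n)
  cst <- ifelse(amide, "amide", "free_acid")
  for (i in seq_len(n)) {
    mp <- mature_segment(segs[i], amide[i], policy)
    disp[i] <- if (is.null(mp)) NA_character_ else mp$display
  }
  data.frame(precursor_id = id, cassette = seq_len(n), segment = segs,
             display = disp, c_state = cst, stringsAsFactors = FALSE)
}

#' Generate one synthetic preprohormone with ground truth
#'
#' @param spec A [precursor_spec()].
#' @param seed Integer seed; the same `(spec, seed)` pair yields
#'   byte-identical output.
#' @return List with `record` (single-row protein record data frame) and
#'   `truth` (one row per cassette: `segment`, intended mature `display`,
#'   `c_state`).
#' @export
generate_precursor <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "precursor_spec"))
  with_seed(seed, {
    parts <- build_parts(spec)
    protein <- assemble_parts(parts)
    list(record = seq_records(id = spec$id, seq = protein,
                              alphabet = "protein",
                              source = spec$class_label),
         truth = parts_truth(parts, spec$id, spec$class_label))
  })
}

# Reverse codon table from the standard genetic code.
reverse_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Back-translate a protein with uniform synonymous codon choice
#'
#' @param protein Protein residue string.
#' @param seed Integer seed.
#' @return Nucleotide string (no stop codon appended).
#' @export
back_translate <- function(protein, seed = 1L) {
  rct <- reverse_codon_table()
  with_seed(seed, {
    paste(vapply(chars(protein), function(a) {
      cods <- rct[[a]]
      if (is.null(cods)) stop("cannot back-translate residue ", a)
      cods[sample.int(length(cods), 1L)]
    }, "", USE.NAMES = FALSE), collapse = "")
  })
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# Wrap a CDS in UTRs: the 5' UTR ends with an in-frame stop so that the
# stop-to-stop ORF of the transcript is exactly the encoded protein.
wrap_transcript <- function(cds, utr5_codons = 8L, utr3_len = 21L) {
  paste0(random_nt(3L * utr5_codons), "TAA", cds, "TAA", random_nt(utr3_len))
}

#' Generate a synthetic transcriptome with ground truth
#'
#' Back-translates the specified precursors (uniform synonymous codon
#' choice), adds decoy transcripts encoding i.i.d. background-frequency
#' proteins without cassette arrays, pads everything with UTRs (the 5' UTR
#' carries an in-frame stop so stop-to-stop ORFs recover the encoded
#' proteins exactly), and shuffles the record order.
#'
#' @param specs List of [precursor_spec()] objects.
#' @param n_decoys Number of decoy transcripts (default 200).
#' @param seed Integer seed.
#' @param decoy_len_range Protein length range of decoys (default 80-250).
#' @param source Dataset label for the records.
#' @return List with `records` (nucleotide record data frame), `proteins`
#'   (the encoded protein records), and `truth` (per transcript:
#'   `is_precursor`, `class`, `n_cassettes`, `displays` semicolon-joined;
#'   plus the per-cassette table as attribute `"cassettes"`).
#' @export
generate_transcriptome <- function(specs, n_decoys = 200L, seed = 1L,
                                   decoy_len_range = c(80L, 250L),
                                   source = "simulated") {
  with_seed(seed, {
    prec <- lapply(seq_along(specs), function(i)
      generate_precursor(specs[[i]], seed = sample.int(2^20, 1L)))
    decoy_prot <- lapply(seq_len(n_decoys), function(i) {
      len <- sample(seq(decoy_len_range[1], decoy_len_range[2]), 1L)
      paste(sample(names(AA_BACKGROUND), len, replace = TRUE,
                   prob = AA_BACKGROUND), collapse = "")
    })
    prot_ids <- c(vapply(prec, function(p) p$record$id, ""),
                  sprintf("decoy_%03d", seq_len(n_decoys)))
    prot_seqs <- c(vapply(prec, function(p) p$record$seq, ""),
                   unlist(decoy_prot, use.names = FALSE) %||% character(0))
    classes <- c(vapply(prec, function(p) p$record$source, ""),
                 rep(NA_character_, n_decoys))
    nt <- vapply(seq_along(prot_seqs), function(i)
      wrap_transcript(back_translate(prot_seqs[i],
                                     seed = sample.int(2^20, 1L))), "")
    ord <- sample(seq_along(prot_ids))
    cassettes <- do.call(rbind, lapply(prec, `[[`, "truth"))
    truth <- data.frame(
      transcript_id = prot_ids,
      is_precursor = seq_along(prot_ids) <= length(prec),
      class = classes,
      n_cassettes = c(vapply(prec, function(p) nrow(p$truth), 0L),
                      rep(0L, n_decoys)),
      displays = c(vapply(prec, function(p)
        paste(p$truth$display, collapse = ";"), ""),
        rep("", n_decoys)),
      stringsAsFactors = FALSE)[ord, , drop = FALSE]
    rownames(truth) <- NULL
    records <- seq_records(id = prot_ids[ord], seq = nt[ord],
                           alphabet = "nucleotide", source = source)
    proteins <- seq_records(id = prot_ids[ord], seq = prot_seqs[ord],
                            alphabet = "protein", source = source)
    attr(truth, "cassettes") <- cassettes
    list(records = records, proteins = proteins, truth = truth)
  })
}

# Rooted 4-class topology with per-branch lengths (relative divergence
# units): Octocorallia is the outgroup; Cubozoa and Scyphozoa are sisters.
# Internal branches are long relative to the tips so that shared derived
# characters reliably outnumber tip homoplasy -- the histories this
# generator emulates are recoverable by construction.
CLASS_TREE <- list(
  branches = c(Octo = 0.7, Medusozoa = 0.6, Stauro = 0.4, CS = 0.5,
               Cubo = 0.2, Scypho = 0.2),
  newick = "(((Cubo,Scypho),Stauro),Octo);")

mutate_string <- function(s, p, pool, fixed_tail = 0L) {
  v <- chars(s)
  n <- length(v) - fixed_tail
  if (n < 1L) return(s)
  hit <- which(runif(n) < p)
  for (i in hit) {
    cand <- setdiff(pool, v[i])
    if (length(cand)) v[i] <- sample(cand, 1L)
  }
  paste(v, collapse = "")
}

mutate_parts <- function(parts, p_spacer, p_core, spec) {
  parts$pro <- mutate_string(parts$pro, p_spacer, PRO_POOL)
  parts$tail <- mutate_string(parts$tail, p_spacer, SPACER_END_POOL)
  parts$spacers <- vapply(parts$spacers, function(s) {
    out <- mutate_string(s, p_spacer, spec$spacer_pool, fixed_tail = 1L)
    out
  }, "", USE.NAMES = FALSE)
  # cassette cores evolve slowly and keep their C-terminal anchor fixed
  parts$cores <- vapply(parts$cores, function(cr)
    mutate_string(cr, p_core, spec$core_sub_pool, fixed_tail = 2L), "",
    USE.NAMES = FALSE)
  parts
}

#' Evolve a precursor along the four-class cnidarian topology
#'
#' Starting from an ancestral precursor built from `spec`, substitutions are
#' applied along the branches of the rooted class tree
#' `(((Cubo,Scypho),Stauro),Octo)`: spacer-type regions (pro-region,
#' spacers, tail) mutate at `rates$spacer` substitutions per site per unit
#' branch length, cassette cores at the reduced `rates$core` with their
#' 2-residue C-terminal anchor held fixed. Replicates per class receive a
#' short extra tip branch (`rates$replicate` units) so taxa are distinct.
#' The true history of the resulting datasets therefore matches the class
#' topology.
#'
#' @param spec A [precursor_spec()] for the ancestral precursor.
#' @param rates List with `spacer`, `core` and optionally `replicate`
#'   (defaults 0.4, 0.05 and 0.05).
#' @param n_per_class Taxa per class (default 1).
#' @param seed Integer seed.
#' @return List with `records` (protein records, ids `<Class>_<i>`, class in
#'   `source`), `truth` (per-taxon cassette table), `class_map` (named
#'   vector taxon -> class) and `tree_newick` (the generating topology).
#' @export
diverge <- function(spec, rates = list(spacer = 0.4, core = 0.05,
                                       replicate = 0.05),
                    n_per_class = 1L, seed = 1L) {
  stopifnot(inherits(spec, "precursor_spec"))
  rates$replicate <- rates$replicate %||% 0.05
  br <- CLASS_TREE$branches
  with_seed(seed, {
    root <- build_parts(spec)
    step <- function(parts, len) {
      mutate_parts(parts, min(0.9, rates$spacer * len),
                   min(0.9, rates$core * len), spec)
    }
    meduso <- step(root, br[["Medusozoa"]])
    cs <- step(meduso, br[["CS"]])
    anc <- list(Octo = step(root, br[["Octo"]]),
                Stauro = step(meduso, br[["Stauro"]]),
                Cubo = step(cs, br[["Cubo"]]),
                Scypho = step(cs, br[["Scypho"]]))
    recs <- list(); truths <- list(); class_map <- character(0)
    for (cls in names(anc)) {
      for (i in seq_len(n_per_class)) {
        tip <- step(anc[[cls]], rates$replicate)
        taxon <- sprintf("%s_%d", cls, i)
        recs[[taxon]] <- seq_records(id = taxon,
                                     seq = assemble_parts(tip),
                                     alphabet = "protein", source = cls)
        truths[[taxon]] <- parts_truth(tip, taxon, cls)
        class_map[taxon] <- cls
      }
    }
    list(records = do.call(rbind, unname(recs)),
         truth = do.call(rbind, unname(truths)),
         class_map = class_map, tree_newick = CLASS_TREE$newick)
  })
}
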