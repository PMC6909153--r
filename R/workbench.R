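# workbench: configuration, end-to-end pipeline, report, benchmark harness.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with its default, plus
#' the dataset manifest. Unknown parameter names are rejected.
#'
#' @param datasets A `data.frame` manifest with columns `path` (FASTA file)
#'   or `records` (in-memory record data frames supplied via the `records`
#'   argument), `dataset` (label), `class` (class/subclass), and optionally
#'   `alphabet` (`"nucleotide"`/`"protein"`, default nucleotide).
#' @param ... Parameter overrides among: `min_copies`, `identity`,
#'   `min_len`, `max_len`, `mode`, `min_orf_aa`, `anchor_len`,
#'   `merge_identity`, `trim` (a [trim_policy()]), `grammar` (a
#'   [site_grammar()]), `signal_calls` (path to an external-call TSV),
#'   `tree_method` (`"none"`, `"parsimony"`, `"nj"`, `"both"`), `seed`,
#'   `outdir`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(datasets, ...) {
  defaults <- list(min_copies = 3L, identity = 0.5, min_len = 3L,
                   max_len = 30L, mode = "similarity", min_orf_aa = 60L,
                   anchor_len = 3L, merge_identity = 0.5,
                   trim = trim_policy(), grammar = site_grammar(),
                   signal_calls = NULL, tree_method = "none", seed = 1L,
                   outdir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  stopifnot(is.data.frame(datasets), nrow(datasets) >= 1L,
            all(c("dataset", "class") %in% names(datasets)))
  if (is.null(datasets$alphabet)) datasets$alphabet <- "nucleotide"
  cfg$datasets <- datasets
  structure(cfg, class = "pipeline_config")
}

#' Read a YAML pipeline configuration
#'
#' The file must contain a `datasets` list (each entry with `path`,
#' `dataset`, `class`, optional `alphabet`) and may set any
#' [pipeline_config()] parameter at the top level.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configurations")
  }
  y <- yaml::read_yaml(path)
  datasets <- do.call(rbind, lapply(y$datasets, function(d)
    data.frame(path = d$path, dataset = d$dataset, class = d$class,
               alphabet = d$alphabet %||% "nucleotide",
               stringsAsFactors = FALSE)))
  y$datasets <- NULL
  do.call(pipeline_config, c(list(datasets = datasets), y))
}

# Annotate one protein record end to end (screen + signal + classify +
# mature); returns NULL for rejected proteins unless keep_rejected.
annotate_protein <- function(rec, params, policy, signal_lookup = NULL,
                             keep_rejected = FALSE) {
  scr <- screen_protein(rec, params)
  sig <- if (!is.null(signal_lookup) && rec$id %in% names(signal_lookup)) {
    signal_lookup[[rec$id]]
  } else {
    suppressWarnings(predict_signal_peptide(rec))
  }
  ann <- classify(scr, sig)
  if (ann$status == "rejected" && !keep_rejected) return(NULL)
  mature_all(ann, policy)
}

#' Annotate every protein of a record set
#'
#' The core convenience entry point: screens each protein for a multi-copy
#' cassette array, calls the signal peptide, classifies, and predicts
#' mature peptides for accepted/review annotations.
#'
#' @param records Protein record data frame.
#' @param params A [detector_params()].
#' @param policy A [trim_policy()].
#' @param signal_lookup Optional named list of `signal_call` objects
#'   (external predictions), keyed by protein id.
#' @return Named list of `cnido_annotation` objects (accepted and review
#'   only).
#' @export
annotate_preprohormones <- function(records, params = detector_params(),
                                    policy = trim_policy(),
                                    signal_lookup = NULL) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    ann <- annotate_protein(records[i, , drop = FALSE], params, policy,
                            signal_lookup)
    if (!is.null(ann)) out[[ann$protein_id]] <- ann
  }
  out
}

# Collect the mature-peptide table of a list of annotations, tagged with
# dataset/class and the precursor's processing-site architecture.
collect_peptides <- function(annotations, dataset = NA_character_,
                             class = NA_character_) {
  rows <- lapply(annotations, function(ann) {
    pep <- ann$mature_peptides
    if (is.null(pep) || nrow(pep) == 0L) return(NULL)
    pep$dataset <- dataset
    pep$class <- class
    pep$arch <- precursor_architecture(ann$detector$sites)
    pep
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(precursor_id = character(), display = character(),
                      core = character(), n_state = character(),
                      c_state = character(), start = integer(),
                      end = integer(), trim_blocked = logical(),
                      dataset = character(), class = character(),
                      arch = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full annotation pipeline
#'
#' Per dataset: read (or take in-memory records), six-frame translate
#' nucleotide input, screen every ORF, call signal peptides, classify,
#' predict mature peptides; then group peptides into families across
#' datasets, build the class presence/absence overview, and (optionally)
#' reconstruct trees for the accepted precursors of the largest families.
#' ORFs of the same parent transcript are collapsed to the best annotation
#' (accepted preferred, then most mature peptides). Every stage appends
#' in/out counts to the run log. With `outdir` set, TSV intermediates are
#' written.
#'
#' @param config A [pipeline_config()].
#' @param records Optional named list of record data frames keyed by
#'   dataset label (bypasses `path`-based reading; used for simulated
#'   bundles).
#' @return An object of class `cnido_report`: `annotations` (per dataset),
#'   `peptides`, `families`, `overview`, `trees`, `log`, `config`.
#' @export
run_pipeline <- function(config, records = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ds <- config$datasets
  if (nrow(ds) == 0L) stop("empty dataset manifest")
  params <- detector_params(min_copies = config$min_copies,
                            identity = config$identity,
                            min_len = config$min_len,
                            max_len = config$max_len,
                            grammar = config$grammar, mode = config$mode)
  signal_lookup <- if (!is.null(config$signal_calls)) {
    read_signal_calls(config$signal_calls)
  }
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  all_ann <- list()
  pep_tabs <- list()
  for (i in seq_len(nrow(ds))) {
    label <- ds$dataset[i]
    recs <- if (!is.null(records) && label %in% names(records)) {
      records[[label]]
    } else {
      read_fasta(ds$path[i], alphabet = ds$alphabet[i], source = label)
    }
    note("dataset ", label, ": ", nrow(recs), " input record(s)")
    prots <- if (all(recs$alphabet == "nucleotide")) {
      six_frame_translate(recs, min_orf_aa = config$min_orf_aa)
    } else recs
    note("dataset ", label, ": ", nrow(prots), " protein(s)/ORF(s)")
    ann <- tryCatch(
      annotate_preprohormones(prots, params, config$trim, signal_lookup),
      error = function(e) stop("stage 'annotate' failed for dataset ",
                               label, ": ", conditionMessage(e)))
    ann <- collapse_by_parent(ann)
    note("dataset ", label, ": ", sum(vapply(ann, function(a)
      a$status == "accepted", TRUE)), " accepted, ",
      sum(vapply(ann, function(a) a$status == "review", TRUE)), " review")
    all_ann[[label]] <- ann
    pep_tabs[[label]] <- collect_peptides(ann, dataset = label,
                                          class = ds$class[i])
  }
  peptides <- do.call(rbind, unname(pep_tabs))
  rownames(peptides) <- NULL
  note("total mature peptides: ", nrow(peptides))
  fams <- group_families(peptides, anchor_len = config$anchor_len,
                         merge_identity = config$merge_identity)
  note("families: ", length(fams))
  class_map <- setNames(ds$class, ds$dataset)
  overview <- if (length(fams)) presence_matrix(fams, class_map) else NULL
  trees <- list()
  if (config$tree_method != "none") {
    trees <- family_trees(all_ann, fams, method = config$tree_method,
                          seed = config$seed)
    note("trees built for ", length(trees), " family(ies)")
  }
  report <- structure(list(annotations = all_ann, peptides = peptides,
                           families = fams, overview = overview,
                           trees = trees, log = log, config = config),
                      class = "cnido_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

# Collapse ORF-level annotations to one per parent transcript: accepted
# beats review, then more mature peptides, then the lexicographically
# first ORF id.
collapse_by_parent <- function(annotations) {
  if (!length(annotations)) return(annotations)
  parent <- sub("_F[+-][123]_[0-9]+$", "", names(annotations))
  keep <- list()
  for (p in unique(parent)) {
    grp <- annotations[parent == p]
    rank <- vapply(grp, function(a) {
      (a$status == "accepted") * 1e6 +
        (if (is.null(a$mature_peptides)) 0L else nrow(a$mature_peptides))
    }, 0)
    ord <- order(-rank, names(grp))
    keep[[p]] <- grp[[ord[1]]]
    keep[[p]]$parent_id <- p
  }
  keep
}

# Align the accepted precursors contributing to each family with >= 4
# members from >= 4 datasets and build the requested tree(s).
family_trees <- function(all_ann, fams, method = "both", seed = 1L) {
  methods <- switch(method, both = c("parsimony", "nj"), method)
  # map precursor id -> protein sequence
  seqs <- list()
  for (label in names(all_ann)) {
    for (ann in all_ann[[label]]) {
      if (ann$status == "accepted") seqs[[ann$protein_id]] <- ann$detector$seq
    }
  }
  out <- list()
  for (f in fams) {
    ids <- unique(f$members$precursor_id)
    ids <- ids[ids %in% names(seqs)]
    if (length(ids) < 4L) next
    aln <- progressive_align(setNames(unlist(seqs[ids]), ids))
    out[[f$id]] <- lapply(setNames(methods, methods), function(m)
      best_tree(aln, method = m, seed = seed))
  }
  out
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$peptides, file.path(outdir, "peptides.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$overview)) {
    write.table(as.data.frame(report$overview),
                file.path(outdir, "family_overview.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  writeLines(report$log, file.path(outdir, "run_log.txt"))
  for (fid in names(report$trees)) {
    for (m in names(report$trees[[fid]])) {
      writeLines(report$trees[[fid]][[m]]$newick,
                 file.path(outdir, sprintf("tree_%s_%s.nwk", fid, m)))
    }
  }
  invisible(outdir)
}

#' @export
print.cnido_report <- function(x, ...) {
  n_acc <- sum(vapply(unlist(x$annotations, recursive = FALSE),
                      function(a) a$status == "accepted", TRUE))
  cat("<cnido_report> ", length(x$annotations), " dataset(s), ", n_acc,
      " accepted precursor(s), ", nrow(x$peptides), " mature peptide(s), ",
      length(x$families), " family(ies)\n", sep = "")
  if (!is.null(x$overview)) {
    cat("\nFamily overview (by class breadth):\n")
    print(as.data.frame(x$overview))
  }
  invisible(x)
}

#' @export
summary.cnido_report <- function(object, ...) {
  cat(paste(object$log, collapse = "\n"), "\n")
  print(object)
  invisible(object)
}

#' Benchmark observed copy counts against published values
#'
#' For each manifest row whose FASTA file is present on disk, runs the
#' pipeline and compares the observed copy count of the expected peptide
#' with the published count; missing files are skipped with a notice. The
#' expected table ships with the package
#' (`inst/extdata/published_copy_counts.tsv`); fetching the public
#' assemblies themselves is deliberately left to the user, keeping the
#' package network-free.
#'
#' @param manifest `data.frame` with columns `species`, `path`, `class`,
#'   and optionally `alphabet`.
#' @param expected Expected-count table (defaults to the shipped one):
#'   columns `species`, `display`, `published_count`.
#' @param config_args Extra arguments passed to [pipeline_config()].
#' @return `data.frame` with `species`, `display`, `published_count`,
#'   `observed_count`, `match`, `status`; zero rows when no file is
#'   present.
#' @export
benchmark <- function(manifest, expected = published_copy_counts(),
                      config_args = list()) {
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    exp_rows <- expected[expected$species == row$species, , drop = FALSE]
    if (is.null(row$path) || is.na(row$path) || !file.exists(row$path)) {
      message("benchmark: file missing for ", row$species, "; skipped")
      next
    }
    rep <- tryCatch({
      ds <- data.frame(path = row$path, dataset = row$species,
                       class = row$class,
                       alphabet = row$alphabet %||% "nucleotide",
                       stringsAsFactors = FALSE)
      run_pipeline(do.call(pipeline_config,
                           c(list(datasets = ds), config_args)))
    }, error = function(e) {
      message("benchmark: ", row$species, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(rep)) next
    counts <- table(rep$peptides$display)
    for (j in seq_len(nrow(exp_rows))) {
      disp <- exp_rows$display[j]
      obs <- if (disp %in% names(counts)) as.integer(counts[[disp]]) else 0L
      out[[length(out) + 1L]] <- data.frame(
        species = row$species, display = disp,
        published_count = exp_rows$published_count[j],
        observed_count = obs,
        match = obs == exp_rows$published_count[j],
        status = "compared", stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(species = character(), display = character(),
                      published_count = integer(),
                      observed_count = integer(), match = logical(),
                      status = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Published per-precursor copy counts
#'
#' The copy counts printed for the RPRSamide-type and GPRRamide
#' preprohormones of the studied species, shipped as a plain-text table and
#' used by [benchmark()] and by the simulated re-creations in the tests.
#'
#' @return `data.frame` with `species`, `class`, `display`,
#'   `published_count`.
#' @export
published_copy_counts <- function() {
  read.delim(system.file("extdata", "published_copy_counts.tsv",
                         package = "cnidopep"),
             stringsAsFactors = FALSE)
}
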