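make_sim_bundle <- function(seed = 17) {
  classes <- c(Cubozoa = "RPRA", Scyphozoa = "LPRS", Staurozoa = "RPRS",
               Octocorallia = "GPRG")
  records <- list()
  manifest <- list()
  for (cls in names(classes)) {
    spec <- precursor_spec(paste0("prec_", cls), classes[[cls]], 6, cls)
    tx <- generate_transcriptome(list(spec), n_decoys = 15,
                                 seed = seed + match(cls, names(classes)))
    label <- paste0("ds_", cls)
    records[[label]] <- tx$records
    manifest[[length(manifest) + 1L]] <-
      data.frame(dataset = label, class = cls, path = NA_character_,
                 stringsAsFactors = FALSE)
  }
  list(records = records, manifest = do.call(rbind, manifest))
}

test_that("pipeline configuration validates its keys and manifest", {
  ds <- data.frame(dataset = "d1", class = "Scyphozoa", path = "x.fa")
  cfg <- pipeline_config(ds, min_copies = 4L)
  expect_equal(cfg$min_copies, 4L)
  expect_error(pipeline_config(ds, not_a_key = 1), "unknown configuration")
  expect_error(pipeline_config(data.frame()), "nrow")
})

test_that("the pipeline annotates a four-class bundle and is deterministic", {
  bundle <- make_sim_bundle()
  cfg <- pipeline_config(bundle$manifest)
  rep1 <- run_pipeline(cfg, records = bundle$records)
  expect_s3_class(rep1, "cnido_report")
  n_acc <- sum(vapply(unlist(rep1$annotations, recursive = FALSE),
                      function(a) a$status == "accepted", TRUE))
  expect_equal(n_acc, 4L)
  # one cross-class family spanning all four classes
  expect_false(is.null(rep1$overview))
  expect_equal(max(rep1$overview$breadth), 4L)
  top <- rep1$overview[which.max(rep1$overview$breadth), ]
  expect_match(top$consensus, "PR")
  # determinism: a rerun reproduces the report
  rep2 <- run_pipeline(cfg, records = bundle$records)
  expect_identical(rep1$peptides, rep2$peptides)
  expect_identical(rep1$log, rep2$log)
})

test_that("the pipeline writes traceable intermediates", {
  bundle <- make_sim_bundle(seed = 23)
  outdir <- withr::local_tempdir()
  cfg <- pipeline_config(bundle$manifest, outdir = outdir)
  rep <- run_pipeline(cfg, records = bundle$records)
  expect_true(file.exists(file.path(outdir, "peptides.tsv")))
  expect_true(file.exists(file.path(outdir, "family_overview.tsv")))
  expect_true(file.exists(file.path(outdir, "run_log.txt")))
  pep <- read.delim(file.path(outdir, "peptides.tsv"))
  expect_equal(nrow(pep), nrow(rep$peptides))
})

test_that("YAML configuration round-trips", {
  skip_if_not_installed("yaml")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("min_copies: 4",
               "identity: 0.6",
               "datasets:",
               "  - path: a.fa",
               "    dataset: ds1",
               "    class: Scyphozoa"), f)
  cfg <- read_pipeline_config(f)
  expect_equal(cfg$min_copies, 4L)
  expect_equal(cfg$identity, 0.6)
  expect_equal(cfg$datasets$dataset, "ds1")
})

test_that("benchmark compares observed and published counts, skipping absences", {
  # no files present: empty comparison, no error
  man <- data.frame(species = "Calvadosia cruxmelitensis",
                    path = "no/such/file.fa", class = "Staurozoa",
                    stringsAsFactors = FALSE)
  expect_message(out <- benchmark(man), "skipped")
  expect_equal(nrow(out), 0L)

  # a simulated stand-in for the staurozoan assembly reproduces the
  # published count of 11 RPRSamide copies
  spec <- precursor_spec("sim_calvadosia", "RPRS", 11, "Staurozoa",
                         spacer_pool = c("D", "V", "F", "A"))
  tx <- generate_transcriptome(list(spec), n_decoys = 10, seed = 29)
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(tx$records, f)
  man2 <- data.frame(species = "Calvadosia cruxmelitensis", path = f,
                     class = "Staurozoa", stringsAsFactors = FALSE)
  out2 <- benchmark(man2)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$observed_count, 11L)
  expect_true(out2$match)
})

test_that("an empty manifest aborts with a stage error", {
  expect_error(pipeline_config(data.frame(dataset = character(),
                                          class = character())))
})
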