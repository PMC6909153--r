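test_that("the five XPRXamide peptides form one family with the printed consensus", {
  fams <- group_families(c("RPRSamide", "LPRSamide", "RPRAamide",
                           "GPRGamide", "KPRSamide"))
  expect_length(fams, 1L)
  cons <- fams[[1]]$consensus
  expect_equal(cons$pattern, "X1PRX2amide")
  expect_equal(cons$wildcards$X2, c("A", "G", "S"))
})

test_that("GRFamide peptides of different lengths share one family", {
  fams <- group_families(c("pQGRFamide", "pQWLRGRFamide", "pQFLRGRFamide"))
  expect_length(fams, 1L)
  expect_match(fams[[1]]$consensus$pattern, "GRFamide$")
  # columns where the short member is absent are wildcards
  expect_true(length(fams[[1]]$consensus$wildcards) >= 1L)
})

test_that("a singleton family's consensus is the literal peptide", {
  fams <- group_families("pQGRFamide")
  expect_length(fams, 1L)
  expect_equal(fams[[1]]$consensus$pattern, "QGRFamide")
  expect_length(fams[[1]]$consensus$wildcards, 0L)
})

test_that("amidated and non-amidated variants of one core share a family", {
  fams <- group_families(c("pQPPGVWamide", "pQPPGVW", "pQPPGTWamide"))
  expect_length(fams, 1L)
  expect_equal(nrow(fams[[1]]$members), 3L)
})

test_that("families partition the peptides and ignore input order", {
  peps <- c("RPRSamide", "LPRSamide", "pQGRFamide", "pQWLRGRFamide",
            "pQPPGVWamide", "CKGQMCWFRamide", "PPFHamide", "RPFLamide")
  fams <- group_families(peps)
  all_members <- unlist(lapply(fams, function(f) f$members$display))
  expect_setequal(all_members, peps)
  expect_equal(length(all_members), length(peps))   # no peptide twice
  set.seed(4)
  fams2 <- group_families(sample(peps))
  part <- function(fs) sort(vapply(fs, function(f)
    paste(sort(f$members$display), collapse = "+"), ""))
  expect_equal(part(fams2), part(fams))
  # the reported cross-class groupings hold
  expect_equal(part(fams),
               sort(c("LPRSamide+RPRSamide",
                      "pQGRFamide+pQWLRGRFamide",
                      "pQPPGVWamide",
                      "CKGQMCWFRamide",
                      "PPFHamide+RPFLamide")))
})

test_that("precursor architecture keeps GPRRamide apart from XPRXamide", {
  pep <- data.frame(
    display = c("RPRSamide", "LPRSamide", "RPRAamide", "GPRRamide",
                "GPRRamide"),
    core = c("RPRS", "LPRS", "RPRA", "GPRR", "GPRR"),
    n_state = "proline_protected",
    c_state = "amide",
    arch = c("dibasic", "dibasic", "dibasic", "monobasic", "monobasic"),
    stringsAsFactors = FALSE)
  fams <- group_families(pep)
  expect_length(fams, 2L)
  sizes <- sort(vapply(fams, function(f) nrow(f$members), 0L))
  expect_equal(sizes, c(2L, 3L))
})

test_that("every member matches its family consensus under right alignment", {
  peps <- c("RPRSamide", "LPRSamide", "RPRAamide", "GPRGamide",
            "pQGRFamide", "pQWLRGRFamide", "pQPPGVWamide", "pQPPGTWamide")
  fams <- group_families(peps)
  for (f in fams) {
    cons <- f$consensus
    # rebuild the column symbols from the pattern
    pat <- sub("amide$", "", cons$pattern)
    syms <- regmatches(pat, gregexpr("X[0-9]+|[A-Z]", pat))[[1]]
    L <- length(syms)
    for (i in seq_len(nrow(f$members))) {
      core <- f$members$core[i]
      padded <- c(rep("-", L - nchar(core)), strsplit(core, "")[[1]])
      for (j in seq_len(L)) {
        if (grepl("^X", syms[j])) {
          expect_true(padded[j] %in% cons$wildcards[[syms[j]]])
        } else {
          expect_equal(padded[j], syms[j])
        }
      }
    }
  }
})

test_that("presence matrix reports breadth and class specificity", {
  pep <- data.frame(
    display = c("RPRSamide", "RPRAamide", "LPRSamide", "GPRGamide",
                "pQHLRYamide", "pQHVRYamide"),
    core = c("RPRS", "RPRA", "LPRS", "GPRG", "QHLRY", "QHVRY"),
    n_state = c(rep("proline_protected", 4), rep("pyroglutamate", 2)),
    c_state = "amide",
    dataset = c("ds_st", "ds_cu", "ds_sc", "ds_oc", "ds_sc", "ds_sc2"),
    stringsAsFactors = FALSE)
  map <- c(ds_st = "Staurozoa", ds_cu = "Cubozoa", ds_sc = "Scyphozoa",
           ds_sc2 = "Scyphozoa", ds_oc = "Octocorallia")
  fams <- group_families(pep)
  ov <- presence_matrix(fams, map)
  expect_s3_class(ov, "family_overview")
  expect_equal(ov$breadth[1], 4L)                 # the XPRX-type family
  expect_true(any(ov$breadth == 1L & ov$class_specific))
  expect_error(presence_matrix(fams, map[-1]), "not mapped")
})

test_that("cystine loop sizes match the worked examples", {
  expect_equal(cystine_loop_size("CKGQMCWFRamide"), 6L)
  expect_equal(cystine_loop_size("CTSPMCWFRPamide"), 6L)
  expect_true(is.na(cystine_loop_size("AAA")))
  expect_true(is.na(cystine_loop_size("ACA")))
  expect_warning(res <- cystine_loop_size("CCACCA"), "two cysteines")
  expect_true(is.na(res))
})
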