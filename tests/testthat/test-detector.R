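test_that("processing-site grammar finds classical tracts", {
  s <- find_processing_sites("AAGKRAA")
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 3L)
  expect_equal(s$end, 5L)
  expect_equal(s$tract, "KR")
  expect_true(s$g_preceded)
  expect_equal(s$site_string, "GKR")

  expect_equal(nrow(find_processing_sites("AAAAAA")), 0L)

  s2 <- find_processing_sites("QPPGVWRRR")
  expect_equal(s2$tract, "RRR")
  expect_false(s2$g_preceded)

  # maximal munch: GKRR is one tract KRR with a G donor
  s3 <- find_processing_sites("AAGKRRAA")
  expect_equal(s3$tract, "KRR")
  expect_true(s3$g_preceded)
})

test_that("monobasic sites require a G donor unless configured otherwise", {
  # bare monobasic K and R are not sites under the default grammar
  expect_equal(nrow(find_processing_sites("AAKAA")), 0L)
  expect_equal(nrow(find_processing_sites("AARAA")), 0L)
  # with a donor they are
  expect_equal(find_processing_sites("AAGKAA")$site_string, "GK")
  expect_equal(find_processing_sites("AAGRAA")$site_string, "GR")
  # the permissive grammar accepts bare monobasic R
  g <- site_grammar(mono_R_requires_G = FALSE)
  expect_equal(find_processing_sites("AARAA", g)$site_string, "R")
  expect_equal(nrow(find_processing_sites("AAKAA", g)), 0L)
})

test_that("candidate extraction slices raw segments between sites", {
  p <- "EARPRSGKREARPRSGKREARPRSGKR"
  sites <- find_processing_sites(p)
  cand <- extract_candidates(p, sites)
  expect_equal(cand$seq, rep("EARPRS", 3))
  expect_true(all(cand$amidation_flag))
  # coordinates re-slice the protein to exactly seq
  expect_equal(substring(p, cand$start + 1L, cand$end), cand$seq)

  # a segment too short for min_len is dropped
  p2 <- "ESGKRAA"
  expect_equal(nrow(extract_candidates(p2, find_processing_sites(p2),
                                       min_len = 3L)), 0L)
  # a segment beyond max_len is dropped
  p3 <- paste0(strrep("W", 40), "GKR", "EARPRS", "GKR")
  cand3 <- extract_candidates(p3, find_processing_sites(p3), max_len = 30L)
  expect_equal(cand3$seq, "EARPRS")
})

test_that("right-anchored identity matches hand-computed values", {
  expect_equal(ranchored_identity("EARPRS", "EARPRS"), 1)
  expect_equal(ranchored_identity("EARPRS", "DARPRS"), 5 / 6)
  expect_equal(ranchored_identity("RPRS", "EARPRS"), 1)   # shorter anchored
  expect_equal(ranchored_identity("XXXX", "XXXX"), 0)     # X never matches
})

test_that("clustering is single-linkage, drops singletons, is order-insensitive", {
  cand <- data.frame(start = c(0L, 10L, 20L),
                     end = c(6L, 16L, 26L),
                     seq = c("EARPRS", "EARPRS", "DARPRS"),
                     amidation_flag = TRUE, site_index = 1:3,
                     stringsAsFactors = FALSE)
  cl <- cluster_candidates(cand, 0.5)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]$members), 3L)
  expect_equal(cl[[1]]$medoid$seq, "EARPRS")
  expect_equal(cl[[1]]$mean_pairwise_identity, mean(c(1, 5 / 6, 5 / 6)))

  far <- data.frame(start = c(0L, 10L), end = c(6L, 16L),
                    seq = c("EARPRS", "WWWWWW"), amidation_flag = TRUE,
                    site_index = 1:2, stringsAsFactors = FALSE)
  expect_length(cluster_candidates(far, 0.5), 0L)

  perm <- cand[c(3, 1, 2), ]
  cl2 <- cluster_candidates(perm, 0.5)
  expect_equal(sort(cl2[[1]]$members$seq), sort(cl[[1]]$members$seq))
  expect_equal(cl2[[1]]$medoid$seq, cl[[1]]$medoid$seq)
})

test_that("screen_protein applies the at-least-three rule", {
  mk <- function(n) paste(rep("EARPRSGKR", n), collapse = "")
  expect_true(screen_protein(mk(3))$is_hit)
  expect_false(screen_protein(mk(2))$is_hit)
  # site_count mode fires on sites alone
  expect_true(screen_protein(mk(3),
                             detector_params(mode = "site_count"))$is_hit)
})

test_that("shuffling a hit protein almost always destroys the hit", {
  g <- generate_precursor(precursor_spec("p", "RPRS", 11), seed = 3)
  v <- strsplit(g$record$seq, "")[[1]]
  set.seed(42)
  hits <- vapply(1:100, function(i)
    screen_protein(paste(sample(v), collapse = ""))$is_hit, TRUE)
  # permutation null recorded once: the shuffle keeps the extreme K/R/G
  # composition, so a small minority of shuffles still fire
  expect_lte(sum(hits), 15L)
})

test_that("detector recovers noisy precursors at >= 95% sensitivity", {
  cores <- c("RPRS", "LPRS", "RPRA", "GPRG", "QPPGVW", "QHLRY")
  hits <- vapply(1:200, function(i) {
    spec <- precursor_spec(paste0("p", i), cores[(i %% 6) + 1],
                           3 + (i %% 30), noise = 0.10)
    screen_protein(generate_precursor(spec, seed = 1000 + i)$record)$is_hit
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
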