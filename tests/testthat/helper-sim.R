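# Shared simulated study conditions: six precursors spanning the four
# classes (copy numbers inside the reported 3-32 range) among 200 decoys.
default_sim_specs <- function() {
  list(
    precursor_spec("prec_stauro", "RPRS", 11, "Staurozoa"),
    precursor_spec("prec_scypho", "LPRS", 7, "Scyphozoa"),
    precursor_spec("prec_cubo", "RPRA", 5, "Cubozoa"),
    precursor_spec("prec_octo", "GPRG", 32, "Octocorallia"),
    precursor_spec("prec_pqp", "QPPGVW", 9, "Scyphozoa",
                   site_weights = c(GKR = 2, RR = 1)),
    precursor_spec("prec_qhlry", "QHLRY", 3, "Scyphozoa",
                   site_weights = c(GR = 1, GKR = 1)))
}

# Annotate a simulated transcriptome and compare with its ground truth.
recover_transcriptome <- function(tx, min_orf_aa = 60L) {
  orfs <- six_frame_translate(tx$records, min_orf_aa = min_orf_aa)
  anns <- cnidopep:::collapse_by_parent(annotate_preprohormones(orfs))
  accepted <- names(anns)[vapply(anns, function(a) a$status == "accepted",
                                 TRUE)]
  truth <- tx$truth
  true_pos <- truth$transcript_id[truth$is_precursor]
  counts_exact <- vapply(true_pos, function(id) {
    want <- sort(strsplit(truth$displays[truth$transcript_id == id],
                          ";")[[1]])
    if (!id %in% names(anns)) return(FALSE)
    identical(want, sort(anns[[id]]$mature_peptides$display))
  }, TRUE)
  list(annotations = anns, accepted = accepted,
       sensitivity = mean(true_pos %in% accepted),
       false_positives = sum(!(accepted %in% true_pos)),
       counts_exact = counts_exact)
}
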