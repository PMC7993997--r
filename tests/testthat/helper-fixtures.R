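# small in-code fixtures shared across test files

# one transcript with explicit region lengths and optional sequence
toy_model <- function(utr5 = 30L, cds = 90L, utr3 = 30L, seq = NULL,
                      id = "T1") {
  if (is.null(seq)) {
    seq <- paste(sample(c("A", "C", "G", "T"), utr5 + cds + utr3,
                        replace = TRUE), collapse = "")
  }
  transcript_models(id, utr5, cds, utr3, sequence = seq)
}

# uniform track: constant count at every position
uniform_track <- function(model, value = 2L) {
  v <- rep(as.integer(value), tx_length(model))
  stats::setNames(list(v), model$transcript_id)
}

# random transcript-model table for round-trip properties
random_models <- function(n, seed = 1) {
  withr::with_seed(seed, {
    transcript_models(
      transcript_id = sprintf("RT%03d", seq_len(n)),
      utr5_len = sample(0:80, n, replace = TRUE),
      cds_len = 3L * sample(2:200, n, replace = TRUE),
      utr3_len = sample(0:120, n, replace = TRUE)
    )
  })
}

# 2x2x2 count matrix with given per-cell means
toy_count_matrix <- function(rna_ref, rpf_ref, rna_per, rpf_per,
                             gene_ids = NULL) {
  stopifnot(is.matrix(rna_ref))
  g <- nrow(rna_ref)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%03d", seq_len(g))
  counts <- cbind(rna_ref, rna_per, rpf_ref, rpf_per)
  libs <- tibble::tibble(
    library_id = c("rna_reference_rep1", "rna_reference_rep2",
                   "rna_perturbed_rep1", "rna_perturbed_rep2",
                   "rpf_reference_rep1", "rpf_reference_rep2",
                   "rpf_perturbed_rep1", "rpf_perturbed_rep2"),
    condition = rep(rep(c("reference", "perturbed"), each = 2), 2),
    assay = rep(c("RNA", "RPF"), each = 4),
    replicate = rep(1:2, 4)
  )
  rownames(counts) <- gene_ids
  colnames(counts) <- libs$library_id
  count_matrix(counts, libs)
}
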