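#!/usr/bin/env Rscript
# mRNA-feature association layer: basal TE, CDS/5'UTR lengths and Kozak
# context scores versus the TE changes; group-vs-all tests for uORF-bearing
# mRNAs; CDS-length pentiles; start-codon context frequencies; hierarchical
# clustering of per-condition TE values.

suppressMessages(library(riboflux))

models <- read_annotation("scratch/dataset/annotation.gff3", "gff3")
models <- read_transcript_fasta(models, "scratch/dataset/transcripts.fa")
te <- readr::read_tsv("results/te_results.tsv", show_col_types = FALSE)
nt <- readr::read_tsv("results/naive_te.tsv", show_col_types = FALSE)
uorfs <- readr::read_tsv("scratch/dataset/uorf_truth.tsv",
                         show_col_types = FALSE)

kept <- models[match(nt$gene_id, models$transcript_id), ]
# context weights from the ~270 best-translated mRNAs
ok <- kept$utr5_len >= 3
top <- which(ok)[order(nt$log2TE_reference[ok],
                       decreasing = TRUE)][1:270]
weights <- build_weight_matrix(
  substr(kept$sequence[top], kept$utr5_len[top] - 2, kept$utr5_len[top] + 4))

ft <- feature_table(kept, nt$log2TE_reference, weights = weights,
                    groups = tibble::tibble(
                      transcript_id = unique(uorfs$transcript_id),
                      uorf = TRUE))
ft$uorf[is.na(ft$uorf)] <- FALSE
readr::write_tsv(ft, "results/feature_table.tsv")

dte <- te$log2dTE[match(ft$transcript_id, te$gene_id)]
corr <- feature_dte_correlations(
  ft[, c("basal_log2te", "cds_len", "utr5_len", "context_score")], dte)
readr::write_tsv(corr, "results/feature_dte_correlations.tsv")
print(corr)

gv <- group_vs_all(dte[is.finite(dte)], ft$uorf[is.finite(dte)])
message(sprintf("uORF-bearing mRNAs vs all: median dTE %.3f vs %.3f (MW p = %.3g)",
                gv$median_group, gv$median_all, gv$mw[["p"]]))

readr::write_tsv(pentile_dte(dte[is.finite(dte)],
                             ft$cds_len[is.finite(dte)],
                             ft$transcript_id[is.finite(dte)]),
                 "results/cds_length_pentiles.tsv")

readr::write_tsv(start_context_frequencies(kept),
                 "results/start_context_frequencies.tsv")

m_te <- as.matrix(nt[, c("log2TE_reference", "log2TE_perturbed")])
rownames(m_te) <- nt$gene_id
cl <- cluster_dte(m_te[stats::complete.cases(m_te), ][1:500, ])
readr::write_tsv(tibble::tibble(gene_id = cl$leaf_order),
                 "results/te_cluster_leaf_order.tsv")
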