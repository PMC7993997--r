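#!/usr/bin/env Rscript
# uORF translation calling and differential relative ribosome occupancy.
# Candidates (AUG + nine near-cognate starts, >= 3 codons, wholly inside the
# 5'UTR) are filtered by the start-site cascade (+1/-1 ratio > 4, combined
# counts > 14, zero-frame fraction > 0.5) and the periodicity/uniformity
# score (> 0.5); RRO = interior uORF counts / interior CDS counts is then
# tested for condition dependence with the region x condition NB GLM.

suppressMessages(library(riboflux))

models <- read_annotation("scratch/dataset/annotation.gff3", "gff3")
models <- read_transcript_fasta(models, "scratch/dataset/transcripts.fa")
meta <- readr::read_tsv("scratch/dataset/libraries.tsv",
                        show_col_types = FALSE)
rpf <- meta[meta$assay == "RPF", ]
tracks <- lapply(setNames(rpf$library_id, rpf$library_id), function(lib) {
  read_positional_counts(file.path("scratch/dataset", paste0(lib, ".wig")),
                         models, "wiggle")
})

pooled <- pool_tracks(tracks)
report <- call_translated_uorfs(models, pooled)
# full report (mostly zero-count candidates) is bulky; keep it in scratch
# and publish the rows with any start-site signal
readr::write_tsv(report, "scratch/uorf_filter_report_full.tsv")
readr::write_tsv(report[report$plus1_count + report$minus1_count > 0, ],
                 "results/uorf_filter_report.tsv")
translated <- report[report$translated, ]
message(sprintf("%d candidates scanned, %d called translated (%d AUG, %d near-cognate)",
                nrow(report), nrow(translated),
                sum(translated$start_codon == "ATG"),
                sum(translated$start_codon != "ATG")))

mat <- read_count_matrix("scratch/dataset/counts.tsv",
                         "scratch/dataset/libraries.tsv")
sf <- size_factors(suppressMessages(filter_genes(mat)))
rro <- compute_rro(translated, models, tracks)
res <- diff_rro(rro, rpf, sf = sf[rpf$library_id])
readr::write_tsv(res, "results/rro_results.tsv")
message(sprintf("RRO tested for %d uORFs; %d significant at FDR < 0.05",
                sum(res$converged), sum(res$class != "ns")))
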