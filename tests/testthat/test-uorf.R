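test_that("candidate enumeration is hand-traceable on a tiny 5'UTR", {
  # 5'UTR AAA ATG GCC TAA AAA then a minimal CDS
  seq <- paste0("AAAATGGCCTAAAAA", "ATGCCCTAA")
  m <- transcript_models("T1", 15L, 9L, 0L, sequence = seq)
  cand <- enumerate_candidates(m)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, 3L)
  expect_equal(cand$start_codon, "ATG")
  expect_equal(cand$n_codons, 3L)
  expect_equal(cand$stop, 9L)
  # no starts at all -> empty
  m0 <- transcript_models("T2", 12L, 9L, 0L,
                          sequence = paste0("CCCCCCCCCCCC", "ATGCCCTAA"))
  expect_equal(nrow(enumerate_candidates(m0)), 0L)
  expect_error(enumerate_candidates(transcript_models("T3", 12L, 9L, 0L)),
               "sequence missing")
})

test_that("enumeration equals a brute-force scan on random sequences", {
  withr::with_seed(101, {
    for (rep in 1:120) {
      utr5 <- sample(9:120, 1)
      seq5 <- paste(sample(c("A", "C", "G", "T"), utr5, replace = TRUE),
                    collapse = "")
      m <- transcript_models("R1", utr5, 9L, 0L,
                             sequence = paste0(seq5, "ATGCCCTAA"))
      got <- enumerate_candidates(m)
      exp <- oracle_scan_uorfs(m$sequence, utr5)
      expect_equal(nrow(got), nrow(exp))
      if (nrow(got)) {
        expect_equal(got$start, exp$start)
        expect_equal(got$stop, exp$stop)
        expect_equal(got$n_codons, exp$n_codons)
        expect_equal(got$start_codon, exp$start_codon)
      }
    }
  })
})

test_that("start-site filters apply the published strict inequalities", {
  seq <- paste0(strrep("C", 3), "ATG", strrep("GCA", 4), "TAA", strrep("C", 3),
                "ATGCCCTAA")
  m <- transcript_models("T1", 24L, 9L, 0L, sequence = seq)
  cand <- enumerate_candidates(m)
  expect_equal(nrow(cand), 1L)
  track <- integer(tx_length(m))
  track[1:3] <- c(2L, 1L, 1L)               # minus1 window = 4
  track[4:6] <- c(10L, 5L, 5L)              # plus1 window = 20
  f <- start_site_filter(cand, track)
  expect_equal(f$plus1_count, 20L)
  expect_equal(f$minus1_count, 4L)
  expect_true(f$ratio_pass)                 # 5 > 4
  expect_true(f$count_pass)                 # 24 > 14
  # boundary: ratio exactly 4 fails, combined exactly 15 passes
  track[1:3] <- c(1L, 1L, 1L)
  track[4:6] <- c(4L, 4L, 4L)
  f2 <- start_site_filter(cand, track)
  expect_false(f2$ratio_pass)               # 12/3 = 4, not > 4
  expect_true(f2$count_pass)                # 15 > 14
  # combined exactly 14 fails
  track[4:6] <- c(4L, 4L, 3L)
  expect_false(start_site_filter(cand, track)$count_pass)
  # minus1 == 0: pass iff plus1 > 4
  track[1:3] <- 0L; track[4:6] <- c(2L, 2L, 1L)
  expect_true(start_site_filter(cand, track)$ratio_pass)
  track[4:6] <- c(2L, 1L, 1L)
  expect_false(start_site_filter(cand, track)$ratio_pass)
})

test_that("the periodicity score hits its closed-form extremes", {
  seq <- paste0(strrep("C", 3), "ATG", strrep("GCA", 8), "TAA", strrep("C", 3),
                "ATGCCCTAA")
  m <- transcript_models("T1", 36L, 9L, 0L, sequence = seq)
  cand <- enumerate_candidates(m)
  track <- integer(tx_length(m))
  body_starts <- seq(4L, 31L, by = 3L)       # frame-0 indices of all 10 codons
  # all counts frame 0, uniform over codons -> score 1
  track[body_starts] <- 5L
  s <- periodicity_score(start_site_filter(cand, track), track)
  expect_equal(s$periodicity_prob, 1)
  # frame fraction exactly 1/3 -> score 0
  track[] <- 0L
  track[4:6] <- c(2L, 2L, 2L); track[7:9] <- c(2L, 2L, 2L)
  s2 <- periodicity_score(start_site_filter(cand, track), track)
  expect_equal(s2$periodicity_prob, 0)
  # everything on one codon of a 10-codon uORF, frame 0 -> PME 0 -> score 0
  track[] <- 0L
  track[7] <- 50L
  s3 <- periodicity_score(start_site_filter(cand, track), track)
  expect_equal(s3$periodicity_prob, 0)
  # zero body counts -> score 0, not translated
  track[] <- 0L
  s4 <- periodicity_score(start_site_filter(cand, track), track)
  expect_equal(s4$periodicity_prob, 0)
  expect_false(s4$translated)
})

test_that("simulated in-frame uORF reads pass the frame filter when deep", {
  cfg <- simulation_config(n_genes = 150, seed = 102, frac_uorf_genes = 1,
                           uorf_inframe_fraction = 0.7,
                           rna_mean_log10_range = c(2.8, 3.5))
  dat <- simulate_counts(simulate_transcriptome(cfg), tracks = TRUE)
  rpf <- library_ids(dat$matrix, assay = "RPF")
  pooled <- pool_tracks(dat$tracks[rpf])
  report <- call_translated_uorfs(dat$models, pooled)
  planted <- paste0(dat$uorf_truth$transcript_id, ":", dat$uorf_truth$start)
  rep_key <- paste0(report$transcript_id, ":", report$start)
  body <- report[rep_key %in% planted, ]
  deep <- body$plus1_count + body$minus1_count >= 50
  expect_gte(mean(body$frame_pass[deep]), 0.95)
})

test_that("lowering any threshold never removes a translated uORF", {
  cfg <- simulation_config(n_genes = 60, seed = 103, frac_uorf_genes = 1,
                           rna_mean_log10_range = c(2.5, 3.2))
  dat <- simulate_counts(simulate_transcriptome(cfg), tracks = TRUE)
  pooled <- pool_tracks(dat$tracks[library_ids(dat$matrix, assay = "RPF")])
  withr::with_seed(104, {
    for (i in 1:8) {
      hi <- list(ratio = runif(1, 4, 8), comb = runif(1, 14, 30),
                 frame = runif(1, 0.5, 0.8), per = runif(1, 0.5, 0.8))
      lo <- list(ratio = runif(1, 0, hi$ratio), comb = runif(1, 0, hi$comb),
                 frame = runif(1, 0.34, hi$frame), per = runif(1, 0, hi$per))
      t_hi <- call_translated_uorfs(dat$models, pooled,
                                    ratio_threshold = hi$ratio,
                                    combined_threshold = hi$comb,
                                    frame_threshold = hi$frame,
                                    periodicity_threshold = hi$per)
      t_lo <- call_translated_uorfs(dat$models, pooled,
                                    ratio_threshold = lo$ratio,
                                    combined_threshold = lo$comb,
                                    frame_threshold = lo$frame,
                                    periodicity_threshold = lo$per)
      expect_true(all(t_hi$uorf_id[t_hi$translated] %in%
                        t_lo$uorf_id[t_lo$translated]))
    }
  })
})

test_that("RRO windows trim edges exactly as enumerated by hand", {
  # 30 nt 5'UTR with a 5-codon uORF starting at position 3
  seq5 <- paste0("AAA", "ATG", "GCA", "GCA", "GCA", "TAA", strrep("A", 12))
  cds <- paste0("ATG", strrep("GCA", 23), "TAA")   # 25 codons
  m <- transcript_models("T1", 30L, 75L, 6L, sequence = paste0(seq5, cds, "AAAAAA"))
  cand <- enumerate_candidates(m)
  expect_equal(cand$start, 3L)
  win <- rro_windows(cand[1, ], m)
  # counting window = codons 2..(n-2): drop the start codon, the stop codon
  # and the last sense codon -> positions 6..11; none fall in the UTR's
  # first (0..2) or last (27..29) triplet
  expect_equal(win$uorf_window, 6:11)
  # CDS: skip first 20 codons (60 nt) and the stop codon
  expect_equal(win$cds_window, (30 + 60):(30 + 75 - 4))
  # the UTR edge triplets are masked out of the uORF window: with the
  # geometric invariants (start >= 3, stop + 3 <= utr5) the interior can
  # never reach them, so the mask must leave a valid window untouched
  expect_equal(win$uorf_window,
               setdiff(6:11, c(0:2, 27:29)))
})

test_that("a 3-codon uORF has no interior and is excluded with a reason", {
  cds25 <- paste0("ATG", strrep("GCA", 23), "TAA")
  seq <- paste0(strrep("A", 6), "ATGGCATAA", strrep("A", 6), cds25)
  m <- transcript_models("T1", 21L, 75L, 0L, sequence = seq)
  cand <- enumerate_candidates(m)
  cand3 <- cand[cand$n_codons == 3L, ][1, ]
  tracks <- list(lib1 = stats::setNames(list(rep(1L, tx_length(m))), "T1"))
  rro <- compute_rro(cand3, m, tracks)
  expect_equal(nrow(rro$uorf_counts), 0L)
  expect_equal(rro$excluded$reason, "empty_uorf_interior")
})

test_that("RRO is a plain count ratio, invariant to library scaling", {
  seq5 <- paste0("AAA", "ATG", strrep("GCA", 4), "TAA", strrep("A", 9))
  cds <- paste0("ATG", strrep("GCA", 28), "TAA")
  m <- transcript_models("T1", 30L, 90L, 3L,
                         sequence = paste0(seq5, cds, "AAA"))
  cand <- enumerate_candidates(m)[1, ]
  v <- integer(tx_length(m))
  win <- rro_windows(cand, m)
  v[win$uorf_window + 1L] <- 2L              # 9 positions -> 18 counts
  v[win$cds_window + 1L] <- 5L
  tracks <- list(libA = stats::setNames(list(v), "T1"),
                 libB = stats::setNames(list(7L * v), "T1"))
  rro <- compute_rro(cand, m, tracks)
  expect_equal(rro$uorf_counts[1, "libA"], sum(v[win$uorf_window + 1L]))
  expect_equal(unname(rro$rro[1, "libA"]), unname(rro$rro[1, "libB"]))
  expect_equal(unname(rro$rro[1, "libA"]),
               sum(v[win$uorf_window + 1L]) / sum(v[win$cds_window + 1L]))
})

test_that("differential RRO enforces count floors and is null on identical data", {
  cfg <- simulation_config(n_genes = 120, seed = 105, frac_uorf_genes = 1,
                           rna_mean_log10_range = c(2.5, 3.3))
  dat <- simulate_counts(simulate_transcriptome(cfg), tracks = TRUE)
  rpf <- dat$matrix$libraries[dat$matrix$libraries$assay == "RPF", ]
  pooled <- pool_tracks(dat$tracks[rpf$library_id])
  rep <- call_translated_uorfs(dat$models, pooled)
  tr <- rep[rep$translated, ]
  rro <- compute_rro(tr, dat$models, dat$tracks[rpf$library_id])
  res <- diff_rro(rro, rpf, sf = dat$size_factors[rpf$library_id])
  excl <- attr(res, "excluded")
  # floors: every excluded-by-floor uORF really is below a floor
  below <- rownames(rro$uorf_counts)[rowMeans(rro$uorf_counts) < 2 |
                                       rowMeans(rro$cds_counts) < 32]
  expect_setequal(excl$uorf_id[grepl("floor", excl$reason)], below)
  expect_true(all(!res$uorf_id %in% below))
  # identical tracks across conditions -> log2dRRO exactly 0
  tracks_dup <- dat$tracks[rpf$library_id]
  tracks_dup[["rpf_perturbed_rep1"]] <- tracks_dup[["rpf_reference_rep1"]]
  tracks_dup[["rpf_perturbed_rep2"]] <- tracks_dup[["rpf_reference_rep2"]]
  rro0 <- compute_rro(tr, dat$models, tracks_dup)
  res0 <- diff_rro(rro0, rpf, sf = NULL)
  expect_equal(res0$log2dRRO[res0$converged],
               rep(0, sum(res0$converged)), tolerance = 1e-6)
})
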