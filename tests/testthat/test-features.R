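test_that("weight matrices normalize frequencies to the most prevalent base", {
  # engineered frequencies 0.5/0.25/0.15/0.10 at position -3
  ctx <- c(rep("AAAATGG", 10), rep("CAAATGG", 5), rep("GAAATGG", 3),
           rep("TAAATGG", 2))
  w <- build_weight_matrix(ctx)
  expect_equal(unname(w["-3", c("A", "C", "G", "T")]), c(1, 0.5, 0.3, 0.2))
  expect_equal(max(w["-3", ]), 1)
  # degenerate input: observed bases weight 1, unobserved get the floor
  w1 <- build_weight_matrix(rep("AAAATGG", 4))
  expect_equal(unname(w1["-2", "A"]), 1)
  expect_equal(unname(w1["-2", "C"]), 1e-3 / 1)
  expect_error(build_weight_matrix(character(0)), "no contexts")
  # uniform random contexts converge to all-ones weights
  withr::with_seed(201, {
    rand <- vapply(1:10000, function(i) {
      paste0(paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = ""),
             "ATG", sample(c("A", "C", "G", "T"), 1))
    }, character(1))
    w2 <- build_weight_matrix(rand)
    expect_gt(min(w2), 0.9)
  })
})

test_that("context scores equal the direct fourth-root-of-product oracle", {
  base_w <- matrix(1, 4, 4, dimnames = list(c("-3", "-2", "-1", "+4"),
                                            c("A", "C", "G", "T")))
  m <- transcript_models("T1", 6L, 9L, 0L, sequence = "AAACCCATGGCATAA")
  w_all1 <- structure(base_w, class = c("context_weight_matrix", "matrix"))
  expect_equal(context_score(m, w_all1), 1)
  w_half <- structure(base_w * 0.5, class = c("context_weight_matrix", "matrix"))
  expect_equal(context_score(m, w_half), 0.5)
  withr::with_seed(202, {
    for (i in 1:1000) {
      w <- structure(matrix(runif(16, 1e-3, 1), 4, 4,
                            dimnames = dimnames(base_w)),
                     class = c("context_weight_matrix", "matrix"))
      got <- context_score(m, w)
      direct <- (w["-3", "C"] * w["-2", "C"] * w["-1", "C"] *
                   w["+4", "G"])^(1 / 4)
      expect_equal(got, direct, tolerance = 1e-12)
    }
  })
  # short 5'UTR -> undefined
  m2 <- transcript_models("T2", 2L, 9L, 0L, sequence = "CCATGGCATAA")
  expect_true(is.na(context_score(m2, w_all1)))
  # monotone in each weight
  w_lo <- structure(base_w * 0.4, class = class(w_all1))
  w_hi <- w_lo; w_hi["-3", "C"] <- 0.9
  expect_gt(context_score(m, w_hi), context_score(m, w_lo))
})

test_that("group-vs-all tests separate shifted groups and handle degenerate input", {
  withr::with_seed(203, {
    vals <- rnorm(300)
    grp <- rep(FALSE, 300); grp[1:100] <- TRUE
    shifted <- vals; shifted[grp] <- shifted[grp] + 1.5
    res <- group_vs_all(shifted, grp)
    expect_lt(res$mw[["p"]], 1e-6)
    expect_lt(res$ks[["p"]], 1e-4)
    expect_gt(res$median_group, res$median_all)
    # CDF table is a valid distribution table
    expect_equal(max(res$cdf$cdf_all), 1)
    expect_true(all(diff(res$cdf$cdf_group) >= 0))
    expect_error(group_vs_all(vals, rep(FALSE, 300)), "empty")
    expect_error(group_vs_all(vals, rep(TRUE, 300)), "strict subset")
    expect_warning(group_vs_all(vals, c(TRUE, rep(FALSE, 299))), "size 1")
  })
})

test_that("rank-based statistics are invariant to monotone transforms", {
  withr::with_seed(204, {
    x <- rexp(200) + 0.1
    y <- x + rnorm(200, 0, 0.3)
    tab <- tibble::tibble(f = x)
    r1 <- feature_dte_correlations(tab, y)
    r2 <- feature_dte_correlations(tibble::tibble(f = log(x)), y)
    expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
    grp <- x > median(x)
    g1 <- group_vs_all(y, grp)
    g2 <- group_vs_all(exp(y), grp)
    expect_equal(g1$mw[["p"]], g2$mw[["p"]], tolerance = 1e-9)
  })
})

test_that("feature correlations hit the exact extremes and flag constants", {
  v <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 9.3, 2.3, 8.4)
  r <- feature_dte_correlations(tibble::tibble(same = v, neg = -v,
                                               const = rep(1, 12)), v)
  expect_equal(r$rho[r$feature == "same"], 1)
  expect_equal(r$rho[r$feature == "neg"], -1)
  expect_true(is.na(r$rho[r$feature == "const"]))
})

test_that("basal TE correlates with competition-driven TE changes", {
  cfg <- simulation_config(n_genes = 1000, seed = 205,
                           te_effect_model = "competition",
                           frac_uorf_genes = 0)
  sim <- simulate_transcriptome(cfg)
  r <- feature_dte_correlations(tibble::tibble(basal_te = sim$te), sim$effects)
  expect_gt(r$rho, 0.9)
})

test_that("clustering merges duplicates first and recovers planted blocks", {
  m <- rbind(a = c(1, 2), b = c(1, 2), c = c(8, 9))
  cl <- cluster_dte(m)
  first <- cl$tree$merge[1, ]
  expect_true(all(first < 0))                # first merge joins two leaves
  expect_equal(cl$tree$height[1], 0)         # identical rows at distance 0
  withr::with_seed(206, {
    blocks <- rbind(matrix(rnorm(40, 2, 0.2), 20),
                    matrix(rnorm(40, -2, 0.2), 20))
    rownames(blocks) <- sprintf("g%02d", 1:40)
    cl2 <- cluster_dte(blocks)
    top2 <- cutree(cl2$tree, 2)
    expect_equal(length(unique(top2[1:20])), 1)
    expect_equal(length(unique(top2[21:40])), 1)
    expect_false(top2[[1]] == top2[[21]])
    # permutation invariance: same merges up to relabeling
    perm <- sample(40)
    cl3 <- cluster_dte(blocks[perm, ])
    expect_equal(cl3$tree$height, cl2$tree$height)
    expect_identical(cl3$leaf_order, cl2$leaf_order)
  })
  expect_error(cluster_dte(matrix(c(1, NA, 2, 3), 2,
                                  dimnames = list(c("a", "b"), NULL))),
               "missing values")
})

test_that("pentiles are equal-size rank bins with sensible box statistics", {
  dte <- c(5, 1, 4, 2, 8, 3, 9, 7, 0, 6)
  lens <- 1:10
  p <- pentile_dte(dte, lens, gene_id = letters[1:10])
  expect_equal(p$n, rep(2L, 5))
  expect_equal(p$feature_min, c(1, 3, 5, 7, 9))
  expect_equal(p$feature_max, c(2, 4, 6, 8, 10))
  expect_equal(p$median[1], median(dte[1:2]))
  # under independence the pentile medians straddle the global median
  withr::with_seed(207, {
    d2 <- rnorm(2000); f2 <- runif(2000)
    p2 <- pentile_dte(d2, f2)
    expect_lt(max(abs(p2$median - median(d2))), 0.15)
  })
})

test_that("start-context frequencies are proper distributions per position", {
  m <- transcript_models(
    c("T1", "T2"), c(10L, 10L), c(9L, 9L), c(0L, 0L),
    sequence = c("AAAAAAAAAAATGGCATAA", "AAAAAAAAAAATGCCCTAA"))
  f <- start_context_frequencies(m)
  expect_true(all(abs(rowSums(f[, c("A", "C", "G", "T")]) - 1) < 1e-12))
  expect_equal(f$A[f$position == -1], 1)
  expect_equal(f$A[f$position == 1], 1)      # the A of the AUG
  expect_equal(f$T[f$position == 2], 1)
  # A-rich planted set exceeds a GC-rich background at -3
  withr::with_seed(208, {
    mk <- function(pre) transcript_models(
      sprintf("S%03d", seq_along(pre)), 6L, 9L, 0L,
      sequence = paste0("AAA", pre, "ATGGCATAA"))
    strong <- mk(replicate(50, paste(sample(c("A", "A", "A", "C"), 3, TRUE),
                                     collapse = "")))
    weak <- mk(replicate(50, paste(sample(c("G", "C"), 3, TRUE),
                                   collapse = "")))
    fs <- start_context_frequencies(strong)
    fw <- start_context_frequencies(weak)
    expect_gt(fs$A[fs$position == -3], fw$A[fw$position == -3])
  })
})

test_that("the feature table joins attributes and groups by transcript", {
  m <- transcript_models(c("T1", "T2"), c(6L, 6L), c(9L, 9L), c(3L, 3L),
                         sequence = c("AAACCCATGGCATAACCC", "CCCAAAATGTTTTAACCC"))
  w <- build_weight_matrix(c("AAAATGG", "CCCATGT", "ACGATGA"))
  ft <- feature_table(m, c(1.5, -0.5), weights = w,
                      attributes = tibble::tibble(transcript_id = "T2",
                                                  half_life = 22),
                      groups = tibble::tibble(transcript_id = c("T1", "T2"),
                                              scl = c(TRUE, FALSE)))
  expect_equal(ft$basal_log2te, c(1.5, -0.5))
  expect_true(is.na(ft$half_life[1]) && ft$half_life[2] == 22)
  expect_identical(ft$scl, c(TRUE, FALSE))
  expect_true(all(ft$context_score > 0 & ft$context_score <= 1))
})
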