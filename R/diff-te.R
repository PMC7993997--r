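#' Median-of-ratios library size factors
#'
#' For each library, the size factor is the median across reference genes of
#' the ratio of that library's count to the gene's geometric mean across all
#' libraries; reference genes are those with strictly positive counts in
#' every library. Factors are rescaled so their geometric mean is 1.
#'
#' @param x a `count_matrix` or plain integer matrix.
#' @return named positive numeric vector, one factor per library.
#' @export
size_factors <- function(x) {
  K <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  ref <- rowSums(K > 0) == ncol(K)
  if (!any(ref)) {
    stop("no gene has positive counts in every library; filter genes first")
  }
  logK <- log(K[ref, , drop = FALSE])
  loggeo <- rowMeans(logK)
  s <- apply(logK, 2, function(col) exp(stats::median(col - loggeo)))
  s / exp(mean(log(s)))
}

#' Remove genes with too few mRNA reads
#'
#' Drops genes whose RNA-assay counts, summed over the RNA libraries of the
#' two compared conditions (four samples with two replicates each), fall
#' below `min_rna_reads` (default 10).
#'
#' @param x a `count_matrix`.
#' @param min_rna_reads threshold; genes with summed RNA counts strictly
#'   below it are removed.
#' @return the filtered `count_matrix`; the number of removed genes is
#'   reported via `message()`.
#' @export
filter_genes <- function(x, min_rna_reads = 10) {
  rna_libs <- library_ids(x, assay = "RNA")
  if (!length(rna_libs)) stop("no RNA libraries in metadata")
  keep <- rowSums(x$counts[, rna_libs, drop = FALSE]) >= min_rna_reads
  message(sum(!keep), " gene(s) removed with < ", min_rna_reads,
          " total mRNA reads")
  count_matrix(x$counts[keep, , drop = FALSE], x$libraries)
}

#' Estimate NB dispersions with trend shrinkage
#'
#' Per-gene method-of-moments dispersion estimates are computed from
#' within-cell normalized means and variances (a cell is one condition x
#' assay combination; every cell needs >= 2 replicates), pooled across cells
#' with degree-of-freedom weights. A dispersion-mean trend
#' `alpha ~ a0 + a1/mu` is fit by robust regression, and the final per-gene
#' dispersion is a log-space compromise between the raw estimate and the
#' trend value, floored at `alpha_floor`. By default the compromise weight is
#' empirical-Bayes: the weight on the per-gene estimate is
#' `prior_var / (prior_var + sampling_var)`, where the sampling variance of
#' the log dispersion follows from the replicate degrees of freedom
#' (`trigamma(df/2)`) and the prior (between-gene) variance is what remains
#' of the observed spread of log estimates around the trend, floored at
#' `0.25^2`. With two replicates per cell the per-gene estimates carry few
#' degrees of freedom, so the weight is small and dispersions lean on the
#' trend - which is what keeps the Wald null calibrated. This replaces the
#' Cox-Reid adjusted-likelihood machinery of full differential-expression
#' packages with a transparent moment estimator; see the methods vignette.
#'
#' @param x a `count_matrix`.
#' @param sf per-library size factors (from [size_factors()]).
#' @param alpha_floor lower bound for every dispersion (default 1e-8).
#' @param shrink_weight optional fixed weight on the per-gene estimate in
#'   log space (e.g. 0.5); `NULL` (default) selects the empirical-Bayes
#'   weight described above.
#' @return a `dispersion_model` list: `alpha` (shrunk, per gene),
#'   `alpha_hat` (raw MoM), `trend` (`c(a0, a1)`), `mu` (per-gene mean
#'   normalized count).
#' @export
estimate_dispersions <- function(x, sf, alpha_floor = 1e-8, shrink_weight = NULL) {
  K <- x$counts
  libs <- x$libraries
  cells <- split(seq_len(nrow(libs)), paste(libs$condition, libs$assay))
  if (any(lengths(cells) < 2L)) {
    stop("every (condition x assay) cell needs >= 2 replicates")
  }
  q <- sweep(K, 2, sf, "/")
  num <- matrix(0, nrow(K), length(cells))
  for (ci in seq_along(cells)) {
    idx <- cells[[ci]]
    qc <- q[, idx, drop = FALSE]
    mu_c <- rowMeans(qc)
    var_c <- apply(qc, 1, stats::var)
    shot <- mu_c * mean(1 / sf[idx])          # Poisson part of var(K/s)
    num[, ci] <- ifelse(mu_c > 0, (var_c - shot) / mu_c^2, NA_real_)
  }
  w <- lengths(cells) - 1L
  alpha_hat <- apply(num, 1, function(r) {
    ok <- is.finite(r)
    if (!any(ok)) return(NA_real_)
    sum(r[ok] * w[ok]) / sum(w[ok])
  })
  mu <- rowMeans(q)
  alpha_hat_f <- pmax(alpha_hat, alpha_floor)
  alpha_hat_f[is.na(alpha_hat_f)] <- alpha_floor

  use <- is.finite(alpha_hat) & mu > 0
  trend <- c(a0 = alpha_floor, a1 = 0)
  if (sum(use) >= 10L) {
    fit <- tryCatch(
      suppressWarnings(MASS::rlm(alpha_hat[use] ~ I(1 / mu[use]), maxit = 50)),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      trend <- c(a0 = max(unname(stats::coef(fit)[1]), alpha_floor),
                 a1 = max(unname(stats::coef(fit)[2]), 0))
    } else {
      trend <- c(a0 = max(stats::median(alpha_hat[use]), alpha_floor), a1 = 0)
    }
  }
  alpha_trend <- pmax(trend[["a0"]] + trend[["a1"]] / pmax(mu, 1e-8), alpha_floor)
  # the robust fit centers on the median of the right-skewed moment
  # estimates; recenter it on their (unbiased) mean so the trend is not
  # systematically low. Ratio of sums = through-origin regression of
  # alpha_hat on the trend, negatives included.
  ok <- is.finite(alpha_hat)
  if (any(ok) && sum(alpha_trend[ok]) > 0) {
    c_adj <- sum(alpha_hat[ok]) / sum(alpha_trend[ok])
    alpha_trend <- pmax(alpha_trend * c_adj, alpha_floor)
  }
  if (is.null(shrink_weight)) {
    df <- sum(w)
    sampling_var <- trigamma(df / 2)
    resid <- log(alpha_hat[use & alpha_hat > alpha_floor]) -
      log(alpha_trend[use & alpha_hat > alpha_floor])
    prior_var <- max(0.25^2,
                     if (length(resid) >= 10L)
                       stats::mad(resid)^2 - sampling_var else 0)
    shrink_weight <- prior_var / (prior_var + sampling_var)
  }
  alpha <- exp(shrink_weight * log(alpha_hat_f) +
                 (1 - shrink_weight) * log(alpha_trend))
  # a non-positive moment estimate carries no information about alpha beyond
  # shot noise; geometric shrinkage toward an arbitrary floor would collapse
  # the SE, so such genes take the trend value instead
  no_info <- !is.finite(alpha_hat) | alpha_hat <= alpha_floor
  alpha[no_info] <- alpha_trend[no_info]
  alpha <- pmax(alpha, alpha_floor)
  structure(list(alpha = alpha, alpha_hat = alpha_hat, trend = trend, mu = mu),
            class = "dispersion_model")
}

# Shared NB interaction GLM: per row of `counts`, fit
#   log mu = log sf + b0 + b1*[level2 of f_assay] + b2*[level2 of f_cond]
#            + b3*[interaction]
# by IRLS (stats::glm.fit with the fixed-theta MASS negative binomial
# family) and return Wald statistics for the interaction term.
nb_interaction_fit <- function(counts, f_assay, f_cond, sf, alpha) {
  f_assay <- factor(f_assay)
  f_cond <- factor(f_cond)
  stopifnot(nlevels(f_assay) == 2L, nlevels(f_cond) == 2L,
            ncol(counts) == length(f_assay), length(f_assay) == length(f_cond),
            length(sf) == length(f_assay))
  X <- stats::model.matrix(~ f_assay * f_cond)
  off <- log(sf)
  n <- nrow(counts)
  beta_assay <- beta_int <- se_int <- rep(NA_real_, n)
  converged <- logical(n)
  for (g in seq_len(n)) {
    y <- counts[g, ]
    fam <- MASS::negative.binomial(theta = 1 / max(alpha[g], 1e-12), link = "log")
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = fam, offset = off,
                                      control = list(maxit = 50))),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) next
    Wv <- fit$weights
    XtWX <- crossprod(X * sqrt(Wv))
    V <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(V)) next
    converged[g] <- TRUE
    beta_assay[g] <- fit$coefficients[2]
    beta_int[g] <- fit$coefficients[4]
    se_int[g] <- sqrt(V[4, 4])
  }
  z <- beta_int / se_int
  p <- 2 * stats::pnorm(-abs(z))
  list(beta_assay = beta_assay, beta_int = beta_int, se_int = se_int,
       wald_z = z, p_value = p, converged = converged)
}

#' Differential translational efficiency via an NB interaction GLM
#'
#' For each gene, fits the negative-binomial log-linear model
#' \deqn{\log \mu_{gj} = \log s_j + \beta_0 + \beta_A [RPF] +
#'   \beta_C [perturbed] + \beta_I [RPF \wedge perturbed]}
#' with fixed shrunk dispersion. TE is the RPF effect against the RNA
#' baseline, so `log2TE_reference = beta_A/ln 2`,
#' `log2TE_perturbed = (beta_A + beta_I)/ln 2`, and the interaction
#' `log2dTE = beta_I/ln 2` is the between-condition change in log2 TE. A
#' two-sided normal Wald test on `beta_I` gives p-values, adjusted by
#' Benjamini-Hochberg across converged genes; genes are classed `up`/`down`
#' at `fdr < fdr_threshold`, else `ns`.
#'
#' @param x a (filtered) `count_matrix` with the full 2x2 design.
#' @param sf size factors from [size_factors()].
#' @param dispersions a `dispersion_model` from [estimate_dispersions()].
#' @param fdr_threshold significance threshold on BH-adjusted p (default
#'   0.05, the 5% FDR line).
#' @return a `te_result` tibble: `gene_id`, `log2TE_reference`,
#'   `log2TE_perturbed`, `log2dTE`, `se`, `wald_z`, `p_value`, `fdr`,
#'   `class`, `converged`.
#' @export
fit_dte <- function(x, sf, dispersions, fdr_threshold = 0.05) {
  libs <- x$libraries
  fit <- nb_interaction_fit(x$counts,
                            f_assay = factor(libs$assay, c("RNA", "RPF")),
                            f_cond = factor(libs$condition,
                                            c("reference", "perturbed")),
                            sf = sf, alpha = dispersions$alpha)
  n_bad <- sum(!fit$converged)
  if (n_bad > 0) message(n_bad, " gene(s) failed to converge; excluded from FDR")
  log2dTE <- fit$beta_int / log(2)
  res <- tibble::tibble(
    gene_id = rownames(x$counts),
    log2TE_reference = fit$beta_assay / log(2),
    log2TE_perturbed = (fit$beta_assay + fit$beta_int) / log(2),
    log2dTE = log2dTE,
    se = fit$se_int / log(2),
    wald_z = fit$wald_z,
    p_value = ifelse(fit$converged, fit$p_value, NA_real_),
    converged = fit$converged
  )
  res$fdr <- NA_real_
  res$fdr[res$converged] <- stats::p.adjust(res$p_value[res$converged], "BH")
  res$class <- ifelse(!res$converged | is.na(res$fdr) | res$fdr >= fdr_threshold,
                      "ns", ifelse(res$log2dTE > 0, "up", "down"))
  class(res) <- c("te_result", class(res))
  res
}

#' Naive per-condition log2 TE
#'
#' The descriptive TE used for basal-TE features and CDF plots:
#' `log2(mean normalized RPF + 0.5) - log2(mean normalized RNA + 0.5)`
#' per condition (pseudocount 0.5; the GLM in [fit_dte()] uses raw counts).
#'
#' @param x a `count_matrix`.
#' @param sf size factors.
#' @return tibble with `gene_id`, `log2TE_reference`, `log2TE_perturbed`.
#' @export
naive_te <- function(x, sf) {
  q <- sweep(x$counts, 2, sf, "/")
  te_for <- function(cond) {
    rpf <- library_ids(x, condition = cond, assay = "RPF")
    rna <- library_ids(x, condition = cond, assay = "RNA")
    log2(rowMeans(q[, rpf, drop = FALSE]) + 0.5) -
      log2(rowMeans(q[, rna, drop = FALSE]) + 0.5)
  }
  tibble::tibble(gene_id = rownames(x$counts),
                 log2TE_reference = te_for("reference"),
                 log2TE_perturbed = te_for("perturbed"))
}

#' Run the full differential-TE stage
#'
#' Convenience wrapper: mRNA-read filter, size factors, dispersion
#' estimation, and the interaction GLM.
#'
#' @param x a `count_matrix`.
#' @param min_rna_reads mRNA-read floor for [filter_genes()].
#' @param fdr_threshold FDR threshold for classification.
#' @return list with `result` (a `te_result` tibble), `size_factors`,
#'   `dispersions`, and the filtered `matrix`.
#' @export
run_dte <- function(x, min_rna_reads = 10, fdr_threshold = 0.05) {
  xf <- filter_genes(x, min_rna_reads)
  sf <- size_factors(xf)
  disp <- estimate_dispersions(xf, sf)
  res <- fit_dte(xf, sf, disp, fdr_threshold)
  list(result = res, size_factors = sf, dispersions = disp, matrix = xf)
}
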