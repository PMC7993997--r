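#' Build an AUG-context weight matrix from reference contexts
#'
#' From a set of start-codon contexts (7-mers covering positions -3..+4,
#' where the A of the AUG is +1), computes per-position base frequencies at
#' the four informative positions (-3, -2, -1, +4) and normalizes each to
#' the most prevalent base, giving relative adaptiveness weights in (0, 1].
#' Unobserved bases get a small frequency floor before normalization so the
#' geometric mean in [context_score()] never annihilates.
#'
#' @param contexts character vector of 7-nt strings (`-3 -2 -1 A T G +4`);
#'   U is canonicalized to T.
#' @param freq_floor frequency assigned to unobserved bases (default 1e-3).
#' @return a `context_weight_matrix`: 4 x 4 numeric matrix, rows
#'   `c("-3","-2","-1","+4")`, columns `c("A","C","G","T")`, max of each row
#'   equal to 1.
#' @export
build_weight_matrix <- function(contexts, freq_floor = 1e-3) {
  contexts <- canonicalize_seq(contexts)
  if (!length(contexts)) stop("no contexts supplied")
  if (any(nchar(contexts) != 7L)) stop("contexts must be 7 nt (-3..+4)")
  positions <- c("-3" = 1L, "-2" = 2L, "-1" = 3L, "+4" = 7L)
  bases <- c("A", "C", "G", "T")
  w <- matrix(NA_real_, 4, 4, dimnames = list(names(positions), bases))
  for (p in names(positions)) {
    obs <- substr(contexts, positions[[p]], positions[[p]])
    f <- table(factor(obs, levels = bases)) / length(obs)
    f <- pmax(as.numeric(f), freq_floor)
    w[p, ] <- f / max(f)
  }
  structure(w, class = c("context_weight_matrix", class(w)))
}

#' AUG-context score (geometric mean of position weights)
#'
#' The context score of a main AUG is the geometric mean of the relative
#' adaptiveness weights of the bases at positions -3, -2, -1 and +4:
#' `(w_-3 * w_-2 * w_-1 * w_+4)^(1/4)`, computed in log space. Transcripts
#' whose 5'UTR is shorter than 3 nt (no -3..-1 context) get `NA`.
#'
#' @param models a `transcript_models` table with sequences.
#' @param weights a `context_weight_matrix` from [build_weight_matrix()].
#' @return numeric vector of scores in (0, 1], `NA` where undefined.
#' @export
context_score <- function(models, weights) {
  stopifnot(inherits(weights, "context_weight_matrix"))
  vapply(seq_len(nrow(models)), function(i) {
    utr5 <- models$utr5_len[i]
    s <- models$sequence[i]
    if (is.na(s) || utr5 < 3L) return(NA_real_)
    ctx <- c("-3" = substr(s, utr5 - 2L, utr5 - 2L),
             "-2" = substr(s, utr5 - 1L, utr5 - 1L),
             "-1" = substr(s, utr5, utr5),
             "+4" = substr(s, utr5 + 4L, utr5 + 4L))
    if (any(!ctx %in% c("A", "C", "G", "T"))) return(NA_real_)
    lw <- vapply(names(ctx), function(p) log(weights[p, ctx[[p]]]), numeric(1))
    exp(mean(lw))
  }, numeric(1))
}

#' Compare a gene group against all mRNAs
#'
#' Two-sided Kolmogorov-Smirnov and Mann-Whitney U tests of the values in a
#' group against the values of all genes (group included, matching the
#' figure convention of plotting a group's CDF against the all-mRNA CDF).
#'
#' @param values numeric vector (e.g. log2 dTE or basal log2 TE).
#' @param group logical vector flagging group members.
#' @return list with `ks` (statistic, p), `mw` (statistic, p),
#'   `median_group`, `median_all`, `n_group`, and a `cdf` tibble for
#'   plotting.
#' @export
group_vs_all <- function(values, group) {
  stopifnot(length(values) == length(group))
  ok <- is.finite(values)
  values <- values[ok]; group <- group[ok]
  if (!any(group)) stop("group is empty")
  if (all(group)) stop("group must be a strict subset")
  if (sum(group) == 1L) warning("group of size 1: tests are near-powerless")
  g <- values[group]
  ks <- suppressWarnings(stats::ks.test(g, values))
  mw <- suppressWarnings(stats::wilcox.test(g, values))
  sorted <- sort(values)
  cdf <- tibble::tibble(
    value = sorted,
    cdf_all = seq_along(sorted) / length(sorted),
    cdf_group = vapply(sorted, function(v) mean(g <= v), numeric(1))
  )
  list(ks = c(statistic = unname(ks$statistic), p = ks$p.value),
       mw = c(statistic = unname(mw$statistic), p = mw$p.value),
       median_group = stats::median(g), median_all = stats::median(values),
       n_group = sum(group), cdf = cdf)
}

#' Spearman correlations of mRNA features with dTE values
#'
#' Rank correlation (average-rank ties, two-sided t-approximation p) of each
#' feature column against a per-gene vector such as log2 dTE or basal TE.
#' Constant features are flagged with `NA`.
#'
#' @param features data frame of numeric per-gene feature columns.
#' @param dte numeric vector, same length as `nrow(features)`.
#' @param min_pairs minimum paired non-missing values (default 10).
#' @return tibble with `feature`, `rho`, `p_value`, `n`.
#' @export
feature_dte_correlations <- function(features, dte, min_pairs = 10L) {
  stopifnot(nrow(features) == length(dte))
  rows <- lapply(names(features), function(f) {
    x <- features[[f]]
    ok <- is.finite(x) & is.finite(dte)
    if (sum(ok) < min_pairs) {
      return(tibble::tibble(feature = f, rho = NA_real_, p_value = NA_real_,
                            n = sum(ok)))
    }
    if (stats::sd(x[ok]) == 0) {
      return(tibble::tibble(feature = f, rho = NA_real_, p_value = NA_real_,
                            n = sum(ok)))
    }
    ct <- suppressWarnings(stats::cor.test(x[ok], dte[ok], method = "spearman",
                                           exact = FALSE))
    tibble::tibble(feature = f, rho = unname(ct$estimate),
                   p_value = ct$p.value, n = sum(ok))
  })
  do.call(rbind, rows)
}

#' Hierarchically cluster dTE profiles
#'
#' Complete-linkage agglomerative clustering on Euclidean distances between
#' gene rows (the default of `stats::hclust`). Rows are pre-sorted by gene
#' id so that distance ties are broken deterministically.
#'
#' @param dte_matrix numeric matrix, genes x conditions, with gene rownames
#'   and no missing values.
#' @param linkage `"complete"` (default) or `"average"`.
#' @return list with `tree` (an `hclust`), `leaf_order` (gene ids in leaf
#'   order) and `ordered` (the reordered matrix, heatmap-ready).
#' @export
cluster_dte <- function(dte_matrix, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  if (nrow(dte_matrix) < 2L) stop("need at least two genes")
  if (anyNA(dte_matrix)) {
    stop("missing values in dTE matrix: impute or filter before clustering")
  }
  if (is.null(rownames(dte_matrix))) stop("dte_matrix needs gene rownames")
  dte_matrix <- dte_matrix[order(rownames(dte_matrix)), , drop = FALSE]
  tree <- stats::hclust(stats::dist(dte_matrix), method = linkage)
  leaf_order <- rownames(dte_matrix)[tree$order]
  list(tree = tree, leaf_order = leaf_order,
       ordered = dte_matrix[tree$order, , drop = FALSE])
}

#' Per-pentile dTE box statistics over a feature
#'
#' Splits genes into five equal-size rank bins of a feature (ties broken by
#' gene id; pentile 1 holds the smallest values, e.g. the 20% of mRNAs with
#' the shortest CDS) and reports box statistics of the dTE values per bin.
#'
#' @param dte numeric per-gene vector.
#' @param feature numeric per-gene vector to bin on (e.g. CDS length).
#' @param gene_id gene ids (tie-break order).
#' @return tibble with `pentile`, `n`, `median`, `q1`, `q3`,
#'   `feature_min`, `feature_max`.
#' @export
pentile_dte <- function(dte, feature, gene_id = seq_along(dte)) {
  stopifnot(length(dte) == length(feature))
  if (length(dte) < 5L) stop("need at least 5 genes for pentiles")
  ord <- order(feature, gene_id)
  n <- length(dte)
  bin <- integer(n)
  bin[ord] <- ceiling(5 * seq_len(n) / n)
  rows <- lapply(1:5, function(b) {
    v <- dte[bin == b]
    f <- feature[bin == b]
    tibble::tibble(pentile = b, n = length(v),
                   median = stats::median(v),
                   q1 = unname(stats::quantile(v, 0.25)),
                   q3 = unname(stats::quantile(v, 0.75)),
                   feature_min = min(f), feature_max = max(f))
  })
  do.call(rbind, rows)
}

#' Base frequencies around the main start codon
#'
#' Per-position base frequency table over the window -6..+3 around the main
#' AUG (the A of the AUG is +1), for a gene set; rows sum to 1. Genes whose
#' 5'UTR is shorter than 6 nt are skipped and counted.
#'
#' @param models a `transcript_models` table with sequences.
#' @param gene_set optional character vector of transcript ids (default all).
#' @return tibble with `position` (-6..-1, +1..+3), base-frequency columns
#'   `A`, `C`, `G`, `T`, and an `n_skipped` attribute.
#' @export
start_context_frequencies <- function(models, gene_set = NULL) {
  if (!is.null(gene_set)) models <- models[models$transcript_id %in% gene_set, ]
  usable <- !is.na(models$sequence) & models$utr5_len >= 6L
  n_skipped <- sum(!usable)
  models <- models[usable, ]
  if (!nrow(models)) stop("no usable transcripts for context frequencies")
  positions <- c(-6:-1, 1:3)
  bases <- c("A", "C", "G", "T")
  rows <- lapply(positions, function(p) {
    at <- ifelse(p < 0, models$utr5_len + p + 1L, models$utr5_len + p)
    obs <- substr(models$sequence, at, at)
    f <- table(factor(obs, levels = bases)) / length(obs)
    tibble::tibble(position = p, A = f[["A"]], C = f[["C"]],
                   G = f[["G"]], T = f[["T"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Assemble the per-gene mRNA feature table
#'
#' Joins transcript architecture, basal TE, context score, and optional
#' user-supplied attributes (abundance, half-life) and group flags into one
#' table for the association analyses.
#'
#' @param models a `transcript_models` table.
#' @param basal_log2te named (by gene or transcript id) or positionally
#'   aligned numeric vector of reference-condition log2 TE.
#' @param weights optional `context_weight_matrix` for context scores.
#' @param attributes optional data frame with `transcript_id` plus numeric
#'   columns (e.g. `abundance`, `half_life`).
#' @param groups optional data frame with `transcript_id` plus logical flag
#'   columns (e.g. `scl`, `rpg`, `uorf_aug`).
#' @return a tibble, one row per transcript.
#' @export
feature_table <- function(models, basal_log2te, weights = NULL,
                          attributes = NULL, groups = NULL) {
  out <- tibble::tibble(
    transcript_id = models$transcript_id,
    gene_id = models$gene_id,
    basal_log2te = as.numeric(basal_log2te),
    cds_len = models$cds_len,
    utr5_len = models$utr5_len
  )
  if (!is.null(weights)) out$context_score <- context_score(models, weights)
  for (extra in list(attributes, groups)) {
    if (is.null(extra)) next
    hit <- match(out$transcript_id, extra$transcript_id)
    for (col in setdiff(names(extra), "transcript_id")) {
      out[[col]] <- extra[[col]][hit]
    }
  }
  out
}
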