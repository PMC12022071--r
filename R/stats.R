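#' Ward hierarchical clustering of an autoscaled matrix
#'
#' Agglomerative clustering with the Ward.D2 criterion on Euclidean
#' distances; the heat-map companion of the multivariate analysis.
#'
#' @param X autoscaled numeric matrix (rows = samples).
#' @return `hclust` object (merge tree, heights, leaf order).
#' @export
hca_ward <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least two rows")
  if (any(!is.finite(X))) stop("X contains non-finite values")
  stats::hclust(stats::dist(X, method = "euclidean"), method = "ward.D2")
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H (via [stats::kruskal.test()]) followed by
#' Dunn's two-sided pairwise z tests on mean ranks, with the p values
#' multiplied by the number of comparisons (capped at 1).
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation (>= 2 groups, each >= 2
#'   values).
#' @return list with `H`, `df`, `p_value`, and `pairwise` (data frame:
#'   group_a, group_b, z, p_raw, p_adj).
#' @export
kruskal_dunn <- function(values, groups) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least two groups")
  if (any(tab < 2)) stop("every group needs at least two values")
  if (length(unique(values)) == 1) {
    # fully tied data carry no rank information
    combs <- utils::combn(names(tab), 2)
    return(list(H = 0, df = length(tab) - 1, p_value = 1,
                pairwise = data.frame(group_a = combs[1, ],
                                      group_b = combs[2, ], z = 0,
                                      p_raw = 1, p_adj = 1,
                                      stringsAsFactors = FALSE)))
  }
  kw <- stats::kruskal.test(values, factor(groups))
  N <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  combs <- utils::combn(names(tab), 2)
  m <- ncol(combs)
  rows <- lapply(seq_len(m), function(k) {
    a <- combs[1, k]; b <- combs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[a]] + 1 / n[[b]]))
    z <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group_a = a, group_b = b, z = z, p_raw = p,
               p_adj = min(p * m, 1), stringsAsFactors = FALSE)
  })
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, pairwise = do.call(rbind, rows))
}

#' Batched two-group tests with Benjamini-Hochberg adjustment
#'
#' Runs a two-sided Mann-Whitney U test (unpaired) or Wilcoxon signed-rank
#' test (paired) for every supplied comparison, and adjusts the batch of
#' raw p values with the Benjamini-Hochberg step-up procedure. Exact null
#' distributions are used for small tie-free samples (both n <= 8
#' unpaired), normal approximation with continuity correction otherwise.
#'
#' @param tests named list; each element is `list(a = , b = )` numeric
#'   vectors (equal lengths when paired).
#' @param paired use the signed-rank test on paired differences.
#' @return data frame: `test`, `statistic`, `p_raw`, `p_adj`, `method`.
#' @export
pairwise_bh <- function(tests, paired = FALSE) {
  rows <- lapply(names(tests), function(nm) {
    a <- tests[[nm]]$a; b <- tests[[nm]]$b
    if (length(a) == 0 || length(b) == 0) stop("empty sample in test ", nm)
    if (paired && length(a) != length(b)) {
      stop("paired test ", nm, " with unequal lengths")
    }
    exact <- if (paired) length(a) <= 25 else max(length(a), length(b)) <= 8
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, paired = paired, exact = exact,
                         correct = TRUE)
    )
    data.frame(test = nm, statistic = unname(ht$statistic),
               p_raw = ht$p.value, method = if (paired)
                 "wilcoxon_signed_rank" else "mann_whitney_u",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out[, c("test", "statistic", "p_raw", "p_adj", "method")]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Explicit step-up arithmetic: sorted raw p values are scaled by `m / i`
#' and monotonicity is enforced by a cumulative minimum from the largest
#' rank down, capped at 1.
#'
#' @param p numeric vector of raw p values.
#' @return adjusted p values in the original order.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(pmin(scaled, 1))))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Pearson correlation matrix and coefficient-of-variation summaries
#'
#' Pairwise Pearson correlations over peptide columns (pairwise-complete
#' rows) plus CV summaries at a grouping level: for every group with at
#' least two members, `CV = 100 * sd / mean` per peptide, cumulated as the
#' mean over peptides and groups.
#'
#' @param X numeric matrix or data frame (rows = observations, columns =
#'   peptides).
#' @param group optional grouping vector (e.g. patient or replicate id)
#'   for the CV summary.
#' @return list with `correlation` (matrix; constant columns give NA) and,
#'   when `group` is given, `cv` (data frame per group x peptide) and
#'   `cumulative_cv_pct` (scalar).
#' @export
corr_and_cv <- function(X, group = NULL) {
  X <- as.matrix(X)
  cm <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs",
                                    method = "pearson"))
  out <- list(correlation = cm)
  if (!is.null(group)) {
    group <- as.character(group)
    rows <- list()
    for (g in unique(group)) {
      sel <- group == g
      if (sum(sel) < 2) next
      mu <- colMeans(X[sel, , drop = FALSE])
      sd_ <- apply(X[sel, , drop = FALSE], 2, stats::sd)
      cv <- ifelse(mu != 0, 100 * sd_ / mu, NA_real_)
      if (any(mu == 0)) warning("zero-mean peptide in group ", g,
                                ": CV undefined")
      rows[[g]] <- data.frame(group = g, peptide = colnames(X), cv_pct = cv,
                              stringsAsFactors = FALSE, row.names = NULL)
    }
    cvdf <- do.call(rbind, rows)
    out$cv <- cvdf
    out$cumulative_cv_pct <- mean(cvdf$cv_pct, na.rm = TRUE)
  }
  out
}

#' Group-contrast scan of a peak table
#'
#' For every peptide column, runs [kruskal_dunn()] across the plaque-type
#' groups and extracts the requested pairwise contrast; convenience layer
#' used by the pipeline and the parameter-recovery experiments.
#'
#' @param pt `peak_table` (or plain matrix/data frame).
#' @param types plaque-type label per row.
#' @param contrast length-2 character vector, e.g. `c("CP", "DP")`.
#' @return data frame: `peptide`, `H`, `p_kw`, `z`, `p_raw`, `p_adj`
#'   (Dunn-adjusted, two-sided).
#' @export
contrast_scan <- function(pt, types, contrast) {
  X <- as.matrix(pt)
  stopifnot(length(types) == nrow(X), length(contrast) == 2)
  # rank tests need at least two observations per group
  counts <- table(types)
  keep_types <- names(counts)[counts >= 2]
  if (!all(contrast %in% keep_types)) {
    stop("contrast group(s) with fewer than two ROIs: ",
         paste(setdiff(contrast, keep_types), collapse = ", "))
  }
  sel <- types %in% keep_types
  X <- X[sel, , drop = FALSE]
  types <- types[sel]
  rows <- lapply(colnames(X), function(pep) {
    kd <- kruskal_dunn(X[, pep], types)
    pw <- kd$pairwise
    hit <- (pw$group_a == contrast[1] & pw$group_b == contrast[2]) |
      (pw$group_a == contrast[2] & pw$group_b == contrast[1])
    data.frame(peptide = pep, H = kd$H, p_kw = kd$p_value,
               z = pw$z[hit][1], p_raw = pw$p_raw[hit][1],
               p_adj = pw$p_adj[hit][1], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
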