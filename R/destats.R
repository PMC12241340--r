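#' Counts-per-million normalization
#'
#' `CPM = count / library_size * 1e6`. The library size defaults to the
#' number of linear-assigned fragments per sample (circRNA abundance is
#' normalized to the linear transcriptome), but any positive per-sample
#' denominator can be supplied.
#'
#' @param counts Integer matrix, features x samples.
#' @param library_size Positive numeric vector, one entry per sample (named
#'   or in column order).
#' @return An `expression_matrix`: numeric matrix with attributes
#'   `scale = "CPM"` and `library_size`.
#' @export
cpm_normalize <- function(counts, library_size) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(library_size), all(counts >= 0))
  if (!is.null(names(library_size)) && !is.null(colnames(counts)))
    library_size <- library_size[colnames(counts)]
  bad <- !is.finite(library_size) | library_size <= 0
  if (any(bad))
    stop("zero or invalid library size for sample(s): ",
         paste(if (!is.null(colnames(counts))) colnames(counts)[bad]
               else which(bad), collapse = ", "))
  m <- sweep(counts, 2, library_size, "/") * 1e6
  structure(m, scale = "CPM", library_size = library_size,
            class = c("expression_matrix", class(m)))
}

#' log2(CPM + c) transform
#'
#' @param m An `expression_matrix` on the CPM scale.
#' @param c Pseudocount, must be > 0 (default 1).
#' @return An `expression_matrix` with `scale = "log2CPM"` and attribute
#'   `pseudocount`.
#' @export
log_transform <- function(m, c = 1.0) {
  if (c <= 0) stop("pseudocount c must be > 0")
  if (!identical(attr(m, "scale"), "CPM"))
    stop("log_transform expects a CPM-scale expression matrix")
  out <- log2(unclass(m) + c)
  structure(out, scale = "log2CPM", pseudocount = c,
            library_size = attr(m, "library_size"),
            class = c("expression_matrix", class(out)))
}

#' Pairwise sample correlation
#'
#' Pearson correlation between sample columns, the replicate-concordance
#' display used for RNase R-treated vs control libraries. Zero-variance
#' columns give `NA` correlations with a warning.
#'
#' @param m A numeric matrix (typically log2CPM), features x samples.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(m) {
  m <- unclass(as.matrix(m))
  if (ncol(m) < 2L) stop("need at least 2 samples")
  v <- apply(m, 2, var)
  if (any(v == 0))
    warning("zero-variance sample(s), correlation undefined: ",
            paste(colnames(m)[v == 0], collapse = ", "))
  suppressWarnings(r <- cor(m))
  diag(r) <- ifelse(v == 0, NA_real_, 1)
  r
}

#' Method-of-moments common dispersion
#'
#' Counts are scaled to a common library size; within each group with at
#' least two samples the per-feature overdispersion `(s^2 - mu) / mu^2` is
#' computed (clamped at zero) and the estimate is the median over features
#' of the group-averaged values. The estimator is a deliberately simple
#' stand-in for a full negative-binomial dispersion fit: it is unbiased in
#' expectation at each feature but needs several degrees of freedom per
#' group before its median is close to the true dispersion.
#'
#' @param counts Integer matrix, features x samples.
#' @param library_size Per-sample library sizes.
#' @param group Factor (or coercible) of group labels per sample.
#' @return Dispersion `phi >= 0`. If no group has >= 2 samples, returns 0
#'   with a warning (Poisson fallback).
#' @export
estimate_common_dispersion <- function(counts, library_size, group) {
  counts <- as.matrix(counts)
  group <- as.factor(group)
  stopifnot(ncol(counts) == length(library_size),
            ncol(counts) == length(group))
  y <- sweep(counts, 2, library_size / mean(library_size), "/")
  ests <- NULL
  for (g in levels(group)) {
    sel <- group == g
    if (sum(sel) < 2L) next
    mu <- rowMeans(y[, sel, drop = FALSE])
    s2 <- apply(y[, sel, drop = FALSE], 1, var)
    e <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), NA_real_)
    ests <- cbind(ests, e)
  }
  if (is.null(ests)) {
    warning("no group has >= 2 samples; returning phi = 0 (Poisson fallback)")
    return(0)
  }
  phi <- median(rowMeans(ests, na.rm = TRUE), na.rm = TRUE)
  if (!is.finite(phi)) 0 else phi
}

# doubled-tail two-sided p for a ~ Binomial(n, p1), vectorized
binom_doubled_tail <- function(a, n, p1) {
  lo <- pbinom(a, n, p1)
  hi <- 1 - pbinom(a - 1, n, p1)
  p <- pmin(1, 2 * pmin(lo, hi))
  p[n == 0] <- 1
  p
}

# beta-binomial pmf on log scale; alpha/beta shape parameters
dbetabinom <- function(x, n, alpha, beta) {
  exp(lchoose(n, x) + lbeta(x + alpha, n - x + beta) - lbeta(alpha, beta))
}

# doubled-tail two-sided p under BetaBinomial(n, p1*theta, (1-p1)*theta)
betabinom_doubled_tail <- function(a, n, p1, theta) {
  if (n == 0) return(1)
  pmf <- dbetabinom(0:n, n, p1 * theta, (1 - p1) * theta)
  cdf <- cumsum(pmf)
  lo <- cdf[a + 1]
  hi <- 1 - if (a == 0) 0 else cdf[a]
  min(1, 2 * min(lo, hi))
}

#' Exact conditional enrichment test (RNase R treated vs control)
#'
#' For each feature, the treated-group total `a` is tested against the
#' combined total `n` conditional on `n`: under no enrichment
#' `a ~ Binomial(n, p1)` with `p1` the treated share of the summed library
#' sizes. The two-sided p-value doubles the smaller tail. With
#' overdispersion `phi > 0` the binomial is replaced by a beta-binomial
#' with the same mean and intra-class correlation `phi / (1 + phi)`
#' (`theta = 1 / phi`), which reduces to the exact binomial as `phi -> 0`.
#' `log2FC` is the log2 ratio of group mean `(CPM + c)`; BH-FDR is applied
#' across features.
#'
#' @param counts Integer matrix, features x samples.
#' @param library_size Per-sample library sizes (linear-assigned fragments
#'   by default in this pipeline).
#' @param group Two-level factor; the *second* level is treated
#'   (enrichment is treated vs control).
#' @param phi Common dispersion (default 0: exact binomial).
#' @param pseudocount `c` added to group-mean CPM before the ratio.
#' @return An `enrichment_table` data.frame: `feature`, `mean_cpm_control`,
#'   `mean_cpm_treated`, `log2fc`, `p`, `q`, `call` (all `ns` until
#'   [call_enriched()] is applied — this function applies it with the
#'   default cutoffs).
#' @export
enrichment_test <- function(counts, library_size, group, phi = 0,
                            pseudocount = 1.0) {
  counts <- as.matrix(counts)
  group <- as.factor(group)
  if (nlevels(group) != 2L)
    stop("group must have exactly two levels (control, treated)")
  stopifnot(ncol(counts) == length(group),
            ncol(counts) == length(library_size), phi >= 0)
  ctrl <- group == levels(group)[1]
  trt <- group == levels(group)[2]
  if (!any(ctrl) || !any(trt)) stop("each group needs >= 1 sample")

  a <- rowSums(counts[, trt, drop = FALSE])
  b <- rowSums(counts[, ctrl, drop = FALSE])
  n <- a + b
  p1 <- sum(library_size[trt]) / sum(library_size)

  if (phi == 0) {
    p <- binom_doubled_tail(a, n, p1)
  } else {
    theta <- 1 / phi
    p <- vapply(seq_along(a), function(i)
      betabinom_doubled_tail(a[i], n[i], p1, theta), numeric(1))
  }
  p[n == 0] <- 1

  cpm <- cpm_normalize(counts, library_size)
  mc <- rowMeans(cpm[, ctrl, drop = FALSE])
  mt <- rowMeans(cpm[, trt, drop = FALSE])
  log2fc <- log2((mt + pseudocount) / (mc + pseudocount))
  log2fc[n == 0] <- 0

  tab <- data.frame(
    feature = if (!is.null(rownames(counts))) rownames(counts)
              else sprintf("feat_%04d", seq_along(a)),
    mean_cpm_control = mc, mean_cpm_treated = mt,
    log2fc = log2fc, p = p, q = bh_adjust(p),
    call = "ns", stringsAsFactors = FALSE, row.names = NULL)
  class(tab) <- c("enrichment_table", "data.frame")
  call_enriched(tab)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values (via [stats::p.adjust()]); monotone in rank order
#' and `q >= p` elementwise.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Classify features as enriched / depleted / ns
#'
#' `enriched` iff `log2fc >= log2(fc_cutoff)` and `q < fdr_cutoff`
#' (a fold change of exactly 2.0 passes at the default cutoff);
#' `depleted` iff `log2fc <= -log2(fc_cutoff)` and `q < fdr_cutoff`.
#'
#' @param tab An `enrichment_table`.
#' @param fc_cutoff Fold-change cutoff (default 2.0).
#' @param fdr_cutoff FDR cutoff (default 0.05).
#' @return The table with the `call` column set.
#' @export
call_enriched <- function(tab, fc_cutoff = 2.0, fdr_cutoff = 0.05) {
  stopifnot(is.data.frame(tab), all(c("log2fc", "q") %in% names(tab)))
  lfc <- log2(fc_cutoff)
  tab$call <- ifelse(tab$log2fc >= lfc & tab$q < fdr_cutoff, "enriched",
              ifelse(tab$log2fc <= -lfc & tab$q < fdr_cutoff, "depleted",
                     "ns"))
  tab
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target - Ct_ref)_condition - (Ct_target - Ct_ref)_control`;
#' relative expression is `2^-ddCt` (ACTB is the usual reference gene for
#' circRNA divergent-primer qPCR).
#'
#' @param ct_target_cond,ct_ref_cond Target and reference Ct in the
#'   condition of interest.
#' @param ct_target_ctrl,ct_ref_ctrl Target and reference Ct in the control.
#' @return Relative expression (> 0); vectorized.
#' @export
ddct <- function(ct_target_cond, ct_ref_cond, ct_target_ctrl, ct_ref_ctrl) {
  vals <- cbind(ct_target_cond, ct_ref_cond, ct_target_ctrl, ct_ref_ctrl)
  if (anyNA(vals)) stop("missing Ct value")
  dd <- (ct_target_cond - ct_ref_cond) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-dd)
}
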