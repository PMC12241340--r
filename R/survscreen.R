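#' Median dichotomization
#'
#' Patients are split at the median of a feature's expression: `high` iff
#' value > median, ties at the median go to `low` (deterministic rule).
#' A constant vector cannot be split; the result is flagged degenerate and
#' such features are excluded from the screen.
#'
#' @param x Numeric vector, one value per patient (>= 2 patients).
#' @return Factor with levels `low`, `high` and attributes `n_low`,
#'   `n_high`, `degenerate`.
#' @export
median_split <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  med <- median(x)
  g <- factor(ifelse(x > med, "high", "low"), levels = c("low", "high"))
  structure(g, n_low = sum(g == "low"), n_high = sum(g == "high"),
            degenerate = length(unique(x)) == 1L)
}

#' Kaplan-Meier product-limit curve
#'
#' Wraps [survival::survfit()]: `S(t)` steps down by `(1 - d_i/n_i)` at each
#' event time; censored times reduce the risk set without a step.
#'
#' @param time Follow-up times (months).
#' @param event Event indicator, 0 = censored, 1 = event.
#' @return A `km_curve` data.frame: `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L,
            all(event %in% c(0, 1)), all(time >= 0))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Wraps [survival::survdiff()]: `chisq = (sum O - sum E)^2 / sum V` with the
#' hypergeometric variance at each event time; p from a chi-square with 1
#' degree of freedom. With no events at all the test is undefined and
#' `p = 1` is returned with a warning.
#'
#' @param time,event As in [km_curve()].
#' @param group Two-level grouping factor, both levels non-empty.
#' @return List with `chisq` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (nlevels(group) != 2L) stop("log-rank test needs exactly two groups")
  if (sum(event) == 0) {
    warning("no events; log-rank test undefined, returning p = 1")
    return(list(chisq = 0, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chisq = unname(sd$chisq), p = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Wraps [survival::coxph()] (partial likelihood, Newton-Raphson, Efron tie
#' handling). Returns the hazard ratio `exp(beta)` for `x` with Wald 95% CI
#' and p-value; optional covariates (e.g. age, grade, subtype) are added to
#' the linear predictor. Monotone likelihood (perfect separation) is
#' flagged and the HR reported as unbounded with a warning.
#'
#' @param time,event As in [km_curve()].
#' @param x The exposure: binary (high/low factor or 0/1) or continuous.
#' @param covariates Optional data.frame of adjustment covariates.
#' @return List with `hr`, `ci` (length-2), `p`, `beta`, `se`, `score_chisq`
#'   (score test at beta = 0, all coefficients), `unbounded` flag and the
#'   underlying `fit`.
#' @export
cox_fit <- function(time, event, x, covariates = NULL) {
  stopifnot(length(time) == length(event), length(time) == length(x))
  if (sum(event) < 1) stop("Cox fit needs at least one event")
  dat <- data.frame(time = time, event = event, x = x)
  form <- survival::Surv(time, event) ~ x
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(time))
    dat <- cbind(dat, covariates)
    form <- stats::as.formula(paste("survival::Surv(time, event) ~ x +",
                                    paste(names(covariates), collapse = " + ")))
  }
  fit <- suppressWarnings(survival::coxph(form, data = dat, ties = "efron"))
  beta <- unname(fit$coefficients[1])
  se <- sqrt(diag(fit$var))[1]
  unbounded <- !is.finite(beta) || abs(beta) > 15 || !is.finite(se) || se > 100
  if (unbounded) {
    warning("monotone partial likelihood (perfect separation); ",
            "HR reported as unbounded")
    hr <- if (beta > 0) Inf else 0
    return(list(hr = hr, ci = c(NA_real_, NA_real_), p = NA_real_,
                beta = beta, se = se,
                score_chisq = unname(fit$score), unbounded = TRUE, fit = fit))
  }
  z <- qnorm(0.975)
  list(hr = exp(beta), ci = exp(beta + c(-z, z) * se),
       p = 2 * pnorm(-abs(beta / se)),
       beta = beta, se = se, score_chisq = unname(fit$score),
       unbounded = FALSE, fit = fit)
}

#' Per-circRNA relapse-free-survival screen
#'
#' For every feature passing the expression filter: median dichotomization
#' of log2 expression, two-group log-rank test, and a univariate Cox fit on
#' the high-vs-low indicator (so the HR describes the same contrast the
#' Kaplan-Meier display shows). Classification: `worse` iff HR > 1 and
#' log-rank p < `p_cutoff`; `better` iff HR < 1 and log-rank p < `p_cutoff`;
#' otherwise `ns`. The raw log-rank p is the screening criterion; BH
#' q-values are reported alongside but not used for classification.
#' Follow-up is truncated at `truncate_months` (events beyond the cap are
#' censored at the cap) for the ten-year analysis.
#'
#' @param expr Numeric matrix of log2 expression, features x patients;
#'   column names must match `clinical$sample_id`.
#' @param clinical Data.frame with `sample_id`, `time_months`, `event`, and
#'   optionally `age`, `grade`, `subtype`.
#' @param p_cutoff Significance cutoff on the log-rank p (default 0.05).
#' @param min_expressed_frac A feature is "expressed" (and tested) iff its
#'   expression exceeds zero in at least this fraction of samples
#'   (default 0.25).
#' @param truncate_months Follow-up cap in months (default 120).
#' @param adjust Optional character vector of clinical columns to add to an
#'   adjusted Cox fit, reported as `hr_adj`/`p_adj` alongside.
#' @return A `survival_screen_table` data.frame with one row per feature:
#'   `feature`, `tested`, `n_low`, `n_high`, `hr`, `ci_lo`, `ci_hi`,
#'   `logrank_chisq`, `p`, `q`, `class`, `neg_log10_p` (volcano-ready), and
#'   adjusted columns when requested.
#' @export
survival_screen <- function(expr, clinical, p_cutoff = 0.05,
                            min_expressed_frac = 0.25,
                            truncate_months = 120, adjust = NULL) {
  expr <- as.matrix(expr)
  stopifnot(all(c("sample_id", "time_months", "event") %in% names(clinical)))
  orphans_e <- setdiff(colnames(expr), clinical$sample_id)
  orphans_c <- setdiff(clinical$sample_id, colnames(expr))
  if (length(orphans_e) || length(orphans_c))
    stop("sample id mismatch between expression and clinical table; ",
         "expression-only: [", paste(orphans_e, collapse = ", "),
         "]; clinical-only: [", paste(orphans_c, collapse = ", "), "]")
  clinical <- clinical[match(colnames(expr), clinical$sample_id), ]

  time <- pmin(clinical$time_months, truncate_months)
  event <- ifelse(clinical$time_months > truncate_months, 0L,
                  as.integer(clinical$event))

  covs <- NULL
  if (!is.null(adjust)) {
    missing_cols <- setdiff(adjust, names(clinical))
    if (length(missing_cols))
      stop("adjustment column(s) not in clinical table: ",
           paste(missing_cols, collapse = ", "))
    covs <- clinical[, adjust, drop = FALSE]
    covs[] <- lapply(covs, function(v) if (is.character(v)) factor(v) else v)
  }

  feats <- rownames(expr)
  if (is.null(feats)) feats <- sprintf("feat_%04d", seq_len(nrow(expr)))
  expressed <- rowMeans(expr > 0) >= min_expressed_frac

  n <- nrow(expr)
  res <- data.frame(feature = feats, tested = FALSE,
                    n_low = NA_integer_, n_high = NA_integer_,
                    hr = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                    logrank_chisq = NA_real_, p = NA_real_, q = NA_real_,
                    class = "untested", stringsAsFactors = FALSE)
  if (!is.null(adjust)) { res$hr_adj <- NA_real_; res$p_adj <- NA_real_ }

  for (i in seq_len(n)) {
    if (!expressed[i]) next
    g <- median_split(expr[i, ])
    if (attr(g, "degenerate")) { res$class[i] <- "degenerate"; next }
    res$n_low[i] <- attr(g, "n_low"); res$n_high[i] <- attr(g, "n_high")
    lr <- tryCatch(logrank_test(time, event, g),
                   warning = function(w) list(chisq = 0, p = 1))
    cx <- tryCatch(suppressWarnings(
                     cox_fit(time, event, as.integer(g == "high"))),
                   error = function(e) NULL)
    res$tested[i] <- TRUE
    res$logrank_chisq[i] <- lr$chisq; res$p[i] <- lr$p
    if (!is.null(cx)) {
      res$hr[i] <- cx$hr; res$ci_lo[i] <- cx$ci[1]; res$ci_hi[i] <- cx$ci[2]
      if (!is.null(covs)) {
        cxa <- tryCatch(suppressWarnings(
                 cox_fit(time, event, as.integer(g == "high"), covs)),
               error = function(e) NULL)
        if (!is.null(cxa)) { res$hr_adj[i] <- cxa$hr; res$p_adj[i] <- cxa$p }
      }
    }
    res$class[i] <-
      if (is.null(cx) || !is.finite(cx$hr)) "ns"
      else if (cx$hr > 1 && lr$p < p_cutoff) "worse"
      else if (cx$hr < 1 && lr$p < p_cutoff) "better"
      else "ns"
  }
  res$q[res$tested] <- bh_adjust(res$p[res$tested])
  res$neg_log10_p <- -log10(res$p)
  class(res) <- c("survival_screen_table", "data.frame")
  res
}
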