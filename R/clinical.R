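#' Two-sample t-test from printed summary statistics
#'
#' Recomputes a two-sided independent-samples t-test from group means,
#' standard deviations and sizes, as printed in a cohort table.  Pooled
#' mode uses the equal-variance statistic with `df = n1 + n2 - 2`; Welch
#' mode uses the Satterthwaite approximation.
#'
#' @param mean1,sd1,n1 First group summary (e.g. controls).
#' @param mean2,sd2,n2 Second group summary (e.g. cases).
#' @param mode `"pooled"` (default) or `"welch"`.
#' @return List with `t`, `df`, `p`.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               mode = c("pooled", "welch")) {
  mode <- match.arg(mode)
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) {
      return(list(t = 0, df = n1 + n2 - 2, p = 1))
    }
    return(list(t = Inf * sign(mean1 - mean2), df = n1 + n2 - 2, p = 0))
  }
  if (mode == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tstat <- (mean1 - mean2) / se
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

#' Feature-by-trait correlation table
#'
#' Correlates each feature column (e.g. promoter methylation level,
#' miRNA expression) against each clinical trait column over subjects,
#' using [correlate()] with pairwise-complete observations.  Cells with
#' fewer than 3 complete pairs or a constant vector are returned as `NA`
#' (constant traits raise a warning and the run continues).
#'
#' @param features Data frame or matrix, subjects x features.
#' @param traits Data frame, subjects x traits, same row order as
#'   `features`.
#' @param method Passed to [correlate()].
#' @return Long data frame: `feature`, `trait`, `r`, `p_value`, `n`.
#' @export
trait_correlations <- function(features, traits,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  features <- as.data.frame(features)
  traits <- as.data.frame(traits)
  traits <- traits[vapply(traits, is.numeric, logical(1))]
  if (nrow(features) != nrow(traits)) {
    stop("features and traits must cover the same subjects",
         call. = FALSE)
  }
  rows <- list()
  for (f in names(features)) {
    for (tr in names(traits)) {
      x <- features[[f]]
      y <- traits[[tr]]
      cc <- complete.cases(x, y)
      r <- NA_real_; p <- NA_real_; n <- sum(cc)
      if (n >= 3) {
        if (sd(y[cc]) == 0) {
          warning("constant trait '", tr, "': correlation unavailable",
                  call. = FALSE)
        } else if (sd(x[cc]) > 0) {
          ct <- correlate(x[cc], y[cc], method = method)
          r <- ct$r; p <- ct$p
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, trait = tr, r = r, p_value = p, n = n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt transform
#'
#' `2^-((ct_target_case - ct_ref_case) - (ct_target_ctrl -
#' ct_ref_ctrl))`: the case-vs-control expression of a target gene
#' normalized to a reference gene from qRT-PCR cycle thresholds.
#'
#' @param ct_target_case,ct_ref_case,ct_target_ctrl,ct_ref_ctrl Finite
#'   CT values (vectorized).
#' @return Relative expression (1 = no change).
#' @export
ddct <- function(ct_target_case, ct_ref_case, ct_target_ctrl,
                 ct_ref_ctrl) {
  args <- list(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (!all(vapply(args, function(a) all(is.finite(a)), logical(1)))) {
    stop("CT values must be finite", call. = FALSE)
  }
  ddct_val <- (ct_target_case - ct_ref_case) -
    (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct_val)
}
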