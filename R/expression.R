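#' Reads-per-million normalization
#'
#' Scales each sample (column) so values are reads per million mapped
#' reads: `raw * 1e6 / column_total`.  Every column of the result sums to
#' exactly one million (up to floating point).
#'
#' @param counts Nonnegative feature x sample count matrix.
#' @return Numeric matrix of RPM values with the input dimnames.
#' @export
rpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    if (is.null(bad)) bad <- which(totals == 0)
    stop("cannot RPM-normalize sample(s) with zero total counts: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sweep(counts, 2, totals, "/") * 1e6
}

#' Reads-per-kilobase-per-million normalization
#'
#' Depth- and length-normalized expression:
#' `raw * 1e9 / (column_total * exon_length_bp)`.
#'
#' @param counts Nonnegative feature x sample count matrix.
#' @param exon_length_bp Positive exon length (bp) per feature, recycled
#'   against `rownames(counts)`; may be a named vector.
#' @return Numeric matrix of RPKM values.
#' @export
rpkm_normalize <- function(counts, exon_length_bp) {
  counts <- as.matrix(counts)
  if (!is.null(names(exon_length_bp)) && !is.null(rownames(counts))) {
    exon_length_bp <- exon_length_bp[rownames(counts)]
  }
  if (length(exon_length_bp) != nrow(counts) || anyNA(exon_length_bp)) {
    missing <- if (!is.null(rownames(counts))) {
      rownames(counts)[is.na(exon_length_bp)]
    } else "<unnamed features>"
    stop("exon_length_bp missing for feature(s): ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (any(exon_length_bp <= 0)) {
    stop("exon_length_bp must be positive", call. = FALSE)
  }
  rpm <- rpm_normalize(counts)
  sweep(rpm, 1, exon_length_bp / 1e3, "/")
}

#' Benjamini-Hochberg Q values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_i = min over p_(j) >= p_(i) of p_(j) * n / rank_j`, capped at 1 and
#' returned in the input order.
#'
#' @param p Vector of p-values in \[0,1\].
#' @return Q values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0,1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Threshold presets for differential screening
#'
#' The miRNA preset requires `|log2FC| >= 1`, p < 0.05 and Q <= 0.05 (the
#' Q criterion as applied at network construction); `"mirna_loose"` drops
#' the Q criterion (first-stage screen).  The mRNA preset requires
#' p < 0.05 and Q <= 0.05 with no fold-change floor.
#'
#' @param preset One of `"mirna"`, `"mirna_loose"`, `"mrna"`.
#' @return List with `lfc_min`, `p_max`, `q_max`.
#' @export
de_presets <- function(preset = c("mirna", "mirna_loose", "mrna")) {
  switch(match.arg(preset),
         mirna = list(lfc_min = 1, p_max = 0.05, q_max = 0.05),
         mirna_loose = list(lfc_min = 1, p_max = 0.05, q_max = 1),
         mrna = list(lfc_min = 0, p_max = 0.05, q_max = 0.05))
}

#' Differential expression screen on a normalized matrix
#'
#' Per feature: group means of the normalized values,
#' `log2FC = log2((mean_case + pc) / (mean_control + pc))`, a two-sided
#' Welch t-test on `log2(value + pc)`, and BH Q values across all tested
#' features.  Features with all-zero values in both groups are excluded
#' before testing; features with zero variance in both groups get p = 1
#' by convention.  A feature is `up`/`down` when `|log2FC| >= lfc_min`,
#' `p < p_max` and `q <= q_max`, and `ns` otherwise.
#'
#' @param norm Normalized feature x sample matrix (RPM or RPKM).
#' @param groups Character vector (`"case"` / `"control"`) parallel to
#'   the columns; each group needs >= 2 samples.
#' @param lfc_min,p_max,q_max Screening thresholds (see [de_presets()]).
#' @param pseudocount Added before logs and ratios; default 1.
#' @return Data frame: `feature_id`, `mean_case`, `mean_control`,
#'   `log2fc`, `p_value`, `q_value`, `status`.
#' @export
de_screen <- function(norm, groups, lfc_min = 1, p_max = 0.05,
                      q_max = 0.05, pseudocount = 1) {
  norm <- as.matrix(norm)
  if (length(groups) != ncol(norm)) {
    stop("groups must match the matrix columns", call. = FALSE)
  }
  if (!all(groups %in% c("case", "control"))) {
    stop("groups must be 'case' or 'control'", call. = FALSE)
  }
  n1 <- sum(groups == "case")
  n2 <- sum(groups == "control")
  if (n1 < 2 || n2 < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  if (is.null(rownames(norm))) {
    rownames(norm) <- sprintf("feature_%d", seq_len(nrow(norm)))
  }

  all_zero <- rowSums(norm != 0) == 0
  if (any(all_zero)) {
    message(sum(all_zero), " feature(s) with all-zero values excluded")
    norm <- norm[!all_zero, , drop = FALSE]
  }
  if (nrow(norm) == 0) {
    return(data.frame(feature_id = character(0), mean_case = numeric(0),
                      mean_control = numeric(0), log2fc = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      status = character(0), stringsAsFactors = FALSE))
  }

  xc <- norm[, groups == "case", drop = FALSE]
  xk <- norm[, groups == "control", drop = FALSE]
  mean_case <- rowMeans(xc)
  mean_control <- rowMeans(xk)
  log2fc <- log2((mean_case + pseudocount) / (mean_control + pseudocount))

  lc <- log2(xc + pseudocount)
  lk <- log2(xk + pseudocount)
  m1 <- rowMeans(lc); m2 <- rowMeans(lk)
  v1 <- apply(lc, 1, var); v2 <- apply(lk, 1, var)

  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- v1 == 0 & v2 == 0
  if (any(degenerate)) {
    message(sum(degenerate),
            " feature(s) with zero variance in both groups: p set to 1")
    p[degenerate] <- 1
  }
  q <- bh_adjust(p)

  sig <- abs(log2fc) >= lfc_min & p < p_max & q <= q_max
  status <- ifelse(sig & log2fc > 0, "up",
                   ifelse(sig & log2fc < 0, "down", "ns"))
  data.frame(feature_id = rownames(norm), mean_case = mean_case,
             mean_control = mean_control, log2fc = log2fc,
             p_value = p, q_value = q, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}
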