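#' Per-sample CpG count table
#'
#' Bundles CpG site coordinates with per-sample methylated (`m`) and
#' unmethylated (`u`) read-count matrices and the sample sheet.  Sites are
#' sorted within chromosome; positions are 0-based.
#'
#' @param sites Data frame with columns `chrom`, `pos` (0-based integer)
#'   and `strand`.
#' @param m,u Integer matrices, sites x samples, of methylated and
#'   unmethylated read counts.
#' @param samples Data frame with columns `sample_id` and `group`
#'   (values `"case"` / `"control"`).
#' @return A `cpg_site_table` list with elements `sites`, `m`, `u`,
#'   `samples`.
#' @export
cpg_site_table <- function(sites, m, u, samples) {
  m <- as.matrix(m)
  u <- as.matrix(u)
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "strand") %in% names(sites)),
            nrow(m) == nrow(sites), nrow(u) == nrow(sites),
            ncol(m) == nrow(samples), ncol(u) == nrow(samples),
            all(c("sample_id", "group") %in% names(samples)))
  if (any(m < 0) || any(u < 0)) {
    stop("negative counts in CpG table", call. = FALSE)
  }
  if (!all(samples$group %in% c("case", "control"))) {
    stop("sample groups must be 'case' or 'control'", call. = FALSE)
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  m <- m[ord, , drop = FALSE]
  u <- u[ord, , drop = FALSE]
  colnames(m) <- colnames(u) <- samples$sample_id
  structure(list(sites = sites, m = m, u = u, samples = samples),
            class = "cpg_site_table")
}

#' Methylation level of a site
#'
#' The fraction of methylated reads, `m / (m + u)`.
#'
#' @param m_count,u_count Nonnegative count vectors.
#' @return Numeric vector of levels in \[0,1\].
#' @export
methylation_level <- function(m_count, u_count) {
  if (any(m_count < 0) || any(u_count < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  cov <- m_count + u_count
  if (any(cov == 0)) {
    stop("methylation level undefined at zero coverage", call. = FALSE)
  }
  m_count / cov
}

#' Call methylated cytosine sites with an exact binomial test
#'
#' Tests each site's methylated count against the null that methylated
#' reads arise only from bisulfite non-conversion/sequencing error at rate
#' `p0`.  The p-value is the exact upper tail
#' P(X >= m | n = m + u, p0).  A site is called methylated when its
#' coverage reaches `depth_min` and p <= `p_max`; sites below the depth
#' floor are never called regardless of p.
#'
#' @param m_count,u_count Methylated / unmethylated read counts
#'   (vectorized).
#' @param p0 Null methylation proportion in (0,1); the bisulfite error
#'   rate.
#' @param depth_min Minimum coverage for a site to be callable.
#' @param p_max Significance threshold.
#' @return Data frame with columns `m`, `u`, `coverage`, `level`,
#'   `p_value`, `is_called`.
#' @export
call_site <- function(m_count, u_count, p0 = 0.005, depth_min = 5,
                      p_max = 0.05) {
  if (length(p0) != 1 || !is.finite(p0) || p0 <= 0 || p0 >= 1) {
    stop("p0 must be a single value in (0,1)", call. = FALSE)
  }
  if (any(m_count < 0) || any(u_count < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  cov <- m_count + u_count
  p <- pbinom(m_count - 1, cov, p0, lower.tail = FALSE)
  level <- ifelse(cov > 0, m_count / cov, NA_real_)
  data.frame(m = m_count, u = u_count, coverage = cov, level = level,
             p_value = p,
             is_called = cov >= depth_min & p <= p_max)
}

#' Classify a DMR as hyper- or hypomethylated in cases
#'
#' @param mean_diff Case mean level minus control mean level (vectorized).
#' @return Character vector `"hyper"` / `"hypo"`; exact ties yield `NA`
#'   with a warning (such regions are dropped by [detect_dmrs()]).
#' @export
classify_dmr <- function(mean_diff) {
  out <- ifelse(mean_diff > 0, "hyper",
                ifelse(mean_diff < 0, "hypo", NA_character_))
  if (anyNA(out)) {
    warning("dropping region(s) with zero case-control difference",
            call. = FALSE)
  }
  out
}

#' Detect differentially methylated regions with a sliding window
#'
#' Slides windows of `window_bp` advanced by `step_bp` over every
#' chromosome carrying CpGs.  A window is testable when it holds at least
#' `min_cpgs` sites passing the coverage rule in both groups.  The default
#' engine pools (m, u) counts within group over the window's qualifying
#' sites and tests the 2x2 table case-vs-control with Fisher's exact test;
#' `test = "level_t"` instead applies a Welch t-test to per-sample
#' coverage-weighted window levels.  P-values are BH-adjusted across all
#' testable windows; windows passing `p_max`, `q_max` and
#' `|mean_diff| >= min_mean_diff` are merged when they overlap (keeping
#' the minimum window p), and each merged region's effect and CpG count
#' are recomputed over its full span.
#'
#' @param cpg A [cpg_site_table()] holding both groups.
#' @param window_bp,step_bp Window width and step in bp.
#' @param min_cpgs Minimum qualifying CpGs for a window to be testable
#'   (must be >= 1).
#' @param min_mean_diff Minimum absolute case-control level difference.
#' @param p_max,q_max Significance thresholds on the window p and BH q.
#' @param depth_min Coverage floor defining a qualifying site.
#' @param coverage_rule `"pooled"`: group coverage summed over samples
#'   must reach `depth_min`; `"per_sample"`: every sample individually
#'   must.
#' @param test `"fisher"` (pooled-count exact test, default) or
#'   `"level_t"` (per-sample Welch t on window levels).
#' @return Data frame of disjoint, sorted DMRs: `chrom`, `start`, `end`
#'   (0-based half-open), `n_cpgs`, `mean_diff`, `p_value`, `q_value`,
#'   `direction`.
#' @export
detect_dmrs <- function(cpg, window_bp = 1000, step_bp = 100,
                        min_cpgs = 3, min_mean_diff = 0.1,
                        p_max = 0.05, q_max = 0.05, depth_min = 5,
                        coverage_rule = c("pooled", "per_sample"),
                        test = c("fisher", "level_t")) {
  stopifnot(inherits(cpg, "cpg_site_table"))
  coverage_rule <- match.arg(coverage_rule)
  test <- match.arg(test)
  if (min_cpgs < 1) stop("min_cpgs must be >= 1", call. = FALSE)

  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_cpgs = integer(0),
                      mean_diff = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(cpg$sites) == 0) return(empty)

  case_cols <- cpg$samples$group == "case"
  ctrl_cols <- !case_cols
  if (!any(case_cols) || !any(ctrl_cols)) {
    stop("need at least one sample per group", call. = FALSE)
  }
  m_case <- rowSums(cpg$m[, case_cols, drop = FALSE])
  u_case <- rowSums(cpg$u[, case_cols, drop = FALSE])
  m_ctrl <- rowSums(cpg$m[, ctrl_cols, drop = FALSE])
  u_ctrl <- rowSums(cpg$u[, ctrl_cols, drop = FALSE])

  cov_all <- cpg$m + cpg$u
  if (coverage_rule == "pooled") {
    qualifies <- (m_case + u_case) >= depth_min &
      (m_ctrl + u_ctrl) >= depth_min
  } else {
    qualifies <- rowSums(cov_all < depth_min) == 0
  }
  if (!any(qualifies)) return(empty)

  sites <- cpg$sites[qualifies, , drop = FALSE]
  m_case <- m_case[qualifies]; u_case <- u_case[qualifies]
  m_ctrl <- m_ctrl[qualifies]; u_ctrl <- u_ctrl[qualifies]
  m_mat <- cpg$m[qualifies, , drop = FALSE]
  cov_mat <- cov_all[qualifies, , drop = FALSE]

  ## candidate windows: only step-aligned windows containing >= 1 site
  win_first <- ceiling((sites$pos - window_bp + 1) / step_bp)
  win_last <- floor(sites$pos / step_bp)
  win_first <- pmax(win_first, 0L)
  keys <- unique(unlist(mapply(function(a, b, chrom) {
    paste(chrom, seq.int(a, b), sep = ":")
  }, win_first, win_last, sites$chrom, SIMPLIFY = FALSE)))
  parts <- strsplit(keys, ":", fixed = TRUE)
  win_chrom <- vapply(parts, `[`, character(1), 1L)
  win_start <- as.integer(vapply(parts, `[`, character(1), 2L)) * step_bp

  win_gr <- GenomicRanges::GRanges(
    win_chrom, IRanges::IRanges(start = win_start + 1L,
                                width = window_bp))
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(start = sites$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(win_gr, site_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)

  n_in_win <- tabulate(qh, nbins = length(win_gr))
  testable <- which(n_in_win >= min_cpgs)
  if (length(testable) == 0) return(empty)

  sum_by_win <- function(x) {
    as.vector(rowsum(x[sh], qh, reorder = FALSE))[
      match(testable, unique(qh))]
  }
  wm_case <- sum_by_win(m_case)
  wu_case <- sum_by_win(u_case)
  wm_ctrl <- sum_by_win(m_ctrl)
  wu_ctrl <- sum_by_win(u_ctrl)

  mean_diff <- wm_case / (wm_case + wu_case) -
    wm_ctrl / (wm_ctrl + wu_ctrl)

  if (test == "fisher") {
    pvals <- mapply(function(a, b, c, d) {
      fisher.test(matrix(c(a, b, c, d), nrow = 2))$p.value
    }, wm_case, wu_case, wm_ctrl, wu_ctrl)
  } else {
    site_sets <- split(sh, qh)[as.character(testable)]
    pvals <- vapply(site_sets, function(idx) {
      lev <- colSums(m_mat[idx, , drop = FALSE]) /
        colSums(cov_mat[idx, , drop = FALSE])
      x <- lev[case_cols]; y <- lev[ctrl_cols]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (length(x) < 2 || length(y) < 2) return(NA_real_)
      if (var(x) == 0 && var(y) == 0) {
        return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
      }
      t.test(x, y)$p.value
    }, numeric(1))
  }
  qvals <- p.adjust(pvals, method = "BH")

  sig <- !is.na(pvals) & pvals <= p_max & qvals <= q_max &
    abs(mean_diff) >= min_mean_diff & mean_diff != 0
  if (!any(sig)) return(empty)

  sig_gr <- win_gr[testable[sig]]
  merged <- GenomicRanges::reduce(sig_gr)
  back <- GenomicRanges::findOverlaps(merged, sig_gr)
  bqh <- S4Vectors::queryHits(back)
  bsh <- S4Vectors::subjectHits(back)
  p_sig <- pvals[sig]
  q_sig <- qvals[sig]
  min_p <- t(vapply(seq_along(merged), function(i) {
    jj <- bsh[bqh == i]
    j <- jj[which.min(p_sig[jj])]
    c(p = p_sig[j], q = q_sig[j])
  }, numeric(2)))

  site_in <- GenomicRanges::findOverlaps(merged, site_gr)
  qh2 <- S4Vectors::queryHits(site_in)
  sh2 <- S4Vectors::subjectHits(site_in)
  reg_stats <- t(vapply(seq_along(merged), function(i) {
    idx <- sh2[qh2 == i]
    mc <- sum(m_case[idx]); uc <- sum(u_case[idx])
    mk <- sum(m_ctrl[idx]); uk <- sum(u_ctrl[idx])
    c(n = length(idx), diff = mc / (mc + uc) - mk / (mk + uk))
  }, numeric(2)))

  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    n_cpgs = as.integer(reg_stats[, "n"]),
    mean_diff = reg_stats[, "diff"],
    p_value = min_p[, "p"],
    q_value = min_p[, "q"],
    stringsAsFactors = FALSE)
  # a merged span can dilute the effect of its significant windows; the
  # output contract is that every reported DMR meets the thresholds
  out <- out[abs(out$mean_diff) >= min_mean_diff, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  out$direction <- classify_dmr(out$mean_diff)
  out <- out[!is.na(out$direction), , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write DMRs as BED6+ and read them back
#'
#' BED columns: chrom, start, end, name, score (`-log10 p`, capped at
#' 1000), strand (`.`), then `mean_diff`, `q_value`, `n_cpgs`,
#' `direction`.
#'
#' @param dmrs DMR data frame from [detect_dmrs()].
#' @param path Output file.
#' @return `write_dmrs`: invisibly, the path.  `read_dmrs`: the DMR data
#'   frame.
#' @export
write_dmrs <- function(dmrs, path) {
  score <- ifelse(dmrs$p_value > 0, pmin(-log10(dmrs$p_value), 1000), 1000)
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
                    name = sprintf("dmr_%d", seq_len(nrow(dmrs))),
                    score = round(score, 3), strand = ".",
                    mean_diff = dmrs$mean_diff, q_value = dmrs$q_value,
                    n_cpgs = dmrs$n_cpgs, direction = dmrs$direction)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dmrs
#' @export
read_dmrs <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "mean_diff", "q_value", "n_cpgs", "direction")
  if (file.size(path) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_cpgs = integer(0),
                      mean_diff = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), direction = character(0))
    return(out)
  }
  bed <- read.delim(path, header = FALSE, col.names = cols,
                    stringsAsFactors = FALSE)
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             n_cpgs = bed$n_cpgs, mean_diff = bed$mean_diff,
             p_value = 10^(-bed$score), q_value = bed$q_value,
             direction = bed$direction, stringsAsFactors = FALSE)
}
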