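# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and, where possible, the
# library routines) they are checking.

# upper-tail binomial probability P(X >= m | n, p) by direct pmf summation
oracle_binom_tail <- function(m, n, p) {
  if (m <= 0) return(1)
  k <- m:n
  sum(choose(n, k) * p^k * (1 - p)^(n - k))
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
# (sum of all table probabilities not exceeding the observed one)
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- r1 + r2
  k <- max(0, c1 - r2):min(r1, c1)
  # log probabilities for numerical stability at pooled-count scale
  logp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  obs <- logp[k == a]
  sum(exp(logp[logp <= obs + 1e-7]))
}

# per-base membership scan for half-open interval overlap
oracle_overlap_pairs <- function(dmrs, promoters) {
  out <- list()
  for (i in seq_len(nrow(dmrs))) {
    bases_i <- seq.int(dmrs$start[i], dmrs$end[i] - 1L)
    for (j in seq_len(nrow(promoters))) {
      if (dmrs$chrom[i] != promoters$chrom[j]) next
      bases_j <- seq.int(promoters$start[j], promoters$end[j] - 1L)
      if (length(intersect(bases_i, bases_j)) >= 1L) {
        out[[length(out) + 1L]] <- data.frame(
          dmr_idx = i, mirna_id = promoters$mirna_id[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(dmr_idx = integer(0), mirna_id = character(0)))
  }
  unique(do.call(rbind, out))
}

# naive sliding scan counting (overlapping) occurrences of `site` in `utr`
oracle_count_sites <- function(site, utr) {
  n <- 0L
  w <- nchar(site)
  for (i in seq_len(nchar(utr) - w + 1L)) {
    if (substr(utr, i, i + w - 1L) == site) n <- n + 1L
  }
  n
}

# reverse complement of a DNA string without Biostrings
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# random interval set on a toy genome
random_intervals <- function(n, chroms = c("chr1", "chr2"), len = 10000L,
                             max_width = 400L) {
  start <- sample.int(len - max_width, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_width, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# small, fast synthetic cohort for end-to-end tests
tiny_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_chroms = 2, chrom_length_bp = 200000L,
               n_mirnas = 20, n_mrnas = 60, n_cpg_per_promoter = 8,
               n_triplets = 2, coverage_mean = 50)
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}
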