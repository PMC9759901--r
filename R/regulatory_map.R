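#' Strand-aware promoter interval upstream of a TSS
#'
#' For a plus-strand locus the promoter is
#' `[max(0, tss - upstream_bp), tss)`; for a minus-strand locus it is the
#' mirror window on the forward axis, `[tss, min(chrom_len, tss +
#' upstream_bp))`.  Coordinates are 0-based half-open.  Windows clipped to
#' zero width (a TSS at the chromosome edge) are rejected.
#'
#' @param tss 0-based TSS position(s).
#' @param strand `"+"` or `"-"` per locus.
#' @param chrom Chromosome name per locus.
#' @param chrom_len Chromosome length per locus.
#' @param upstream_bp Promoter length upstream of the TSS (default
#'   2000 bp).
#' @return Data frame `chrom`, `start`, `end`, `strand`.
#' @export
promoter_region <- function(tss, strand, chrom, chrom_len,
                            upstream_bp = 2000) {
  if (any(tss < 0 | tss > chrom_len)) {
    stop("TSS outside chromosome bounds", call. = FALSE)
  }
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  start <- ifelse(strand == "+", pmax(0, tss - upstream_bp), tss)
  end <- ifelse(strand == "+", tss, pmin(chrom_len, tss + upstream_bp))
  if (any(start >= end)) {
    stop("empty promoter window at TSS ",
         paste(tss[start >= end], collapse = ", "), call. = FALSE)
  }
  data.frame(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

#' Match DMRs to miRNA promoters by interval overlap
#'
#' Emits a (DMR, miRNA) pair whenever the DMR interval and the promoter
#' interval intersect by at least 1 bp under 0-based half-open semantics;
#' each pair is emitted at most once.
#'
#' @param dmrs Data frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [detect_dmrs()].
#' @param promoters Data frame with `chrom`, `start`, `end`, `mirna_id`.
#' @return Data frame `dmr_idx` (row index into `dmrs`), `dmr_id`
#'   (`chrom:start-end`), `mirna_id`.
#' @export
overlap_dmr_promoters <- function(dmrs, promoters) {
  empty <- data.frame(dmr_idx = integer(0), dmr_id = character(0),
                      mirna_id = character(0), stringsAsFactors = FALSE)
  if (nrow(dmrs) == 0 || nrow(promoters) == 0) return(empty)
  lv <- union(dmrs$chrom, promoters$chrom)
  dmr_gr <- GenomicRanges::GRanges(
    factor(dmrs$chrom, lv), IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  prom_gr <- GenomicRanges::GRanges(
    factor(promoters$chrom, lv),
    IRanges::IRanges(promoters$start + 1L, promoters$end))
  hits <- GenomicRanges::findOverlaps(dmr_gr, prom_gr)
  if (length(hits) == 0) return(empty)
  out <- data.frame(
    dmr_idx = S4Vectors::queryHits(hits),
    dmr_id = sprintf("%s:%d-%d", dmrs$chrom[S4Vectors::queryHits(hits)],
                     dmrs$start[S4Vectors::queryHits(hits)],
                     dmrs$end[S4Vectors::queryHits(hits)]),
    mirna_id = promoters$mirna_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  unique(out)
}

# canonical seed-match site (5'->3' on the UTR) for a miRNA sequence;
# DNA alphabet
.seed_site <- function(mirna_seq, seed_type) {
  s <- chartr("Uu", "Tt", toupper(mirna_seq))
  rc <- function(from, to) {
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(s, from, to))))
  }
  switch(seed_type,
         "7mer-m8" = rc(2, 8),
         "8mer" = paste0(rc(2, 8), "A"),
         "7mer-A1" = paste0(rc(2, 7), "A"),
         stop("unknown seed_type: ", seed_type, call. = FALSE))
}

#' Predict miRNA targets by exact seed match
#'
#' A pair (miRNA, mRNA) is emitted when the canonical seed site occurs at
#' least once in the mRNA 3'UTR; `n_sites` counts all occurrences,
#' overlapping ones included.  For the default `7mer-m8` seed the site is
#' the reverse complement of miRNA positions 2-8 (1-based from the 5'
#' end); `8mer` appends an A opposite position 1 and `7mer-A1` pairs
#' positions 2-7 plus that A.  U and T are interchangeable.
#'
#' @param mirna_seqs Named character vector of miRNA sequences (>= 8 nt).
#' @param utr_seqs Named character vector of 3'UTR sequences.
#' @param seed_type `"7mer-m8"` (default), `"8mer"` or `"7mer-A1"`.
#' @return Data frame `mirna_id`, `mrna_id`, `n_sites`,
#'   `source = "seed_match"`.
#' @export
predict_targets <- function(mirna_seqs, utr_seqs,
                            seed_type = c("7mer-m8", "8mer", "7mer-A1")) {
  seed_type <- match.arg(seed_type)
  empty <- data.frame(mirna_id = character(0), mrna_id = character(0),
                      n_sites = integer(0), source = character(0),
                      stringsAsFactors = FALSE)
  if (length(mirna_seqs) == 0 || length(utr_seqs) == 0) return(empty)
  short <- nchar(mirna_seqs) < 8
  if (any(short)) {
    stop("miRNA sequence(s) shorter than 8 nt: ",
         paste(names(mirna_seqs)[short], collapse = ", "), call. = FALSE)
  }
  check_alpha <- function(x, what) {
    bad <- grepl("[^ACGUTacgut]", x)
    if (any(bad)) {
      stop("non-ACGU/T characters in ", what, ": ",
           paste(names(x)[bad], collapse = ", "), call. = FALSE)
    }
  }
  check_alpha(mirna_seqs, "miRNA sequence(s)")
  check_alpha(utr_seqs, "UTR sequence(s)")

  utrs <- Biostrings::DNAStringSet(chartr("Uu", "Tt", toupper(utr_seqs)))
  res <- lapply(names(mirna_seqs), function(id) {
    site <- .seed_site(mirna_seqs[[id]], seed_type)
    n <- Biostrings::vcountPattern(site, utrs)
    hit <- n >= 1
    if (!any(hit)) return(NULL)
    data.frame(mirna_id = id, mrna_id = names(utr_seqs)[hit],
               n_sites = n[hit], source = "seed_match",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}

#' Load an externally computed miRNA-target pair table
#'
#' Reads a TSV with columns `mirna_id` and `mrna_id` (extra columns are
#' ignored), deduplicates, and tags the pairs as `external`.
#'
#' @param path TSV file with a header line.
#' @return Data frame `mirna_id`, `mrna_id`, `n_sites = NA`,
#'   `source = "external"`.
#' @export
load_target_map <- function(path) {
  df <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e),
                                          call. = FALSE))
  if (!all(c("mirna_id", "mrna_id") %in% names(df))) {
    stop("target map needs columns mirna_id and mrna_id", call. = FALSE)
  }
  bad <- which(is.na(df$mirna_id) | is.na(df$mrna_id) |
                 df$mirna_id == "" | df$mrna_id == "")
  if (length(bad)) {
    stop("malformed target-map row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  out <- unique(df[, c("mirna_id", "mrna_id"), drop = FALSE])
  rownames(out) <- NULL
  out$n_sites <- rep(NA_integer_, nrow(out))
  out$source <- rep("external", nrow(out))
  out
}
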