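#' Pearson or Spearman correlation with a t-transform p-value
#'
#' Pearson r from the closed-form definition with the two-sided p from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom;
#' Spearman ranks both vectors first (average ranks on ties) and applies
#' the same transform.  Zero variance in either vector yields `r = NA`
#' (an undefined-correlation signal; [build_network()] skips and counts
#' such edges).
#'
#' @param x,y Paired numeric vectors, length >= 3, finite.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `p`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  n <- length(x)
  sx <- sd(x)
  sy <- sd(y)
  if (sx == 0 || sy == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- min(1, max(-1, r))
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Per-sample methylation level of each DMR
#'
#' Coverage-weighted mean level over the CpGs inside each region:
#' `sum(m) / sum(m + u)` per sample.  Samples with zero coverage in a
#' region get `NA`.
#'
#' @param dmrs Data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param cpg A [cpg_site_table()].
#' @return Numeric matrix, regions x samples.
#' @export
dmr_methylation_levels <- function(dmrs, cpg) {
  stopifnot(inherits(cpg, "cpg_site_table"))
  n_s <- nrow(cpg$samples)
  out <- matrix(NA_real_, nrow(dmrs), n_s,
                dimnames = list(NULL, cpg$samples$sample_id))
  if (nrow(dmrs) == 0 || nrow(cpg$sites) == 0) return(out)
  lv <- union(dmrs$chrom, cpg$sites$chrom)
  dmr_gr <- GenomicRanges::GRanges(
    factor(dmrs$chrom, lv),
    IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  site_gr <- GenomicRanges::GRanges(
    factor(cpg$sites$chrom, lv),
    IRanges::IRanges(cpg$sites$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(dmr_gr, site_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  for (i in unique(qh)) {
    idx <- sh[qh == i]
    m <- colSums(cpg$m[idx, , drop = FALSE])
    cov <- m + colSums(cpg$u[idx, , drop = FALSE])
    out[i, ] <- ifelse(cov > 0, m / cov, NA_real_)
  }
  out
}

#' Assemble the DMR-miRNA-mRNA regulatory network
#'
#' Candidate methylation->miRNA edges are promoter-overlap pairs whose
#' DMR passed screening and whose miRNA is differentially expressed;
#' candidate miRNA->mRNA edges are target pairs with both features
#' differentially expressed.  Each candidate is scored by [correlate()]
#' on per-sample values (DMR coverage-weighted methylation level vs miRNA
#' RPM; miRNA RPM vs mRNA RPKM) and retained when `p <= edge_p_max` and
#' `|r| >= r_min`; strict mode additionally requires `r < 0` on both edge
#' kinds and sign-consistent endpoints (hypo promoter with up miRNA,
#' hyper with down; miRNA and target mRNA with opposite statuses),
#' matching a hypomethylation-activates / miRNA-represses chain.
#' Triplets are DMR-miRNA-mRNA chains sharing a retained miRNA; nodes are
#' features with at least one retained edge.
#'
#' @param dmrs Screened DMR data frame ([detect_dmrs()]).
#' @param de_mirna,de_mrna Differential tables ([de_screen()]).
#' @param promoter_pairs Output of [overlap_dmr_promoters()].
#' @param target_pairs Output of [predict_targets()] or
#'   [load_target_map()].
#' @param cpg [cpg_site_table()] used to summarize DMR methylation.
#' @param mirna_norm,mrna_norm Normalized expression matrices whose
#'   columns align with `cpg`'s samples.
#' @param r_min Minimum absolute correlation for retention.
#' @param edge_p_max Maximum correlation p-value for retention.
#' @param mode `"strict"` (sign-constrained, default) or `"permissive"`.
#' @param method Correlation method, passed to [correlate()].
#' @return A `regulatory_network` list: `nodes` (id, type, direction),
#'   `edges` (all scored candidates with a `retained` flag), `triplets`,
#'   `mode`, `thresholds`, and `n_skipped` (candidates with undefined
#'   correlation).
#' @export
build_network <- function(dmrs, de_mirna, de_mrna, promoter_pairs,
                          target_pairs, cpg, mirna_norm, mrna_norm,
                          r_min = 0.7, edge_p_max = 0.05,
                          mode = c("strict", "permissive"),
                          method = "pearson") {
  mode <- match.arg(mode)
  sample_ids <- cpg$samples$sample_id
  if (!identical(colnames(mirna_norm), sample_ids) ||
      !identical(colnames(mrna_norm), sample_ids)) {
    stop("sample columns of the matrices do not align", call. = FALSE)
  }

  dmr_id <- if (nrow(dmrs)) {
    sprintf("%s:%d-%d", dmrs$chrom, dmrs$start, dmrs$end)
  } else character(0)
  meth_levels <- dmr_methylation_levels(dmrs, cpg)

  mirna_status <- setNames(de_mirna$status, de_mirna$feature_id)
  mrna_status <- setNames(de_mrna$status, de_mrna$feature_id)

  edge_cols <- c("kind", "from", "to", "from_direction", "to_direction",
                 "r", "p_value", "retained")
  empty_edges <- data.frame(kind = character(0), from = character(0),
                            to = character(0),
                            from_direction = character(0),
                            to_direction = character(0), r = numeric(0),
                            p_value = numeric(0), retained = logical(0),
                            stringsAsFactors = FALSE)
  n_skipped <- 0L

  score <- function(kind, from, to, from_dir, to_dir, x, y) {
    cc <- complete.cases(x, y)
    if (sum(cc) < 3) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    ct <- correlate(x[cc], y[cc], method = method)
    if (is.na(ct$r)) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    retained <- ct$p <= edge_p_max && abs(ct$r) >= r_min
    if (mode == "strict") {
      consistent <- if (kind == "meth_mirna") {
        (from_dir == "hypo" && to_dir == "up") ||
          (from_dir == "hyper" && to_dir == "down")
      } else {
        (from_dir == "up" && to_dir == "down") ||
          (from_dir == "down" && to_dir == "up")
      }
      retained <- retained && ct$r < 0 && consistent
    }
    data.frame(kind = kind, from = from, to = to,
               from_direction = from_dir, to_direction = to_dir,
               r = ct$r, p_value = ct$p, retained = retained,
               stringsAsFactors = FALSE)
  }

  meth_edges <- list()
  if (nrow(promoter_pairs) && nrow(dmrs)) {
    for (i in seq_len(nrow(promoter_pairs))) {
      di <- promoter_pairs$dmr_idx[i]
      mid <- promoter_pairs$mirna_id[i]
      st <- mirna_status[mid]
      if (is.na(st) || st == "ns") next
      if (!mid %in% rownames(mirna_norm)) next
      meth_edges[[length(meth_edges) + 1L]] <-
        score("meth_mirna", dmr_id[di], mid, dmrs$direction[di], st,
              meth_levels[di, ], mirna_norm[mid, ])
    }
  }
  target_edges <- list()
  if (nrow(target_pairs)) {
    for (i in seq_len(nrow(target_pairs))) {
      mid <- target_pairs$mirna_id[i]
      gid <- target_pairs$mrna_id[i]
      st1 <- mirna_status[mid]
      st2 <- mrna_status[gid]
      if (is.na(st1) || st1 == "ns" || is.na(st2) || st2 == "ns") next
      if (!mid %in% rownames(mirna_norm) ||
          !gid %in% rownames(mrna_norm)) next
      target_edges[[length(target_edges) + 1L]] <-
        score("mirna_mrna", mid, gid, st1, st2,
              mirna_norm[mid, ], mrna_norm[gid, ])
    }
  }

  edges <- rbind(empty_edges,
                 do.call(rbind, c(meth_edges, target_edges)))
  edges <- unique(edges[, edge_cols])
  rownames(edges) <- NULL

  ret <- edges[edges$retained, , drop = FALSE]
  me <- ret[ret$kind == "meth_mirna", , drop = FALSE]
  te <- ret[ret$kind == "mirna_mrna", , drop = FALSE]
  if (nrow(me) && nrow(te)) {
    triplets <- merge(
      data.frame(dmr = me$from, mirna = me$to,
                 stringsAsFactors = FALSE),
      data.frame(mirna = te$from, mrna = te$to,
                 stringsAsFactors = FALSE),
      by = "mirna")[, c("dmr", "mirna", "mrna")]
    triplets <- unique(triplets)
    rownames(triplets) <- NULL
  } else {
    triplets <- data.frame(dmr = character(0), mirna = character(0),
                           mrna = character(0), stringsAsFactors = FALSE)
  }

  node_rows <- list()
  if (nrow(me)) {
    node_rows$dmr <- data.frame(id = me$from, type = "dmr",
                                direction = me$from_direction,
                                stringsAsFactors = FALSE)
  }
  mir_ids <- unique(c(me$to, te$from))
  if (length(mir_ids)) {
    node_rows$mirna <- data.frame(id = mir_ids, type = "mirna",
                                  direction = unname(mirna_status[mir_ids]),
                                  stringsAsFactors = FALSE)
  }
  if (nrow(te)) {
    node_rows$mrna <- data.frame(id = te$to, type = "mrna",
                                 direction = te$to_direction,
                                 stringsAsFactors = FALSE)
  }
  nodes <- if (length(node_rows)) {
    unique(do.call(rbind, node_rows))
  } else {
    data.frame(id = character(0), type = character(0),
               direction = character(0), stringsAsFactors = FALSE)
  }
  rownames(nodes) <- NULL

  structure(list(nodes = nodes, edges = edges, triplets = triplets,
                 mode = mode,
                 thresholds = list(r_min = r_min,
                                   edge_p_max = edge_p_max),
                 n_skipped = n_skipped),
            class = "regulatory_network")
}

#' Summarize a regulatory network
#'
#' Node counts per class and direction, retained edge counts per kind,
#' and the triplet count.  Direction subtotals always sum to class
#' totals.
#'
#' @param network A `regulatory_network`.
#' @return Named list of counts.
#' @export
summarize_network <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  nd <- network$nodes
  cnt <- function(type, dir = NULL) {
    sel <- nd$type == type
    if (!is.null(dir)) sel <- sel & nd$direction == dir
    sum(sel)
  }
  ret <- network$edges[network$edges$retained, , drop = FALSE]
  list(n_dmr = cnt("dmr"),
       n_dmr_hypo = cnt("dmr", "hypo"),
       n_dmr_hyper = cnt("dmr", "hyper"),
       n_mirna = cnt("mirna"),
       n_mirna_up = cnt("mirna", "up"),
       n_mirna_down = cnt("mirna", "down"),
       n_mrna = cnt("mrna"),
       n_mrna_up = cnt("mrna", "up"),
       n_mrna_down = cnt("mrna", "down"),
       n_edges_meth = sum(ret$kind == "meth_mirna"),
       n_edges_target = sum(ret$kind == "mirna_mrna"),
       n_triplets = nrow(network$triplets))
}

#' Export a regulatory network
#'
#' Writes `nodes.tsv` and `edges.tsv` (all scored candidates with the
#' `retained` flag) and, for `format = "graphml"`, the retained subgraph
#' as GraphML readable by [import_network_graphml()].
#'
#' @param network A `regulatory_network`.
#' @param dir Output directory (created if missing).
#' @param format `"tsv"`, `"graphml"`, or both.
#' @return Invisibly, the written file paths.
#' @export
export_network <- function(network, dir, format = c("tsv", "graphml")) {
  stopifnot(inherits(network, "regulatory_network"))
  if (!all(format %in% c("tsv", "graphml"))) {
    stop("unknown format: ",
         paste(setdiff(format, c("tsv", "graphml")), collapse = ", "),
         call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  if ("tsv" %in% format) {
    np <- file.path(dir, "nodes.tsv")
    ep <- file.path(dir, "edges.tsv")
    write.table(network$nodes, np, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(network$edges, ep, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, np, ep)
  }
  if ("graphml" %in% format) {
    gp <- file.path(dir, "network.graphml")
    ret <- network$edges[network$edges$retained, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      ret[, c("from", "to", "kind", "r", "p_value")],
      directed = TRUE, vertices = network$nodes)
    igraph::write_graph(g, gp, format = "graphml")
    paths <- c(paths, gp)
  }
  invisible(paths)
}

#' Import a GraphML network written by [export_network()]
#'
#' @param path GraphML file.
#' @return A `regulatory_network` with the retained edges (all imported
#'   edges are retained by construction) and recomputed triplets.
#' @export
import_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  edges <- igraph::as_data_frame(g, what = "edges")
  if (nrow(nodes)) {
    nodes <- data.frame(id = nodes$name, type = nodes$type,
                        direction = nodes$direction,
                        stringsAsFactors = FALSE)
  } else {
    nodes <- data.frame(id = character(0), type = character(0),
                        direction = character(0),
                        stringsAsFactors = FALSE)
  }
  if (nrow(edges)) {
    dir_of <- setNames(nodes$direction, nodes$id)
    edges <- data.frame(kind = edges$kind, from = edges$from,
                        to = edges$to,
                        from_direction = unname(dir_of[edges$from]),
                        to_direction = unname(dir_of[edges$to]),
                        r = edges$r, p_value = edges$p_value,
                        retained = TRUE, stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(kind = character(0), from = character(0),
                        to = character(0), from_direction = character(0),
                        to_direction = character(0), r = numeric(0),
                        p_value = numeric(0), retained = logical(0),
                        stringsAsFactors = FALSE)
  }
  me <- edges[edges$kind == "meth_mirna", , drop = FALSE]
  te <- edges[edges$kind == "mirna_mrna", , drop = FALSE]
  if (nrow(me) && nrow(te)) {
    triplets <- unique(merge(
      data.frame(dmr = me$from, mirna = me$to, stringsAsFactors = FALSE),
      data.frame(mirna = te$from, mrna = te$to,
                 stringsAsFactors = FALSE),
      by = "mirna")[, c("dmr", "mirna", "mrna")])
    rownames(triplets) <- NULL
  } else {
    triplets <- data.frame(dmr = character(0), mirna = character(0),
                           mrna = character(0), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, triplets = triplets,
                 mode = NA_character_, thresholds = list(),
                 n_skipped = 0L),
            class = "regulatory_network")
}
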