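test_that("correlate matches the closed-form definition and cor.test", {
  x <- 1:10
  expect_identical(correlate(x, x)$r, 1)
  expect_identical(correlate(x, -2 * x + 3)$r, -1)
  expect_identical(correlate(x, x)$p, 0)
  # hand-computed on the fixed 5-point vectors:
  # r = 10 / sqrt(10 * 14.8) = 0.82199...
  x5 <- c(1, 2, 3, 4, 5)
  y5 <- c(2, 1, 4, 3, 6)
  ct <- correlate(x5, y5)
  expect_equal(ct$r, 10 / sqrt(10 * 14.8), tolerance = 1e-12)
  expect_equal(ct$r, 0.8220, tolerance = 1e-3)
  ref <- cor.test(x5, y5)
  expect_equal(ct$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ct$p, ref$p.value, tolerance = 1e-12)
  set.seed(2)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    got <- correlate(a, b)
    ref <- cor.test(a, b)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("spearman ranks first and handles ties like cor.test", {
  set.seed(3)
  a <- sample(1:5, 12, replace = TRUE)
  b <- a + rnorm(12)
  got <- correlate(a, b, method = "spearman")
  ref <- suppressWarnings(cor.test(a, b, method = "spearman"))
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
})

test_that("degenerate correlation inputs are signalled", {
  expect_error(correlate(1:2, 1:2), "3")
  expect_error(correlate(1:5, c(1, 2, NA, 4, 5)), "finite")
  flat <- correlate(rep(1, 5), 1:5)
  expect_true(is.na(flat$r) && is.na(flat$p))
})

# hand-built inputs with one perfectly consistent triplet and controllable
# extras
network_fixture <- function(extra_sign = NULL) {
  samples <- data.frame(sample_id = sprintf("s%d", 1:10),
                        group = rep(c("case", "control"), each = 5))
  pos <- seq(1000L, 1900L, by = 100L)
  lev_case <- 0.1; lev_ctrl <- 0.5
  m <- cbind(matrix(10L, 10, 5), matrix(50L, 10, 5))
  u <- 100L - m
  colnames(m) <- colnames(u) <- samples$sample_id
  cpg <- cpg_site_table(data.frame(chrom = "chr1", pos = pos,
                                   strand = "+"), m, u, samples)
  dmrs <- data.frame(chrom = "chr1", start = 1000L, end = 1901L,
                     n_cpgs = 10L, mean_diff = -0.4, p_value = 1e-12,
                     q_value = 1e-10, direction = "hypo")
  mk_de <- function(ids, status) {
    data.frame(feature_id = ids, mean_case = 1, mean_control = 1,
               log2fc = ifelse(status == "up", 2,
                               ifelse(status == "down", -2, 0)),
               p_value = 1e-4, q_value = 1e-3, status = status,
               stringsAsFactors = FALSE)
  }
  up <- c(55, 60, 52, 58, 61, 11, 9, 13, 10, 12)
  dn <- c(9, 12, 10, 13, 11, 52, 61, 55, 60, 57)
  mirna_norm <- matrix(up, 1, dimnames = list("mir-1", samples$sample_id))
  mrna_norm <- matrix(dn, 1, dimnames = list("gene-1", samples$sample_id))
  de_mirna <- mk_de("mir-1", "up")
  de_mrna <- mk_de("gene-1", "down")
  promoter_pairs <- data.frame(dmr_idx = 1L, dmr_id = "chr1:1000-1901",
                               mirna_id = "mir-1")
  target_pairs <- data.frame(mirna_id = "mir-1", mrna_id = "gene-1",
                             n_sites = 1L, source = "seed_match")
  list(dmrs = dmrs, de_mirna = de_mirna, de_mrna = de_mrna,
       promoter_pairs = promoter_pairs, target_pairs = target_pairs,
       cpg = cpg, mirna_norm = mirna_norm, mrna_norm = mrna_norm)
}

build_fixture_network <- function(fx, ...) {
  build_network(fx$dmrs, fx$de_mirna, fx$de_mrna, fx$promoter_pairs,
                fx$target_pairs, fx$cpg, fx$mirna_norm, fx$mrna_norm, ...)
}

test_that("a consistent planted triplet is retained in strict mode", {
  fx <- network_fixture()
  net <- build_fixture_network(fx, mode = "strict")
  expect_identical(nrow(net$triplets), 1L)
  expect_identical(net$triplets$mirna, "mir-1")
  expect_identical(net$triplets$mrna, "gene-1")
  s <- summarize_network(net)
  expect_identical(s$n_dmr, 1L)
  expect_identical(s$n_mirna_up, 1L)
  expect_identical(s$n_mrna_down, 1L)
  expect_identical(s$n_triplets, 1L)
  ret <- net$edges[net$edges$retained, ]
  expect_true(all(ret$r < 0))
})

test_that("all-ns differential tables gate out every edge", {
  fx <- network_fixture()
  fx$de_mirna$status <- "ns"
  fx$de_mrna$status <- "ns"
  net <- build_fixture_network(fx)
  expect_identical(nrow(net$edges), 0L)
  expect_identical(nrow(net$nodes), 0L)
  s <- summarize_network(net)
  expect_true(all(unlist(s) == 0))
})

test_that("strict mode rejects positively correlated candidate edges", {
  fx <- network_fixture()
  # make the mRNA co-vary with the miRNA (positive r) but keep status
  # 'down' nominally
  fx$mrna_norm[1, ] <- fx$mirna_norm[1, ] + rep(c(0.3, -0.2), 5)
  strict <- build_fixture_network(fx, mode = "strict")
  expect_identical(sum(strict$edges$retained &
                         strict$edges$kind == "mirna_mrna"), 0L)
  permissive <- build_fixture_network(fx, mode = "permissive")
  expect_identical(sum(permissive$edges$retained &
                         permissive$edges$kind == "mirna_mrna"), 1L)
})

test_that("strict mode enforces sign-consistent endpoint directions", {
  fx <- network_fixture()
  # anticorrelated but direction-inconsistent: hypo promoter with a
  # down-regulated miRNA
  fx$de_mirna$status <- "down"
  net <- build_fixture_network(fx, mode = "strict")
  expect_identical(sum(net$edges$retained &
                         net$edges$kind == "meth_mirna"), 0L)
})

test_that("raising r_min or lowering edge_p_max never adds edges", {
  b <- generate_cohort(tiny_config(seed = 41, n_triplets = 2))
  res <- analyze_cohort(b, pipeline_config(synth = tiny_config(seed = 41),
                                           mode = "permissive",
                                           r_min = 0.3, edge_p_max = 0.2))
  base_edges <- res$network$edges
  key <- function(e) paste(e$kind, e$from, e$to)
  for (rmin in c(0.5, 0.8, 0.95)) {
    net2 <- build_network(res$dmrs, res$de_mirna, res$de_mrna,
                          res$promoter_pairs, res$target_pairs, b$cpg,
                          res$mirna_rpm, res$mrna_rpkm, r_min = rmin,
                          edge_p_max = 0.2, mode = "permissive")
    expect_true(all(key(net2$edges[net2$edges$retained, ]) %in%
                      key(base_edges[base_edges$retained, ])))
  }
  net3 <- build_network(res$dmrs, res$de_mirna, res$de_mrna,
                        res$promoter_pairs, res$target_pairs, b$cpg,
                        res$mirna_rpm, res$mrna_rpkm, r_min = 0.3,
                        edge_p_max = 0.01, mode = "permissive")
  expect_true(all(key(net3$edges[net3$edges$retained, ]) %in%
                    key(base_edges[base_edges$retained, ])))
})

test_that("every retained edge satisfies the configured thresholds", {
  for (mode in c("strict", "permissive")) {
    b <- generate_cohort(tiny_config(seed = 43, n_triplets = 3,
                                     n_mirnas = 15, n_mrnas = 40))
    res <- analyze_cohort(b, pipeline_config(
      synth = tiny_config(seed = 43), mode = mode))
    ret <- res$network$edges[res$network$edges$retained, ]
    if (nrow(ret) == 0) next
    expect_true(all(abs(ret$r) >= 0.7))
    expect_true(all(ret$p_value <= 0.05))
    if (mode == "strict") expect_true(all(ret$r < 0))
    # every triplet's two edges are retained
    tp <- res$network$triplets
    for (i in seq_len(nrow(tp))) {
      expect_true(any(ret$kind == "meth_mirna" & ret$from == tp$dmr[i] &
                        ret$to == tp$mirna[i]))
      expect_true(any(ret$kind == "mirna_mrna" & ret$from == tp$mirna[i] &
                        ret$to == tp$mrna[i]))
    }
    # every node participates in >= 1 retained edge
    expect_true(all(res$network$nodes$id %in% c(ret$from, ret$to)))
  }
})

test_that("direction subtotals sum to class totals", {
  b <- generate_cohort(tiny_config(seed = 47, n_triplets = 2))
  res <- analyze_cohort(b, pipeline_config(synth = tiny_config(seed = 47),
                                           mode = "permissive"))
  s <- summarize_network(res$network)
  expect_identical(s$n_dmr, s$n_dmr_hypo + s$n_dmr_hyper)
  expect_identical(s$n_mirna, s$n_mirna_up + s$n_mirna_down)
  expect_identical(s$n_mrna, s$n_mrna_up + s$n_mrna_down)
})

test_that("networks export and round-trip through TSV and GraphML", {
  fx <- network_fixture()
  net <- build_fixture_network(fx)
  dir <- withr::local_tempdir()
  export_network(net, dir, format = c("tsv", "graphml"))
  edges <- read.delim(file.path(dir, "edges.tsv"))
  expect_identical(nrow(edges), nrow(net$edges))
  back <- import_network_graphml(file.path(dir, "network.graphml"))
  expect_setequal(back$nodes$id, net$nodes$id)
  ret <- net$edges[net$edges$retained, ]
  expect_setequal(paste(back$edges$from, back$edges$to),
                  paste(ret$from, ret$to))
  expect_equal(sort(back$edges$r), sort(ret$r), tolerance = 1e-6)
  expect_identical(nrow(back$triplets), nrow(net$triplets))
  expect_error(export_network(net, dir, format = "dot"), "format")
})

test_that("an empty network exports a header-only TSV and empty graph", {
  fx <- network_fixture()
  fx$de_mirna$status <- "ns"
  fx$de_mrna$status <- "ns"
  net <- build_fixture_network(fx)
  dir <- withr::local_tempdir()
  export_network(net, dir, format = c("tsv", "graphml"))
  lines <- readLines(file.path(dir, "edges.tsv"))
  expect_identical(length(lines), 1L)
  back <- import_network_graphml(file.path(dir, "network.graphml"))
  expect_identical(nrow(back$nodes), 0L)
  expect_identical(nrow(back$edges), 0L)
})
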