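test_that("invalid configurations are rejected with the field named", {
  expect_error(synth_config(n_case = 0), "n_case")
  expect_error(synth_config(meth_base = 0.8, meth_delta = 0.4),
               "meth_delta")
  expect_error(synth_config(n_mirnas = 5, n_mrnas = 5, n_triplets = 6),
               "n_triplets")
  expect_error(synth_config(error_rate_p0 = 0), "error_rate_p0")
  expect_error(synth_config(bb_overdispersion = 1), "bb_overdispersion")
})

test_that("same config and seed give bit-identical bundles", {
  cfg <- tiny_config(seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("a null generator plants nothing", {
  cfg <- tiny_config(seed = 3, n_triplets = 0)
  b <- generate_cohort(cfg)
  expect_identical(nrow(b$truth$triplets), 0L)
  # every site shares the baseline methylation: group means agree within
  # sampling noise at every promoter
  lev <- b$cpg$m / (b$cpg$m + b$cpg$u)
  case <- rowMeans(lev[, b$samples$group == "case"], na.rm = TRUE)
  ctrl <- rowMeans(lev[, b$samples$group == "control"], na.rm = TRUE)
  expect_lt(abs(mean(case - ctrl, na.rm = TRUE)), 0.02)
})

test_that("bundle tables are mutually consistent", {
  b <- generate_cohort(tiny_config(seed = 5))
  ids <- b$samples$sample_id
  expect_identical(colnames(b$cpg$m), ids)
  expect_identical(colnames(b$mirna_counts), ids)
  expect_identical(colnames(b$mrna_counts), ids)
  expect_identical(b$clinical$sample_id, ids)
  expect_setequal(names(b$mirna_seqs), b$mirna_annotation$mirna_id)
  expect_setequal(names(b$utr_seqs), b$mrna_annotation$mrna_id)
  expect_true(all(b$cpg$m >= 0), all(b$cpg$u >= 0))
  # planted DMR intervals lie inside the promoter of their miRNA
  tr <- b$truth$triplets
  ann <- b$mirna_annotation[match(tr$mirna_id, b$mirna_annotation$mirna_id), ]
  prom <- promoter_region(ann$tss, ann$strand, ann$chrom,
                          b$chrom_lengths[ann$chrom],
                          upstream_bp = b$config$upstream_bp)
  expect_true(all(tr$dmr_start >= prom$start & tr$dmr_end <= prom$end))
  # sign consistency of planted chains
  hypo <- tr$meth_direction == "hypo"
  expect_true(all(tr$mirna_direction[hypo] == "up" &
                    tr$mrna_direction[hypo] == "down"))
  expect_true(all(tr$mirna_direction[!hypo] == "down" &
                    tr$mrna_direction[!hypo] == "up"))
})

test_that("planted methylation difference converges to meth_delta", {
  # Monte-Carlo check of the generator mean against its own contract:
  # average control-minus-case level at a planted hypo DMR
  diffs <- vapply(1:50, function(s) {
    cfg <- tiny_config(seed = 7000 + s, n_mirnas = 6, n_mrnas = 10,
                       n_triplets = 1, coverage_mean = 50)
    b <- generate_cohort(cfg)
    tr <- b$truth$triplets
    lev <- dmr_methylation_levels(
      data.frame(chrom = tr$dmr_chrom, start = tr$dmr_start,
                 end = tr$dmr_end), b$cpg)
    mean(lev[, b$samples$group == "control"]) -
      mean(lev[, b$samples$group == "case"])
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 0.4), 0.05)
})

test_that("planted expression effects match the configured log2FC", {
  # measured on raw counts: the planted effect is defined relative to the
  # library, so depth normalization is not involved
  lfcs <- vapply(1:40, function(s) {
    cfg <- tiny_config(seed = 8000 + s, n_mirnas = 50, n_mrnas = 20,
                       n_triplets = 1)
    b <- generate_cohort(cfg)
    x <- b$mirna_counts[b$truth$triplets$mirna_id[1], ]
    log2(mean(x[b$samples$group == "case"]) /
           mean(x[b$samples$group == "control"]))
  }, numeric(1))
  expect_lt(abs(mean(lfcs) - 2), 0.2)
})

test_that("planted seed sites are exclusive to their true pair", {
  b <- generate_cohort(tiny_config(seed = 19, n_triplets = 3,
                                   n_mirnas = 12, n_mrnas = 30))
  tr <- b$truth$triplets
  pairs <- predict_targets(b$mirna_seqs[tr$mirna_id], b$utr_seqs)
  expect_setequal(paste(pairs$mirna_id, pairs$mrna_id),
                  paste(tr$mirna_id, tr$mrna_id))
})

test_that("gensini scores track the configured anchor correlation", {
  # sampling distribution of r at n = 10 is wide; check the mean over
  # replicate cohorts
  rs <- vapply(1:60, function(s) {
    cfg <- tiny_config(seed = 9000 + s, n_mirnas = 6, n_mrnas = 10,
                       n_triplets = 1, gensini_anchor = "methylation",
                       gensini_r = -0.772)
    b <- generate_cohort(cfg)
    tr <- b$truth$triplets
    lev <- dmr_methylation_levels(
      data.frame(chrom = tr$dmr_chrom, start = tr$dmr_start,
                 end = tr$dmr_end), b$cpg)
    correlate(as.vector(lev), b$clinical$Gensini)$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - (-0.772)), 0.25)
})

test_that("bundles round-trip through write_bundle/read_bundle", {
  b <- generate_cohort(tiny_config(seed = 23))
  dir <- withr::local_tempdir()
  manifest <- write_bundle(b, dir)
  expect_true(all(file.exists(file.path(dir, manifest$file))))
  b2 <- read_bundle(dir)
  expect_identical(b2$cpg$m, b$cpg$m)
  expect_identical(b2$cpg$u, b$cpg$u)
  expect_identical(b2$mirna_counts, b$mirna_counts)
  expect_identical(b2$mrna_counts, b$mrna_counts)
  expect_identical(b2$mirna_seqs, b$mirna_seqs)
  expect_identical(b2$utr_seqs, b$utr_seqs)
  expect_equal(b2$clinical, b$clinical, tolerance = 1e-10)
  expect_equal(b2$truth$triplets, b$truth$triplets)
  expect_identical(b2$mirna_annotation$tss, b$mirna_annotation$tss)
  # FASTA record count and ids match the annotation
  expect_length(b2$mirna_seqs, nrow(b$mirna_annotation))
})

test_that("an empty bundle writes a valid zero-row manifest", {
  cfg <- tiny_config(seed = 1)
  samples <- data.frame(sample_id = c("A1", "A2", "N1", "N2"),
                        group = c("case", "case", "control", "control"),
                        stringsAsFactors = FALSE)
  mk <- function(n) matrix(integer(0), 0, 4,
                           dimnames = list(NULL, samples$sample_id))
  empty <- structure(list(
    config = cfg, samples = samples,
    cpg = cpg_site_table(
      data.frame(chrom = character(0), pos = integer(0),
                 strand = character(0)), mk(), mk(), samples),
    mirna_counts = mk(), mrna_counts = mk(),
    mirna_annotation = data.frame(mirna_id = character(0),
                                  chrom = character(0), tss = integer(0),
                                  strand = character(0)),
    mrna_annotation = data.frame(mrna_id = character(0),
                                 exon_length_bp = integer(0)),
    mirna_seqs = setNames(character(0), character(0)),
    utr_seqs = setNames(character(0), character(0)),
    clinical = data.frame(sample_id = samples$sample_id,
                          group = samples$group, Gensini = c(1, 2, 3, 4)),
    chrom_lengths = c(chr1 = 1000L),
    truth = list(triplets = data.frame())), class = "cohort_bundle")
  dir <- withr::local_tempdir()
  manifest <- write_bundle(empty, dir)
  expect_identical(manifest$rows[manifest$file == "cpg_counts.tsv"], 0L)
  expect_identical(manifest$rows[manifest$file == "mirna.fa"], 0L)
})
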