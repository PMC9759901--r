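#' Pipeline configuration
#'
#' Collects all stage thresholds plus either a synthetic-cohort block or
#' an input directory (exactly one must be given).  Defaults encode the
#' screening criteria used throughout the package: site depth >= 5 at
#' p <= 0.05, 1 kb windows stepped 100 bp with >= 3 CpGs and a 0.1 level
#' difference, |log2FC| >= 1 with p < 0.05 and Q <= 0.05 for miRNA,
#' p < 0.05 and Q <= 0.05 for mRNA, 2 kb promoters, 7mer-m8 seed
#' matching, and strict anticorrelated edge retention at |r| >= 0.7.
#'
#' @param synth A [synth_config()], or `NULL` when reading real inputs.
#' @param input_dir Directory of a written bundle ([write_bundle()]), or
#'   `NULL` when simulating.
#' @param depth_min,p0,site_p_max Site-calling parameters.
#' @param window_bp,step_bp,min_cpgs,min_mean_diff,dmr_p_max,dmr_q_max
#'   DMR-detection parameters.
#' @param mirna_preset,mrna_preset Differential-screen thresholds
#'   ([de_presets()]).
#' @param pseudocount Pseudocount for the differential screen.
#' @param upstream_bp Promoter window length.
#' @param seed_type Seed-match class ([predict_targets()]).
#' @param target_map Optional path to an external miRNA-target pair
#'   table used instead of seed matching.
#' @param r_min,edge_p_max,mode Network retention parameters
#'   ([build_network()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synth = NULL, input_dir = NULL,
                            depth_min = 5, p0 = 0.005, site_p_max = 0.05,
                            window_bp = 1000, step_bp = 100,
                            min_cpgs = 3, min_mean_diff = 0.1,
                            dmr_p_max = 0.05, dmr_q_max = 0.05,
                            mirna_preset = de_presets("mirna"),
                            mrna_preset = de_presets("mrna"),
                            pseudocount = 1, upstream_bp = 2000,
                            seed_type = "7mer-m8", target_map = NULL,
                            r_min = 0.7, edge_p_max = 0.05,
                            mode = c("strict", "permissive")) {
  if (is.null(synth) == is.null(input_dir)) {
    stop("exactly one of 'synth' and 'input_dir' must be given",
         call. = FALSE)
  }
  structure(list(synth = synth, input_dir = input_dir,
                 depth_min = depth_min, p0 = p0, site_p_max = site_p_max,
                 window_bp = window_bp, step_bp = step_bp,
                 min_cpgs = min_cpgs, min_mean_diff = min_mean_diff,
                 dmr_p_max = dmr_p_max, dmr_q_max = dmr_q_max,
                 mirna_preset = mirna_preset, mrna_preset = mrna_preset,
                 pseudocount = pseudocount, upstream_bp = upstream_bp,
                 seed_type = seed_type, target_map = target_map,
                 r_min = r_min, edge_p_max = edge_p_max,
                 mode = match.arg(mode)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML file holds the [pipeline_config()] fields at top level; a
#' `synth:` block holds [synth_config()] fields.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synth)) y$synth <- do.call(synth_config, y$synth)
  do.call(pipeline_config, y)
}

#' Run the full analysis chain on a cohort bundle
#'
#' Executes every stage in order on an in-memory bundle: per-sample site
#' calling, sliding-window DMR detection, RPM/RPKM normalization,
#' differential screening of both expression layers, promoter assignment
#' for differentially expressed miRNAs, DMR-promoter overlap, target
#' pairing (seed match or external table) restricted to differential
#' features, network assembly, trait correlations for the first planted
#' triplet (when truth is available), and triplet-recovery scoring
#' against the truth.
#'
#' @param bundle A `cohort_bundle` (from [generate_cohort()] or
#'   [read_bundle()]).
#' @param config A [pipeline_config()].
#' @return List with `dmrs`, `de_mirna`, `de_mrna`, `promoter_pairs`,
#'   `target_pairs`, `network`, `trait_cor`, `recovery` and a `summary`
#'   list of stage funnel counts.
#' @export
analyze_cohort <- function(bundle, config) {
  stopifnot(inherits(bundle, "cohort_bundle"),
            inherits(config, "pipeline_config"))
  groups <- bundle$samples$group

  ## methylation layer
  calls <- call_site(as.vector(bundle$cpg$m), as.vector(bundle$cpg$u),
                     p0 = config$p0, depth_min = config$depth_min,
                     p_max = config$site_p_max)
  n_called <- sum(calls$is_called)
  dmrs <- detect_dmrs(bundle$cpg, window_bp = config$window_bp,
                      step_bp = config$step_bp,
                      min_cpgs = config$min_cpgs,
                      min_mean_diff = config$min_mean_diff,
                      p_max = config$dmr_p_max, q_max = config$dmr_q_max,
                      depth_min = config$depth_min)

  ## expression layer
  mirna_rpm <- rpm_normalize(bundle$mirna_counts)
  lens <- setNames(bundle$mrna_annotation$exon_length_bp,
                   bundle$mrna_annotation$mrna_id)
  mrna_rpkm <- rpkm_normalize(bundle$mrna_counts, lens)
  de_mirna <- do.call(de_screen,
                      c(list(norm = mirna_rpm, groups = groups,
                             pseudocount = config$pseudocount),
                        config$mirna_preset))
  de_mrna <- do.call(de_screen,
                     c(list(norm = mrna_rpkm, groups = groups,
                            pseudocount = config$pseudocount),
                       config$mrna_preset))

  ## regulatory map: promoters of DE miRNAs, targets among DE mRNAs
  de_mir_ids <- de_mirna$feature_id[de_mirna$status != "ns"]
  de_mrna_ids <- de_mrna$feature_id[de_mrna$status != "ns"]
  ann <- bundle$mirna_annotation
  ann <- ann[ann$mirna_id %in% de_mir_ids, , drop = FALSE]
  if (nrow(ann)) {
    promoters <- promoter_region(ann$tss, ann$strand, ann$chrom,
                                 bundle$chrom_lengths[ann$chrom],
                                 upstream_bp = config$upstream_bp)
    promoters$mirna_id <- ann$mirna_id
  } else {
    promoters <- data.frame(chrom = character(0), start = integer(0),
                            end = integer(0), strand = character(0),
                            mirna_id = character(0),
                            stringsAsFactors = FALSE)
  }
  promoter_pairs <- overlap_dmr_promoters(dmrs, promoters)

  if (!is.null(config$target_map)) {
    target_pairs <- load_target_map(config$target_map)
    target_pairs <- target_pairs[
      target_pairs$mirna_id %in% de_mir_ids &
        target_pairs$mrna_id %in% de_mrna_ids, , drop = FALSE]
  } else {
    target_pairs <- predict_targets(
      bundle$mirna_seqs[intersect(de_mir_ids, names(bundle$mirna_seqs))],
      bundle$utr_seqs[intersect(de_mrna_ids, names(bundle$utr_seqs))],
      seed_type = config$seed_type)
  }

  network <- build_network(dmrs, de_mirna, de_mrna, promoter_pairs,
                           target_pairs, bundle$cpg, mirna_rpm,
                           mrna_rpkm, r_min = config$r_min,
                           edge_p_max = config$edge_p_max,
                           mode = config$mode)

  ## clinical layer: traits vs the first planted chain when truth exists
  trait_cor <- NULL
  truth <- bundle$truth$triplets
  if (!is.null(bundle$clinical) && nrow(truth) > 0) {
    dmr1 <- data.frame(chrom = truth$dmr_chrom[1],
                       start = truth$dmr_start[1],
                       end = truth$dmr_end[1])
    feats <- data.frame(
      promoter_methylation = as.vector(
        dmr_methylation_levels(dmr1, bundle$cpg)),
      mirna_rpm = mirna_rpm[truth$mirna_id[1], ])
    tr <- bundle$clinical[setdiff(names(bundle$clinical),
                                  c("sample_id", "group"))]
    trait_cor <- trait_correlations(feats, tr)
  }

  recovery <- if (nrow(truth) >= 0 && !is.null(bundle$truth)) {
    evaluate_recovery(network, truth)
  } else NULL

  summary <- list(
    n_sites = nrow(bundle$cpg$sites),
    n_site_calls = n_called,
    n_dmrs = nrow(dmrs),
    n_dmrs_hyper = sum(dmrs$direction == "hyper"),
    n_dmrs_hypo = sum(dmrs$direction == "hypo"),
    n_de_mirna = length(de_mir_ids),
    n_de_mirna_up = sum(de_mirna$status == "up"),
    n_de_mirna_down = sum(de_mirna$status == "down"),
    n_de_mrna = length(de_mrna_ids),
    n_de_mrna_up = sum(de_mrna$status == "up"),
    n_de_mrna_down = sum(de_mrna$status == "down"),
    n_promoter_pairs = nrow(promoter_pairs),
    n_target_pairs = nrow(target_pairs),
    network = summarize_network(network),
    recovery = recovery)

  list(dmrs = dmrs, de_mirna = de_mirna, de_mrna = de_mrna,
       promoter_pairs = promoter_pairs, target_pairs = target_pairs,
       mirna_rpm = mirna_rpm, mrna_rpkm = mrna_rpkm,
       network = network, trait_cor = trait_cor, recovery = recovery,
       summary = summary)
}

#' Score recovered triplets against the planted truth
#'
#' A recovered (DMR, miRNA, mRNA) chain matches a planted one when the
#' miRNA and mRNA identifiers agree and the recovered DMR interval
#' overlaps the planted interval.  Precision is the fraction of recovered
#' chains that match some planted one; recall is the fraction of planted
#' chains matched by some recovered one.  Either is `NA` when its
#' denominator is zero.
#'
#' @param network A `regulatory_network`.
#' @param truth Truth triplet data frame (`bundle$truth$triplets`).
#' @return List: `n_recovered`, `n_matched`, `n_planted`, `precision`,
#'   `recall`.
#' @export
evaluate_recovery <- function(network, truth) {
  rec <- network$triplets
  n_rec <- nrow(rec)
  n_pl <- nrow(truth)
  if (n_rec == 0 || n_pl == 0) {
    return(list(n_recovered = n_rec, n_matched = 0L, n_planted = n_pl,
                precision = if (n_rec == 0) NA_real_ else 0,
                recall = if (n_pl == 0) NA_real_ else 0))
  }
  parse_id <- function(id) {
    m <- regmatches(id, regexec("^(.+):(\\d+)-(\\d+)$", id))[[1]]
    list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
  }
  matched_rec <- logical(n_rec)
  matched_pl <- logical(n_pl)
  for (i in seq_len(n_rec)) {
    d <- parse_id(rec$dmr[i])
    for (k in seq_len(n_pl)) {
      if (rec$mirna[i] == truth$mirna_id[k] &&
          rec$mrna[i] == truth$mrna_id[k] &&
          d$chrom == truth$dmr_chrom[k] &&
          d$start < truth$dmr_end[k] && truth$dmr_start[k] < d$end) {
        matched_rec[i] <- TRUE
        matched_pl[k] <- TRUE
      }
    }
  }
  list(n_recovered = n_rec, n_matched = sum(matched_rec),
       n_planted = n_pl,
       precision = mean(matched_rec), recall = mean(matched_pl))
}

#' Run the whole pipeline and write every artifact
#'
#' Generates (or reads) the cohort, runs [analyze_cohort()], and writes
#' all intermediate and final artifacts to `out_dir`: the cohort bundle,
#' `dmrs.bed`, differential tables, pair tables, the network (TSV +
#' GraphML), trait correlations, `summary.json` and a `manifest.json`
#' listing every file.  Identical config and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the result list of [analyze_cohort()] with the
#'   bundle attached as `$bundle`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fail_marker <- file.path(out_dir, "FAILED")
  stage <- "input"
  res <- tryCatch({
    bundle <- if (!is.null(config$synth)) {
      generate_cohort(config$synth)
    } else {
      read_bundle(config$input_dir)
    }
    stage <- "cohort serialization"
    write_bundle(bundle, file.path(out_dir, "cohort"))
    stage <- "analysis"
    out <- analyze_cohort(bundle, config)
    out$bundle <- bundle
    out
  }, error = function(e) {
    writeLines(sprintf("stage '%s' failed: %s", stage,
                       conditionMessage(e)), fail_marker)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  tsv <- function(x, file) {
    write.table(x, file.path(out_dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
    file
  }
  files <- c(
    { write_dmrs(res$dmrs, file.path(out_dir, "dmrs.bed")); "dmrs.bed" },
    tsv(res$de_mirna, "de_mirna.tsv"),
    tsv(res$de_mrna, "de_mrna.tsv"),
    tsv(res$promoter_pairs, "promoter_pairs.tsv"),
    tsv(res$target_pairs, "target_pairs.tsv"))
  export_network(res$network, out_dir, format = c("tsv", "graphml"))
  files <- c(files, "nodes.tsv", "edges.tsv", "network.graphml")
  if (!is.null(res$trait_cor)) {
    files <- c(files, tsv(res$trait_cor, "trait_correlations.tsv"))
  }
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, "summary.json", "cohort")
  jsonlite::write_json(list(files = files, seed = config$synth$seed),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}

#' Median triplet precision and recall over replicate cohorts
#'
#' Repeats the full chain (generate -> DMRs -> differential screens ->
#' mapping -> network) over `n_seeds` seeds derived from `base_seed` and
#' returns the per-seed recovery scores with their medians.
#'
#' @param config A [synth_config()]; its seed field is replaced per
#'   replicate by `base_seed + i`.
#' @param pipeline A [pipeline_config()] template (its `synth` field is
#'   overwritten each replicate).
#' @param n_seeds Number of replicate cohorts.
#' @param base_seed Base for per-replicate seeds.
#' @return List with `per_seed` (data frame of precision/recall) and
#'   `median_precision`, `median_recall`.
#' @export
recovery_experiment <- function(config, pipeline = NULL, n_seeds = 25,
                                base_seed = 1000) {
  if (is.null(pipeline)) pipeline <- pipeline_config(synth = config)
  rows <- lapply(seq_len(n_seeds), function(i) {
    cfg_i <- config
    cfg_i$seed <- as.integer(base_seed + i)
    pl <- pipeline
    pl$synth <- cfg_i
    bundle <- generate_cohort(cfg_i)
    res <- analyze_cohort(bundle, pl)
    data.frame(seed = cfg_i$seed,
               precision = res$recovery$precision,
               recall = res$recovery$recall,
               n_recovered = res$recovery$n_recovered)
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       median_precision = median(per_seed$precision, na.rm = TRUE),
       median_recall = median(per_seed$recall, na.rm = TRUE))
}
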