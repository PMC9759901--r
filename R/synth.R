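#' Configuration for the synthetic cohort generator
#'
#' Assembles and validates the parameters of a two-group synthetic cohort
#' with planted DMR -> miRNA -> mRNA regulatory triplets.  Defaults mirror
#' a small sequencing cohort (5 cases vs 5 controls) with moderate
#' bisulfite depth and million-read expression libraries.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param n_case,n_control Samples per group.
#' @param n_chroms,chrom_length_bp Number and length of synthetic
#'   chromosomes on which miRNA loci (and hence promoters and CpGs) are
#'   placed.
#' @param n_mirnas,n_mrnas Number of miRNA and mRNA features.
#' @param n_cpg_per_promoter CpG sites simulated inside each miRNA
#'   promoter.
#' @param n_triplets Number of planted regulatory chains
#'   (promoter DMR -> miRNA -> target mRNA).  Must not exceed
#'   `min(n_mirnas, n_mrnas)`.
#' @param meth_base Baseline methylation level of every CpG, in (0,1).
#' @param meth_delta Group difference in methylation level planted at
#'   triplet promoters (case minus control is `-meth_delta` for a
#'   hypomethylated chain).  `meth_base` plus/minus `meth_delta` must stay
#'   in \[0,1\].
#' @param coverage_mean Mean per-sample bisulfite depth (Poisson).
#' @param bb_overdispersion Beta-binomial overdispersion rho in \[0,1);
#'   0 gives pure binomial counts.
#' @param expr_log2fc Planted expression effect: the case/control log2
#'   fold change applied to triplet miRNAs (and, with opposite sign, to
#'   their target mRNAs).
#' @param nb_dispersion Negative-binomial dispersion of expression counts
#'   (`size = 1/nb_dispersion`); 0 gives Poisson counts.
#' @param library_size_mean Mean sequencing library size per sample;
#'   realized sizes are log-normal around it.
#' @param utr_length_bp Length of each simulated 3'UTR.
#' @param error_rate_p0 Bisulfite non-conversion/error rate: the null
#'   methylation proportion a downstream site caller should assume.
#' @param upstream_bp Promoter length used when placing promoter CpGs
#'   (strand-aware window upstream of each miRNA TSS).
#' @param prop_hyper Fraction of planted triplets that follow the
#'   hypermethylated chain (hyper promoter, down miRNA, up mRNA); the
#'   rest follow the hypomethylated chain (hypo, up, down).
#' @param gensini_r Target correlation between the Gensini severity score
#'   and the anchor variable of the first planted triplet.
#' @param gensini_anchor Whether Gensini is anchored to the first planted
#'   miRNA's log2 expression (`"mirna"`) or to the first planted
#'   promoter's methylation level (`"methylation"`).
#'
#' @return A validated `synth_config` list.
#' @seealso [generate_cohort()]
#' @export
synth_config <- function(seed = 1L,
                         n_case = 5L, n_control = 5L,
                         n_chroms = 2L, chrom_length_bp = 1e6L,
                         n_mirnas = 50L, n_mrnas = 200L,
                         n_cpg_per_promoter = 10L, n_triplets = 5L,
                         meth_base = 0.5, meth_delta = 0.4,
                         coverage_mean = 30L, bb_overdispersion = 0.05,
                         expr_log2fc = 2, nb_dispersion = 0.05,
                         library_size_mean = 1e6L, utr_length_bp = 500L,
                         error_rate_p0 = 0.005, upstream_bp = 2000L,
                         prop_hyper = 0,
                         gensini_r = 0.834,
                         gensini_anchor = c("mirna", "methylation")) {
  cfg <- list(seed = as.integer(seed),
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_chroms = as.integer(n_chroms),
              chrom_length_bp = as.integer(chrom_length_bp),
              n_mirnas = as.integer(n_mirnas), n_mrnas = as.integer(n_mrnas),
              n_cpg_per_promoter = as.integer(n_cpg_per_promoter),
              n_triplets = as.integer(n_triplets),
              meth_base = meth_base, meth_delta = meth_delta,
              coverage_mean = coverage_mean,
              bb_overdispersion = bb_overdispersion,
              expr_log2fc = expr_log2fc, nb_dispersion = nb_dispersion,
              library_size_mean = library_size_mean,
              utr_length_bp = as.integer(utr_length_bp),
              error_rate_p0 = error_rate_p0,
              upstream_bp = as.integer(upstream_bp),
              prop_hyper = prop_hyper,
              gensini_r = gensini_r,
              gensini_anchor = match.arg(gensini_anchor))

  .cfg_check <- function(ok, field, why) {
    if (!isTRUE(ok)) {
      stop(sprintf("invalid synth_config field '%s': %s", field, why),
           call. = FALSE)
    }
  }
  .cfg_check(cfg$n_case >= 1L, "n_case", "must be >= 1")
  .cfg_check(cfg$n_control >= 1L, "n_control", "must be >= 1")
  .cfg_check(cfg$n_chroms >= 1L, "n_chroms", "must be >= 1")
  .cfg_check(cfg$chrom_length_bp >= 1L, "chrom_length_bp", "must be >= 1")
  .cfg_check(cfg$n_mirnas >= 1L, "n_mirnas", "must be >= 1")
  .cfg_check(cfg$n_mrnas >= 1L, "n_mrnas", "must be >= 1")
  .cfg_check(cfg$n_cpg_per_promoter >= 1L, "n_cpg_per_promoter",
             "must be >= 1")
  .cfg_check(cfg$n_triplets >= 0L, "n_triplets", "must be >= 0")
  .cfg_check(cfg$n_triplets <= min(cfg$n_mirnas, cfg$n_mrnas), "n_triplets",
             "must not exceed min(n_mirnas, n_mrnas)")
  .cfg_check(cfg$meth_base > 0 && cfg$meth_base < 1, "meth_base",
             "must lie in (0,1)")
  .cfg_check(cfg$meth_delta >= 0, "meth_delta", "must be >= 0")
  .cfg_check(cfg$meth_base + cfg$meth_delta <= 1 &&
               cfg$meth_base - cfg$meth_delta >= 0, "meth_delta",
             "meth_base +/- meth_delta must stay within [0,1]")
  .cfg_check(cfg$coverage_mean > 0, "coverage_mean", "must be positive")
  .cfg_check(cfg$bb_overdispersion >= 0 && cfg$bb_overdispersion < 1,
             "bb_overdispersion", "must lie in [0,1)")
  .cfg_check(cfg$nb_dispersion >= 0, "nb_dispersion", "must be >= 0")
  .cfg_check(cfg$library_size_mean > 0, "library_size_mean",
             "must be positive")
  .cfg_check(cfg$utr_length_bp >= 30L, "utr_length_bp", "must be >= 30")
  .cfg_check(cfg$error_rate_p0 > 0 && cfg$error_rate_p0 < 1,
             "error_rate_p0", "must lie in (0,1)")
  .cfg_check(cfg$upstream_bp >= 1L, "upstream_bp", "must be >= 1")
  .cfg_check(cfg$prop_hyper >= 0 && cfg$prop_hyper <= 1, "prop_hyper",
             "must lie in [0,1]")
  .cfg_check(cfg$gensini_r >= -1 && cfg$gensini_r <= 1, "gensini_r",
             "must lie in [-1,1]")

  # promoters of adjacent loci must not overlap so each CpG belongs to
  # exactly one miRNA promoter
  per_chrom <- ceiling(cfg$n_mirnas / cfg$n_chroms)
  spacing <- cfg$chrom_length_bp %/% (per_chrom + 1L)
  .cfg_check(spacing >= 2L * cfg$upstream_bp + 100L, "chrom_length_bp",
             sprintf(paste0("too short to place %d miRNA loci per ",
                            "chromosome with disjoint %d bp promoters"),
                     per_chrom, cfg$upstream_bp))

  structure(cfg, class = "synth_config")
}

# run `expr` with a private, seeded RNG stream and restore the caller's
.with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.rand_seq <- function(n, len, alphabet) {
  vapply(seq_len(n),
         function(i) paste(sample(alphabet, len, replace = TRUE),
                           collapse = ""),
         character(1))
}

# mutate away chance occurrences of forbidden k-mers without touching an
# optional protected site; bounded point-mutation loop
.scrub_sites <- function(utr, forbidden, keep = NULL) {
  for (iter in seq_len(200L)) {
    hit_at <- NA_integer_
    hit_len <- 0L
    for (site in forbidden) {
      at <- regexpr(site, utr, fixed = TRUE)[1]
      if (at > 0) {
        if (!is.null(keep)) {
          kp <- regexpr(keep, utr, fixed = TRUE)[1]
          if (kp > 0 && at < kp + nchar(keep) && kp < at + nchar(site)) {
            # overlapping the protected site: mutate just outside it
            next
          }
        }
        hit_at <- at
        hit_len <- nchar(site)
        break
      }
    }
    if (is.na(hit_at)) return(utr)
    mid <- hit_at + hit_len %/% 2L
    old <- substr(utr, mid, mid)
    substr(utr, mid, mid) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  utr
}

# beta-binomial draws with mean mu and overdispersion rho (rho = 0 ->
# binomial); vectorized over size/mu
.rbetabinom <- function(size, mu, rho) {
  mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
  if (rho <= 0) {
    return(rbinom(length(size), size, mu))
  }
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  p <- rbeta(length(size), a, b)
  rbinom(length(size), size, p)
}

# NB draws with mean mu and dispersion phi (var = mu + phi mu^2)
.rnbinom_mu <- function(mu, phi) {
  if (phi <= 0) {
    return(rpois(length(mu), mu))
  }
  rnbinom(length(mu), size = 1 / phi, mu = mu)
}

#' Generate a complete synthetic cohort
#'
#' Draws a seeded two-group cohort: per-sample CpG methylated /
#' unmethylated counts (beta-binomial over Poisson coverage), miRNA and
#' mRNA count matrices (negative binomial with log-normal library sizes),
#' miRNA TSS annotation, miRNA and 3'UTR sequences with planted seed-match
#' sites for true targets, a clinical trait table, and the ground truth of
#' every planted regulatory triplet.
#'
#' Planted chains are sign-consistent: a hypomethylated promoter carries
#' an upregulated miRNA whose target mRNA is downregulated in cases (and
#' the mirror pattern for hypermethylated chains).  Non-planted features
#' are drawn from the null with no group effect.  The Gensini severity
#' score is generated with a configurable correlation to the first
#' planted triplet (see [synth_config()]); with no planted triplets it is
#' drawn from per-group normals.
#'
#' @param config A [synth_config()].
#' @return A `cohort_bundle` list with elements `samples`, `cpg` (a
#'   [cpg_site_table()]), `mirna_counts`, `mrna_counts`,
#'   `mirna_annotation`, `mrna_annotation`, `mirna_seqs`, `utr_seqs`,
#'   `clinical`, `chrom_lengths`, `truth` and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop("config must be created by synth_config()", call. = FALSE)
  }
  .with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  n_s <- cfg$n_case + cfg$n_control
  samples <- data.frame(
    sample_id = c(sprintf("A%d", seq_len(cfg$n_case)),
                  sprintf("N%d", seq_len(cfg$n_control))),
    group = c(rep("case", cfg$n_case), rep("control", cfg$n_control)),
    stringsAsFactors = FALSE)

  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  chrom_lengths <- setNames(rep(cfg$chrom_length_bp, cfg$n_chroms), chroms)

  ## --- miRNA loci: evenly spaced TSSs, random strands -----------------
  mir_ids <- sprintf("mir-%03d", seq_len(cfg$n_mirnas))
  chrom_of <- chroms[((seq_len(cfg$n_mirnas) - 1L) %% cfg$n_chroms) + 1L]
  idx_on_chrom <- ave(seq_len(cfg$n_mirnas), chrom_of, FUN = seq_along)
  per_chrom <- ceiling(cfg$n_mirnas / cfg$n_chroms)
  spacing <- cfg$chrom_length_bp %/% (per_chrom + 1L)
  strand <- sample(c("+", "-"), cfg$n_mirnas, replace = TRUE)
  # keep the strand-aware promoter window inside the chromosome
  tss <- idx_on_chrom * spacing
  mirna_annotation <- data.frame(mirna_id = mir_ids, chrom = chrom_of,
                                 tss = as.integer(tss), strand = strand,
                                 stringsAsFactors = FALSE)

  promoters <- promoter_region(mirna_annotation$tss,
                               mirna_annotation$strand,
                               mirna_annotation$chrom,
                               chrom_lengths[mirna_annotation$chrom],
                               upstream_bp = cfg$upstream_bp)
  promoters$mirna_id <- mir_ids

  ## --- planted triplets ----------------------------------------------
  mrna_ids <- sprintf("gene-%04d", seq_len(cfg$n_mrnas))
  n_t <- cfg$n_triplets
  if (n_t > 0L) {
    t_mirna <- sample(mir_ids, n_t)
    t_mrna <- sample(mrna_ids, n_t)
    n_hyper <- round(cfg$prop_hyper * n_t)
    meth_dir <- c(rep("hyper", n_hyper), rep("hypo", n_t - n_hyper))
  } else {
    t_mirna <- character(0)
    t_mrna <- character(0)
    meth_dir <- character(0)
  }

  ## --- CpG sites: n_cpg_per_promoter evenly spaced per promoter ------
  n_cpg <- cfg$n_cpg_per_promoter
  rel <- round(seq(0.05, 0.95, length.out = n_cpg) * (cfg$upstream_bp - 1L))
  site_list <- lapply(seq_len(cfg$n_mirnas), function(i) {
    data.frame(chrom = promoters$chrom[i],
               pos = as.integer(promoters$start[i] + rel),
               strand = "+",
               mirna_id = mir_ids[i],
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_list)
  ord <- order(match(sites$chrom, chroms), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  n_sites <- nrow(sites)

  # per-site per-group mean methylation
  mu_control <- rep(cfg$meth_base, n_sites)
  mu_case <- rep(cfg$meth_base, n_sites)
  if (n_t > 0L) {
    for (k in seq_len(n_t)) {
      in_prom <- sites$mirna_id == t_mirna[k]
      shift <- if (meth_dir[k] == "hypo") -cfg$meth_delta else cfg$meth_delta
      mu_case[in_prom] <- cfg$meth_base + shift
    }
  }

  coverage <- matrix(rpois(n_sites * n_s, cfg$coverage_mean),
                     nrow = n_sites, ncol = n_s)
  m_counts <- matrix(0L, n_sites, n_s)
  for (j in seq_len(n_s)) {
    mu <- if (samples$group[j] == "case") mu_case else mu_control
    m_counts[, j] <- .rbetabinom(coverage[, j], mu, cfg$bb_overdispersion)
  }
  u_counts <- coverage - m_counts
  colnames(m_counts) <- colnames(u_counts) <- samples$sample_id

  cpg <- cpg_site_table(sites[, c("chrom", "pos", "strand")],
                        m_counts, u_counts, samples)

  ## --- expression ------------------------------------------------------
  lib_sd <- 0.2
  lib_mirna <- rlnorm(n_s, log(cfg$library_size_mean) - lib_sd^2 / 2, lib_sd)
  lib_mrna <- rlnorm(n_s, log(cfg$library_size_mean) - lib_sd^2 / 2, lib_sd)

  draw_counts <- function(ids, base_meanlog, lib, planted, planted_dir) {
    w <- rlnorm(length(ids), base_meanlog, 1)
    w <- w / sum(w) * 1e6  # baseline abundances on a counts-per-million scale
    fc <- matrix(1, length(ids), n_s)
    if (length(planted)) {
      for (k in seq_along(planted)) {
        i <- match(planted[k], ids)
        eff <- 2^(if (planted_dir[k] == "up") cfg$expr_log2fc
                  else -cfg$expr_log2fc)
        fc[i, samples$group == "case"] <- eff
      }
    }
    mu <- (w * fc) * rep(lib / 1e6, each = length(ids))
    cnt <- matrix(.rnbinom_mu(as.vector(mu), cfg$nb_dispersion),
                  nrow = length(ids),
                  dimnames = list(ids, samples$sample_id))
    storage.mode(cnt) <- "integer"
    cnt
  }

  mirna_dir <- ifelse(meth_dir == "hypo", "up", "down")
  mrna_dir <- ifelse(meth_dir == "hypo", "down", "up")
  mirna_counts <- draw_counts(mir_ids, log(50), lib_mirna, t_mirna, mirna_dir)
  mrna_counts <- draw_counts(mrna_ids, log(30), lib_mrna, t_mrna, mrna_dir)

  mrna_annotation <- data.frame(
    mrna_id = mrna_ids,
    exon_length_bp = as.integer(round(runif(cfg$n_mrnas, 500, 5000))),
    stringsAsFactors = FALSE)

  ## --- sequences -------------------------------------------------------
  mirna_seqs <- setNames(.rand_seq(cfg$n_mirnas, 22L,
                                   c("A", "C", "G", "U")), mir_ids)
  utr_seqs <- setNames(.rand_seq(cfg$n_mrnas, cfg$utr_length_bp,
                                 c("A", "C", "G", "T")), mrna_ids)
  if (n_t > 0L) {
    planted_sites <- vapply(t_mirna, function(id) {
      .seed_site(mirna_seqs[[id]], "7mer-m8")
    }, character(1))
    # the truth table must be exhaustive for planted miRNAs: scrub chance
    # occurrences of a planted seed site from every UTR that is not its
    # true target, then plant one guaranteed site per true pair
    for (j in seq_along(utr_seqs)) {
      forbidden <- planted_sites[t_mrna != names(utr_seqs)[j]]
      if (length(forbidden)) {
        utr_seqs[[j]] <- .scrub_sites(utr_seqs[[j]], forbidden)
      }
    }
    for (k in seq_len(n_t)) {
      site <- planted_sites[k]
      utr <- utr_seqs[[t_mrna[k]]]
      at <- sample.int(nchar(utr) - nchar(site) + 1L, 1L)
      substr(utr, at, at + nchar(site) - 1L) <- site
      forbidden <- planted_sites[t_mrna != t_mrna[k]]
      if (length(forbidden)) utr <- .scrub_sites(utr, forbidden, keep = site)
      utr_seqs[[t_mrna[k]]] <- utr
    }
  }

  ## --- truth -----------------------------------------------------------
  if (n_t > 0L) {
    prom_idx <- match(t_mirna, promoters$mirna_id)
    dmr_start <- integer(n_t)
    dmr_end <- integer(n_t)
    for (k in seq_len(n_t)) {
      ps <- sites$pos[sites$mirna_id == t_mirna[k]]
      dmr_start[k] <- min(ps)
      dmr_end[k] <- max(ps) + 1L
    }
    truth_triplets <- data.frame(
      dmr_chrom = promoters$chrom[prom_idx],
      dmr_start = dmr_start, dmr_end = dmr_end,
      mirna_id = t_mirna, mrna_id = t_mrna,
      meth_direction = meth_dir,
      mirna_direction = mirna_dir,
      mrna_direction = mrna_dir,
      meth_delta = cfg$meth_delta,
      expr_log2fc = cfg$expr_log2fc,
      stringsAsFactors = FALSE)
  } else {
    truth_triplets <- data.frame(
      dmr_chrom = character(0), dmr_start = integer(0),
      dmr_end = integer(0), mirna_id = character(0),
      mrna_id = character(0), meth_direction = character(0),
      mirna_direction = character(0), mrna_direction = character(0),
      meth_delta = numeric(0), expr_log2fc = numeric(0),
      stringsAsFactors = FALSE)
  }

  ## --- clinical traits -------------------------------------------------
  clinical <- .draw_clinical(cfg, samples, truth_triplets, cpg,
                             mirna_counts)

  structure(list(config = cfg, samples = samples, cpg = cpg,
                 mirna_counts = mirna_counts, mrna_counts = mrna_counts,
                 mirna_annotation = mirna_annotation,
                 mrna_annotation = mrna_annotation,
                 mirna_seqs = mirna_seqs, utr_seqs = utr_seqs,
                 clinical = clinical, chrom_lengths = chrom_lengths,
                 truth = list(triplets = truth_triplets)),
            class = "cohort_bundle")
}

# per-group (control, case) moments loosely modeled on a small
# angiography cohort; units: years, mmHg, mmol/L, Gensini points
.trait_params <- list(
  age     = c(57.0, 8.15, 66.4, 5.32),
  SBP     = c(125, 10, 138, 15),
  DBP     = c(78, 8, 85, 10),
  FPG     = c(5.2, 0.6, 6.9, 1.8),
  TC      = c(2.75, 0.48, 3.97, 0.82),
  TG      = c(1.26, 1.35, 2.33, 1.47),
  LDL_C   = c(2.55, 0.51, 3.07, 0.97),
  HDL_C   = c(1.39, 0.42, 1.02, 0.16))

.draw_clinical <- function(cfg, samples, truth, cpg, mirna_counts) {
  n_s <- nrow(samples)
  is_case <- samples$group == "case"
  out <- data.frame(sample_id = samples$sample_id, group = samples$group,
                    stringsAsFactors = FALSE)
  for (nm in names(.trait_params)) {
    pp <- .trait_params[[nm]]
    v <- ifelse(is_case, rnorm(n_s, pp[3], pp[4]), rnorm(n_s, pp[1], pp[2]))
    out[[nm]] <- pmax(v, 0.05)
  }
  gensini_ctrl <- c(1.3, 1.15)
  gensini_case <- c(59.6, 8.0)
  if (nrow(truth) > 0L) {
    if (cfg$gensini_anchor == "mirna") {
      anchor <- log2(rpm_normalize(mirna_counts)[truth$mirna_id[1], ] + 1)
    } else {
      dmr1 <- data.frame(chrom = truth$dmr_chrom[1],
                         start = truth$dmr_start[1],
                         end = truth$dmr_end[1])
      anchor <- as.vector(dmr_methylation_levels(dmr1, cpg))
    }
    z <- as.vector(scale(anchor))
    if (any(!is.finite(z))) z <- rnorm(n_s)
    r <- cfg$gensini_r
    gz <- r * z + sqrt(max(0, 1 - r^2)) * rnorm(n_s)
    mix_mean <- mean(c(gensini_ctrl[1], gensini_case[1]))
    mix_sd <- sqrt(mean(c(gensini_ctrl[2], gensini_case[2])^2) +
                     (gensini_case[1] - gensini_ctrl[1])^2 / 4)
    out$Gensini <- pmax(mix_mean + mix_sd * gz, 0)
  } else {
    out$Gensini <- pmax(ifelse(is_case,
                               rnorm(n_s, gensini_case[1], gensini_case[2]),
                               rnorm(n_s, gensini_ctrl[1], gensini_ctrl[2])),
                        0)
  }
  out
}

#' Write a synthetic cohort bundle to plain-text files
#'
#' Serializes every component of a [generate_cohort()] bundle to a
#' directory of standard plain-text formats: CpG counts as a BED-like TSV
#' (chrom, 0-based position, strand, per-sample m/u columns), count
#' matrices and annotation as TSV, the miRNA TSS annotation as BED6,
#' sequences as FASTA, the truth and a file manifest as JSON.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a manifest data frame with one row per file
#'   (`file`, `rows`).
#' @seealso [read_bundle()]
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  tsv <- function(x, file, row.names = FALSE) {
    path <- file.path(dir, file)
    tryCatch(write.table(x, path, sep = "\t", quote = FALSE,
                         row.names = row.names, col.names = TRUE),
             error = function(e) stop("cannot write ", path, ": ",
                                      conditionMessage(e), call. = FALSE))
    nrow(x)
  }
  manifest <- list()

  manifest$samples.tsv <- tsv(bundle$samples, "samples.tsv")

  cpg <- bundle$cpg
  cpg_df <- cpg$sites
  for (s in bundle$samples$sample_id) {
    cpg_df[[paste0("m_", s)]] <- cpg$m[, s]
    cpg_df[[paste0("u_", s)]] <- cpg$u[, s]
  }
  manifest$cpg_counts.tsv <- tsv(cpg_df, "cpg_counts.tsv")

  mir_cnt <- data.frame(feature_id = rownames(bundle$mirna_counts),
                        bundle$mirna_counts, check.names = FALSE)
  manifest$mirna_counts.tsv <- tsv(mir_cnt, "mirna_counts.tsv")
  mrna_cnt <- data.frame(feature_id = rownames(bundle$mrna_counts),
                         bundle$mrna_counts, check.names = FALSE)
  manifest$mrna_counts.tsv <- tsv(mrna_cnt, "mrna_counts.tsv")

  ann <- bundle$mirna_annotation
  bed <- data.frame(chrom = ann$chrom, start = ann$tss,
                    end = ann$tss + 1L, name = ann$mirna_id,
                    score = rep(0L, nrow(ann)), strand = ann$strand)
  path <- file.path(dir, "mirna_annotation.bed")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  manifest$mirna_annotation.bed <- nrow(bed)

  manifest$mrna_annotation.tsv <- tsv(bundle$mrna_annotation,
                                      "mrna_annotation.tsv")
  manifest$clinical.tsv <- tsv(bundle$clinical, "clinical.tsv")
  manifest$chrom_lengths.tsv <- tsv(
    data.frame(chrom = names(bundle$chrom_lengths),
               length_bp = as.integer(bundle$chrom_lengths)),
    "chrom_lengths.tsv")

  if (length(bundle$mirna_seqs)) {
    Biostrings::writeXStringSet(
      Biostrings::RNAStringSet(bundle$mirna_seqs),
      file.path(dir, "mirna.fa"))
  } else {
    file.create(file.path(dir, "mirna.fa"))
  }
  manifest$mirna.fa <- length(bundle$mirna_seqs)
  if (length(bundle$utr_seqs)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(bundle$utr_seqs),
      file.path(dir, "utr.fa"))
  } else {
    file.create(file.path(dir, "utr.fa"))
  }
  manifest$utr.fa <- length(bundle$utr_seqs)

  jsonlite::write_json(bundle$truth$triplets,
                       file.path(dir, "truth.json"), digits = NA)
  manifest$truth.json <- nrow(bundle$truth$triplets)
  jsonlite::write_json(bundle$config[setdiff(names(bundle$config), NULL)],
                       file.path(dir, "synth_config.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$synth_config.json <- 1L

  mf <- data.frame(file = names(manifest),
                   rows = as.integer(unlist(manifest)),
                   stringsAsFactors = FALSE)
  jsonlite::write_json(mf, file.path(dir, "manifest.json"), digits = NA)
  invisible(mf)
}

#' Read a cohort bundle written by [write_bundle()]
#'
#' @param dir Directory containing the bundle files.
#' @return A `cohort_bundle` (the `config` element is restored from
#'   `synth_config.json`).
#' @export
read_bundle <- function(dir) {
  rd <- function(file, ...) read.delim(file.path(dir, file),
                                       stringsAsFactors = FALSE, ...)
  samples <- rd("samples.tsv")
  cpg_df <- rd("cpg_counts.tsv")
  m <- as.matrix(cpg_df[, paste0("m_", samples$sample_id), drop = FALSE])
  u <- as.matrix(cpg_df[, paste0("u_", samples$sample_id), drop = FALSE])
  colnames(m) <- colnames(u) <- samples$sample_id
  cpg <- cpg_site_table(cpg_df[, c("chrom", "pos", "strand")], m, u,
                        samples)

  read_counts <- function(file) {
    df <- rd(file, check.names = FALSE)
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- df$feature_id
    storage.mode(mat) <- "integer"
    mat
  }
  mirna_counts <- read_counts("mirna_counts.tsv")
  mrna_counts <- read_counts("mrna_counts.tsv")

  bed <- read.delim(file.path(dir, "mirna_annotation.bed"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "name",
                                  "score", "strand"))
  mirna_annotation <- data.frame(mirna_id = bed$name, chrom = bed$chrom,
                                 tss = bed$start, strand = bed$strand,
                                 stringsAsFactors = FALSE)

  read_fasta <- function(file, rna = FALSE) {
    path <- file.path(dir, file)
    if (file.size(path) == 0) return(setNames(character(0), character(0)))
    ss <- if (rna) Biostrings::readRNAStringSet(path)
          else Biostrings::readDNAStringSet(path)
    setNames(as.character(ss), names(ss))
  }

  cl <- rd("chrom_lengths.tsv")
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  if (length(truth) == 0) {
    truth <- data.frame(dmr_chrom = character(0), dmr_start = integer(0),
                        dmr_end = integer(0), mirna_id = character(0),
                        mrna_id = character(0),
                        meth_direction = character(0),
                        mirna_direction = character(0),
                        mrna_direction = character(0),
                        meth_delta = numeric(0), expr_log2fc = numeric(0),
                        stringsAsFactors = FALSE)
  }
  cfg <- jsonlite::read_json(file.path(dir, "synth_config.json"),
                             simplifyVector = TRUE)

  structure(list(config = do.call(synth_config, cfg), samples = samples,
                 cpg = cpg, mirna_counts = mirna_counts,
                 mrna_counts = mrna_counts,
                 mirna_annotation = mirna_annotation,
                 mrna_annotation = rd("mrna_annotation.tsv"),
                 mirna_seqs = read_fasta("mirna.fa", rna = TRUE),
                 utr_seqs = read_fasta("utr.fa"),
                 clinical = rd("clinical.tsv"),
                 chrom_lengths = setNames(cl$length_bp, cl$chrom),
                 truth = list(triplets = truth)),
            class = "cohort_bundle")
}
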