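#' Configuration for the synthetic methylation-study generator
#'
#' Describes a multi-dataset, multi-tissue methylation study with planted
#' ground truth. Age-linear signal is planted in M-value space (the scale on
#' which clocks are trained); beta-values are obtained by the inverse logit2
#' transform, so they are strictly inside (0, 1) before missingness.
#'
#' Clock CpG categories:
#' * shared: age slope present in every tissue and both sexes;
#' * tissue-specific: age slope only in the CpG's native tissue, and
#'   inflated inter-individual noise (`nonnative_noise_sd`) elsewhere,
#'   emulating tissue-specific regulatory variability;
#' * sex-modulated: age slope present in females only.
#'
#' @param tissues Character vector of MeSH-style tissue codes.
#' @param datasets_per_tissue,samples_per_dataset Integers.
#' @param age_range Numeric length-2; ages are drawn uniformly inside it
#'   (open interval), default `c(20, 85)` matching the modelling window.
#' @param n_background_cpgs Number of CpGs without age signal.
#' @param n_shared_clock_cpgs,n_tissue_specific_clock_cpgs,n_sex_modulated_cpgs
#'   Clock CpG counts (tissue-specific count is per tissue).
#' @param slope_range Absolute M-units per year for planted slopes; signs
#'   are random.
#' @param baseline_range M-units; baselines are clamped so beta stays in
#'   (0.01, 0.99) over the age range at +/- 3 total noise SD.
#' @param batch_sd SD of dataset-level intercepts (M-units).
#' @param noise_sd Residual SD (M-units).
#' @param dataset_age_span Length-2: range of per-dataset age-window
#'   widths (years). Each dataset samples its ages from a random window
#'   of that width inside `age_range`, emulating the heterogeneous age
#'   composition of real cohorts; this induces between-dataset variance
#'   in clock scores, the structure the random-intercept comparison
#'   models are built for.
#' @param dataset_noise_mult Length-2: range of per-dataset multipliers
#'   on `noise_sd` (technical quality differences between cohorts).
#' @param dataset_size_jitter Relative half-width of the per-dataset
#'   sample-count jitter: each dataset's size is uniform in
#'   `samples_per_dataset * (1 +/- jitter)` (minimum 4), so cohort sizes
#'   vary as they do on public repositories and the log-sample-size
#'   covariate of the comparison models is never degenerate.
#' @param nonnative_noise_sd Residual SD of tissue-specific CpGs outside
#'   their native tissue; default `2 * noise_sd`.
#' @param missing_rate Fraction of entries set missing uniformly at random.
#' @param n_xy_probes,n_rs_probes Counts of sex-chromosome and SNP-control
#'   probes (no age signal), present to exercise the probe filters.
#' @param seed Integer master seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(tissues = c("A12.207.152", "A08.186.211.730",
                                         "A03.620"),
                             datasets_per_tissue = 4,
                             samples_per_dataset = 120,
                             age_range = c(20, 85),
                             n_background_cpgs = 100,
                             n_shared_clock_cpgs = 6,
                             n_tissue_specific_clock_cpgs = 3,
                             n_sex_modulated_cpgs = 0,
                             slope_range = c(0.04, 0.08),
                             baseline_range = c(-2, 2),
                             batch_sd = 0.2,
                             noise_sd = 0.5,
                             dataset_age_span = c(30, 65),
                             dataset_noise_mult = c(0.7, 1.4),
                             dataset_size_jitter = 0.3,
                             nonnative_noise_sd = NULL,
                             missing_rate = 0.01,
                             n_xy_probes = 10,
                             n_rs_probes = 5,
                             seed = 1L) {
  cfg <- list(tissues = tissues, datasets_per_tissue = datasets_per_tissue,
              samples_per_dataset = samples_per_dataset,
              age_range = age_range,
              n_background_cpgs = n_background_cpgs,
              n_shared_clock_cpgs = n_shared_clock_cpgs,
              n_tissue_specific_clock_cpgs = n_tissue_specific_clock_cpgs,
              n_sex_modulated_cpgs = n_sex_modulated_cpgs,
              slope_range = slope_range, baseline_range = baseline_range,
              batch_sd = batch_sd, noise_sd = noise_sd,
              dataset_age_span = dataset_age_span,
              dataset_noise_mult = dataset_noise_mult,
              dataset_size_jitter = dataset_size_jitter,
              nonnative_noise_sd = nonnative_noise_sd %||% (2 * noise_sd),
              missing_rate = missing_rate, n_xy_probes = n_xy_probes,
              n_rs_probes = n_rs_probes, seed = as.integer(seed))
  counts <- c(cfg$datasets_per_tissue, cfg$samples_per_dataset,
              cfg$n_background_cpgs, cfg$n_shared_clock_cpgs,
              cfg$n_tissue_specific_clock_cpgs, cfg$n_sex_modulated_cpgs,
              cfg$n_xy_probes, cfg$n_rs_probes)
  if (any(counts < 0)) cb_stop_code("generator counts must be >= 0")
  if (cfg$noise_sd < 0 || cfg$batch_sd < 0) {
    cb_stop_code("noise_sd and batch_sd must be >= 0")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    cb_stop_code("missing_rate must be in [0, 1)")
  }
  if (cfg$dataset_size_jitter < 0 || cfg$dataset_size_jitter >= 1) {
    cb_stop_code("dataset_size_jitter must be in [0, 1)")
  }
  if (cfg$age_range[1] <= 0 || cfg$age_range[2] > 120 ||
      diff(cfg$age_range) <= 0) {
    cb_stop_code("age_range must be an increasing interval within (0, 120)")
  }
  class(cfg) <- "generator_config"
  cfg
}

inv_logit2 <- function(m) 1 / (1 + 2^(-m))

#' Simulate a multi-dataset methylation study with known ground truth
#'
#' For clock CpG `j` and sample `i` in dataset `g`, the M-value is
#' `M_ij = b_j + s_j(tissue_i, sex_i) * age_i + u_jg + e_ij` with
#' `u ~ N(0, batch_sd^2)` and `e ~ N(0, noise_sd^2)`; background,
#' sex-chromosome and SNP-control probes have zero slope. Beta-values are
#' `2^M / (1 + 2^M)`. Ages are uniform on the configured range, sexes
#' balanced Bernoulli(1/2) and missing entries dropped uniformly at random.
#'
#' One RNG substream is derived per dataset from the master seed, so adding
#' a dataset does not perturb existing ones.
#'
#' @param config A [generator_config()].
#' @return A list with elements `study` (a [methylation_study()]) and
#'   `truth` (planted CpG ids per category, slopes, baselines and the
#'   dataset-level batch intercepts).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_t <- length(config$tissues)
  if (n_t < 1 || config$datasets_per_tissue < 1) {
    cb_stop_code("need at least one tissue and one dataset per tissue")
  }

  # --- probe universe (drawn from the master seed) ----------------------
  ids <- character(0)
  category <- character(0)
  native <- character(0)
  mk <- function(prefix, n) if (n > 0) sprintf("%s%05d", prefix, seq_len(n))
                            else character(0)
  add <- function(id, cat, nat) {
    ids <<- c(ids, id)
    category <<- c(category, rep(cat, length(id)))
    native <<- c(native, rep(nat, length(id)))
  }
  add(mk("cgBG", config$n_background_cpgs), "background", NA)
  add(mk("cgSH", config$n_shared_clock_cpgs), "shared", NA)
  for (t in seq_len(n_t)) {
    add(sprintf("cgT%d_%05d", t,
                seq_len(config$n_tissue_specific_clock_cpgs)),
        "tissue_specific", config$tissues[t])
  }
  add(mk("cgFX", config$n_sex_modulated_cpgs), "sex_modulated", NA)
  add(mk("cgXY", config$n_xy_probes), "xy", NA)
  add(mk("rsCT", config$n_rs_probes), "rs", NA)
  p <- length(ids)
  is_clock <- category %in% c("shared", "tissue_specific", "sex_modulated")

  globals <- with_seed(config$seed, {
    slope <- numeric(p)
    slope[is_clock] <- stats::runif(sum(is_clock), config$slope_range[1],
                                    config$slope_range[2]) *
      sample(c(-1, 1), sum(is_clock), replace = TRUE)
    chrom <- sample(as.character(1:22), p, replace = TRUE)
    if (config$n_xy_probes > 0) {
      chrom[category == "xy"] <- sample(c("X", "Y"), config$n_xy_probes,
                                        replace = TRUE)
    }
    # gene annotation: clock CpGs map to synthetic genes (two CpGs per
    # gene within a category); ~70% of background CpGs carry one gene
    genes <- character(p)
    idx_clock <- which(is_clock)
    genes[idx_clock] <- sprintf("GENE%04d", ceiling(seq_along(idx_clock) / 2))
    idx_bg <- which(category == "background")
    has_gene <- stats::runif(length(idx_bg)) < 0.7
    genes[idx_bg[has_gene]] <- sprintf("BGENE%04d", which(has_gene))
    # baselines, clamped so beta stays in (0.01, 0.99) at +/- 3 total SD
    b <- stats::runif(p, config$baseline_range[1], config$baseline_range[2])
    sig3 <- 3 * sqrt((max(config$noise_sd, config$nonnative_noise_sd) *
                        max(config$dataset_noise_mult, 1))^2 +
                       config$batch_sd^2)
    lim <- log2(0.99 / 0.01)
    span <- cbind(pmin(slope * config$age_range[1], slope * config$age_range[2]),
                  pmax(slope * config$age_range[1], slope * config$age_range[2]))
    blo <- -lim + sig3 - span[, 1]
    bhi <- lim - sig3 - span[, 2]
    mid <- (blo + bhi) / 2
    b <- ifelse(blo > bhi, mid, pmin(pmax(b, blo), bhi))
    list(slope = slope, chrom = chrom, genes = genes, baseline = b)
  })

  probes <- data.frame(
    cpg_id = ids, chromosome = globals$chrom, gene_symbols = globals$genes,
    probe_class = ifelse(category == "rs", "rs", "cg"),
    unreliable = FALSE, stringsAsFactors = FALSE)

  # --- per-dataset substreams ------------------------------------------
  gse_tab <- expand.grid(d = seq_len(config$datasets_per_tissue),
                         tissue = config$tissues, stringsAsFactors = FALSE)
  gse_tab$gse_id <- sprintf("GSE%05d",
                            10000L + 100L * match(gse_tab$tissue,
                                                  config$tissues) + gse_tab$d)
  n_per <- config$samples_per_dataset
  betas <- vector("list", nrow(gse_tab))
  sheets <- vector("list", nrow(gse_tab))
  batch <- matrix(0, p, nrow(gse_tab),
                  dimnames = list(ids, gse_tab$gse_id))
  fem_extra <- ifelse(category == "sex_modulated", globals$slope, 0)
  base_slope <- ifelse(category %in% c("shared", "tissue_specific"),
                       globals$slope, 0)

  for (k in seq_len(nrow(gse_tab))) {
    tis <- gse_tab$tissue[k]
    gse <- gse_tab$gse_id[k]
    res <- with_seed(cell_seed(config$seed, "dataset", gse), {
      n_g <- max(4L, as.integer(round(n_per *
        stats::runif(1, 1 - config$dataset_size_jitter,
                     1 + config$dataset_size_jitter))))
      span <- min(stats::runif(1, config$dataset_age_span[1],
                               config$dataset_age_span[2]),
                  diff(config$age_range))
      lo <- stats::runif(1, config$age_range[1],
                         config$age_range[2] - span)
      age <- stats::runif(n_g, lo, lo + span)
      noise_mult <- stats::runif(1, config$dataset_noise_mult[1],
                                 config$dataset_noise_mult[2])
      sex <- ifelse(stats::runif(n_g) < 0.5, "F", "M")
      u <- stats::rnorm(p, 0, config$batch_sd)
      slope_t <- base_slope
      off <- category == "tissue_specific" & native != tis
      slope_t[off] <- 0
      sd_vec <- rep(config$noise_sd * noise_mult, p)
      sd_vec[off] <- config$nonnative_noise_sd * noise_mult
      eps <- matrix(stats::rnorm(p * n_g, 0, sd_vec), p, n_g)
      m <- globals$baseline + u +
        outer(slope_t, age) + outer(fem_extra, age) *
        rep(sex == "F", each = p) + eps
      bet <- inv_logit2(m)
      if (config$missing_rate > 0) {
        bet[stats::runif(p * n_g) < config$missing_rate] <- NA_real_
      }
      list(beta = bet, age = age, sex = sex, u = u)
    })
    batch[, k] <- res$u
    betas[[k]] <- res$beta
    sheets[[k]] <- data.frame(
      sample_id = sprintf("%s_S%04d", gse, seq_along(res$age)),
      gse_id = gse, age = res$age, sex = res$sex, tissue_code = tis,
      status = "control", family_id = NA_character_,
      stringsAsFactors = FALSE)
  }

  beta <- do.call(cbind, betas)
  samples <- do.call(rbind, sheets)
  rownames(beta) <- ids
  colnames(beta) <- samples$sample_id

  truth <- structure(list(
    cpg_ids = list(
      shared = ids[category == "shared"],
      tissue_specific = split(ids[category == "tissue_specific"],
                              native[category == "tissue_specific"]),
      sex_modulated = ids[category == "sex_modulated"]),
    category = stats::setNames(category, ids),
    native_tissue = stats::setNames(native, ids),
    slopes = stats::setNames(globals$slope, ids),
    female_slopes = stats::setNames(fem_extra, ids),
    baselines = stats::setNames(globals$baseline, ids),
    batch_intercepts = batch,
    config = config), class = "clock_ground_truth")

  list(study = methylation_study(beta, samples, probes), truth = truth)
}

#' All planted clock CpG ids of a ground-truth object
#'
#' @param truth The `truth` element returned by [simulate_study()].
#' @param tissue Optional tissue code: restrict tissue-specific CpGs to
#'   that tissue.
#' @return Character vector of CpG ids.
#' @export
planted_cpgs <- function(truth, tissue = NULL) {
  ts <- truth$cpg_ids$tissue_specific
  ts <- if (is.null(tissue)) unlist(ts, use.names = FALSE) else ts[[tissue]]
  c(truth$cpg_ids$shared, ts, truth$cpg_ids$sex_modulated)
}

#' Simulate a score table with a known fixed effect
#'
#' Direct generator for mixed-model parameter-recovery and calibration
#' tests: `score = effect * x + a_g + e`, `a_g ~ N(0, group_sd^2)`,
#' `e ~ N(0, resid_sd^2)`, where `x` is the standardized log subsample
#' size. The score is stored in the `adjusted_r2` column; all
#' experimental-design labels are filled with balanced values (`penalty`
#' alternates `elastic_net` / `lasso` within each dataset).
#'
#' @param n_gse Number of datasets (random-intercept groups), at least 2.
#' @param effect Fixed-effect slope on the standardized log size.
#' @param group_sd,resid_sd SDs of the random intercept and residual.
#' @param seed Integer seed.
#' @param n_per_gse Records per dataset.
#' @param sizes Pool of subsample sizes cycled within each dataset.
#' @return A score table (data frame) with the standard columns.
#' @export
simulate_score_table <- function(n_gse, effect, group_sd, resid_sd, seed,
                                 n_per_gse = 10,
                                 sizes = c(25, 50, 100, 200, 400, 800)) {
  if (n_gse < 2) cb_stop_code("n_gse must be >= 2")
  with_seed(seed, {
    gse <- rep(sprintf("GSE%03d", seq_len(n_gse)), each = n_per_gse)
    size <- rep_len(rep_len(sizes, n_per_gse), n_gse * n_per_gse)
    x <- standardize(log(size))
    a <- rep(stats::rnorm(n_gse, 0, group_sd), each = n_per_gse)
    e <- stats::rnorm(n_gse * n_per_gse, 0, resid_sd)
    score <- effect * x + a + e
    data.frame(
      adjusted_r2 = score, rmse = NA_real_, split = "validation",
      n = n_per_gse, gse_id = gse, tissue = "simulated",
      penalty = rep_len(c("elastic_net", "lasso"), n_gse * n_per_gse),
      sex_config = "joint", validation_sex = "joint",
      subsample_size = size, tissue_specific = 1L,
      stringsAsFactors = FALSE)
  })
}
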