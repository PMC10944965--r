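DEFAULT_LADDER <- c(25, 50, 75, 100, 125, 150, 175, 200, 300, 400, 500,
                    750, 1000, 1250, 1750, 2000, 2250, 2500, 2750)

#' Experiment plan for the benchmarking harness
#'
#' @param tissues Named list of tissue targets; each element is a list
#'   with `code` (MeSH-style code or prefix) and optional `exact`
#'   (default `FALSE`: dot-boundary prefix aggregation). Names are the
#'   tissue labels used in the score table.
#' @param penalties Character vector of penalty names.
#' @param sex_train Training sex configurations, subset of
#'   `c("joint", "male", "female")`.
#' @param ladder Subsampling ladder (strictly increasing sizes); the full
#'   training-set size is always appended. Ladder points above the
#'   training-set size are silently dropped.
#' @param min_samples Minimum samples on each side of a split (3).
#' @param blood_code Tissue code treated as blood for the transfer
#'   experiment (`NULL` disables it).
#' @param seed Master seed; per-cell seeds are derived by hashing the cell
#'   labels with it.
#' @return An `experiment_plan`.
#' @export
experiment_plan <- function(tissues, penalties = "elastic_net",
                            sex_train = "joint", ladder = DEFAULT_LADDER,
                            min_samples = 3, blood_code = NULL, seed = 1L) {
  if (is.character(tissues)) {
    tissues <- stats::setNames(lapply(tissues, function(code)
      list(code = code, exact = FALSE)), tissues)
  }
  if (is.unsorted(ladder, strictly = TRUE)) {
    cb_stop_code("ladder must be strictly increasing")
  }
  if (min_samples < 3) cb_stop_code("min_samples must be >= 3")
  stopifnot(all(penalties %in% c("ridge", "lasso", "elastic_net")),
            all(sex_train %in% c("joint", "male", "female")))
  structure(list(tissues = tissues, penalties = penalties,
                 sex_train = sex_train, ladder = ladder,
                 min_samples = min_samples, blood_code = blood_code,
                 seed = as.integer(seed)),
            class = "experiment_plan")
}

#' Select the samples of a tissue target
#'
#' A sample matches when its tissue code equals the target or extends it
#' at a dot boundary (MeSH-style hierarchical aggregation). Suffix-labeled
#' codes listed in `aliases` (e.g. `"CD4"` for sorted blood-cell subsets)
#' are folded into their parent code before matching, so exact targets can
#' still absorb them.
#'
#' @param samples A sample sheet data frame.
#' @param target_code Tissue code or prefix.
#' @param exact If `TRUE`, match the (alias-folded) code exactly instead
#'   of by prefix.
#' @param aliases Character vector of suffix labels folded into the parent
#'   code.
#' @return Logical vector over the rows of `samples`.
#' @export
aggregate_tissue <- function(samples, target_code, exact = FALSE,
                             aliases = c("CD4", "CD8", "PBMC")) {
  codes <- samples$tissue_code
  if (length(aliases) > 0) {
    pat <- paste0("\\.(", paste(aliases, collapse = "|"), ")$")
    codes <- sub(pat, "", codes)
  }
  if (exact) {
    codes == target_code
  } else {
    codes == target_code | startsWith(codes, paste0(target_code, "."))
  }
}

#' Age-stratified subsampling of a training set
#'
#' Samples are allocated to decade age strata (20-30, ..., 80-85 by
#' default); per-stratum quotas are proportional to stratum size with
#' largest-remainder rounding, and the draw within each stratum is
#' uniform under `seed`. The excluded complement forms the test set.
#'
#' @param samples Sample sheet data frame of the training set.
#' @param size Target subsample size, at most `nrow(samples)`.
#' @param seed Integer seed.
#' @param breaks Stratum boundaries on age (right-closed bins).
#' @return List with integer row indices `subsample` and `test`
#'   (disjoint, union = all rows).
#' @export
stratified_subsample <- function(samples, size, seed = 1L,
                                 breaks = c(20, 30, 40, 50, 60, 70, 80, 85)) {
  n <- nrow(samples)
  if (size > n) cb_stop_code("subsample size exceeds the training set")
  if (size == n) {
    return(list(subsample = seq_len(n), test = integer(0)))
  }
  lo <- min(breaks[1], floor(min(samples$age)))
  hi <- max(breaks[length(breaks)], ceiling(max(samples$age)))
  brk <- unique(c(lo, breaks[breaks > lo & breaks < hi], hi))
  stratum <- cut(samples$age, breaks = brk, right = TRUE,
                 include.lowest = TRUE)
  counts <- table(stratum)
  exact <- size * as.vector(counts) / n
  quota <- floor(exact)
  rem <- size - sum(quota)
  if (rem > 0) {
    frac <- exact - quota
    # largest remainders first; ties broken by stratum order
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1
  }
  sub <- with_seed(seed, {
    unlist(lapply(seq_along(counts), function(s) {
      idx <- which(as.integer(stratum) == s)
      if (quota[s] >= length(idx)) idx
      else idx[sample.int(length(idx), quota[s])]
    }), use.names = FALSE)
  })
  sub <- sort(sub)
  list(subsample = sub, test = setdiff(seq_len(n), sub))
}

subset_by_sex <- function(study, sex_config) {
  if (sex_config == "joint") return(study)
  want <- if (sex_config == "male") "M" else "F"
  subset_study(study, samples = study$samples$sex == want)
}

# One leave-one-dataset-out cell: train on `train` (already subsampled &
# sex-filtered), score on training/test/validation splits. Returns rows
# plus the fitted model.
run_cell <- function(train, test, validation, penalty, tissue_label,
                     sex_config, subsample_size, seed, blacklist,
                     min_samples, epsilon = 1e-6, tissue_specific = 1L) {
  flt <- filter_probes(train, validation, blacklist)
  m_train <- study_to_m(flt$train, epsilon)
  model <- fit_clock(M = m_train, age = flt$train$samples$age,
                     penalty = penalty, seed = seed,
                     provenance = list(
                       tissue = tissue_label, sex_config = sex_config,
                       gse_ids = unique(flt$train$samples$gse_id),
                       subsample_size = subsample_size,
                       seed = seed))
  rows <- list()
  rows$training <- score_clock(
    model, m_train, flt$train$samples$age, split = "training",
    gse_id = "pooled", tissue = tissue_label, sex_config = sex_config,
    validation_sex = sex_config, subsample_size = subsample_size,
    tissue_specific = tissue_specific)
  if (!is.null(test) && ncol(test$beta) > 0) {
    rows$test <- tryCatch({
      flt_t <- filter_probes(test, validation, blacklist)
      keep <- intersect(flt_t$train$probes$cpg_id, flt$train$probes$cpg_id)
      m_test <- study_to_m(subset_study(flt_t$train, probes = keep), epsilon)
      score_clock(model, m_test, flt_t$train$samples$age, split = "test",
                  gse_id = "pooled", tissue = tissue_label,
                  sex_config = sex_config, validation_sex = sex_config,
                  subsample_size = subsample_size,
                  tissue_specific = tissue_specific)
    }, clockbench_error = function(e) NULL)
  }
  m_val <- study_to_m(flt$validation, epsilon)
  val_gse <- unique(flt$validation$samples$gse_id)
  for (vsex in c("joint", "male", "female")) {
    idx <- if (vsex == "joint") seq_len(nrow(flt$validation$samples))
           else which(flt$validation$samples$sex ==
                        if (vsex == "male") "M" else "F")
    if (length(idx) < min_samples) next
    rows[[paste0("validation_", vsex)]] <- score_clock(
      model, m_val[idx, , drop = FALSE],
      flt$validation$samples$age[idx], split = "validation",
      gse_id = val_gse[1], tissue = tissue_label, sex_config = sex_config,
      validation_sex = vsex, subsample_size = subsample_size,
      tissue_specific = tissue_specific)
  }
  list(scores = do.call(rbind, rows[!vapply(rows, is.null, TRUE)]),
       model = model)
}

#' Leave-one-dataset-out validation within one tissue
#'
#' Each dataset (`gse_id`) is iteratively held out; a clock is trained on
#' the remaining datasets pooled and validated on the held-out one.
#' Clocks are produced only when both sides have at least
#' `plan$min_samples` samples after sex-configuration filtering; skipped
#' cells are logged. Subsampling ladder points above the training-set
#' size are silently dropped and the full size is always included.
#'
#' @param study A sample-filtered, imputed [methylation_study()] of one
#'   tissue with at least two datasets.
#' @param plan An [experiment_plan()].
#' @param tissue_label Label stored in the score rows.
#' @param blacklist Probe blacklist passed to [filter_probes()].
#' @param keep_models If `TRUE`, full-size models are kept and returned.
#' @return A list with `scores` (score table), `models` (named list of
#'   full-size clocks) and `skipped` (data frame of skipped cells with
#'   reasons).
#' @export
leave_one_dataset_out <- function(study, plan, tissue_label,
                                  blacklist = character(0),
                                  keep_models = FALSE) {
  gses <- unique(study$samples$gse_id)
  if (length(gses) < 2) {
    cb_stop_code("leave-one-dataset-out requires at least 2 datasets")
  }
  scores <- list()
  models <- list()
  skipped <- list()
  log_skip <- function(...) {
    skipped[[length(skipped) + 1]] <<- data.frame(..., stringsAsFactors = FALSE)
  }
  for (g in gses) {
    validation <- subset_study(study, samples = study$samples$gse_id == g)
    train_all <- subset_study(study, samples = study$samples$gse_id != g)
    if (nrow(validation$samples) < plan$min_samples) {
      log_skip(tissue = tissue_label, gse = g, penalty = NA, sex = NA,
               size = NA, reason = "validation set below minimum size")
      next
    }
    for (sex_cfg in plan$sex_train) {
      train_sex <- subset_by_sex(train_all, sex_cfg)
      n_train <- nrow(train_sex$samples)
      if (n_train < plan$min_samples) {
        log_skip(tissue = tissue_label, gse = g, penalty = NA,
                 sex = sex_cfg, size = NA,
                 reason = "training set below minimum size")
        next
      }
      sizes <- c(plan$ladder[plan$ladder < n_train], n_train)
      for (pen_name in plan$penalties) {
        for (size in sizes) {
          seed <- cell_seed(plan$seed, tissue_label, g, pen_name,
                            sex_cfg, size)
          parts <- stratified_subsample(train_sex$samples, size,
                                        seed = seed)
          train <- subset_study(train_sex, samples = parts$subsample)
          test <- if (length(parts$test) > 0) {
            subset_study(train_sex, samples = parts$test)
          } else NULL
          cell <- tryCatch(
            run_cell(train, test, validation, penalty_spec(pen_name),
                     tissue_label, sex_cfg, size, seed, blacklist,
                     plan$min_samples),
            clockbench_error = function(e) conditionMessage(e))
          if (is.character(cell)) {
            log_skip(tissue = tissue_label, gse = g, penalty = pen_name,
                     sex = sex_cfg, size = size, reason = cell)
            next
          }
          scores[[length(scores) + 1]] <- cell$scores
          if (keep_models && size == n_train) {
            models[[paste(tissue_label, g, pen_name, sex_cfg,
                          sep = "|")]] <- cell$model
          }
        }
      }
    }
  }
  list(scores = if (length(scores)) do.call(rbind, scores) else NULL,
       models = models,
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
}

#' Blood-to-tissue transfer experiment
#'
#' Trains a single clock on all blood samples (per penalty, males and
#' females jointly) and scores it on every validation dataset of each
#' non-blood tissue; emitted records carry `tissue_specific = 0` and are
#' paired with the tissue-trained records for the mixed-model contrast.
#'
#' @param blood_study Sample-filtered, imputed blood study.
#' @param tissue_studies Named list of non-blood studies (labels become
#'   the `tissue` column).
#' @param plan An [experiment_plan()].
#' @param blacklist Probe blacklist.
#' @return A list with `scores` and `models` (one blood clock per
#'   penalty).
#' @export
run_transfer <- function(blood_study, tissue_studies, plan,
                         blacklist = character(0)) {
  scores <- list()
  models <- list()
  n_blood <- nrow(blood_study$samples)
  for (pen_name in plan$penalties) {
    seed <- cell_seed(plan$seed, "blood_transfer", pen_name)
    # shared probe universe across blood and all target tissues
    pooled <- tissue_studies[[1]]
    if (length(tissue_studies) > 1) {
      for (ts in tissue_studies[-1]) {
        keep <- intersect(pooled$probes$cpg_id, ts$probes$cpg_id)
        pooled <- subset_study(pooled, probes = keep)
      }
    }
    flt <- filter_probes(blood_study, pooled, blacklist)
    m_blood <- study_to_m(flt$train)
    model <- fit_clock(M = m_blood, age = flt$train$samples$age,
                       penalty = penalty_spec(pen_name), seed = seed,
                       provenance = list(
                         tissue = "blood", sex_config = "joint",
                         gse_ids = unique(flt$train$samples$gse_id),
                         subsample_size = n_blood, seed = seed))
    models[[pen_name]] <- model
    probe_keep <- flt$train$probes$cpg_id
    for (lab in names(tissue_studies)) {
      ts <- tissue_studies[[lab]]
      for (g in unique(ts$samples$gse_id)) {
        val <- subset_study(ts, samples = ts$samples$gse_id == g)
        val <- subset_study(val,
                            probes = intersect(probe_keep,
                                               val$probes$cpg_id))
        m_val <- study_to_m(impute_missing(val))
        if (anyNA(m_val)) {
          keep_p <- colSums(is.na(m_val)) == 0
          m_val <- m_val[, keep_p, drop = FALSE]
        }
        for (vsex in c("joint", "male", "female")) {
          idx <- if (vsex == "joint") seq_len(nrow(val$samples))
                 else which(val$samples$sex ==
                              if (vsex == "male") "M" else "F")
          if (length(idx) < plan$min_samples) next
          rec <- tryCatch(
            score_clock(model, m_val[idx, , drop = FALSE],
                        val$samples$age[idx], split = "validation",
                        gse_id = g, tissue = lab, sex_config = "joint",
                        validation_sex = vsex, subsample_size = n_blood,
                        tissue_specific = 0L),
            clockbench_error = function(e) NULL)
          if (!is.null(rec)) scores[[length(scores) + 1]] <- rec
        }
      }
    }
  }
  list(scores = if (length(scores)) do.call(rbind, scores) else NULL,
       models = models)
}

#' Run the full benchmarking design
#'
#' Sample filtering, per-dataset imputation, then per tissue target:
#' leave-one-dataset-out validation across penalties, sex configurations
#' and the subsampling ladder; finally, when `plan$blood_code` is set,
#' the blood-to-tissue transfer experiment. Deterministic under
#' `plan$seed`.
#'
#' @param study A raw [methylation_study()] (all tissues pooled).
#' @param plan An [experiment_plan()].
#' @param blacklist Probe blacklist.
#' @param keep_models Keep full-size models for the selection analysis.
#' @return List with `scores`, `models` (per tissue), `transfer_models`,
#'   `skipped` and `filter_report`.
#' @export
run_full_benchmark <- function(study, plan, blacklist = character(0),
                               keep_models = FALSE) {
  fs <- filter_samples(study, seed = plan$seed)
  imputed <- impute_missing(fs$study)
  scores <- list()
  models <- list()
  skipped <- list()
  tissue_subsets <- list()
  for (lab in names(plan$tissues)) {
    tgt <- plan$tissues[[lab]]
    sel <- aggregate_tissue(imputed$samples, tgt$code,
                            exact = isTRUE(tgt$exact))
    if (!any(sel)) next
    tissue_subsets[[lab]] <- subset_study(imputed, samples = which(sel))
  }
  for (lab in names(tissue_subsets)) {
    sub <- tissue_subsets[[lab]]
    if (length(unique(sub$samples$gse_id)) < 2) {
      skipped[[length(skipped) + 1]] <- data.frame(
        tissue = lab, gse = NA, penalty = NA, sex = NA, size = NA,
        reason = "fewer than 2 datasets", stringsAsFactors = FALSE)
      next
    }
    res <- leave_one_dataset_out(sub, plan, lab, blacklist,
                                 keep_models = keep_models)
    scores[[lab]] <- res$scores
    models[[lab]] <- res$models
    if (!is.null(res$skipped)) {
      skipped[[length(skipped) + 1]] <- res$skipped
    }
  }
  transfer_models <- NULL
  if (!is.null(plan$blood_code)) {
    is_blood <- vapply(names(plan$tissues), function(lab)
      identical(plan$tissues[[lab]]$code, plan$blood_code), TRUE)
    blood_lab <- names(plan$tissues)[is_blood][1]
    others <- tissue_subsets[setdiff(names(tissue_subsets), blood_lab)]
    if (!is.na(blood_lab) && blood_lab %in% names(tissue_subsets) &&
        length(others) > 0) {
      tr <- run_transfer(tissue_subsets[[blood_lab]], others, plan,
                         blacklist)
      scores[["transfer"]] <- tr$scores
      transfer_models <- tr$models
    }
  }
  all_scores <- do.call(rbind, scores[!vapply(scores, is.null, TRUE)])
  rownames(all_scores) <- NULL
  list(scores = all_scores, models = models,
       transfer_models = transfer_models,
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
       filter_report = fs$report)
}
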