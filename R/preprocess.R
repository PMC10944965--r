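#' Filter samples by age window, health status and paired-sample rule
#'
#' Retains control samples with age in (20, 85]; within each `family_id`
#' (twins, repeated measurements) exactly one sample is retained, chosen
#' uniformly at random under `seed`. Samples without a `family_id` are
#' their own family.
#'
#' @param study A [methylation_study()].
#' @param seed Integer seed for the random deduplication draw.
#' @param age_min,age_max Window bounds: samples with `age <= age_min` or
#'   `age > age_max` are removed.
#' @return A list with `study` (filtered) and `report` (a `filter_report`
#'   with per-rule counts and removed ids; counts reconcile exactly with
#'   the size change).
#' @export
filter_samples <- function(study, seed = 1L, age_min = 20, age_max = 85) {
  stopifnot(inherits(study, "methylation_study"))
  sheet <- study$samples
  removed <- list()

  keep <- rep(TRUE, nrow(sheet))
  low <- keep & sheet$age <= age_min
  removed$age_low <- sheet$sample_id[low]
  keep <- keep & !low
  high <- keep & sheet$age > age_max
  removed$age_high <- sheet$sample_id[high]
  keep <- keep & !high
  nonctl <- keep & sheet$status != "control"
  removed$non_control <- sheet$sample_id[nonctl]
  keep <- keep & !nonctl

  # one random representative per family among survivors
  surv <- sheet[keep, , drop = FALSE]
  fam <- surv$family_id
  dup_drop <- character(0)
  if (any(!is.na(fam))) {
    with_seed(seed, {
      for (f in unique(fam[!is.na(fam)])) {
        members <- surv$sample_id[!is.na(fam) & fam == f]
        if (length(members) > 1) {
          keep_one <- members[sample.int(length(members), 1)]
          dup_drop <- c(dup_drop, setdiff(members, keep_one))
        }
      }
    })
  }
  removed$paired_duplicate <- dup_drop
  keep <- keep & !(sheet$sample_id %in% dup_drop)

  if (!any(keep)) {
    counts <- lengths(removed)
    rule <- names(counts)[counts > 0][which.max(counts[counts > 0])]
    cb_stop_empty(sprintf(
      "sample filtering removed every sample (dominant rule: %s)", rule))
  }
  out <- subset_study(study, samples = which(keep))
  report <- structure(list(kind = "samples", counts = lengths(removed),
                           removed = removed, seed = seed,
                           n_in = nrow(sheet), n_out = sum(keep)),
                      class = "filter_report")
  list(study = out, report = report)
}

#' Filter probes for a train/validation study pair
#'
#' Retains the probes present in both studies, minus probes with any
#' remaining missing value (after imputation), minus SNP-control (`rs`)
#' probes, minus X/Y-chromosome probes, minus probes flagged unreliable in
#' either annotation or listed in `blacklist`. The retained set is sorted
#' by CpG id so the output is invariant to input probe order, and both
#' outputs share an identical probe order.
#'
#' @param train,validation [methylation_study()] objects.
#' @param blacklist Character vector of CpG ids to drop (consumed as a
#'   plain id list, e.g. a published unreliable-probe list).
#' @return A list with `train`, `validation` and `report`.
#' @export
filter_probes <- function(train, validation, blacklist = character(0)) {
  stopifnot(inherits(train, "methylation_study"),
            inherits(validation, "methylation_study"))
  ids_t <- train$probes$cpg_id
  ids_v <- validation$probes$cpg_id
  shared <- sort(intersect(ids_t, ids_v))
  removed <- list(
    probe_not_shared = sort(union(setdiff(ids_t, ids_v),
                                  setdiff(ids_v, ids_t))))

  # classification of shared probes, each counted once, rule precedence:
  # rs -> xy -> unreliable/blacklist -> missing
  ann <- rbind(train$probes[match(shared, ids_t), , drop = FALSE])
  ann_v <- validation$probes[match(shared, ids_v), , drop = FALSE]
  cls <- rep("keep", length(shared))
  is_rs <- ann$probe_class == "rs" | ann_v$probe_class == "rs"
  is_xy <- ann$chromosome %in% c("X", "Y") | ann_v$chromosome %in% c("X", "Y")
  is_bad <- ann$unreliable | ann_v$unreliable | shared %in% blacklist
  has_na <- rowSums(is.na(train$beta[shared, , drop = FALSE])) > 0 |
    rowSums(is.na(validation$beta[shared, , drop = FALSE])) > 0
  cls[has_na] <- "probe_missing"
  cls[is_bad] <- "probe_unreliable"
  cls[is_xy] <- "probe_xy"
  cls[is_rs] <- "probe_rs"
  for (rule in c("probe_rs", "probe_xy", "probe_unreliable",
                 "probe_missing")) {
    removed[[rule]] <- shared[cls == rule]
  }
  retained <- shared[cls == "keep"]
  if (length(retained) == 0) {
    cb_stop_empty("probe filtering retained no probe")
  }

  report <- structure(list(kind = "probes", counts = lengths(removed),
                           removed = removed,
                           n_in = length(union(ids_t, ids_v)),
                           n_out = length(retained)),
                      class = "filter_report")
  list(train = subset_study(train, probes = retained),
       validation = subset_study(validation, probes = retained),
       report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report: %s> %d -> %d\n", x$kind, x$n_in, x$n_out))
  for (nm in names(x$counts)) {
    cat(sprintf("  %-18s %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}

#' Impute missing beta-values by per-probe, per-dataset means
#'
#' Each missing beta is replaced by the mean of the non-missing values of
#' the same probe within the same dataset (`gse_id`). This is a simple,
#' documented stand-in for model-based methylation imputation; probes
#' entirely missing within a dataset remain missing and are caught by
#' [filter_probes()].
#'
#' @param study A [methylation_study()].
#' @return The imputed study.
#' @export
impute_missing <- function(study) {
  stopifnot(inherits(study, "methylation_study"))
  beta <- study$beta
  for (g in unique(study$samples$gse_id)) {
    idx <- which(study$samples$gse_id == g)
    block <- beta[, idx, drop = FALSE]
    nas <- which(is.na(block), arr.ind = TRUE)
    if (nrow(nas) == 0) next
    means <- rowMeans(block, na.rm = TRUE)   # NaN if fully missing
    fill <- means[nas[, 1]]
    fill[is.nan(fill)] <- NA_real_
    block[nas] <- fill
    beta[, idx] <- block
  }
  study$beta <- beta
  study
}

#' Normalization hook
#'
#' Between-dataset normalization is a pluggable step: the default method
#' `"none"` is the identity. Users working with real array data can supply
#' their own function of signature `function(study, ...) study`.
#'
#' @param study A [methylation_study()].
#' @param method `"none"` or `"custom"`.
#' @param fun Normalization function when `method = "custom"`.
#' @param ... Passed to `fun`.
#' @return A normalized `methylation_study`.
#' @export
normalize_study <- function(study, method = c("none", "custom"), fun = NULL,
                            ...) {
  method <- match.arg(method)
  if (method == "none") return(study)
  if (!is.function(fun)) cb_stop_code("method 'custom' requires `fun`")
  out <- fun(study, ...)
  stopifnot(inherits(out, "methylation_study"))
  out
}

#' Logit2 transform of beta-values to M-values
#'
#' `M = log2(beta / (1 - beta))`, with beta clamped to
#' `[epsilon, 1 - epsilon]` so boundary values stay finite. Strictly
#' increasing on the clamped range and antisymmetric about beta = 0.5.
#'
#' @param beta Numeric vector or matrix with values in `[0, 1]` (`NA`
#'   allowed and propagated).
#' @param epsilon Clamp width, default `1e-6`.
#' @return M-values with the shape of the input.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  vals <- beta[!is.na(beta)]
  if (any(vals < 0 | vals > 1)) {
    cb_stop_range("beta values must lie in [0, 1]")
  }
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) dim(out) <- dim(beta)
  dimnames(out) <- dimnames(beta)
  out
}

#' M-value matrix of a study, samples by probes
#'
#' Convenience accessor used by the modelling layer: transposes the
#' (probes x samples) beta matrix and applies [beta_to_m()].
#'
#' @param study A preprocessed [methylation_study()] (no missing values).
#' @param epsilon Clamp width for the logit2 transform.
#' @return Numeric matrix, samples in rows, probes in columns.
#' @export
study_to_m <- function(study, epsilon = 1e-6) {
  t(beta_to_m(study$beta, epsilon))
}
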