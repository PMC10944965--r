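#' Construct a methylation study
#'
#' Bundles a CpG-by-sample matrix of beta-values with its sample sheet and
#' probe annotation, after validating the joint invariants. This is the unit
#' of data every pipeline stage consumes.
#'
#' @param beta Numeric matrix, probes in rows and samples in columns, values
#'   in `[0, 1]`, `NA` allowed. Row names are CpG ids, column names sample ids.
#' @param samples Data frame with columns `sample_id`, `gse_id`, `age`, `sex`
#'   (`"F"`/`"M"`), `tissue_code`, `status` (`"control"`/`"case"`) and an
#'   optional `family_id` marking paired samples (twins, repeated measures).
#' @param probes Data frame with columns `cpg_id`, `chromosome` (`"1"`-`"22"`,
#'   `"X"`, `"Y"`), `gene_symbols` (`";"`-separated, possibly empty),
#'   `probe_class` (`"cg"`, `"rs"`, `"ch"`) and logical `unreliable`.
#'
#' @return An object of class `methylation_study`: a list with elements
#'   `beta`, `samples`, `probes`. Columns of `beta` are reordered to match
#'   the sample sheet, rows to match the annotation.
#' @export
methylation_study <- function(beta, samples, probes) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  if (is.null(samples$family_id)) samples$family_id <- NA_character_
  beta <- as.matrix(beta)
  storage.mode(beta) <- "double"

  validate_sample_sheet(samples)
  validate_probe_annotation(probes)

  if (nrow(beta) != nrow(probes)) {
    cb_stop_dimension(sprintf(
      "beta has %d rows but the annotation describes %d probes",
      nrow(beta), nrow(probes)))
  }
  if (ncol(beta) != nrow(samples)) {
    cb_stop_dimension(sprintf(
      "beta has %d columns but the sample sheet describes %d samples",
      ncol(beta), nrow(samples)))
  }
  if (!is.null(colnames(beta))) {
    if (!setequal(colnames(beta), samples$sample_id)) {
      cb_stop_dimension("beta column names do not match sample_id set")
    }
    # sample-sheet order is authoritative
    beta <- beta[, samples$sample_id, drop = FALSE]
  } else {
    colnames(beta) <- samples$sample_id
  }
  if (!is.null(rownames(beta))) {
    if (!setequal(rownames(beta), probes$cpg_id)) {
      cb_stop_dimension("beta row names do not match cpg_id set")
    }
    beta <- beta[probes$cpg_id, , drop = FALSE]
  } else {
    rownames(beta) <- probes$cpg_id
  }

  bad <- beta[!is.na(beta) & (beta < 0 | beta > 1)]
  if (length(bad) > 0) {
    cb_stop_range(sprintf(
      "%d beta value(s) outside [0, 1] (first offender: %g)",
      length(bad), bad[1]))
  }

  structure(list(beta = beta, samples = samples, probes = probes),
            class = "methylation_study")
}

validate_sample_sheet <- function(samples) {
  needed <- c("sample_id", "gse_id", "age", "sex", "tissue_code", "status")
  missing <- setdiff(needed, names(samples))
  if (length(missing) > 0) {
    cb_stop_dimension(paste("sample sheet lacks column(s):",
                            paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) {
    cb_stop_duplicate("duplicated sample_id in sample sheet")
  }
  if (any(!is.finite(samples$age)) || any(samples$age <= 0)) {
    cb_stop_code("age must be a positive finite number for every sample")
  }
  if (!all(samples$sex %in% c("F", "M"))) {
    cb_stop_code("sex must be one of {F, M}")
  }
  if (!all(nzchar(samples$tissue_code))) {
    cb_stop_code("tissue_code must be non-empty")
  }
  if (!all(samples$status %in% c("control", "case"))) {
    cb_stop_code("status must be one of {control, case}")
  }
  invisible(samples)
}

validate_probe_annotation <- function(probes) {
  needed <- c("cpg_id", "chromosome", "gene_symbols", "probe_class",
              "unreliable")
  missing <- setdiff(needed, names(probes))
  if (length(missing) > 0) {
    cb_stop_dimension(paste("probe annotation lacks column(s):",
                            paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(probes$cpg_id)) {
    cb_stop_duplicate("duplicated cpg_id in probe annotation")
  }
  if (!all(probes$probe_class %in% c("cg", "rs", "ch"))) {
    cb_stop_code("probe_class must be one of {cg, rs, ch}")
  }
  if (!all(probes$chromosome %in% c(as.character(1:22), "X", "Y"))) {
    cb_stop_code("chromosome must be one of 1-22, X, Y")
  }
  invisible(probes)
}

#' @export
print.methylation_study <- function(x, ...) {
  cat(sprintf(
    "<methylation_study> %d probes x %d samples, %d dataset(s), %d tissue(s)\n",
    nrow(x$beta), ncol(x$beta), length(unique(x$samples$gse_id)),
    length(unique(x$samples$tissue_code))))
  nm <- sum(is.na(x$beta))
  cat(sprintf("  age range [%.1f, %.1f]; %d missing beta value(s) (%.2f%%)\n",
              min(x$samples$age), max(x$samples$age), nm,
              100 * nm / length(x$beta)))
  invisible(x)
}

#' @export
dim.methylation_study <- function(x) dim(x$beta)

#' Subset a methylation study
#'
#' @param study A [methylation_study()].
#' @param samples Sample ids, indices or a logical vector over samples.
#' @param probes CpG ids, indices or a logical vector over probes.
#' @return The subsetted `methylation_study`.
#' @export
subset_study <- function(study, samples = NULL, probes = NULL) {
  stopifnot(inherits(study, "methylation_study"))
  beta <- study$beta
  sheet <- study$samples
  ann <- study$probes
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) {
      match(samples, sheet$sample_id)
    } else if (is.logical(samples)) which(samples) else samples
    if (anyNA(idx)) cb_stop_dimension("unknown sample id in subset")
    sheet <- sheet[idx, , drop = FALSE]
    beta <- beta[, idx, drop = FALSE]
  }
  if (!is.null(probes)) {
    idx <- if (is.character(probes)) {
      match(probes, ann$cpg_id)
    } else if (is.logical(probes)) which(probes) else probes
    if (anyNA(idx)) cb_stop_dimension("unknown cpg id in subset")
    ann <- ann[idx, , drop = FALSE]
    beta <- beta[idx, , drop = FALSE]
  }
  rownames(sheet) <- NULL
  rownames(ann) <- NULL
  structure(list(beta = beta, samples = sheet, probes = ann),
            class = "methylation_study")
}
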