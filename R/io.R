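# All tables are tab-separated UTF-8 with '.' decimal and "NA" for missing;
# the first matrix column is cpg_id. Reals are written with 17 significant
# digits so every reader/writer pair round-trips to <= 1e-12 relative error.

SCORE_COLUMNS <- c("adjusted_r2", "rmse", "split", "n", "gse_id", "tissue",
                   "penalty", "sex_config", "validation_sex",
                   "subsample_size", "tissue_specific")

fmt_real <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, "")
  out
}

read_tsv <- function(path) {
  if (!file.exists(path)) {
    cb_stop(sprintf("file not found: %s", path), "clockbench_error_io")
  }
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    na.strings = "NA", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a methylation study from its three tables
#'
#' Reads the beta-value matrix (first column `cpg_id`, one column per
#' sample), the sample sheet and the probe annotation, validates them
#' jointly and returns the in-memory study. The sample-sheet order is
#' authoritative: matrix columns are reordered to match it.
#'
#' @param matrix_path,sheet_path,annotation_path Paths to the three
#'   tab-separated files.
#' @return A [methylation_study()].
#' @export
read_study <- function(matrix_path, sheet_path, annotation_path) {
  mat <- read_tsv(matrix_path)
  if (names(mat)[1] != "cpg_id") {
    cb_stop_dimension("matrix file must have 'cpg_id' as its first column")
  }
  beta <- as.matrix(mat[, -1, drop = FALSE])
  rownames(beta) <- mat$cpg_id

  sheet <- read_tsv(sheet_path)
  ann <- read_tsv(annotation_path)
  # columns serialized as character come back typed
  sheet$age <- as.numeric(sheet$age)
  if (!is.null(ann$unreliable)) ann$unreliable <- as.logical(ann$unreliable)
  if (!is.null(ann$gene_symbols)) {
    ann$gene_symbols[is.na(ann$gene_symbols)] <- ""
  }
  methylation_study(beta, sheet, ann)
}

#' Write a methylation study to its three tables
#'
#' @param study A [methylation_study()].
#' @param matrix_path,sheet_path,annotation_path Output paths.
#' @return The matrix path, invisibly.
#' @export
write_study <- function(study, matrix_path, sheet_path, annotation_path) {
  stopifnot(inherits(study, "methylation_study"))
  mat <- data.frame(cpg_id = rownames(study$beta), stringsAsFactors = FALSE)
  vals <- apply(study$beta, 2, fmt_real)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(study$beta))
  mat <- cbind(mat, as.data.frame(vals, stringsAsFactors = FALSE,
                                  check.names = FALSE))
  names(mat) <- c("cpg_id", colnames(study$beta))
  write_tsv(mat, matrix_path)
  write_tsv(study$samples, sheet_path)
  write_tsv(study$probes, annotation_path)
  invisible(matrix_path)
}

#' Write a trained clock to disk
#'
#' The file has a key-value metadata block (lines starting with `#`)
#' followed by a two-column table `cpg_id` / `coefficient` holding the
#' non-zero coefficients only. `read_clock(write_clock(m))` reproduces the
#' model to 1e-12.
#'
#' @param model A [clock_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clock <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  if (!is.finite(model$intercept) || any(!is.finite(model$coefficients))) {
    cb_stop("clock model has non-finite coefficient(s)",
            "clockbench_error_nonfinite")
  }
  nz <- model$coefficients[model$coefficients != 0]
  nz_std <- model$coef_std[names(nz)]
  prov <- model$provenance
  meta <- c(
    penalty = model$penalty$name,
    alpha = fmt_real(model$penalty$alpha),
    lambda = fmt_real(model$lambda),
    intercept = fmt_real(model$intercept),
    tissue = prov$tissue %||% "NA",
    sex_config = prov$sex_config %||% "NA",
    n_train = as.character(prov$n_train %||% NA),
    gse_ids = paste(prov$gse_ids %||% character(), collapse = ","),
    subsample_size = as.character(prov$subsample_size %||% NA),
    seed = as.character(prov$seed %||% NA)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s\t%s", names(meta), meta), con)
  writeLines("cpg_id\tcoefficient\tcoefficient_std", con)
  if (length(nz) > 0) {
    writeLines(sprintf("%s\t%s\t%s", names(nz), fmt_real(nz),
                       fmt_real(nz_std)), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a clock written by [write_clock()]
#'
#' @param path Path to a clock file.
#' @return A [clock_model()]. Probes absent from the file carry coefficient
#'   zero; the reconstructed coefficient vector holds the non-zero entries.
#' @export
read_clock <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^#", "", meta_lines), "\t", fixed = TRUE))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                           stringsAsFactors = FALSE)
  coefs <- stats::setNames(as.numeric(tab$coefficient), tab$cpg_id)
  coef_std <- stats::setNames(as.numeric(tab$coefficient_std), tab$cpg_id)
  num_or_na <- function(x) if (x == "NA") NA_integer_ else as.integer(x)
  real_or_na <- function(x) if (x == "NA") NA_real_ else as.numeric(x)
  clock_model(
    intercept = real_or_na(meta[["intercept"]]),
    coefficients = coefs,
    coef_std = coef_std,
    penalty = penalty_spec(meta[["penalty"]]),
    lambda = real_or_na(meta[["lambda"]]),
    provenance = list(
      tissue = meta[["tissue"]],
      sex_config = meta[["sex_config"]],
      n_train = num_or_na(meta[["n_train"]]),
      gse_ids = strsplit(meta[["gse_ids"]], ",", fixed = TRUE)[[1]],
      subsample_size = num_or_na(meta[["subsample_size"]]),
      seed = num_or_na(meta[["seed"]])
    )
  )
}

#' Write / read a clock score table
#'
#' One row per score record with the fixed column set
#' `adjusted_r2, rmse, split, n, gse_id, tissue, penalty, sex_config,
#' validation_sex, subsample_size, tissue_specific`.
#'
#' @param records Data frame of score records (one row each).
#' @param path File path.
#' @return `path` (write) or the score table (read).
#' @export
write_scores <- function(records, path) {
  if (is.null(records) || nrow(records) == 0) {
    cb_stop_empty("no score records to write")
  }
  missing <- setdiff(SCORE_COLUMNS, names(records))
  if (length(missing) > 0) {
    cb_stop_dimension(paste("score table lacks column(s):",
                            paste(missing, collapse = ", ")))
  }
  out <- records[, SCORE_COLUMNS]
  out$adjusted_r2 <- fmt_real(out$adjusted_r2)
  out$rmse <- fmt_real(out$rmse)
  write_tsv(out, path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- read_tsv(path)
  df$adjusted_r2 <- as.numeric(df$adjusted_r2)
  df$rmse <- as.numeric(df$rmse)
  df$n <- as.integer(df$n)
  df$subsample_size <- as.integer(df$subsample_size)
  df$tissue_specific <- as.integer(df$tissue_specific)
  df
}

#' Write / read a comparison-result table
#'
#' @param results Data frame of mixed-model comparison results.
#' @param path File path.
#' @return `path` (write) or the table (read).
#' @export
write_comparisons <- function(results, path) {
  out <- results
  for (cn in names(out)) {
    if (is.double(out[[cn]])) out[[cn]] <- fmt_real(out[[cn]])
  }
  write_tsv(out, path)
}

#' @rdname write_comparisons
#' @export
read_comparisons <- function(path) {
  df <- read_tsv(path)
  for (cn in c("partial_corr", "se", "t_statistic", "df", "p_value", "p_by",
               "tau2", "sigma2")) {
    if (cn %in% names(df)) df[[cn]] <- as.numeric(df[[cn]])
  }
  df
}
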