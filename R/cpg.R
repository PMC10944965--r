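#' Selection profile of the clocks trained in one tissue
#'
#' Stacks the coefficient vectors of a set of clocks into a clocks-by-CpGs
#' matrix (zeros included). Coefficients are taken on the
#' standardized-predictor scale by default, the scale on which a common
#' absolute threshold is meaningful across CpGs.
#'
#' @param models List of [clock_model()] objects (one per experiment
#'   cell); names become clock ids.
#' @param tissue Tissue label stored with the profile.
#' @param scale `"standardized"` or `"original"`.
#' @return A `selection_profile`: list with `tissue`, `coef` (matrix) and
#'   `scale`.
#' @export
selection_profile <- function(models, tissue = NA_character_,
                              scale = c("standardized", "original")) {
  scale <- match.arg(scale)
  stopifnot(length(models) >= 1)
  if (is.null(names(models)) || anyDuplicated(names(models))) {
    names(models) <- sprintf("clock_%03d", seq_along(models))
  }
  cpgs <- sort(unique(unlist(lapply(models, function(m)
    names(m$coefficients)))))
  mat <- matrix(0, length(models), length(cpgs),
                dimnames = list(names(models), cpgs))
  for (i in seq_along(models)) {
    v <- if (scale == "standardized") models[[i]]$coef_std
         else models[[i]]$coefficients
    mat[i, names(v)] <- v
  }
  structure(list(tissue = tissue, coef = mat, scale = scale),
            class = "selection_profile")
}

#' @export
print.selection_profile <- function(x, ...) {
  cat(sprintf("<selection_profile> %s: %d clock(s) x %d CpG(s), %s scale\n",
              x$tissue, nrow(x$coef), ncol(x$coef), x$scale))
  invisible(x)
}

#' Zero out small coefficients
#'
#' Coefficients with `|c| <= cut` are set to exactly 0 (closed interval:
#' a coefficient exactly at the bound is zeroed).
#'
#' @param profile A [selection_profile()].
#' @param cut Non-negative threshold, default 0.1.
#' @return The thresholded profile.
#' @export
threshold_coefficients <- function(profile, cut = 0.1) {
  stopifnot(inherits(profile, "selection_profile"), cut >= 0)
  profile$coef[abs(profile$coef) <= cut] <- 0
  profile
}

#' Drop unstable CpGs
#'
#' Removes CpG columns whose non-zero fraction across clocks is below
#' `min_frac` (strictly: a CpG selected in exactly 10% of clocks is
#' kept at the default).
#'
#' @param profile A [selection_profile()].
#' @param min_frac Minimum non-zero fraction, default 0.10.
#' @return The filtered profile.
#' @export
stability_filter <- function(profile, min_frac = 0.10) {
  stopifnot(inherits(profile, "selection_profile"))
  frac <- colMeans(profile$coef != 0)
  profile$coef <- profile$coef[, frac >= min_frac, drop = FALSE]
  profile
}

#' Consensus CpG sets of a profile
#'
#' @param profile A (thresholded) [selection_profile()].
#' @return List with `all_clocks` (CpGs selected by every clock) and
#'   `any_clock` (CpGs selected by at least one clock).
#' @export
consensus_sets <- function(profile) {
  stopifnot(inherits(profile, "selection_profile"))
  nz <- profile$coef != 0
  cpgs <- colnames(profile$coef)
  list(all_clocks = cpgs[colSums(nz) == nrow(nz)],
       any_clock = cpgs[colSums(nz) > 0])
}

#' Map CpGs to gene symbols
#'
#' Union of the annotated gene symbols over the given CpGs; CpGs with an
#' empty annotation contribute nothing.
#'
#' @param cpgs Character vector of CpG ids.
#' @param annotation A probe annotation data frame (`cpg_id`,
#'   `gene_symbols` with `";"`-separated symbols).
#' @return Character vector of gene symbols (sorted, unique).
#' @export
map_to_genes <- function(cpgs, annotation) {
  if (length(cpgs) == 0) return(character(0))
  idx <- match(cpgs, annotation$cpg_id)
  if (anyNA(idx)) {
    cb_stop(paste("unknown cpg_id(s):",
                  paste(cpgs[is.na(idx)], collapse = ", ")),
            "clockbench_error_missing_probe")
  }
  syms <- unlist(strsplit(annotation$gene_symbols[idx], ";", fixed = TRUE))
  sort(unique(syms[nzchar(syms)]))
}

#' Three-set overlap (Venn) counts
#'
#' Counts of the 7 regions of a three-set Venn diagram by membership
#' enumeration; region counts sum to the size of the union.
#'
#' @param set_a,set_b,set_c Character vectors (labeled sets).
#' @param labels Length-3 labels used in the region names.
#' @return Named integer vector over the 7 regions (`"A"` = only in A,
#'   `"A&B"` = in A and B only, ..., `"A&B&C"`), with `labels`
#'   substituted for A, B, C.
#' @export
overlap_counts <- function(set_a, set_b, set_c,
                           labels = c("A", "B", "C")) {
  u <- unique(c(set_a, set_b, set_c))
  ina <- u %in% set_a
  inb <- u %in% set_b
  inc <- u %in% set_c
  regions <- c(
    sum(ina & !inb & !inc), sum(!ina & inb & !inc), sum(!ina & !inb & inc),
    sum(ina & inb & !inc), sum(ina & !inb & inc), sum(!ina & inb & inc),
    sum(ina & inb & inc))
  names(regions) <- c(labels,
                      paste(labels[1], labels[2], sep = "&"),
                      paste(labels[1], labels[3], sep = "&"),
                      paste(labels[2], labels[3], sep = "&"),
                      paste(labels, collapse = "&"))
  regions
}

#' Compare selected genes with prior clocks' gene lists
#'
#' For each gene, lists the reference clocks whose gene set contains it
#' (case-insensitive symbol match). Reference lists are supplied by the
#' caller (e.g. read from a two-column TSV `clock_name`, `gene`), not
#' bundled.
#'
#' @param genes Character vector of gene symbols.
#' @param reference Named list: clock name -> character vector of genes.
#' @return Data frame with columns `gene` and `clocks` (`";`"-separated,
#'   empty when no reference clock uses the gene).
#' @export
compare_to_reference_clocks <- function(genes, reference) {
  if (length(reference) == 0) cb_stop_code("reference map is empty")
  if (length(genes) == 0) {
    return(data.frame(gene = character(0), clocks = character(0),
                      stringsAsFactors = FALSE))
  }
  ref_up <- lapply(reference, toupper)
  clocks <- vapply(genes, function(g) {
    hit <- names(reference)[vapply(ref_up, function(r)
      toupper(g) %in% r, TRUE)]
    paste(hit, collapse = ";")
  }, "")
  data.frame(gene = genes, clocks = unname(clocks),
             stringsAsFactors = FALSE)
}
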