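#' Default run configuration
#'
#' Nested list consumed by [run_command()] / [run_report()]; can be
#' written to and read from a YAML file. Every default is printable via
#' `yaml::as.yaml(default_config())` for auditability.
#'
#' @param seed Master seed.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    generator = list(
      tissues = c("A12.207.152", "A08.186.211.730", "A03.620"),
      datasets_per_tissue = 4L, samples_per_dataset = 120L,
      n_background_cpgs = 100L, n_shared_clock_cpgs = 6L,
      n_tissue_specific_clock_cpgs = 3L, n_sex_modulated_cpgs = 0L,
      noise_sd = 0.5, batch_sd = 0.2, missing_rate = 0.01,
      n_xy_probes = 10L, n_rs_probes = 5L),
    plan = list(
      penalties = c("elastic_net", "lasso"),
      sex_train = "joint",
      ladder = c(25, 50, 75, 100),
      blood = "A12.207.152"),
    preprocess = list(epsilon = 1e-6, blacklist = character(0)),
    compare = list(
      penalty_pair = c("lasso", "elastic_net"))
  )
}

#' Read a YAML run configuration
#'
#' @param path YAML file; missing keys fall back to [default_config()].
#' @return A configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_cfg(base[[nm]], over[[nm]])
      } else {
        over[[nm]]
      }
    }
    base
  }
  merge_cfg(default_config(), user)
}

cfg_generator <- function(config) {
  do.call(generator_config, c(config$generator, list(seed = config$seed)))
}

cfg_plan <- function(config) {
  gen <- config$generator
  tissues <- stats::setNames(lapply(gen$tissues, function(code)
    list(code = code, exact = FALSE)), gen$tissues)
  experiment_plan(tissues = tissues,
                  penalties = config$plan$penalties,
                  sex_train = config$plan$sex_train,
                  ladder = config$plan$ladder,
                  blood_code = config$plan$blood,
                  seed = config$seed)
}

write_truth <- function(truth, path) {
  df <- data.frame(cpg_id = names(truth$category),
                   category = unname(truth$category),
                   native_tissue = unname(truth$native_tissue),
                   slope = fmt_real(unname(truth$slopes)),
                   female_slope = fmt_real(unname(truth$female_slopes)),
                   baseline = fmt_real(unname(truth$baselines)),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Headline mixed-model comparisons of a benchmark score table
#'
#' Runs the four summary analyses on validation-split records: size
#' effect (per penalty), penalty contrast, sex-specific contrast (when
#' sex-stratified clocks are present) and tissue-specific-versus-blood
#' contrast (when transfer records are present). Benjamini-Yekutieli
#' adjustment is applied within each (analysis, response) family.
#'
#' @param scores A score table.
#' @param penalty_pair Pair for the penalty contrast.
#' @return A comparison-result data frame.
#' @export
headline_comparisons <- function(scores,
                                 penalty_pair = c("lasso", "elastic_net")) {
  val <- scores[scores$split == "validation", , drop = FALSE]
  joint <- val[val$sex_config == "joint" & val$validation_sex == "joint" &
                 val$tissue_specific == 1, , drop = FALSE]
  out <- list()
  run_family <- function(rows_fun, label) {
    for (resp in c("adjusted_r2", "rmse")) {
      fam <- tryCatch(rows_fun(resp), clockbench_error = function(e) NULL)
      if (is.null(fam)) next
      fam <- adjust_comparison_family(fam)
      fam$analysis <- label
      out[[length(out) + 1]] <<- fam
    }
  }
  run_family(function(resp) {
    rows <- lapply(unique(joint$penalty), function(pen) {
      r <- compare_scores(joint[joint$penalty == pen, , drop = FALSE],
                          "size", resp)
      r$contrast <- pen
      r
    })
    do.call(rbind, rows)
  }, "size_effect")
  if (all(penalty_pair %in% joint$penalty)) {
    run_family(function(resp)
      compare_scores(joint, "penalty", resp, pair = penalty_pair),
      "penalty")
  }
  sex_rows <- val[val$tissue_specific == 1 &
                    val$penalty == "elastic_net" &
                    val$validation_sex %in% c("male", "female") &
                    (val$sex_config == "joint" |
                       val$sex_config == val$validation_sex), ,
                  drop = FALSE]
  if (nrow(sex_rows) > 0 && any(sex_rows$sex_config != "joint")) {
    run_family(function(resp)
      compare_scores(sex_rows, "sex_specific", resp), "sex_specific")
  }
  if (any(val$tissue_specific == 0)) {
    ts_rows <- val[val$penalty == "elastic_net" &
                     val$sex_config == "joint" &
                     val$validation_sex == "joint", , drop = FALSE]
    ts_rows <- ts_rows[ts_rows$tissue %in%
                         unique(ts_rows$tissue[ts_rows$tissue_specific == 0]), ,
                       drop = FALSE]
    if (nrow(ts_rows) > 0) {
      run_family(function(resp)
        compare_scores(ts_rows, "tissue_specific", resp),
        "tissue_specific")
    }
  }
  do.call(rbind, out)
}

#' Selection analysis across tissues
#'
#' Builds per-tissue selection profiles from full-size elastic-net
#' clocks, applies coefficient thresholding and the stability filter,
#' computes per-tissue consensus sets and the three-tissue overlap counts
#' at CpG and gene level.
#'
#' @param models Named list (per tissue) of lists of [clock_model()]s.
#' @param annotation Probe annotation data frame.
#' @param cut,min_frac Thresholding and stability parameters.
#' @return List with `profiles`, `consensus`, `cpg_overlap_all`,
#'   `cpg_overlap_any`, `gene_overlap_all`, `gene_overlap_any` (overlap
#'   counts are present when exactly three tissues are given).
#' @export
selection_analysis <- function(models, annotation, cut = 0.1,
                               min_frac = 0.10) {
  keep <- vapply(models, function(ms) length(ms) > 0, TRUE)
  models <- models[keep]
  profiles <- lapply(names(models), function(lab) {
    elnet <- Filter(function(m) m$penalty$name == "elastic_net",
                    models[[lab]])
    if (length(elnet) == 0) return(NULL)
    stability_filter(threshold_coefficients(
      selection_profile(elnet, tissue = lab), cut), min_frac)
  })
  names(profiles) <- names(models)
  profiles <- profiles[!vapply(profiles, is.null, TRUE)]
  consensus <- lapply(profiles, consensus_sets)
  out <- list(profiles = profiles, consensus = consensus)
  if (length(consensus) == 3) {
    labs <- names(consensus)
    sets_all <- lapply(consensus, `[[`, "all_clocks")
    sets_any <- lapply(consensus, `[[`, "any_clock")
    out$cpg_overlap_all <- overlap_counts(sets_all[[1]], sets_all[[2]],
                                          sets_all[[3]], labels = labs)
    out$cpg_overlap_any <- overlap_counts(sets_any[[1]], sets_any[[2]],
                                          sets_any[[3]], labels = labs)
    g_all <- lapply(sets_all, map_to_genes, annotation = annotation)
    g_any <- lapply(sets_any, map_to_genes, annotation = annotation)
    out$gene_overlap_all <- overlap_counts(g_all[[1]], g_all[[2]],
                                           g_all[[3]], labels = labs)
    out$gene_overlap_any <- overlap_counts(g_any[[1]], g_any[[2]],
                                           g_any[[3]], labels = labs)
    out$genes_any <- g_any
  }
  out
}

#' Run the full synthetic end-to-end study
#'
#' Chains simulate, sample/probe preprocessing, the benchmarking harness,
#' the headline mixed-model comparisons and the CpG-selection analysis,
#' writing every artifact into `out_dir`: the study tables, the ground
#' truth, the long-format score table, the comparison table, selection
#' TSVs and a YAML summary of the four headline checks.
#'
#' @param config Configuration list ([default_config()] shape).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `scores`, `comparisons`, `selection`
#'   and `summary`.
#' @export
run_report <- function(config = default_config(), out_dir = tempdir()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- simulate_study(cfg_generator(config))
  write_study(gen$study, file.path(out_dir, "beta_matrix.tsv"),
              file.path(out_dir, "sample_sheet.tsv"),
              file.path(out_dir, "probe_annotation.tsv"))
  write_truth(gen$truth, file.path(out_dir, "ground_truth.tsv"))

  plan <- cfg_plan(config)
  bench <- run_full_benchmark(gen$study, plan,
                              blacklist = config$preprocess$blacklist,
                              keep_models = TRUE)
  write_scores(bench$scores, file.path(out_dir, "scores.tsv"))
  if (!is.null(bench$skipped)) {
    write_tsv(bench$skipped, file.path(out_dir, "skipped_cells.tsv"))
  }

  comparisons <- headline_comparisons(
    bench$scores, penalty_pair = config$compare$penalty_pair)
  write_comparisons(comparisons, file.path(out_dir, "comparisons.tsv"))

  sel <- selection_analysis(bench$models, gen$study$probes)
  sel_tab <- do.call(rbind, lapply(names(sel$consensus), function(lab) {
    data.frame(tissue = lab,
               consensus = c("all_clocks", "any_clock"),
               n_cpgs = c(length(sel$consensus[[lab]]$all_clocks),
                          length(sel$consensus[[lab]]$any_clock)),
               stringsAsFactors = FALSE)
  }))
  write_tsv(sel_tab, file.path(out_dir, "selection_consensus.tsv"))
  if (!is.null(sel$cpg_overlap_any)) {
    venn <- rbind(
      data.frame(level = "cpg", consensus = "all_clocks",
                 region = names(sel$cpg_overlap_all),
                 count = as.integer(sel$cpg_overlap_all)),
      data.frame(level = "cpg", consensus = "any_clock",
                 region = names(sel$cpg_overlap_any),
                 count = as.integer(sel$cpg_overlap_any)),
      data.frame(level = "gene", consensus = "all_clocks",
                 region = names(sel$gene_overlap_all),
                 count = as.integer(sel$gene_overlap_all)),
      data.frame(level = "gene", consensus = "any_clock",
                 region = names(sel$gene_overlap_any),
                 count = as.integer(sel$gene_overlap_any)))
    write_tsv(venn, file.path(out_dir, "venn_counts.tsv"))
  }

  pick <- function(analysis, resp) {
    r <- comparisons[comparisons$analysis == analysis &
                       comparisons$response == resp, , drop = FALSE]
    if (nrow(r) == 0) NULL
    else list(partial_corr = r$partial_corr, contrast = r$contrast,
              p_by = r$p_by)
  }
  summary <- list(
    size_effect = pick("size_effect", "adjusted_r2"),
    penalty = pick("penalty", "adjusted_r2"),
    sex_specific = pick("sex_specific", "adjusted_r2"),
    tissue_specific = pick("tissue_specific", "adjusted_r2"))
  yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  invisible(list(scores = bench$scores, comparisons = comparisons,
                 selection = sel, summary = summary,
                 truth = gen$truth, models = bench$models))
}

#' Single command entry point
#'
#' Dispatches the pipeline subcommands used by the command-line wrapper.
#' Inputs are read from, and artifacts written to, the paths in
#' `config$paths`; every stage is deterministic under `config$seed`.
#'
#' @param command One of `"simulate"`, `"preprocess"`, `"train"`,
#'   `"score"`, `"benchmark"`, `"compare"`, `"select"`, `"report"`.
#' @param config Configuration list; `config$paths` supplies `out_dir`
#'   and the input paths required by the command (`matrix`, `sheet`,
#'   `annotation` for a study; `clock`, `scores` where relevant).
#' @return Invisibly, the command's main artifact.
#' @export
run_command <- function(command, config = default_config()) {
  paths <- config$paths %||% list()
  out_dir <- paths$out_dir %||% tempdir()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study_in <- function() {
    read_study(paths$matrix, paths$sheet, paths$annotation)
  }
  switch(
    command,
    simulate = {
      gen <- simulate_study(cfg_generator(config))
      write_study(gen$study, file.path(out_dir, "beta_matrix.tsv"),
                  file.path(out_dir, "sample_sheet.tsv"),
                  file.path(out_dir, "probe_annotation.tsv"))
      write_truth(gen$truth, file.path(out_dir, "ground_truth.tsv"))
      invisible(gen)
    },
    preprocess = {
      study <- study_in()
      fs <- filter_samples(study, seed = config$seed)
      imp <- impute_missing(fs$study)
      write_study(imp, file.path(out_dir, "filtered_matrix.tsv"),
                  file.path(out_dir, "filtered_sheet.tsv"),
                  file.path(out_dir, "filtered_annotation.tsv"))
      counts <- data.frame(rule = names(fs$report$counts),
                           removed = as.integer(fs$report$counts))
      write_tsv(counts, file.path(out_dir, "filter_report.tsv"))
      invisible(imp)
    },
    train = {
      study <- impute_missing(study_in())
      keep <- rowSums(is.na(study$beta)) == 0 &
        study$probes$probe_class != "rs" &
        !(study$probes$chromosome %in% c("X", "Y")) &
        !study$probes$unreliable &
        !(study$probes$cpg_id %in% config$preprocess$blacklist)
      study <- subset_study(study, probes = which(keep))
      model <- fit_clock(study,
                         penalty = config$plan$penalties[1],
                         seed = config$seed)
      write_clock(model, file.path(out_dir, "clock.tsv"))
      invisible(model)
    },
    score = {
      model <- read_clock(paths$clock)
      study <- impute_missing(study_in())
      m <- study_to_m(subset_study(
        study, probes = which(rowSums(is.na(study$beta)) == 0)))
      rec <- score_clock(model, m, study$samples$age,
                         tissue = model$provenance$tissue)
      if (is.null(rec)) cb_stop_code("fewer than 3 evaluable samples")
      write_scores(rec, file.path(out_dir, "scores.tsv"))
      invisible(rec)
    },
    benchmark = {
      study <- study_in()
      bench <- run_full_benchmark(study, cfg_plan(config),
                                  blacklist = config$preprocess$blacklist)
      write_scores(bench$scores, file.path(out_dir, "scores.tsv"))
      invisible(bench$scores)
    },
    compare = {
      scores <- read_scores(paths$scores)
      cmp <- headline_comparisons(scores,
                                  penalty_pair = config$compare$penalty_pair)
      write_comparisons(cmp, file.path(out_dir, "comparisons.tsv"))
      invisible(cmp)
    },
    select = {
      clocks <- lapply(paths$clocks, read_clock)
      ann <- read_tsv(paths$annotation)
      ann$gene_symbols[is.na(ann$gene_symbols)] <- ""
      tissues <- vapply(clocks, function(m)
        m$provenance$tissue %||% "all", "")
      sel <- selection_analysis(split(clocks, tissues), ann)
      cons <- do.call(rbind, lapply(names(sel$consensus), function(lab)
        data.frame(tissue = lab,
                   n_all = length(sel$consensus[[lab]]$all_clocks),
                   n_any = length(sel$consensus[[lab]]$any_clock))))
      write_tsv(cons, file.path(out_dir, "selection_consensus.tsv"))
      invisible(sel)
    },
    report = run_report(config, out_dir),
    cb_stop_code(sprintf("unknown command '%s'", command))
  )
}
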