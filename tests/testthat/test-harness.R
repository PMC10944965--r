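test_that("tissue aggregation follows dot-boundary prefixes and aliases", {
  sheet <- data.frame(tissue_code = c(
    "A08.186.211.730.885.287.500.270.700", "A12.207.152.CD4",
    "A03x.1", "A03", "A03.620", "A12.207.152"))
  expect_true(aggregate_tissue(sheet, "A08")[1])
  expect_true(aggregate_tissue(sheet, "A12.207.152", exact = TRUE)[2])
  expect_false(aggregate_tissue(sheet, "A12.207.152", exact = TRUE,
                                aliases = character(0))[2])
  expect_false(aggregate_tissue(sheet, "A03")[3])    # dot boundary
  expect_identical(which(aggregate_tissue(sheet, "A03")), c(4L, 5L))
})

test_that("stratified subsampling uses largest-remainder quotas", {
  # strata of sizes (10, 10, 5) via ages in three decade bins
  sheet <- data.frame(age = c(runif(10, 21, 29), runif(10, 31, 39),
                              runif(5, 41, 49)))
  full <- stratified_subsample(sheet, 25, seed = 1)
  expect_identical(full$subsample, 1:25)
  expect_length(full$test, 0)
  part <- stratified_subsample(sheet, 20, seed = 1)
  strat <- findInterval(sheet$age[part$subsample], c(30, 40))
  expect_identical(as.vector(table(strat)), c(8L, 8L, 4L))
  # partition property
  expect_identical(sort(c(part$subsample, part$test)), 1:25)
  expect_identical(part, stratified_subsample(sheet, 20, seed = 1))
  expect_error(stratified_subsample(sheet, 26, seed = 1),
               class = "clockbench_error_bad_code")
})

test_that("proportional quotas hold for a uniform age distribution", {
  withr::with_seed(5, sheet <- data.frame(age = runif(100, 21, 84)))
  part <- stratified_subsample(sheet, 50, seed = 2)
  bins <- cut(sheet$age, c(20, 30, 40, 50, 60, 70, 80, 85))
  for (b in levels(bins)) {
    in_bin <- sum(bins == b)
    picked <- sum(bins[part$subsample] == b)
    expect_lte(abs(picked - in_bin / 2), 1)
  }
})

lodo_cfg <- function(seed, noise = 0) {
  generator_config(tissues = "A03", datasets_per_tissue = 3,
                   samples_per_dataset = 20, n_background_cpgs = 15,
                   n_shared_clock_cpgs = 4,
                   n_tissue_specific_clock_cpgs = 0, noise_sd = noise,
                   batch_sd = 0, missing_rate = 0, n_xy_probes = 0,
                   n_rs_probes = 0, dataset_size_jitter = 0,
                   dataset_noise_mult = c(1, 1),
                   dataset_age_span = c(60, 64), seed = seed)
}

test_that("leave-one-dataset-out emits the expected record set", {
  gen <- simulate_study(lodo_cfg(31))
  plan <- experiment_plan(tissues = list(A03 = list(code = "A03")),
                          penalties = "elastic_net", ladder = c(10),
                          seed = 5)
  res <- suppressWarnings(
    leave_one_dataset_out(gen$study, plan, "A03"))
  val <- res$scores[res$scores$split == "validation" &
                      res$scores$validation_sex == "joint", ]
  # 3 held-out datasets x 2 ladder points (10, full)
  expect_equal(nrow(val), 6)
  expect_setequal(unique(val$gse_id), unique(gen$study$samples$gse_id))
  expect_true(all(res$scores$n >= 3))
  # noiseless generator: every validation fit is exact
  expect_true(all(val$adjusted_r2 > 1 - 1e-6))
  # training and test splits are also scored
  expect_true(all(c("training", "test") %in% res$scores$split))
  expect_error(leave_one_dataset_out(
    subset_study(gen$study,
                 samples = gen$study$samples$gse_id ==
                   gen$study$samples$gse_id[1]),
    plan, "A03"), class = "clockbench_error_bad_code")
})

test_that("undersized validation datasets are skipped with a reason", {
  gen <- simulate_study(lodo_cfg(32))
  keep <- gen$study$samples$gse_id != "GSE10103" |
    gen$study$samples$sample_id %in%
      gen$study$samples$sample_id[gen$study$samples$gse_id == "GSE10103"][1:2]
  small <- subset_study(gen$study, samples = which(keep))
  plan <- experiment_plan(tissues = list(A03 = list(code = "A03")),
                          penalties = "elastic_net", ladder = c(10),
                          seed = 5)
  res <- suppressWarnings(leave_one_dataset_out(small, plan, "A03"))
  expect_false("GSE10103" %in% res$scores$gse_id)
  expect_true(any(grepl("below minimum", res$skipped$reason)))
})

test_that("ladder points above the training size are silently dropped", {
  gen <- simulate_study(lodo_cfg(33))
  plan <- experiment_plan(tissues = list(A03 = list(code = "A03")),
                          penalties = "elastic_net",
                          ladder = c(10, 5000), seed = 5)
  res <- suppressWarnings(leave_one_dataset_out(gen$study, plan, "A03"))
  expect_setequal(unique(res$scores$subsample_size), c(10L, 40L))
})

test_that("the full benchmark is deterministic under its seed", {
  cfg <- generator_config(tissues = c("A03", "A08"),
                          datasets_per_tissue = 2,
                          samples_per_dataset = 15, n_background_cpgs = 10,
                          n_shared_clock_cpgs = 3,
                          n_tissue_specific_clock_cpgs = 1,
                          noise_sd = 0.3, missing_rate = 0,
                          n_xy_probes = 2, n_rs_probes = 1, seed = 77)
  gen <- simulate_study(cfg)
  plan <- default_tissue_plan(cfg, seed = 9, ladder = c(10))
  a <- suppressWarnings(run_full_benchmark(gen$study, plan))
  b <- suppressWarnings(run_full_benchmark(gen$study, plan))
  expect_identical(a$scores, b$scores)
  expect_true(all(a$scores$n >= 3))
})

test_that("blood transfer records pair with tissue-trained records", {
  cfg <- generator_config(datasets_per_tissue = 2, samples_per_dataset = 25,
                          n_background_cpgs = 15, n_shared_clock_cpgs = 3,
                          n_tissue_specific_clock_cpgs = 2,
                          missing_rate = 0, n_xy_probes = 0,
                          n_rs_probes = 0, seed = 41)
  gen <- simulate_study(cfg)
  plan <- default_tissue_plan(cfg, seed = 3, ladder = c(15),
                              blood = "A12.207.152")
  res <- suppressWarnings(run_full_benchmark(gen$study, plan))
  tr <- res$scores[res$scores$tissue_specific == 0, ]
  expect_gt(nrow(tr), 0)
  expect_false("A12.207.152" %in% tr$tissue)
  expect_true(all(tr$split == "validation"))
  # every transfer tissue also has tissue-trained validation records
  own <- res$scores[res$scores$tissue_specific == 1 &
                      res$scores$split == "validation", ]
  expect_true(all(unique(tr$tissue) %in% own$tissue))
})
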