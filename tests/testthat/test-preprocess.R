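study_with_ages <- function(ages, status = "control", family = NA) {
  n <- length(ages)
  beta <- matrix(runif(2 * n, 0.2, 0.8), 2,
                 dimnames = list(c("cg01", "cg02"),
                                 sprintf("s%02d", seq_len(n))))
  methylation_study(beta, data.frame(
    sample_id = colnames(beta), gse_id = "GSE1", age = ages, sex = "F",
    tissue_code = "A03", status = status, family_id = family,
    stringsAsFactors = FALSE),
    data.frame(cpg_id = rownames(beta), chromosome = "1",
               gene_symbols = "", probe_class = "cg", unreliable = FALSE,
               stringsAsFactors = FALSE))
}

test_that("the age window keeps (20, 85] exactly", {
  out <- filter_samples(study_with_ages(c(20, 20.5, 85, 86)), seed = 1)
  expect_identical(sort(out$study$samples$age), c(20.5, 85))
  expect_equal(out$report$counts[["age_low"]], 1)
  expect_equal(out$report$counts[["age_high"]], 1)
})

test_that("exactly one sample per family survives, deterministically", {
  st <- study_with_ages(c(30, 40, 50, 60),
                        family = c("fam1", "fam1", NA, NA))
  out <- filter_samples(st, seed = 5)
  kept <- out$study$samples
  expect_equal(nrow(kept), 3)
  expect_equal(sum(kept$sample_id %in% c("s01", "s02")), 1)
  again <- filter_samples(st, seed = 5)
  expect_identical(kept$sample_id, again$study$samples$sample_id)
})

test_that("non-control samples are removed and clean input is untouched", {
  st <- study_with_ages(c(30, 40, 50), status = c("control", "case",
                                                  "control"))
  out <- filter_samples(st, seed = 1)
  expect_identical(out$study$samples$sample_id, c("s01", "s03"))
  clean <- study_with_ages(c(30, 40, 50))
  expect_identical(filter_samples(clean, 1)$study$samples,
                   clean$samples)
  expect_error(filter_samples(study_with_ages(c(10, 12)), 1),
               class = "clockbench_error_empty_result")
})

test_that("sample-filter counts reconcile with the size change", {
  st <- study_with_ages(c(18, 30, 40, 90, 55, 60),
                        status = c("control", "case", "control", "control",
                                   "control", "control"),
                        family = c(NA, NA, "f", "f", "f", NA))
  out <- filter_samples(st, seed = 2)
  expect_equal(sum(out$report$counts),
               nrow(st$samples) - nrow(out$study$samples))
})

probe_fixture <- function() {
  # 10 shared probes: 2 rs, 1 chrX, 1 blacklisted, 1 missing-after-imputation
  ids <- sprintf("cg%02d", 1:10)
  beta_t <- matrix(runif(40, 0.2, 0.8), 10,
                   dimnames = list(ids, sprintf("t%d", 1:4)))
  beta_v <- matrix(runif(30, 0.2, 0.8), 10,
                   dimnames = list(ids, sprintf("v%d", 1:3)))
  beta_t["cg05", ] <- NA   # fully missing in the training dataset
  probes <- data.frame(
    cpg_id = ids,
    chromosome = c("1", "2", "X", "4", "5", "6", "7", "8", "9", "10"),
    gene_symbols = "", probe_class = c("rs", "rs", rep("cg", 8)),
    unreliable = FALSE, stringsAsFactors = FALSE)
  sheet <- function(ids, gse) data.frame(
    sample_id = ids, gse_id = gse, age = seq(30, 30 + 10 * (length(ids) - 1),
                                             by = 10),
    sex = "M", tissue_code = "A03", status = "control",
    stringsAsFactors = FALSE)
  list(train = methylation_study(beta_t, sheet(colnames(beta_t), "GSE1"),
                                 probes),
       validation = methylation_study(beta_v, sheet(colnames(beta_v), "GSE2"),
                                      probes))
}

test_that("probe filters remove rs, XY, blacklist and missing probes", {
  withr::with_seed(1, fx <- probe_fixture())
  out <- filter_probes(impute_missing(fx$train), impute_missing(fx$validation),
                       blacklist = "cg04")
  expect_identical(out$train$probes$cpg_id,
                   c("cg06", "cg07", "cg08", "cg09", "cg10"))
  expect_identical(out$train$probes$cpg_id, out$validation$probes$cpg_id)
  expect_equal(out$report$counts[["probe_rs"]], 2)
  expect_equal(out$report$counts[["probe_xy"]], 1)
  expect_equal(out$report$counts[["probe_unreliable"]], 1)
  expect_equal(out$report$counts[["probe_missing"]], 1)
})

test_that("probe filtering is invariant to input probe order", {
  withr::with_seed(2, fx <- probe_fixture())
  shuffled <- subset_study(fx$train, probes = sample(10))
  a <- filter_probes(impute_missing(fx$train), impute_missing(fx$validation))
  b <- filter_probes(impute_missing(shuffled), impute_missing(fx$validation))
  expect_identical(a$train$probes$cpg_id, b$train$probes$cpg_id)
  expect_equal(a$train$beta, b$train$beta)
})

test_that("disjoint probe sets raise the empty-set error", {
  withr::with_seed(3, fx <- probe_fixture())
  other <- fx$validation
  other$probes$cpg_id <- sprintf("ch%02d", 1:10)
  rownames(other$beta) <- other$probes$cpg_id
  expect_error(filter_probes(fx$train, other),
               class = "clockbench_error_empty_result")
})

test_that("probe-filter counts conserve the probe universe", {
  withr::with_seed(4, fx <- probe_fixture())
  out <- filter_probes(impute_missing(fx$train), impute_missing(fx$validation),
                       blacklist = "cg04")
  expect_equal(sum(out$report$counts) + nrow(out$train$probes),
               out$report$n_in)
})

test_that("imputation fills per-probe per-dataset means and nothing else", {
  beta <- matrix(c(0.2, NA, 0.4, 0.5, 0.6, NA), nrow = 1)
  dimnames(beta) <- list("cg01", sprintf("s%d", 1:6))
  st <- methylation_study(beta, data.frame(
    sample_id = colnames(beta), gse_id = rep(c("GSE1", "GSE2"), each = 3),
    age = c(30, 40, 50, 30, 40, 50), sex = "F", tissue_code = "A03",
    status = "control", stringsAsFactors = FALSE),
    data.frame(cpg_id = "cg01", chromosome = "1", gene_symbols = "",
               probe_class = "cg", unreliable = FALSE,
               stringsAsFactors = FALSE))
  out <- impute_missing(st)
  expect_equal(out$beta["cg01", "s2"], 0.3)       # mean(0.2, 0.4)
  expect_equal(out$beta["cg01", "s6"], 0.55)      # mean(0.5, 0.6)
  # no missing: identity; fully missing within a dataset: stays missing
  expect_identical(impute_missing(out)$beta, out$beta)
  beta2 <- beta; beta2[1, 4:6] <- NA
  st2 <- st; st2$beta <- beta2
  expect_true(all(is.na(impute_missing(st2)$beta[1, 4:6])))
})

test_that("the logit2 transform matches its closed form and clamps", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(1, epsilon = 1e-6), log2((1 - 1e-6) / 1e-6))
  expect_error(beta_to_m(1.01), class = "clockbench_error_beta_range")
  b <- seq(0.01, 0.99, by = 0.01)
  m <- beta_to_m(b)
  expect_true(all(diff(m) > 0))                       # strictly increasing
  expect_equal(m, -rev(beta_to_m(rev(1 - b))))        # antisymmetry
  mat <- matrix(c(0.2, 0.8, NA, 0.5), 2)
  out <- beta_to_m(mat)
  expect_identical(dim(out), dim(mat))
  expect_true(is.na(out[1, 2]))
})

test_that("the normalization hook defaults to the identity", {
  st <- tiny_study()
  expect_identical(normalize_study(st), st)
  doubled <- normalize_study(st, method = "custom",
                             fun = function(s) { s$beta <- s$beta / 2; s })
  expect_equal(doubled$beta, st$beta / 2)
  expect_error(normalize_study(st, method = "custom"),
               class = "clockbench_error_bad_code")
})
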