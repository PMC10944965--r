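# Fixture builders and independent oracles shared across the suite.

tiny_study <- function() {
  beta <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), nrow = 3,
                 dimnames = list(c("cg01", "cg02", "cg03"), c("s1", "s2")))
  samples <- data.frame(
    sample_id = c("s1", "s2"), gse_id = c("GSE1", "GSE1"),
    age = c(30, 60), sex = c("F", "M"),
    tissue_code = "A12.207.152", status = "control",
    stringsAsFactors = FALSE)
  probes <- data.frame(
    cpg_id = c("cg01", "cg02", "cg03"), chromosome = c("1", "2", "3"),
    gene_symbols = c("GENE1", "", "GENE2;GENE3"), probe_class = "cg",
    unreliable = FALSE, stringsAsFactors = FALSE)
  methylation_study(beta, samples, probes)
}

# random valid study with controllable size
random_study <- function(n_probes = 8, n_samples = 10, n_gse = 2,
                         missing_rate = 0, seed = 1) {
  withr::with_seed(seed, {
    beta <- matrix(runif(n_probes * n_samples, 0.05, 0.95), n_probes,
                   dimnames = list(sprintf("cg%03d", seq_len(n_probes)),
                                   sprintf("s%03d", seq_len(n_samples))))
    if (missing_rate > 0) {
      beta[runif(length(beta)) < missing_rate] <- NA
    }
    samples <- data.frame(
      sample_id = colnames(beta),
      gse_id = sprintf("GSE%d", rep_len(seq_len(n_gse), n_samples)),
      age = runif(n_samples, 21, 84),
      sex = sample(c("F", "M"), n_samples, replace = TRUE),
      tissue_code = "A12.207.152", status = "control",
      stringsAsFactors = FALSE)
    probes <- data.frame(
      cpg_id = rownames(beta),
      chromosome = sample(as.character(1:22), n_probes, replace = TRUE),
      gene_symbols = "", probe_class = "cg", unreliable = FALSE,
      stringsAsFactors = FALSE)
    methylation_study(beta, samples, probes)
  })
}

random_clock <- function(n_cpg = 5, seed = 1) {
  withr::with_seed(seed, {
    coefs <- setNames(round(rnorm(n_cpg), 6), sprintf("cg%03d", seq_len(n_cpg)))
    coefs[sample(n_cpg, 1)] <- 0
    clock_model(intercept = rnorm(1), coefficients = coefs,
                coef_std = coefs * 2, penalty = penalty_spec("lasso"),
                lambda = 0.123,
                provenance = list(tissue = "A12.207.152",
                                  sex_config = "joint", n_train = 42L,
                                  gse_ids = c("GSE1", "GSE2"),
                                  subsample_size = 40L, seed = 7L))
  })
}

# the solver's standardization (1/n variance), used by the oracles
std_design <- function(M, age) {
  n <- nrow(M)
  ctr <- colMeans(M)
  Xc <- sweep(M, 2, ctr)
  sc <- sqrt(colSums(Xc^2) / n)
  list(Xs = sweep(Xc, 2, sc, "/"), yc = age - mean(age), n = n)
}

enet_objective <- function(w, Xs, yc, lam, alpha) {
  r <- yc - Xs %*% w
  sum(r^2) / (2 * nrow(Xs)) +
    lam * (alpha * sum(abs(w)) + (1 - alpha) / 2 * sum(w^2))
}

# independent numeric minimizer: accelerated proximal gradient (FISTA)
# with full-vector updates — a different algorithm family from cyclic
# coordinate minimization, provably convergent on this strongly convex
# objective (simplex methods stall at the L1 kinks)
pg_minimize <- function(Xs, yc, lam, alpha, iters = 2e5, tol = 1e-14) {
  n <- nrow(Xs)
  G <- crossprod(Xs) / n
  q <- drop(crossprod(Xs, yc)) / n
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values) +
    lam * (1 - alpha)
  st <- 1 / L
  w <- z <- rep(0, ncol(Xs))
  th <- 1
  for (k in seq_len(iters)) {
    grad <- drop(G %*% z) - q + lam * (1 - alpha) * z
    wn <- z - st * grad
    wn <- sign(wn) * pmax(abs(wn) - st * lam * alpha, 0)
    thn <- (1 + sqrt(1 + 4 * th^2)) / 2
    z <- wn + ((th - 1) / thn) * (wn - w)
    done <- max(abs(wn - w)) < tol
    w <- wn
    th <- thn
    if (done) break
  }
  list(par = as.numeric(w), value = enet_objective(w, Xs, yc, lam, alpha))
}

# brute-force REML oracle: dense-matrix restricted likelihood evaluated on
# a two-stage zooming grid over (log tau2, log sigma2)
grid_reml <- function(y, X, groups) {
  X <- as.matrix(X)
  n <- length(y)
  Z <- outer(groups, unique(groups), `==`) * 1
  neg2_reml <- function(tau2, sigma2) {
    V <- sigma2 * diag(n) + tau2 * tcrossprod(Z)
    Vi <- solve(V)
    XtVX <- t(X) %*% Vi %*% X
    beta <- solve(XtVX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    as.numeric(determinant(V)$modulus + determinant(XtVX)$modulus +
                 t(r) %*% Vi %*% r)
  }
  lt <- seq(log(1e-6), log(10), length.out = 41)
  ls <- seq(log(1e-4), log(10), length.out = 41)
  for (zoom in 1:10) {
    grid <- expand.grid(lt = lt, ls = ls)
    val <- mapply(function(a, b) neg2_reml(exp(a), exp(b)),
                  grid$lt, grid$ls)
    best <- grid[which.min(val), ]
    wt <- diff(range(lt)) / 8
    ws <- diff(range(ls)) / 8
    lt <- seq(best$lt - wt, best$lt + wt, length.out = 21)
    ls <- seq(best$ls - ws, best$ls + ws, length.out = 21)
  }
  tau2 <- exp(best$lt); sigma2 <- exp(best$ls)
  V <- sigma2 * diag(n) + tau2 * tcrossprod(Z)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  list(tau2 = tau2, sigma2 = sigma2, beta = drop(beta))
}

default_tissue_plan <- function(cfg, seed, penalties = "elastic_net",
                                sex_train = "joint", ladder = c(25, 50),
                                blood = NULL) {
  experiment_plan(
    tissues = stats::setNames(
      lapply(cfg$tissues, function(code) list(code = code, exact = FALSE)),
      cfg$tissues),
    penalties = penalties, sex_train = sex_train, ladder = ladder,
    blood_code = blood, seed = seed)
}
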