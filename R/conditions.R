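#' @keywords internal
"_PACKAGE"

#' @useDynLib clockbench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Named condition helpers: every documented validation failure raises a
# distinct condition class so callers (and tests) can discriminate them.
cb_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "clockbench_error")))
}

cb_stop_dimension <- function(msg) cb_stop(msg, "clockbench_error_dimension")
cb_stop_duplicate <- function(msg) cb_stop(msg, "clockbench_error_duplicate_id")
cb_stop_range     <- function(msg) cb_stop(msg, "clockbench_error_beta_range")
cb_stop_code      <- function(msg) cb_stop(msg, "clockbench_error_bad_code")
cb_stop_empty     <- function(msg) cb_stop(msg, "clockbench_error_empty_result")

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded helpers do not perturb the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic 31-bit hash of experiment-cell labels, combined with the
# master seed, so every benchmark cell gets an independent reproducible seed.
cell_seed <- function(master, ...) {
  s <- paste(c(as.character(master), vapply(list(...), as.character, "")),
             collapse = "|")
  h <- as.integer(master) %% 2147483562L
  for (ch in utf8ToInt(s)) {
    h <- as.integer((as.double(h) * 31 + ch) %% 2147483562)
  }
  h + 1L
}
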