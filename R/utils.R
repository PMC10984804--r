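# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so generators are reproducible without side
# effects on the session.
.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

.is_count_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && !is.null(rownames(x)) && !is.null(colnames(x))
}

.check_count_matrix <- function(counts) {
  .assert(.is_count_matrix(counts),
          "`counts` must be a numeric matrix with gene rownames and sample colnames")
  .assert(!anyDuplicated(rownames(counts)), "duplicate gene ids in `counts`")
  .assert(!anyDuplicated(colnames(counts)), "duplicate sample ids in `counts`")
  .assert(all(counts >= 0), "`counts` must be non-negative")
  invisible(counts)
}

# Geometric mean, used for the TMM factor rescaling contract.
.geomean <- function(x) exp(mean(log(x)))
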