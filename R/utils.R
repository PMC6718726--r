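# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Days per month used to convert overall survival in days to the
# short/medium/long grouping (Julian year / 12).
MONTH_DAYS <- 30.4375

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generators are pure functions of (config, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Population (n-denominator) standard deviation.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Stratified, globally balanced k-fold assignment: members of each class are
# shuffled, classes concatenated, and fold ids cycled over that ordering so
# fold sizes differ by at most one while classes stay spread across folds.
make_folds <- function(classes, k, seed = NULL) {
  n <- length(classes)
  if (k < 2L) stopf("need at least 2 folds")
  if (k > n) stopf("more folds (%d) than observations (%d)", k, n)
  with_seed(seed, {
    ord <- unlist(lapply(split(seq_len(n), classes),
                         function(ix) ix[sample.int(length(ix))]),
                  use.names = FALSE)
    folds <- integer(n)
    folds[ord] <- rep_len(sample.int(k), n)
    folds
  })
}
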