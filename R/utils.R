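# Internal helpers shared across modules.

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so generators do not perturb the session RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
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

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_fraction <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (open && (x <= 0 || x >= 1)) || (!open && (x < 0 || x > 1))) {
    stop(sprintf("`%s` must be a proportion in %s", name,
                 if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  }
  as.numeric(x)
}

#' Split-chain potential scale reduction factor
#'
#' Computes the split-\eqn{\widehat{R}} convergence diagnostic for a single
#' MCMC chain: the chain is split in half and the usual between/within
#' variance ratio is formed. Values near 1 indicate the two halves explore
#' the same distribution.
#'
#' @param x Numeric vector of (post burn-in, thinned) draws.
#' @return A single numeric \eqn{\widehat{R}} value; `NA` if fewer than 4
#'   draws are supplied or the chain is constant.
#' @export
rhat_split <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L) return(NA_real_)
  half <- n %/% 2L
  chains <- list(x[seq_len(half)], x[(n - half + 1L):n])
  m <- length(chains)
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  w <- mean(vars)
  if (!is.finite(w) || w <= 0) return(NA_real_)
  b <- half * stats::var(means)
  var_plus <- (half - 1) / half * w + b / half
  sqrt(var_plus / w)
}

# Significance stars at the conventional thresholds used in trial reports.
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi <= 1e-4) "****"
    else if (pi <= 1e-3) "***"
    else if (pi <= 0.01) "**"
    else if (pi <= 0.05) "*"
    else "ns"
  }, character(1))
}
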