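# Independent oracles used by the tests. These re-derive the quantities the
# package computes through deliberately different algorithms, so agreement
# is evidence of correctness rather than repetition.

# Additive relationship matrix via the coancestry recursion f(i, j) with a
# matrix memo; A = 2f, diagonal 1 + F. Independent of the tabular method.
oracle_a_matrix <- function(ped) {
  ped <- as.data.frame(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  f <- matrix(NA_real_, n, n)
  kin <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (!is.na(f[i, j])) return(f[i, j])
    val <- if (i == j) {
      0.5 * (1 + kin(si[i], di[i]))
    } else {
      a <- max(i, j); b <- min(i, j)
      0.5 * (kin(b, si[a]) + kin(b, di[a]))
    }
    f[i, j] <<- val; f[j, i] <<- val
    val
  }
  for (i in seq_len(n)) for (j in i:n) kin(i, j)
  out <- 2 * f
  dimnames(out) <- list(ped$id, ped$id)
  out
}

# Random valid pedigree: founders plus offspring whose parents are drawn
# from earlier individuals (occasionally selfed).
random_pedigree <- function(n, n_founders = 5L) {
  id <- sprintf("I%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1L):n) {
    p <- sample(seq_len(i - 1L), 2L, replace = TRUE)
    if (stats::runif(1) < 0.2) p[2] <- p[1]   # selfing
    sire[i] <- id[p[1]]; dam[i] <- id[p[2]]
  }
  data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
}

# Exhaustive Otsu: between-class variance computed by raw subsetting at
# every interior bin edge.
oracle_otsu <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  edges <- min(v) + seq_len(n_bins - 1L) * (max(v) - min(v)) / n_bins
  bcv <- vapply(edges, function(t) {
    a <- v[v <= t]; b <- v[v > t]
    if (!length(a) || !length(b)) return(-Inf)
    (length(a) / length(v)) * (length(b) / length(v)) *
      (mean(a) - mean(b))^2
  }, numeric(1))
  edges[which.max(bcv)]
}

# Textbook Welch statistic.
oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p)
}

# Direct mixed-model-equation solve for the single-trait animal model with
# identity residual structure and known variances.
oracle_mme <- function(y, line_id, ainv, sigma_a2, sigma_e2) {
  ids <- rownames(ainv)
  zid <- match(line_id, ids)
  n <- length(y); q <- nrow(ainv)
  Z <- matrix(0, n, q)
  Z[cbind(seq_len(n), zid)] <- 1
  X <- matrix(1, n, 1)
  C <- rbind(cbind(crossprod(X) / sigma_e2, crossprod(X, Z) / sigma_e2),
             cbind(crossprod(Z, X) / sigma_e2,
                   crossprod(Z) / sigma_e2 + as.matrix(ainv) / sigma_a2))
  rhs <- c(crossprod(X, y), crossprod(Z, y)) / sigma_e2
  sol <- solve(C, rhs)
  list(mu = sol[1], g = stats::setNames(sol[-1], ids))
}

# Small simulated progeny-row dataset shared by several tests.
make_pr_dataset <- function(n_crosses = 150, n_founders = 20,
                            selfing = 2, h2 = c(0.3, 0.3, 0.3),
                            spatial_sd = 0, seed = 1) {
  ped <- simulate_pedigree(n_founders, n_crosses, selfing, seed = seed)
  arch <- genetic_architecture(h2 = h2)
  bv <- simulate_breeding_values(ped, arch, seed = seed + 1)
  lines <- attr(ped, "line_ids")
  lay <- field_layout(lines, c("FND0001", "FND0002"), n_cols = 15)
  pheno <- simulate_trial(lay, bv, arch, spatial_sd = spatial_sd,
                          seed = seed + 2)
  list(ped = ped, arch = arch, bv = bv, lines = lines, layout = lay,
       pheno = pheno, ainv = a_inverse(ped))
}
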