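#' Fit a pedigree-based animal model by Gibbs sampling
#'
#' Fits the single-trait mixed model
#' \deqn{y = X\beta + Zg + e, \quad g \sim N(0, A\sigma_a^2), \quad
#'       e \sim N(0, R\sigma_e^2)}
#' where \eqn{A} is the pedigree numerator relationship matrix (supplied as
#' its sparse inverse), \eqn{R} an optional field correlation matrix, and
#' the fixed part holds the intercept plus any covariates on the right-hand
#' side of `formula` (e.g. `yield ~ acc` for yield adjusted for canopy
#' coverage, a distinct selection trait from yield itself). Replicated
#' checks share one genetic effect across their plots. Posterior samples
#' are drawn by single-site Gibbs with scaled-inverse-chi-square updates
#' for the variance components; the posterior means of \eqn{g} are the
#' reported breeding values (BLUPs), and narrow-sense heritability is the
#' posterior mean of \eqn{\sigma_a^2 / (\sigma_a^2 + \sigma_e^2)} computed
#' draw by draw.
#'
#' Covariates are centered and scaled before sampling for a well-behaved
#' chain; reported coefficients are rescaled to the original units. One
#' regression slope is fitted per covariate (not per genotype). Priors are
#' weakly informative scaled-inverse-chi-square with `nu = 1` and scale
#' one tenth of the phenotypic variance for each component, chosen diffuse
#' enough not to pull the heritability toward one half on unreplicated
#' data.
#'
#' @param formula Model formula: response on the left, fixed covariates on
#'   the right (`~ 1` for none).
#' @param data Plot-level data frame; must contain the response, the
#'   covariates and the `line` column.
#' @param ainv Sparse \eqn{A^{-1}} from [a_inverse()] (dimnames are the
#'   individual ids; may include unphenotyped ancestors).
#' @param line Name of the column in `data` holding the individual id of
#'   each plot.
#' @param R Optional `"spatial_r"` object from [build_spatial_R()], or a
#'   correlation matrix, for the correlated-residual spatial adjustment.
#'   With `spatial = "covariate"` the neighbor-average phenotype is added
#'   as a fixed covariate instead and `R` is ignored.
#' @param spatial `"none"`, `"correlation"` or `"covariate"`.
#' @param niter,burnin,thin Chain settings (defaults 6000 / 1000 / 5).
#' @param priors List with `nu_a`, `S_a`, `nu_e`, `S_e`; `NULL` for the
#'   defaults described above.
#' @param fix_variances Optional `c(sigma_a2 =, sigma_e2 =)` to hold the
#'   variance components fixed (degenerate priors); used for validation
#'   against the direct mixed-model-equation solution.
#' @param seed Integer seed (mandatory: chains are reproducible).
#' @return An object of class `"animal_model"` with posterior summaries,
#'   thinned draws and convergence diagnostics. Use [blup()],
#'   [heritability()], `coef()`, `summary()`, [blup_correlations()].
#' @examples
#' ped <- simulate_pedigree(20, 60, 3, seed = 1)
#' arch <- genetic_architecture()
#' bv <- simulate_breeding_values(ped, arch, seed = 2)
#' lay <- field_layout(attr(ped, "line_ids"), c("FND0001", "FND0002"),
#'                     n_cols = 8)
#' ph <- simulate_trial(lay, bv, arch, seed = 3)
#' fit <- animal_model(yield ~ 1, ph, a_inverse(ped), niter = 600,
#'                     burnin = 100, seed = 4)
#' heritability(fit)
#' @export
animal_model <- function(formula, data, ainv, line = "line_id", R = NULL,
                         spatial = c("none", "correlation", "covariate"),
                         niter = 6000L, burnin = 1000L, thin = 5L,
                         priors = NULL, fix_variances = NULL, seed) {
  if (missing(spatial) && !is.null(R)) spatial <- "correlation"
  spatial <- match.arg(spatial)
  cl <- match.call()
  niter <- check_count(niter, "niter", min = 1L)
  burnin <- check_count(burnin, "burnin", min = 0L)
  thin <- check_count(thin, "thin", min = 1L)
  if (burnin >= niter) stop("niter must exceed burnin", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(is.data.frame(data), line %in% names(data))

  trait <- deparse(formula[[2]])
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (spatial == "covariate") {
    data$.nbr <- neighbor_covariate(data, trait)
    formula <- stats::update(formula, . ~ . + .nbr)
    mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
    y <- stats::model.response(mf)
  }
  X <- stats::model.matrix(formula, mf)
  # center/scale non-intercept columns
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  for (j in seq_len(ncol(X))) {
    if (colnames(X)[j] == "(Intercept)") next
    ctr[j] <- mean(X[, j])
    s <- stats::sd(X[, j])
    scl[j] <- if (is.finite(s) && s > 0) s else 1
    X[, j] <- (X[, j] - ctr[j]) / scl[j]
  }

  ids <- rownames(ainv)
  if (is.null(ids)) stop("ainv must carry individual ids as dimnames",
                         call. = FALSE)
  zid <- match(as.character(data[[line]]), ids)
  if (anyNA(zid)) {
    stop("phenotyped lines missing from the relationship matrix: ",
         paste(utils::head(unique(data[[line]][is.na(zid)]), 5),
               collapse = ", "), call. = FALSE)
  }

  use_rinv <- FALSE
  rinv <- matrix(0, 1, 1)
  r_obj <- NULL
  if (spatial == "correlation") {
    if (is.null(R)) R <- build_spatial_R(data, trait)
    r_obj <- R
    rmat <- if (inherits(R, "spatial_r")) R$R else R
    rmat <- as.matrix(rmat)
    if (nrow(rmat) != nrow(data)) {
      stop("R dimension must equal the number of plots", call. = FALSE)
    }
    ev_min <- min(eigen(rmat, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min <= 0) stop("R must be positive definite", call. = FALSE)
    rinv <- solve(rmat)
    use_rinv <- TRUE
  }

  vy <- stats::var(y)
  if (is.null(priors)) {
    # proper but diffuse: a scale prior centered high (e.g. half the
    # phenotypic variance with several df) implicitly centers h2 at 0.5
    # and visibly biases low-heritability traits upward on unreplicated
    # data, so the default keeps both scales small and the df minimal
    priors <- list(nu_a = 1, S_a = 0.1 * vy, nu_e = 1, S_e = 0.1 * vy)
  }
  fix_var <- !is.null(fix_variances)
  sa2_fix <- if (fix_var) fix_variances[["sigma_a2"]] else 0
  se2_fix <- if (fix_var) fix_variances[["sigma_e2"]] else 0

  res <- with_seed(seed, {
    .gibbs_animal(as.numeric(y), X, as.integer(zid),
                  methods::as(methods::as(ainv, "CsparseMatrix"),
                              "generalMatrix"),
                  rinv, use_rinv,
                  niter, burnin, thin,
                  priors$nu_a, priors$S_a, priors$nu_e, priors$S_e,
                  fix_var, sa2_fix, se2_fix)
  })

  draws <- data.frame(sigma_a2 = as.numeric(res$sigma_a2),
                      sigma_e2 = as.numeric(res$sigma_e2))
  bdraws <- res$b
  colnames(bdraws) <- colnames(X)
  # rescale coefficients to original covariate units
  borig <- bdraws
  for (j in seq_len(ncol(borig))) {
    if (colnames(borig)[j] == "(Intercept)") next
    borig[, j] <- borig[, j] / scl[j]
  }
  if ("(Intercept)" %in% colnames(borig) && ncol(borig) > 1L) {
    adj <- as.matrix(bdraws[, -match("(Intercept)", colnames(bdraws)),
                            drop = FALSE]) %*%
      (ctr[colnames(X) != "(Intercept)"] / scl[colnames(X) != "(Intercept)"])
    borig[, "(Intercept)"] <- borig[, "(Intercept)"] - as.numeric(adj)
  }
  draws$h2 <- draws$sigma_a2 / (draws$sigma_a2 + draws$sigma_e2)

  g <- stats::setNames(as.numeric(res$g_mean), ids)
  phenotyped <- unique(as.character(data[[line]]))
  fitted_vals <- as.numeric(X %*% colMeans(bdraws)) + g[zid]

  structure(list(
    call = cl, trait = trait, formula = formula,
    blup = g, blup_sd = stats::setNames(sqrt(pmax(res$g_var, 0)), ids),
    phenotyped = phenotyped,
    coefficients = colMeans(borig),
    coef_draws = borig,
    draws = draws,
    h2 = mean(draws$h2),
    sigma_a2 = mean(draws$sigma_a2), sigma_e2 = mean(draws$sigma_e2),
    diagnostics = c(rhat_sigma_a2 = rhat_split(draws$sigma_a2),
                    rhat_sigma_e2 = rhat_split(draws$sigma_e2)),
    spatial = spatial, R = r_obj, priors = priors,
    chain = c(niter = niter, burnin = burnin, thin = thin, seed = seed),
    fitted.values = fitted_vals,
    residuals = as.numeric(y) - fitted_vals,
    y = as.numeric(y), line_index = zid,
    nobs = length(y)),
    class = "animal_model")
}

#' Breeding values (BLUPs) from a fitted animal model
#'
#' @param object An `"animal_model"`.
#' @param all Return genetic effects for every pedigree individual
#'   (`TRUE`) or only the phenotyped ones (default).
#' @return Named numeric vector of posterior-mean genetic effects.
#' @export
blup <- function(object, all = FALSE) {
  UseMethod("blup")
}

#' @export
blup.animal_model <- function(object, all = FALSE) {
  if (all) object$blup else object$blup[object$phenotyped]
}

#' Narrow-sense heritability from posterior draws
#'
#' Computes \eqn{h^2 = \sigma_a^2 / (\sigma_a^2 + \sigma_e^2)} for each
#' kept draw and averages the ratios (ratio-then-average, not a ratio of
#' posterior means).
#'
#' @param object An `"animal_model"` fit.
#' @param ... Unused.
#' @return Posterior-mean heritability in `[0, 1]`.
#' @export
heritability <- function(object, ...) UseMethod("heritability")

#' @export
heritability.animal_model <- function(object, ...) {
  mean(object$draws$h2)
}

#' Pearson correlations among BLUP vectors of several fits
#'
#' The phenotypic-correlation summary of a multi-trait evaluation: pairwise
#' Pearson correlations among the breeding-value vectors of the supplied
#' fits, over the intersection of their phenotyped lines.
#'
#' @param fits Named list of `"animal_model"` objects (or named numeric
#'   BLUP vectors).
#' @return Symmetric correlation matrix.
#' @export
blup_correlations <- function(fits) {
  vecs <- lapply(fits, function(f) if (inherits(f, "animal_model"))
    blup(f) else f)
  common <- Reduce(intersect, lapply(vecs, names))
  if (length(common) < 3L) stop("need at least 3 shared lines", call. = FALSE)
  m <- sapply(vecs, function(v) v[common])
  stats::cor(m)
}

#' @export
print.animal_model <- function(x, ...) {
  cat("Animal model (Gibbs):", x$trait, "\n")
  cat(sprintf("  %d plots, %d phenotyped lines; chain %d/%d/%d\n",
              x$nobs, length(x$phenotyped), x$chain["niter"],
              x$chain["burnin"], x$chain["thin"]))
  cat(sprintf("  sigma_a2 = %.4g  sigma_e2 = %.4g  h2 = %.3f\n",
              x$sigma_a2, x$sigma_e2, x$h2))
  invisible(x)
}

#' @export
summary.animal_model <- function(object, ...) {
  qs <- function(v) stats::quantile(v, c(0.025, 0.5, 0.975))
  vc <- rbind(sigma_a2 = c(mean = mean(object$draws$sigma_a2),
                           qs(object$draws$sigma_a2)),
              sigma_e2 = c(mean = mean(object$draws$sigma_e2),
                           qs(object$draws$sigma_e2)),
              h2 = c(mean = mean(object$draws$h2), qs(object$draws$h2)))
  co <- rbind(mean = colMeans(object$coef_draws),
              sd = apply(object$coef_draws, 2, stats::sd))
  out <- list(call = object$call, trait = object$trait, varcomp = vc,
              coefficients = t(co), diagnostics = object$diagnostics,
              n = object$nobs, n_lines = length(object$phenotyped))
  class(out) <- "summary.animal_model"
  out
}

#' @export
print.summary.animal_model <- function(x, ...) {
  cat("Animal model (Gibbs):", x$trait, "\n")
  cat(sprintf("%d plots, %d phenotyped lines\n", x$n, x$n_lines))
  cat("\nVariance components (posterior):\n")
  print(round(x$varcomp, 4))
  cat("\nFixed effects (posterior, original scale):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("\nsplit R-hat: sigma_a2 %.3f, sigma_e2 %.3f\n",
              x$diagnostics["rhat_sigma_a2"], x$diagnostics["rhat_sigma_e2"]))
  invisible(x)
}

#' @export
coef.animal_model <- function(object, ...) object$coefficients

#' @export
fitted.animal_model <- function(object, ...) object$fitted.values

#' @export
residuals.animal_model <- function(object, ...) object$residuals

#' @export
predict.animal_model <- function(object, lines = NULL, ...) {
  mu <- object$coefficients[["(Intercept)"]]
  g <- if (is.null(lines)) blup(object) else object$blup[lines]
  mu + g
}

#' @export
plot.animal_model <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(oldpar))
  graphics::plot(x$draws$sigma_a2, type = "l", xlab = "kept draw",
                 ylab = expression(sigma[a]^2), main = x$trait)
  graphics::plot(x$draws$h2, type = "l", xlab = "kept draw",
                 ylab = expression(h^2), main = "heritability")
  invisible(x)
}

#' Fit a trait with a fixed covariate in the animal model
#'
#' Convenience wrapper for covariate-adjusted traits such as yield given
#' ACC: identical sampler with one additional fixed regression slope on the
#' centered covariate.
#'
#' @param pheno Plot-level data.
#' @param ainv Sparse relationship inverse.
#' @param trait,covariate Column names in `pheno`.
#' @param ... Passed to [animal_model()].
#' @return An `"animal_model"`.
#' @export
fit_trait_with_covariate <- function(pheno, ainv, trait, covariate, ...) {
  f <- stats::as.formula(paste(trait, "~", covariate))
  animal_model(f, pheno, ainv, ...)
}
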