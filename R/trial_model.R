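#' Fit a multi-location yield-trial mixed model by REML
#'
#' Fits the alpha-lattice trial model
#' \deqn{y_{ijkl} = \mu + g_i + loc_j + r_{k(j)} + b_{l(k(j))} +
#'       (g \times loc)_{ij} + e_{ijkl}}
#' with independent random effects for genotype, location, replication
#' nested in location, incomplete block nested in replication, and
#' genotype-by-location interaction. Variance components are estimated by
#' direct maximization of the profiled restricted log-likelihood over log
#' variance ratios (residual variance profiled out; non-negativity enforced
#' by the log parameterization; components shrinking to zero are dropped
#' and the model refit). Genotype can be random (preliminary trials;
#' effects are empirical BLUPs) or fixed (advanced trials; generalized
#' least squares with sum-to-zero contrasts). Covariates on the right-hand
#' side of `formula` (e.g. maturity R8) are centered and enter as fixed
#' regressions.
#'
#' Components that the design cannot identify (a single location, a single
#' replicate, no blocking) are dropped with a warning before fitting.
#'
#' @param formula Response on the left; optional fixed covariates on the
#'   right (`~ 1` for none).
#' @param data Plot-level data frame with columns `line_id`, `location`,
#'   `rep`, `block` (block may be absent).
#' @param genotype `"random"` or `"fixed"`.
#' @param n_starts Number of optimizer starts (the best is kept).
#' @param tol Convergence tolerance on the restricted log-likelihood.
#' @return An object of class `"trial_model"`: variance components
#'   (`varcomp`), fixed effects (`beta`), genotype effects (`genotype_eff`)
#'   with standard errors, the restricted log-likelihood (`logLik`), and
#'   bookkeeping. Use [adjusted_means()], `summary()`, `coef()`,
#'   `residuals()`.
#' @examples
#' sim <- simulate_yield_trial(sprintf("L%02d", 1:20),
#'                             rnorm(20, 0, 20), mu = 500, seed = 1)
#' fit <- trial_model(yield ~ 1, sim)
#' fit$varcomp
#' @export
trial_model <- function(formula, data, genotype = c("random", "fixed"),
                        n_starts = 2L, tol = 1e-8) {
  genotype <- match.arg(genotype)
  cl <- match.call()
  stopifnot(is.data.frame(data))
  need <- c("line_id", "location", "rep")
  if (!all(need %in% names(data))) {
    stop("data must have columns line_id, location, rep", call. = FALSE)
  }
  response <- deparse(formula[[2]])
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- as.numeric(stats::model.response(mf))
  n <- length(y)

  covar <- stats::model.matrix(formula, mf)
  covar <- covar[, colnames(covar) != "(Intercept)", drop = FALSE]
  cov_center <- if (ncol(covar)) colMeans(covar) else numeric(0)
  covar <- sweep(covar, 2, cov_center, "-")

  geno <- factor(as.character(data$line_id))
  loc <- factor(as.character(data$location))
  repf <- factor(paste(data$location, data$rep, sep = ":"))
  has_block <- "block" %in% names(data) && !all(is.na(data$block))
  blockf <- if (has_block) {
    factor(paste(data$location, data$rep, data$block, sep = ":"))
  } else NULL

  rand <- list()
  dropped <- character(0)
  if (genotype == "random") rand$genotype <- geno
  if (nlevels(loc) >= 2L) rand$location <- loc else {
    dropped <- c(dropped, "location", "gxl")
  }
  if (nlevels(repf) > nlevels(loc)) rand$rep_in_location <- repf else {
    dropped <- c(dropped, "rep_in_location")
  }
  if (has_block && nlevels(blockf) > nlevels(repf)) {
    rand$block <- blockf
  } else dropped <- c(dropped, "block")
  if (nlevels(loc) >= 2L) {
    rand$gxl <- factor(paste(as.character(geno), as.character(loc),
                             sep = ":"))
  }
  if (length(dropped)) {
    warning("dropping unidentifiable components: ",
            paste(unique(dropped), collapse = ", "))
  }

  Zs <- lapply(rand, function(f) {
    Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                         dims = c(length(f), nlevels(f)),
                         dimnames = list(NULL, levels(f)))
  })
  ZZt <- lapply(Zs, function(Z) as.matrix(Matrix::tcrossprod(Z)))

  if (genotype == "fixed") {
    gm <- stats::model.matrix(~ geno, contrasts.arg = list(geno = "contr.sum"))
    X <- cbind(gm, covar)
    colnames(X)[1] <- "(Intercept)"
  } else {
    X <- cbind(`(Intercept)` = 1, covar)
  }
  p <- qr(X)$rank
  if (p < ncol(X)) stop("singular fixed-effect design", call. = FALSE)

  k <- length(ZZt)
  profile <- function(theta) {
    V0 <- diag(n)
    for (j in seq_len(k)) V0 <- V0 + exp(theta[j]) * ZZt[[j]]
    ch <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(ch)) return(list(rll = -1e10))
    W <- backsolve(ch, cbind(y, X), transpose = TRUE)
    wy <- W[, 1]
    wx <- W[, -1, drop = FALSE]
    xtvx <- crossprod(wx)
    beta <- tryCatch(solve(xtvx, crossprod(wx, wy)),
                     error = function(e) NULL)
    if (is.null(beta)) return(list(rll = -1e10))
    q_form <- sum(wy^2) - as.numeric(crossprod(beta, crossprod(wx, wy)))
    q_form <- max(q_form, 1e-12)
    se2 <- q_form / (n - p)
    logdet_v <- 2 * sum(log(diag(ch)))
    logdet_x <- as.numeric(determinant(xtvx, logarithm = TRUE)$modulus)
    rll <- -0.5 * ((n - p) * log(se2) + logdet_v + logdet_x +
                     (n - p) * (1 + log(2 * pi)))
    list(rll = rll, beta = as.numeric(beta), se2 = se2, chol = ch,
         xtvx = xtvx)
  }

  obj <- function(theta) -profile(theta)$rll
  starts <- list(rep(log(0.1), k), rep(log(1), k))
  if (n_starts > 2L) {
    for (s in seq_len(n_starts - 2L)) {
      starts[[2L + s]] <- stats::runif(k, log(0.01), log(2))
    }
  }
  best <- NULL
  if (k > 0L) {
    for (s in seq_len(min(n_starts, length(starts)))) {
      o <- stats::optim(starts[[s]], obj, method = "L-BFGS-B",
                        lower = rep(log(1e-10), k),
                        upper = rep(log(1e6), k),
                        control = list(factr = tol / .Machine$double.eps))
      if (is.null(best) || o$value < best$value) best <- o
    }
    theta <- best$par
  } else {
    theta <- numeric(0)
  }
  # truncate vanishing components at zero and refit without them
  active <- if (k > 0L) exp(theta) > 1e-7 else logical(0)
  zeroed <- names(rand)[!active]
  if (length(zeroed)) {
    keep <- which(active)
    ZZt_full <- ZZt
    ZZt <- ZZt[keep]
    k2 <- length(ZZt)
    if (k2 > 0L) {
      o <- stats::optim(theta[keep], function(th) {
        V0 <- diag(n)
        for (j in seq_len(k2)) V0 <- V0 + exp(th[j]) * ZZt[[j]]
        ch <- tryCatch(chol(V0), error = function(e) NULL)
        if (is.null(ch)) return(1e10)
        W <- backsolve(ch, cbind(y, X), transpose = TRUE)
        wy <- W[, 1]; wx <- W[, -1, drop = FALSE]
        xtvx <- crossprod(wx)
        beta <- solve(xtvx, crossprod(wx, wy))
        q_form <- max(sum(wy^2) -
                        as.numeric(crossprod(beta, crossprod(wx, wy))),
                      1e-12)
        se2 <- q_form / (n - p)
        0.5 * ((n - p) * log(se2) + 2 * sum(log(diag(ch))) +
                 as.numeric(determinant(xtvx, TRUE)$modulus) +
                 (n - p) * (1 + log(2 * pi)))
      }, method = "L-BFGS-B", lower = rep(log(1e-10), k2),
      upper = rep(log(1e6), k2))
      th_full <- rep(log(1e-10), k)
      th_full[keep] <- o$par
      theta <- th_full
    } else {
      theta <- rep(log(1e-10), k)
    }
    ZZt <- ZZt_full
  }

  # coordinate polish at tight tolerance when few components remain: the
  # profiled likelihood is flat near the optimum, and the closed-form
  # balanced cases deserve near-exact agreement
  act2 <- if (k > 0L) which(exp(theta) > 1e-7) else integer(0)
  if (length(act2) > 0L && length(act2) <= 2L) {
    for (cycle in 1:2) {
      for (j in act2) {
        o1 <- stats::optimize(function(t) {
          th <- theta; th[j] <- t; obj(th)
        }, interval = c(theta[j] - 2, theta[j] + 2), tol = 1e-11)
        theta[j] <- o1$minimum
      }
    }
  }
  fin <- profile(theta)
  gam <- if (k > 0L) stats::setNames(exp(theta), names(rand)) else numeric(0)
  gam[!active] <- 0
  se2 <- fin$se2
  varcomp <- c(stats::setNames(gam * se2, names(rand)), residual = se2)

  # BLUPs of random effects: u_k = gamma_k Z_k' V0^{-1} (y - X beta)
  ch <- fin$chol
  resid_marg <- y - as.numeric(X %*% fin$beta)
  v0inv_r <- backsolve(ch, backsolve(ch, resid_marg, transpose = TRUE))
  blups <- list()
  for (j in seq_len(k)) {
    if (gam[j] == 0) {
      blups[[names(rand)[j]]] <- stats::setNames(
        rep(0, nlevels(rand[[j]])), levels(rand[[j]]))
      next
    }
    u <- gam[j] * as.numeric(Matrix::crossprod(Zs[[j]], v0inv_r))
    blups[[names(rand)[j]]] <- stats::setNames(u, levels(rand[[j]]))
  }

  # genotype effects, their SEs and adjusted means
  vcov_beta <- se2 * solve(fin$xtvx)
  if (genotype == "random") {
    g_eff <- blups$genotype
    # prediction error variance: sg2 I - sg2^2 Z' P Z  (P = REML projector)
    Zg <- as.matrix(Zs$genotype)
    sg2 <- varcomp["genotype"]
    v0inv_Z <- backsolve(ch, backsolve(ch, Zg, transpose = TRUE))
    xtv0z <- crossprod(X, v0inv_Z)
    ztpz <- crossprod(Zg, v0inv_Z) -
      t(xtv0z) %*% solve(fin$xtvx, xtv0z)
    pev <- pmax(sg2 - (sg2 / se2)^2 * se2 * diag(ztpz), 0)
    g_se <- sqrt(pev)
    mu <- fin$beta[1]
    mu_se <- sqrt(vcov_beta[1, 1])
  } else {
    gl <- levels(geno)
    q_g <- length(gl)
    L <- matrix(0, q_g, ncol(X))
    L[, 1] <- 1
    eff_cols <- 1L + seq_len(q_g - 1L)
    L[seq_len(q_g - 1L), eff_cols] <- diag(q_g - 1L)
    L[q_g, eff_cols] <- -1
    est <- as.numeric(L %*% fin$beta)
    se_adj <- sqrt(pmax(diag(L %*% vcov_beta %*% t(L)), 0))
    mu <- fin$beta[1]
    g_eff <- stats::setNames(est - mu, gl)
    g_se <- stats::setNames(se_adj, gl)
    mu_se <- sqrt(vcov_beta[1, 1])
  }

  fitted_vals <- as.numeric(X %*% fin$beta)
  for (j in seq_len(k)) {
    fitted_vals <- fitted_vals +
      as.numeric(Zs[[j]] %*% blups[[names(rand)[j]]])
  }
  if (genotype == "fixed") {
    # genotype contribution already inside X beta
  }

  structure(list(
    call = cl, response = response, genotype = genotype,
    varcomp = varcomp, beta = stats::setNames(fin$beta, colnames(X)),
    vcov_beta = vcov_beta,
    mu = mu, mu_se = mu_se,
    genotype_eff = g_eff, genotype_se = g_se,
    blups = blups, gamma = gam, dropped = unique(dropped),
    zeroed = if (exists("zeroed")) zeroed else character(0),
    logLik = fin$rll, n = n, p = p,
    cov_center = cov_center,
    fitted.values = fitted_vals, residuals = y - fitted_vals,
    y = y, data_levels = list(genotype = levels(geno),
                              location = levels(loc))),
    class = "trial_model")
}

#' Adjusted genotype means from a fitted trial model
#'
#' Adjusted values are \eqn{\mu + g_i}: the overall mean plus each
#' genotype's (random or fixed) effect, expressed in the units of the
#' response and at the mean of any fixed covariates.
#'
#' @param fit A `"trial_model"`.
#' @return A data frame with `line_id`, `adjusted`, `se` and `trait`.
#' @export
adjusted_means <- function(fit) {
  stopifnot(inherits(fit, "trial_model"))
  data.frame(line_id = names(fit$genotype_eff),
             adjusted = as.numeric(fit$mu + fit$genotype_eff),
             se = as.numeric(sqrt(fit$genotype_se^2 + fit$mu_se^2)),
             trait = fit$response,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Yield adjusted for maturity
#'
#' Refits the trial model with centered R8 (days to maturity) as a fixed
#' covariate, removing the confounding of later maturity with higher
#' yield, and returns the adjusted means.
#'
#' @param data Trial data with `yield` and `r8` columns (names
#'   configurable).
#' @param response,covariate Column names.
#' @param ... Passed to [trial_model()].
#' @return A list with the fit (`fit`) and its [adjusted_means()]
#'   (`means`).
#' @export
yield_given_r8 <- function(data, response = "yield", covariate = "r8", ...) {
  f <- stats::as.formula(paste(response, "~", covariate))
  fit <- trial_model(f, data, ...)
  list(fit = fit, means = adjusted_means(fit))
}

#' @export
print.trial_model <- function(x, ...) {
  cat(sprintf("Trial model (REML): %s, genotype %s\n", x$response,
              x$genotype))
  cat(sprintf("  %d plots, %d genotypes, %d locations; RLL = %.3f\n",
              x$n, length(x$data_levels$genotype),
              length(x$data_levels$location), x$logLik))
  cat("variance components:\n")
  print(round(x$varcomp, 4))
  invisible(x)
}

#' @export
summary.trial_model <- function(object, ...) {
  out <- list(call = object$call, response = object$response,
              genotype = object$genotype, varcomp = object$varcomp,
              beta = object$beta, logLik = object$logLik,
              dropped = object$dropped, zeroed = object$zeroed,
              n = object$n)
  class(out) <- "summary.trial_model"
  out
}

#' @export
print.summary.trial_model <- function(x, ...) {
  cat(sprintf("Trial model (REML): %s, genotype %s, %d plots\n",
              x$response, x$genotype, x$n))
  cat("\nVariance components:\n")
  print(round(x$varcomp, 4))
  cat("\nFixed effects:\n")
  bshow <- x$beta[!grepl("^geno", names(x$beta))]
  print(round(bshow, 4))
  if (length(x$dropped)) {
    cat("\ndropped (unidentifiable):", paste(x$dropped, collapse = ", "),
        "\n")
  }
  if (length(x$zeroed)) {
    cat("zeroed components:", paste(x$zeroed, collapse = ", "), "\n")
  }
  cat(sprintf("\nrestricted log-likelihood: %.4f\n", x$logLik))
  invisible(x)
}

#' @export
coef.trial_model <- function(object, ...) object$beta

#' @export
fitted.trial_model <- function(object, ...) object$fitted.values

#' @export
residuals.trial_model <- function(object, ...) object$residuals

#' @export
logLik.trial_model <- function(object, ...) {
  structure(object$logLik, df = length(object$beta) +
              sum(object$varcomp > 0), class = "logLik")
}

#' @export
predict.trial_model <- function(object, ...) {
  stats::setNames(object$mu + object$genotype_eff,
                  names(object$genotype_eff))
}

#' @export
plot.trial_model <- function(x, ...) {
  graphics::plot(x$fitted.values, x$residuals, xlab = "fitted",
                 ylab = "residual",
                 main = paste("Trial model:", x$response))
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
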