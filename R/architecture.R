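#' Genetic architecture of the simulated traits
#'
#' Bundles the population-level parameters the generator draws from: trait
#' names, narrow-sense heritabilities, the genetic correlation matrix, the
#' phenotypic standard deviations and the population means. The additive
#' covariance between traits t and u is
#' \eqn{r_{tu} \, h_t \sigma_{p,t} \, h_u \sigma_{p,u}} with
#' \eqn{h_t = \sqrt{h^2_t}}, so each trait's breeding-value variance is
#' \eqn{h^2_t \sigma_{p,t}^2}.
#'
#' Defaults describe a progeny-row soybean scenario: grain yield (kg/ha),
#' average canopy coverage (ACC, as a fraction) and days to maturity (R8,
#' days after planting), with an ACC-yield genetic correlation of 0.87.
#'
#' @param trait_names Character vector of trait labels.
#' @param h2 Numeric vector of narrow-sense heritabilities in `[0, 1]`.
#' @param genetic_corr Symmetric positive-semidefinite correlation matrix
#'   (unit diagonal) among the traits' additive values.
#' @param pheno_sd Positive phenotypic standard deviations, in trait units.
#' @param trait_means Population means, in trait units.
#' @return An object of class `"genetic_architecture"`.
#' @examples
#' arch <- genetic_architecture()
#' arch$h2
#' @export
genetic_architecture <- function(trait_names = c("yield", "acc", "r8"),
                                 h2 = c(yield = 0.23, acc = 0.06, r8 = 0.36),
                                 genetic_corr = default_genetic_corr(),
                                 pheno_sd = c(yield = 600, acc = 0.05, r8 = 6),
                                 trait_means = c(yield = 3500, acc = 0.25,
                                                 r8 = 105)) {
  k <- length(trait_names)
  h2 <- as.numeric(h2); pheno_sd <- as.numeric(pheno_sd)
  trait_means <- as.numeric(trait_means)
  genetic_corr <- as.matrix(genetic_corr)
  if (length(h2) != k || length(pheno_sd) != k || length(trait_means) != k ||
      !all(dim(genetic_corr) == k)) {
    stop("architecture component lengths must match the number of traits",
         call. = FALSE)
  }
  if (any(h2 < 0 | h2 > 1)) stop("h2 must lie in [0, 1]", call. = FALSE)
  if (any(pheno_sd <= 0)) stop("pheno_sd must be positive", call. = FALSE)
  if (max(abs(genetic_corr - t(genetic_corr))) > 1e-10 ||
      max(abs(diag(genetic_corr) - 1)) > 1e-10) {
    stop("genetic_corr must be symmetric with unit diagonal", call. = FALSE)
  }
  if (min(eigen(genetic_corr, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-10) {
    stop("genetic_corr must be positive semidefinite", call. = FALSE)
  }
  structure(list(trait_names = trait_names, h2 = stats::setNames(h2, trait_names),
                 genetic_corr = structure(genetic_corr,
                                          dimnames = list(trait_names,
                                                          trait_names)),
                 pheno_sd = stats::setNames(pheno_sd, trait_names),
                 trait_means = stats::setNames(trait_means, trait_names)),
            class = "genetic_architecture")
}

#' @rdname genetic_architecture
#' @export
default_genetic_corr <- function() {
  m <- diag(3)
  dimnames(m) <- list(c("yield", "acc", "r8"), c("yield", "acc", "r8"))
  m["yield", "acc"] <- m["acc", "yield"] <- 0.87
  m["yield", "r8"] <- m["r8", "yield"] <- 0.3
  m["acc", "r8"] <- m["r8", "acc"] <- 0.0
  m
}

# Additive (breeding-value) covariance matrix among traits.
additive_cov <- function(arch) {
  sd_a <- sqrt(arch$h2) * arch$pheno_sd
  arch$genetic_corr * tcrossprod(sd_a)
}

# Symmetric square root of a PSD matrix, tolerant of zero eigenvalues
# (traits with h2 = 0). Errors on clearly negative eigenvalues.
psd_sqrt <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1)) {
    stop("trait covariance is not positive semidefinite", call. = FALSE)
  }
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' @export
print.genetic_architecture <- function(x, ...) {
  cat("Genetic architecture:", length(x$trait_names), "traits\n")
  df <- data.frame(trait = x$trait_names, h2 = x$h2, pheno_sd = x$pheno_sd,
                   mean = x$trait_means, row.names = NULL)
  print(df, ...)
  cat("genetic correlations:\n")
  print(round(x$genetic_corr, 3))
  invisible(x)
}
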