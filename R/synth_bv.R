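#' Simulate multi-trait breeding values along a pedigree
#'
#' Draws additive genetic values for every individual in the pedigree from
#' a zero-mean multivariate normal with covariance
#' \eqn{\Sigma_g \otimes A}, where \eqn{A} is the pedigree numerator
#' relationship matrix and \eqn{\Sigma_g} the trait additive covariance
#' implied by the architecture (variance \eqn{h^2_t \sigma_{p,t}^2} for
#' trait t, correlations from `genetic_corr`).
#'
#' Two equivalent samplers are provided. The default `"gene_drop"` walks the
#' pedigree: founders are drawn from \eqn{N(0, \Sigma_g)}; an offspring gets
#' its parent-average plus an independent Mendelian-sampling deviation with
#' covariance \eqn{d_i \Sigma_g}, where
#' \eqn{d_i = 1 - \sum_p (1 + F_p)/4} is the Mendelian-sampling variance
#' used in [a_inverse()]. This costs O(n) and never forms \eqn{A}. The
#' `"cholesky"` sampler forms \eqn{L_A Z L_{\Sigma}'} explicitly and is
#' intended for small pedigrees and cross-checks.
#'
#' @param ped A pedigree (see [as_pedigree()]).
#' @param arch A [genetic_architecture()].
#' @param seed Integer seed.
#' @param method `"gene_drop"` (default) or `"cholesky"`.
#' @return Numeric matrix, individuals (pedigree order) x traits, with
#'   dimnames.
#' @examples
#' ped <- simulate_pedigree(10, 20, 3, seed = 2)
#' bv <- simulate_breeding_values(ped, genetic_architecture(), seed = 3)
#' colnames(bv)
#' @export
simulate_breeding_values <- function(ped, arch, seed,
                                     method = c("gene_drop", "cholesky")) {
  method <- match.arg(method)
  ped <- as_pedigree(ped)
  stopifnot(inherits(arch, "genetic_architecture"))
  sigma_g <- additive_cov(arch)
  lg <- psd_sqrt(sigma_g)
  n <- nrow(ped)
  k <- length(arch$trait_names)
  bv <- with_seed(seed, {
    if (method == "cholesky") {
      a <- build_a_matrix(ped)
      ea <- eigen(a, symmetric = TRUE)
      la <- ea$vectors %*% (sqrt(pmax(ea$values, 0)) * t(ea$vectors))
      z <- matrix(stats::rnorm(n * k), n, k)
      la %*% z %*% t(lg)
    } else {
      idx <- stats::setNames(seq_len(n), ped$id)
      si <- idx[ped$sire]
      di <- idx[ped$dam]
      f <- ped_inbreeding(ped)
      z <- matrix(stats::rnorm(n * k), n, k) %*% t(lg)
      out <- matrix(0, n, k)
      for (i in seq_len(n)) {
        par <- c(si[i], di[i])
        par <- par[!is.na(par)]
        if (!length(par)) {
          out[i, ] <- z[i, ]
        } else {
          pa <- colSums(out[par, , drop = FALSE]) / 2
          d_i <- 1 - sum((1 + f[par]) / 4)
          out[i, ] <- pa + sqrt(d_i) * z[i, ]
        }
      }
      out
    }
  })
  dimnames(bv) <- list(ped$id, arch$trait_names)
  bv
}
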