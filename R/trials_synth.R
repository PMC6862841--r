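#' Simulate a multi-location alpha-lattice yield trial
#'
#' Generates plot data with the variance structure of a replicated yield
#' trial: genotype (the supplied genetic values), random location,
#' replication nested in location, incomplete block nested in replication
#' (plots assigned to blocks of `block_size` within each replicate),
#' genotype-by-location interaction, and iid residual. Optionally a second
#' maturity-like trait and a linear dependence of the response on it can be
#' generated for covariate-adjustment studies.
#'
#' @param line_ids Character vector of genotypes.
#' @param genetic_values Named (or positional) numeric vector of true
#'   genotype effects for the response.
#' @param mu Overall mean of the response.
#' @param n_loc,n_rep Locations and replications per location.
#' @param block_size Plots per incomplete block within a replicate.
#' @param vc Named list of variance components: `loc`, `rep`, `block`,
#'   `gxl`, `e`.
#' @param r8_values Optional named numeric vector of true maturity values
#'   (days); when supplied, an `r8` column (with residual sd `r8_sd`) is
#'   generated and `r8_slope` times the line's maturity deviation is added
#'   to the response.
#' @param r8_sd,r8_slope See `r8_values`.
#' @param seed Integer seed.
#' @return Data frame with `plot_id`, `line_id`, `trial`, `location`,
#'   `rep`, `block` and the response column `yield` (plus `r8` when
#'   requested).
#' @export
simulate_yield_trial <- function(line_ids, genetic_values, mu = 3500,
                                 n_loc = 2L, n_rep = 2L, block_size = 10L,
                                 vc = list(loc = 0.5, rep = 0.2, block = 0.1,
                                           gxl = 0.3, e = 1),
                                 r8_values = NULL, r8_sd = 1.5,
                                 r8_slope = 0, seed) {
  line_ids <- as.character(line_ids)
  q <- length(line_ids)
  if (is.null(names(genetic_values))) names(genetic_values) <- line_ids
  stopifnot(all(line_ids %in% names(genetic_values)))
  n_loc <- check_count(n_loc, "n_loc", min = 1L)
  n_rep <- check_count(n_rep, "n_rep", min = 1L)
  block_size <- check_count(block_size, "block_size", min = 2L)
  with_seed(seed, {
    loc_eff <- stats::rnorm(n_loc, 0, sqrt(vc$loc))
    rep_eff <- matrix(stats::rnorm(n_loc * n_rep, 0, sqrt(vc$rep)),
                      n_loc, n_rep)
    gxl_eff <- matrix(stats::rnorm(q * n_loc, 0, sqrt(vc$gxl)), q, n_loc,
                      dimnames = list(line_ids, NULL))
    rows <- vector("list", n_loc * n_rep)
    idx <- 0L
    for (j in seq_len(n_loc)) {
      for (r in seq_len(n_rep)) {
        ord <- sample(line_ids)            # fresh randomization per rep
        blk <- ceiling(seq_along(ord) / block_size)
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          line_id = ord, location = sprintf("LOC%d", j),
          rep = sprintf("R%d", r), block = sprintf("B%02d", blk),
          loc_eff = loc_eff[j], rep_eff = rep_eff[j, r],
          gxl_eff = gxl_eff[ord, j], stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    blocks <- unique(out[, c("location", "rep", "block")])
    blk_eff <- stats::rnorm(nrow(blocks), 0, sqrt(vc$block))
    names(blk_eff) <- paste(blocks$location, blocks$rep, blocks$block)
    out$block_eff <- blk_eff[paste(out$location, out$rep, out$block)]
    out$resid <- stats::rnorm(nrow(out), 0, sqrt(vc$e))
    out$yield <- mu + genetic_values[out$line_id] + out$loc_eff +
      out$rep_eff + out$block_eff + out$gxl_eff + out$resid
    if (!is.null(r8_values)) {
      stopifnot(all(line_ids %in% names(r8_values)))
      out$r8 <- r8_values[out$line_id] + stats::rnorm(nrow(out), 0, r8_sd)
      # maturity acts on the plot's realized R8
      out$yield <- out$yield +
        r8_slope * (out$r8 - mean(r8_values[line_ids]))
    }
    out$plot_id <- sprintf("YT%05d", seq_len(nrow(out)))
    out$trial <- "YT"
    rownames(out) <- NULL
    out[, c("plot_id", "line_id", "trial", "location", "rep", "block",
            "yield", if (!is.null(r8_values)) "r8")]
  })
}
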