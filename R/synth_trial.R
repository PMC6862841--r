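#' Lay out an unreplicated progeny-row trial with replicated checks
#'
#' Assigns every cell of a rows x columns field grid exactly once: each
#' experimental line to a single one-row plot (unreplicated), with check
#' cultivars inserted systematically every `check_spacing` plots and used to
#' fill any remainder of the grid, so each check is replicated. This mimics a
#' modified augmented design; the check density is a free parameter of the
#' design rather than a fixed constant.
#'
#' @param line_ids Character vector of experimental line ids (each planted
#'   once).
#' @param check_ids Character vector of check cultivar ids (each planted at
#'   least twice).
#' @param n_cols Number of field columns (plots per pass).
#' @param check_spacing One plot in every `check_spacing` consecutive plots
#'   is a check.
#' @param plot_length_m,row_spacing_m Plot geometry in meters (defaults: a
#'   1.83 m single-row plot on 0.76 m row spacing).
#' @return An object of class `"field_layout"`: a list with `n_rows`,
#'   `n_cols`, the plot assignment table `plots` (columns `plot_id`,
#'   `field_row`, `field_col`, `line_id`, `is_check`), `check_ids` and the
#'   plot geometry.
#' @examples
#' lay <- field_layout(sprintf("L%03d", 1:95), c("CHK1", "CHK2"), n_cols = 10)
#' table(lay$plots$is_check)
#' @export
field_layout <- function(line_ids, check_ids, n_cols = 50L,
                         check_spacing = 20L, plot_length_m = 1.83,
                         row_spacing_m = 0.76) {
  line_ids <- as.character(line_ids)
  check_ids <- as.character(check_ids)
  if (!length(line_ids) || !length(check_ids)) {
    stop("need at least one line and one check", call. = FALSE)
  }
  if (anyDuplicated(c(line_ids, check_ids))) {
    stop("line and check ids must be distinct", call. = FALSE)
  }
  n_cols <- check_count(n_cols, "n_cols", min = 1L)
  check_spacing <- check_count(check_spacing, "check_spacing", min = 2L)
  n_lines <- length(line_ids)
  # total plots T satisfies T = n_lines + floor(T / check_spacing)
  total <- n_lines
  repeat {
    new_total <- n_lines + floor(total / check_spacing)
    if (new_total == total) break
    total <- new_total
  }
  n_rows <- ceiling(total / n_cols)
  n_plots <- n_rows * n_cols
  is_check_pos <- (seq_len(total) %% check_spacing) == 0L
  ids <- character(n_plots)
  line_pos <- which(!is_check_pos)
  check_pos <- c(which(is_check_pos),
                 if (n_plots > total) (total + 1L):n_plots)
  ids[line_pos] <- line_ids
  ids[check_pos] <- rep_len(check_ids, length(check_pos))
  plots <- data.frame(
    plot_id = sprintf("P%05d", seq_len(n_plots)),
    field_row = rep(seq_len(n_rows), each = n_cols),
    field_col = rep(seq_len(n_cols), times = n_rows),
    line_id = ids,
    is_check = ids %in% check_ids,
    stringsAsFactors = FALSE
  )
  counts <- table(plots$line_id[plots$is_check])
  if (any(counts < 2L)) {
    stop("each check must appear at least twice; reduce the number of ",
         "checks or the check spacing", call. = FALSE)
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, plots = plots,
                 check_ids = check_ids, plot_length_m = plot_length_m,
                 row_spacing_m = row_spacing_m),
            class = "field_layout")
}

#' @export
print.field_layout <- function(x, ...) {
  cat(sprintf("Field layout: %d x %d grid, %d plots (%d lines, %d check plots)\n",
              x$n_rows, x$n_cols, nrow(x$plots), sum(!x$plots$is_check),
              sum(x$plots$is_check)))
  invisible(x)
}

# Smooth random spatial surface: sum of `n_waves` random-phase 2-D cosines,
# rescaled so the realized standard deviation over the grid equals `sd`.
cosine_surface <- function(n_rows, n_cols, sd, n_waves = 3L) {
  if (sd == 0) return(matrix(0, n_rows, n_cols))
  r <- matrix(seq_len(n_rows), n_rows, n_cols)
  cc <- matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE)
  s <- matrix(0, n_rows, n_cols)
  for (k in seq_len(n_waves)) {
    fr <- stats::runif(1, 0.5, 2.5)
    fc <- stats::runif(1, 0.5, 2.5)
    phi <- stats::runif(1, 0, 2 * pi)
    s <- s + cos(2 * pi * (fr * r / n_rows + fc * cc / n_cols) + phi)
  }
  obs_sd <- stats::sd(as.vector(s))
  if (obs_sd < 1e-12) return(matrix(0, n_rows, n_cols))
  (s - mean(s)) / obs_sd * sd
}

#' Simulate plot phenotypes for a progeny-row trial
#'
#' For every plot in the layout, each trait's phenotype is
#' `trait mean + breeding value + spatial effect + residual`. The spatial
#' effect is one smooth random cosine surface over the field grid, shared
#' across traits and scaled to each trait's `spatial_sd` — a fertile patch
#' raises growth, maturity and yield together, which is what makes
#' environmental covariance between canopy cover and yield realistic. The
#' iid residual
#' variance is \eqn{(1-h^2)\sigma_p^2 - \mathrm{spatial\_sd}^2}, floored at
#' `residual_floor` \eqn{\times\,\sigma_p^2} so downstream models remain
#' well-posed. Requesting more spatial variance than the non-genetic
#' variance available is an error.
#'
#' @param layout A [field_layout()].
#' @param bv Breeding-value matrix (individuals x traits) covering every
#'   assigned line and check, e.g. from [simulate_breeding_values()].
#' @param arch The [genetic_architecture()] used to draw `bv`.
#' @param spatial_sd Spatial-effect standard deviation per trait, in trait
#'   units (recycled).
#' @param seed Integer seed.
#' @param residual_floor Minimum residual variance as a fraction of
#'   \eqn{\sigma_p^2}.
#' @return A data frame with plot identifiers, design columns
#'   (`field_row`, `field_col`, `is_check`) and one phenotype column per
#'   trait. True spatial surfaces and residuals are attached as attributes
#'   `"spatial"` and `"residuals"` for ground-truth checks.
#' @export
simulate_trial <- function(layout, bv, arch, spatial_sd = 0, seed,
                           residual_floor = 1e-6) {
  stopifnot(inherits(layout, "field_layout"),
            inherits(arch, "genetic_architecture"))
  traits <- arch$trait_names
  k <- length(traits)
  spatial_sd <- rep_len(as.numeric(spatial_sd), k)
  plots <- layout$plots
  missing_lines <- setdiff(plots$line_id, rownames(bv))
  if (length(missing_lines)) {
    stop("breeding values missing for assigned lines: ",
         paste(utils::head(missing_lines, 5), collapse = ", "), call. = FALSE)
  }
  resid_var <- (1 - arch$h2) * arch$pheno_sd^2 - spatial_sd^2
  if (any(resid_var < -1e-12)) {
    stop("spatial_sd^2 exceeds the non-genetic variance (1 - h2) * pheno_sd^2",
         call. = FALSE)
  }
  resid_var <- pmax(resid_var, residual_floor * arch$pheno_sd^2)
  n <- nrow(plots)
  with_seed(seed, {
    base_surface <- cosine_surface(layout$n_rows, layout$n_cols, 1)
    spatial <- lapply(seq_len(k), function(t) base_surface * spatial_sd[t])
    names(spatial) <- traits
    residuals <- matrix(stats::rnorm(n * k), n, k) %*% diag(sqrt(resid_var), k)
    colnames(residuals) <- traits
    out <- plots
    for (t in seq_len(k)) {
      sp <- spatial[[t]][cbind(plots$field_row, plots$field_col)]
      out[[traits[t]]] <- arch$trait_means[t] + bv[plots$line_id, t] +
        sp + residuals[, t]
    }
    attr(out, "spatial") <- spatial
    attr(out, "residuals") <- residuals
    out
  })
}
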