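#' Excess Green index on chromaticity-normalized channels
#'
#' For each pixel, channels are normalized to chromaticity coordinates
#' \eqn{r = R/(R+G+B)}, \eqn{g = G/(R+G+B)}, \eqn{b = B/(R+G+B)} (a black
#' pixel gets \eqn{r = g = b = 1/3}), and the Excess Green index is
#' \eqn{ExG = 2g - r - b}. Normalization makes the index invariant to
#' uniform illumination changes and bounds it to \eqn{[-1, 2]}: 2 for pure
#' green, 0 for any gray.
#'
#' @param x A `"plot_image"` (see [simulate_plot_image()],
#'   [read_plot_image()]) or an `H x W x 3` numeric array of RGB channels.
#' @return Numeric `H x W` matrix of ExG values.
#' @examples
#' px <- array(c(50, 150, 100), c(1, 1, 3))
#' excess_green(px)  # 0.5
#' @export
excess_green <- function(x) {
  px <- if (inherits(x, "plot_image")) x$pixels else x
  if (length(dim(px)) != 3L || dim(px)[3] < 3L) {
    stop("expected an H x W x 3 RGB array", call. = FALSE)
  }
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  s <- r + g + b
  zero <- s == 0
  s[zero] <- 1
  gn <- g / s
  rn <- r / s
  bn <- b / s
  gn[zero] <- 1 / 3; rn[zero] <- 1 / 3; bn[zero] <- 1 / 3
  2 * gn - rn - bn
}

#' Otsu threshold over equal-width histogram bin edges
#'
#' Considers the `n_bins - 1` interior edges of an equal-width binning of
#' `[min(values), max(values)]` as candidate thresholds and returns the edge
#' maximizing the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2}, where class 0 holds the
#' values \eqn{\le} the edge. Foreground is defined as values strictly
#' greater than the returned threshold (ties go to background).
#'
#' @param values Numeric vector or matrix (e.g. an ExG raster).
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold (a bin edge) with attribute `"bcv"` holding the
#'   maximal between-class variance, or `NA` for a constant input (no
#'   separable classes).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- sort(as.numeric(values))
  n <- length(v)
  if (n < 2L || v[1] == v[n]) {
    return(structure(NA_real_, bcv = 0))
  }
  n_bins <- check_count(n_bins, "n_bins", min = 2L)
  edges <- v[1] + seq_len(n_bins - 1L) * (v[n] - v[1]) / n_bins
  n0 <- findInterval(edges, v)           # values <= edge
  cs <- cumsum(v)
  total <- cs[n]
  sum0 <- ifelse(n0 > 0L, cs[pmax(n0, 1L)], 0)
  w0 <- n0 / n
  w1 <- 1 - w0
  valid <- n0 > 0L & n0 < n
  bcv <- rep(-Inf, length(edges))
  mu0 <- sum0[valid] / n0[valid]
  mu1 <- (total - sum0[valid]) / (n - n0[valid])
  bcv[valid] <- w0[valid] * w1[valid] * (mu0 - mu1)^2
  if (!any(is.finite(bcv))) return(structure(NA_real_, bcv = 0))
  best <- which.max(bcv)
  structure(edges[best], bcv = bcv[best])
}

#' Canopy cover fraction of one plot image
#'
#' Computes the ExG raster, finds the Otsu threshold, and returns the
#' fraction of pixels strictly above it. Two degenerate cases are guarded:
#' a constant ExG raster yields coverage by the fixed cutoff, and a
#' near-unimodal raster (maximal between-class variance below `guard_bcv`,
#' or more than 99% of pixels on one side of `guard_cutoff`) is classified
#' by the fixed cutoff `ExG > guard_cutoff` instead of the unstable
#' data-driven split. This keeps all-soil and all-canopy frames from being
#' split down the middle of their noise.
#'
#' @inheritParams excess_green
#' @param n_bins Histogram bins for [otsu_threshold()].
#' @param guard_cutoff Fixed ExG cutoff used when the histogram is
#'   (near-)unimodal.
#' @param guard_bcv Between-class-variance floor below which the Otsu split
#'   is considered degenerate.
#' @return Coverage fraction in `[0, 1]`, with attributes `"threshold"`
#'   (the value used; `NA` when the fixed cutoff was applied) and
#'   `"guarded"`.
#' @export
coverage_from_image <- function(x, n_bins = 256L, guard_cutoff = 0.1,
                                guard_bcv = 1e-4) {
  exg <- excess_green(x)
  thr <- otsu_threshold(exg, n_bins = n_bins)
  green_like <- mean(exg > guard_cutoff)
  if (is.na(thr) || attr(thr, "bcv") < guard_bcv ||
      green_like > 0.99 || green_like < 0.01) {
    if (is.na(thr) && stats::sd(as.numeric(exg)) == 0 &&
        exg[1] <= guard_cutoff) {
      # constant raster with no green signal: no separable canopy
      return(structure(0, threshold = NA_real_, guarded = TRUE))
    }
    return(structure(green_like, threshold = NA_real_, guarded = TRUE))
  }
  structure(mean(exg > as.numeric(thr)), threshold = as.numeric(thr),
            guarded = FALSE)
}

#' Per-date plot coverage: median over replicate images
#'
#' The canopy coverage of a plot at one sampling date is the median of the
#' coverages from its replicated images (midpoint of the middle two for
#' even counts).
#'
#' @param coverages Numeric vector of per-replicate coverage fractions
#'   (length >= 1).
#' @return The median coverage.
#' @examples
#' date_coverage(c(0.2, 0.4, 0.6, 0.9))  # 0.5
#' @export
date_coverage <- function(coverages) {
  coverages <- as.numeric(coverages)
  if (!length(coverages) || anyNA(coverages)) {
    stop("need at least one non-missing replicate coverage", call. = FALSE)
  }
  stats::median(coverages)
}

#' Average canopy coverage (ACC) of a plot
#'
#' ACC is the unweighted arithmetic mean of the per-date median coverages;
#' missing dates are simply left out of the mean.
#'
#' @param per_date Numeric vector of per-date median coverages; names (if
#'   any) are recorded as the dates used.
#' @return The ACC fraction with attribute `"dates_used"`.
#' @examples
#' average_canopy_coverage(c(dap15 = 0.1, dap29 = 0.3, dap34 = 0.5))  # 0.3
#' @export
average_canopy_coverage <- function(per_date) {
  keep <- !is.na(per_date)
  if (!any(keep)) stop("need at least one date", call. = FALSE)
  structure(mean(as.numeric(per_date[keep])),
            dates_used = if (is.null(names(per_date))) which(keep)
                         else names(per_date)[keep])
}

#' Coverage and ACC tables from a collection of plot images
#'
#' `coverage_table()` maps every image through [coverage_from_image()] and
#' aggregates replicates to per-plot-date medians; `acc_table()` averages
#' the per-date medians into one ACC value per plot. Coverages are stored
#' as fractions; the `*_pct` columns carry the percent rendering used in
#' reports.
#'
#' @param images A list of `"plot_image"` records carrying `plot_id`,
#'   `dap`, `replicate` (e.g. from [simulate_plot_images()]), or a manifest
#'   data frame with a `path` column as written by
#'   [simulate_plot_images()] (paths resolved relative to `dir`).
#' @param dir Directory for manifest paths.
#' @inheritParams coverage_from_image
#' @return `coverage_table()`: a data frame with `plot_id`, `dap`,
#'   `coverage`, `coverage_pct`, `n_images`, `threshold`.
#' @export
coverage_table <- function(images, dir = ".", n_bins = 256L,
                           guard_cutoff = 0.1, guard_bcv = 1e-4) {
  if (is.data.frame(images)) {
    images <- lapply(seq_len(nrow(images)), function(i) {
      read_plot_image(file.path(dir, images$path[i]),
                      plot_id = images$plot_id[i], dap = images$dap[i],
                      replicate = images$replicate[i])
    })
  }
  per_image <- do.call(rbind, lapply(images, function(img) {
    cov <- coverage_from_image(img, n_bins = n_bins,
                               guard_cutoff = guard_cutoff,
                               guard_bcv = guard_bcv)
    data.frame(plot_id = img$plot_id, dap = img$dap,
               coverage = as.numeric(cov),
               threshold = attr(cov, "threshold"),
               stringsAsFactors = FALSE)
  }))
  split_by <- interaction(per_image$plot_id, per_image$dap, drop = TRUE)
  out <- do.call(rbind, lapply(split(per_image, split_by), function(d) {
    data.frame(plot_id = d$plot_id[1], dap = d$dap[1],
               coverage = date_coverage(d$coverage),
               n_images = nrow(d),
               threshold = stats::median(d$threshold),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$plot_id, out$dap), , drop = FALSE]
  out$coverage_pct <- round(100 * out$coverage, 1)
  rownames(out) <- NULL
  out[, c("plot_id", "dap", "coverage", "coverage_pct", "n_images",
          "threshold")]
}

#' @rdname coverage_table
#' @param coverage A data frame from `coverage_table()`.
#' @return `acc_table()`: a data frame with `plot_id`, `acc`, `acc_pct`,
#'   `n_dates`.
#' @export
acc_table <- function(coverage) {
  out <- do.call(rbind, lapply(split(coverage, coverage$plot_id),
                               function(d) {
    acc <- average_canopy_coverage(stats::setNames(d$coverage,
                                                   paste0("dap", d$dap)))
    data.frame(plot_id = d$plot_id[1], acc = as.numeric(acc),
               n_dates = length(attr(acc, "dates_used")),
               stringsAsFactors = FALSE)
  }))
  out$acc_pct <- round(100 * out$acc, 1)
  rownames(out) <- NULL
  out[, c("plot_id", "acc", "acc_pct", "n_dates")]
}
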