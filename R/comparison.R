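#' Compare selection categories on adjusted means
#'
#' For every pair of selection categories, performs a Welch (unequal
#' variance) two-sample t-test on the adjusted means of the lines each
#' category selected. A line selected by several categories contributes to
#' each of them. Significance stars follow the conventional thresholds
#' (`*` p <= 0.05, `**` 0.01, `***` 0.001, `****` 0.0001, `ns` otherwise);
#' no multiple-testing correction is applied across pairs.
#'
#' @param means Adjusted means: a data frame from [adjusted_means()] or a
#'   named numeric vector.
#' @param membership A `"selection_outcome"` from [combine_categories()],
#'   or a named list of character vectors of line ids per category.
#' @return An object of class `"category_comparison"`: a data frame with
#'   one row per category pair (`mean_1`, `mean_2`, `n_1`, `n_2`, `t`,
#'   `df`, `p`, `stars`), with the per-category means in
#'   `attr(, "category_means")`.
#' @export
compare_categories <- function(means, membership) {
  vals <- if (is.data.frame(means)) {
    stats::setNames(means$adjusted, means$line_id)
  } else means
  sets <- if (inherits(membership, "selection_outcome")) {
    membership$selected
  } else membership
  samples <- lapply(sets, function(ids) vals[intersect(ids, names(vals))])
  sizes <- vapply(samples, length, integer(1))
  if (any(sizes < 2L)) {
    stop("each category needs >= 2 lines with adjusted means; short: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  cats <- names(samples)
  pairs <- utils::combn(cats, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- samples[[pairs[1, j]]]
    b <- samples[[pairs[2, j]]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate: both samples constant, Welch denominator is zero
      eq <- isTRUE(all.equal(mean(a), mean(b)))
      tt <- list(statistic = c(t = if (eq) 0 else
                                 sign(mean(a) - mean(b)) * Inf),
                 parameter = c(df = NA_real_),
                 p.value = if (eq) 1 else 0)
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
    }
    data.frame(category_1 = pairs[1, j], category_2 = pairs[2, j],
               mean_1 = mean(a), mean_2 = mean(b),
               n_1 = length(a), n_2 = length(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$stars <- p_stars(out$p)
  attr(out, "category_means") <- vapply(samples, mean, numeric(1))
  class(out) <- c("category_comparison", "data.frame")
  out
}

#' @export
print.category_comparison <- function(x, ...) {
  cat("Category comparison (Welch two-sample t-tests):\n")
  df <- as.data.frame(x)
  df$mean_1 <- round(df$mean_1, 2); df$mean_2 <- round(df$mean_2, 2)
  df$t <- round(df$t, 3); df$df <- round(df$df, 1)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Attribute top-ranked trial lines to their selection categories
#'
#' Ranks evaluated lines by adjusted mean and, for the top `k`, lists
#' every progeny-row selection category that had selected each line. The
#' summary counts how many of the top lines were reached only through the
#' canopy-based categories (ACC and/or the covariate-adjusted yield), how
#' many through direct yield selection alone, and the remainder (mixed or
#' unattributed).
#'
#' @inheritParams compare_categories
#' @param k Number of top-ranked lines to attribute.
#' @param yield_category Name of the direct-yield category in
#'   `membership`.
#' @return An object of class `"rank_attribution"`: data frame with
#'   `rank`, `line_id`, `adjusted`, `categories`, and a `summary`
#'   attribute with the three counts (which partition `k`).
#' @export
top_rank_attribution <- function(means, membership, k = 10L,
                                 yield_category = "Yield") {
  k <- check_count(k, "k", min = 1L)
  vals <- if (is.data.frame(means)) {
    stats::setNames(means$adjusted, means$line_id)
  } else means
  memb <- if (inherits(membership, "selection_outcome")) {
    stats::setNames(membership$membership$categories,
                    membership$membership$line_id)
  } else membership
  k <- min(k, length(vals))
  ord <- order(-vals, names(vals), method = "radix")
  top <- names(vals)[ord[seq_len(k)]]
  labels <- unname(memb[top])
  labels[is.na(labels)] <- ""
  out <- data.frame(rank = seq_len(k), line_id = top,
                    adjusted = unname(vals[top]), categories = labels,
                    stringsAsFactors = FALSE)
  sets <- strsplit(labels, "+", fixed = TRUE)
  has_yield <- vapply(sets, function(s) yield_category %in% s, logical(1))
  has_other <- vapply(sets, function(s)
    length(setdiff(s, yield_category)) > 0, logical(1))
  summary <- c(canopy_only = sum(!has_yield & has_other),
               yield_alone = sum(has_yield & !has_other),
               mixed_or_none = sum((has_yield & has_other) |
                                     (!has_yield & !has_other)))
  attr(out, "summary") <- summary
  class(out) <- c("rank_attribution", "data.frame")
  out
}

#' @export
print.rank_attribution <- function(x, ...) {
  cat("Top-ranked lines and their selection categories:\n")
  print(as.data.frame(x), row.names = FALSE)
  s <- attr(x, "summary")
  cat(sprintf(
    "\ncanopy-based only: %d, yield alone: %d, mixed/none: %d\n",
    s["canopy_only"], s["yield_alone"], s["mixed_or_none"]))
  invisible(x)
}
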