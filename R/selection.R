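#' Truncation selection on BLUP rankings
#'
#' Selects the top `floor(fraction * n)` lines (minimum 1) by descending
#' value; ties are broken by line id (lexicographically smaller id wins),
#' so selections are reproducible. With 2747 candidate progenies and a 9%
#' intensity this selects 247 lines; 7.5% of 4052 selects 303.
#'
#' @param blups Named numeric vector (line id -> BLUP).
#' @param fraction Selected proportion in (0, 1).
#' @return Character vector of selected line ids, in rank order.
#' @examples
#' select_top(c(a = 1, b = 3, c = 2), 0.5)  # "b"
#' @export
select_top <- function(blups, fraction) {
  if (!length(blups)) stop("empty BLUP vector", call. = FALSE)
  if (is.null(names(blups)) || anyNA(names(blups))) {
    stop("blups must be named by line id", call. = FALSE)
  }
  fraction <- check_fraction(fraction, "fraction")
  n_sel <- max(1L, floor(fraction * length(blups)))
  ord <- order(-blups, names(blups), method = "radix")
  names(blups)[ord[seq_len(n_sel)]]
}

#' Combine per-category selections with overlap accounting
#'
#' Takes the selected set of each selection category (e.g. Yield, ACC,
#' Yield|ACC) over the same candidate universe and returns the union, a
#' per-line membership table and the counts of every category combination
#' — the bookkeeping needed because a line can be picked by more than one
#' category, making the total selected smaller than the sum of the
#' category counts.
#'
#' @param per_category Named list of character vectors of selected line
#'   ids.
#' @return An object of class `"selection_outcome"`: list with `selected`
#'   (the per-category sets), `union_selected`, `membership` (data frame
#'   `line_id`, `categories`), `overlap_counts` (named count per
#'   combination label, categories joined by `+`), and `fraction_requested`
#'   if supplied via attributes on `per_category`.
#' @export
combine_categories <- function(per_category) {
  if (is.null(names(per_category)) || any(names(per_category) == "")) {
    stop("per_category must be a named list", call. = FALSE)
  }
  cats <- names(per_category)
  union_sel <- sort(unique(unlist(per_category)))
  labels <- vapply(union_sel, function(id) {
    paste(cats[vapply(per_category, function(s) id %in% s, logical(1))],
          collapse = "+")
  }, character(1))
  membership <- data.frame(line_id = union_sel, categories = unname(labels),
                           stringsAsFactors = FALSE)
  overlap <- table(labels)
  structure(list(selected = per_category,
                 union_selected = union_sel,
                 membership = membership,
                 overlap_counts = stats::setNames(as.integer(overlap),
                                                  names(overlap))),
            class = "selection_outcome")
}

#' @export
print.selection_outcome <- function(x, ...) {
  cat(sprintf("Selection outcome: %d categories, union of %d lines\n",
              length(x$selected), length(x$union_selected)))
  for (nm in names(x$selected)) {
    cat(sprintf("  %-12s %d lines\n", nm, length(x$selected[[nm]])))
  }
  cat("overlaps:\n")
  print(x$overlap_counts)
  invisible(x)
}

#' Membership test helpers for selection outcomes
#'
#' `selected_by()` returns the line ids selected by exactly the given
#' combination of categories (or by at least those categories when
#' `exact = FALSE`).
#'
#' @param outcome A `"selection_outcome"`.
#' @param categories Character vector of category names.
#' @param exact Require exactly this combination.
#' @return Character vector of line ids.
#' @export
selected_by <- function(outcome, categories, exact = TRUE) {
  stopifnot(inherits(outcome, "selection_outcome"))
  label_sets <- strsplit(outcome$membership$categories, "+", fixed = TRUE)
  hit <- vapply(label_sets, function(s) {
    if (exact) setequal(s, categories) else all(categories %in% s)
  }, logical(1))
  outcome$membership$line_id[hit]
}

#' Split selected lines into early and late maturity groups
#'
#' Classifies each selected line against a check cultivar's maturity: lines
#' with R8 at or below the check's are "early" (boundary ties assigned
#' early), later lines are "late". The two groups feed separate early and
#' late yield trials.
#'
#' @param selected Character vector of selected line ids.
#' @param r8 Named numeric vector of maturity values (days after planting;
#'   typically BLUP-adjusted R8).
#' @param check_r8 The check's maturity value.
#' @return List with components `early` and `late` (character vectors); an
#'   exhaustive, disjoint partition of `selected`.
#' @export
split_early_late <- function(selected, r8, check_r8) {
  missing_r8 <- setdiff(selected, names(r8))
  if (length(missing_r8)) {
    stop("R8 missing for lines: ",
         paste(utils::head(missing_r8, 5), collapse = ", "), call. = FALSE)
  }
  vals <- r8[selected]
  list(early = selected[vals <= check_r8], late = selected[vals > check_r8])
}

#' Selection intensity of truncation selection
#'
#' For a selected proportion p under a standard normal, the selection
#' intensity is \eqn{i = \phi(z_p) / p} with \eqn{z_p} the upper-p
#' quantile: the mean standardized deviation of the selected fraction.
#'
#' @param fraction Selected proportion in (0, 1).
#' @return Dimensionless intensity (strictly decreasing in the fraction).
#' @examples
#' selection_intensity(0.5)   # 0.7979
#' selection_intensity(0.09)  # about 1.80
#' @export
selection_intensity <- function(fraction) {
  vapply(fraction, function(p) {
    p <- check_fraction(p, "fraction")
    stats::dnorm(stats::qnorm(1 - p)) / p
  }, numeric(1))
}

#' Predicted response to selection (breeder's equation)
#'
#' Expected genetic gain per cycle
#' \deqn{\Delta G = h^2 \, i \, \sigma_p / L}
#' with heritability \eqn{h^2}, selection intensity \eqn{i} implied by the
#' selected fraction, phenotypic standard deviation \eqn{\sigma_p} and
#' cycle length \eqn{L} (years per cycle).
#'
#' @param h2 Narrow-sense heritability in `[0, 1]`.
#' @param fraction Selected proportion in (0, 1).
#' @param sigma_p Phenotypic standard deviation in trait units.
#' @param L Cycle length (default 1).
#' @return An object of class `"response_prediction"`: list with
#'   `delta_g`, `intensity_i` and the inputs.
#' @examples
#' predicted_gain(0.25, 0.09, 300)
#' @export
predicted_gain <- function(h2, fraction, sigma_p, L = 1) {
  stopifnot(h2 >= 0, h2 <= 1, sigma_p > 0, L > 0)
  i <- selection_intensity(fraction)
  structure(list(delta_g = h2 * i * sigma_p / L, intensity_i = i,
                 h2 = h2, fraction = fraction, sigma_p = sigma_p, L = L),
            class = "response_prediction")
}

#' @export
print.response_prediction <- function(x, ...) {
  cat(sprintf(
    "Predicted response: dG = h2 * i * sigma_p / L = %.3g (i = %.3f, p = %.3g)\n",
    x$delta_g, x$intensity_i, x$fraction))
  invisible(x)
}
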