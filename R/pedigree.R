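#' Pedigree tables
#'
#' A pedigree is a data frame with columns `id`, `sire`, `dam` and
#' (optionally) `generation`. Unknown parents are `NA` (or `""` on disk).
#' Selfing is encoded by recording the same progenitor as both sire and dam,
#' which lets the tabular relationship-matrix recursion accumulate inbreeding
#' without special cases. `as_pedigree()` validates the records, checks for
#' cycles and reorders them topologically (parents before offspring, ties by
#' input order).
#'
#' @param x A data frame with columns `id`, `sire`, `dam` and optionally
#'   `generation`.
#' @return A data frame of class `"pedigree"`, topologically ordered.
#' @examples
#' ped <- as_pedigree(data.frame(
#'   id = c("A", "B", "X"), sire = c(NA, NA, "A"), dam = c(NA, NA, "B")))
#' build_a_matrix(ped)
#' @export
as_pedigree <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  req <- c("id", "sire", "dam")
  if (!all(req %in% names(x))) {
    stop("pedigree needs columns id, sire, dam", call. = FALSE)
  }
  for (col in req) {
    x[[col]] <- as.character(x[[col]])
    x[[col]][!is.na(x[[col]]) & x[[col]] == ""] <- NA_character_
  }
  if (!("generation" %in% names(x))) x$generation <- NA_character_
  if (anyNA(x$id)) stop("pedigree ids must be non-missing", call. = FALSE)
  if (anyDuplicated(x$id)) stop("duplicated pedigree ids", call. = FALSE)
  known_parents <- stats::na.omit(unique(c(x$sire, x$dam)))
  missing_ids <- setdiff(known_parents, x$id)
  if (length(missing_ids)) {
    stop("parents not present as individuals: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  ord <- ped_topological_order(x)
  out <- x[ord, c("id", "sire", "dam", "generation"), drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

# Kahn's algorithm, stable in input order; errors on cycles (an individual
# that is its own ancestor).
ped_topological_order <- function(x) {
  n <- nrow(x)
  idx <- seq_len(n)
  names(idx) <- x$id
  si <- idx[x$sire]
  di <- idx[x$dam]
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in unique(stats::na.omit(c(si[i], di[i])))) {
      indeg[i] <- indeg[i] + 1L
      children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- sort(c(queue, ch))
    }
  }
  if (length(out) != n) stop("pedigree contains a cycle", call. = FALSE)
  out
}

#' Numerator relationship matrix by the tabular method
#'
#' Builds the additive (numerator) relationship matrix \eqn{A} from a
#' pedigree: founders get \eqn{A_{ii} = 1} and zero off-diagonals among
#' themselves; an offspring \eqn{o} of parents \eqn{(s, d)} gets
#' \eqn{A_{oj} = (A_{sj} + A_{dj})/2} against every earlier individual and
#' \eqn{A_{oo} = 1 + A_{sd}/2}. A single known parent is treated as if the
#' missing parent were an unrelated founder. Diagonals are \eqn{1 + F_i}
#' with \eqn{F_i} the inbreeding coefficient; a chain of \eqn{t} selfing
#' generations from a non-inbred individual gives \eqn{A_{ii} = 2 - (1/2)^t}.
#'
#' @param ped A pedigree (coerced with [as_pedigree()]).
#' @return A dense symmetric matrix with dimnames set to the individual ids,
#'   in topological order.
#' @seealso [a_inverse()] for the sparse inverse used in mixed-model fitting.
#' @export
build_a_matrix <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    prev <- seq_len(i - 1L)
    if (length(prev)) {
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + A[s, prev] / 2
      if (!is.na(d)) row <- row + A[d, prev] / 2
      A[i, prev] <- row
      A[prev, i] <- row
    }
    asd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    A[i, i] <- 1 + asd / 2
  }
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' Computes \eqn{F_i = A_{sd}/2}, the coancestry of the parents, by a
#' memoized kinship recursion. Runs in time proportional to the number of
#' distinct ancestor pairs visited, so deep selfing chains stay cheap and no
#' dense matrix is formed.
#'
#' @inheritParams build_a_matrix
#' @return Named numeric vector of inbreeding coefficients in pedigree order.
#' @export
ped_inbreeding <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  memo <- new.env(parent = emptyenv())
  kin <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste0(i, ":", j)
    val <- memo[[key]]
    if (!is.null(val)) return(val)
    if (i == j) {
      val <- 0.5 * (1 + kin(si[i], di[i]))
    } else {
      # j is the later individual; recurse through its parents
      val <- 0.5 * (kin(i, si[j]) + kin(i, di[j]))
    }
    memo[[key]] <- val
    val
  }
  f <- vapply(seq_len(n), function(i) {
    if (is.na(si[i]) || is.na(di[i])) 0 else kin(si[i], di[i])
  }, numeric(1))
  names(f) <- ped$id
  f
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles \eqn{A^{-1}} directly from the pedigree by Henderson's rules
#' accounting for inbreeding: each individual contributes
#' \eqn{1/d_i} to its diagonal, \eqn{-1/(2 d_i)} to each individual-parent
#' pair and \eqn{1/(4 d_i)} to each parent-parent pair, where
#' \eqn{d_i = 1 - \sum_{p} (1 + F_p)/4} over known parents is the Mendelian
#' sampling variance. The result is sparse (at most a 3x3 block per
#' individual), which is what makes animal models with thousands of
#' individuals tractable.
#'
#' @inheritParams build_a_matrix
#' @return A sparse symmetric [Matrix::dsCMatrix-class] with dimnames set to
#'   the individual ids.
#' @export
a_inverse <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  f <- ped_inbreeding(ped)
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  k <- 0L
  add <- function(i, j, v) {
    k <<- k + 1L
    ii[k] <<- i; jj[k] <<- j; xx[k] <<- v
  }
  for (i in seq_len(n)) {
    par <- c(si[i], di[i])
    par <- par[!is.na(par)]
    d_i <- 1 - sum((1 + f[par]) / 4)
    b <- 1 / d_i
    add(i, i, b)
    for (p in par) {
      add(i, p, -b / 2)
      add(p, i, -b / 2)
      for (q in par) add(p, q, b / 4)
    }
  }
  ii <- ii[seq_len(k)]; jj <- jj[seq_len(k)]; xx <- xx[seq_len(k)]
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                       dimnames = list(ped$id, ped$id))
}

#' Read and write pedigree CSV files
#'
#' The on-disk dialect has columns `id`, `sire`, `dam`, `generation`, with
#' empty strings for unknown parents (founders).
#'
#' @param path Path to a CSV file.
#' @return `read_pedigree()` returns a validated pedigree;
#'   `write_pedigree()` returns `path` invisibly.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  as_pedigree(df)
}

#' @rdname read_pedigree
#' @param ped A pedigree.
#' @export
write_pedigree <- function(ped, path) {
  ped <- as_pedigree(ped)
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- ""
  out$dam[is.na(out$dam)] <- ""
  out$generation[is.na(out$generation)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
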