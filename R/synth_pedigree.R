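#' Simulate a breeding pedigree of selfed biparental crosses
#'
#' Generates the pedigree structure of an early-generation line-breeding
#' program: a set of unrelated founders, biparental crosses among them, and a
#' chain of selfing generations after each cross (F1 selfed to F2, F2 to F3,
#' ...). Each selfing step records the single progenitor as both sire and
#' dam, so the tabular relationship recursion accumulates the expected
#' inbreeding (\eqn{F = 1 - (1/2)^t} after \eqn{t} selfing generations from
#' the F1). The terminal individual of each chain is the line that gets
#' phenotyped in a progeny row.
#'
#' @param n_founders Number of unrelated founders (>= 2).
#' @param n_crosses Number of biparental crosses; parents are drawn at random
#'   (distinct) from the founders.
#' @param selfing_generations Number of selfing steps after each cross
#'   (3 for an F4 line derived from the F1).
#' @param seed Integer seed; the same seed reproduces the pedigree exactly.
#' @return A [as_pedigree()] data frame. The terminal (phenotyped) line ids
#'   are in `attr(, "line_ids")`.
#' @examples
#' ped <- simulate_pedigree(10, 5, selfing_generations = 3, seed = 1)
#' head(ped)
#' attr(ped, "line_ids")
#' @export
simulate_pedigree <- function(n_founders, n_crosses, selfing_generations,
                              seed) {
  n_founders <- check_count(n_founders, "n_founders", min = 2L)
  n_crosses <- check_count(n_crosses, "n_crosses", min = 1L)
  selfing_generations <- check_count(selfing_generations,
                                     "selfing_generations", min = 0L)
  founders <- sprintf("FND%04d", seq_len(n_founders))
  with_seed(seed, {
    id <- founders
    sire <- rep(NA_character_, n_founders)
    dam <- rep(NA_character_, n_founders)
    gen <- rep("F0", n_founders)
    line_ids <- character(n_crosses)
    for (j in seq_len(n_crosses)) {
      parents <- sample(founders, 2L, replace = FALSE)
      prev <- sprintf("L%05d_F1", j)
      id <- c(id, prev); sire <- c(sire, parents[1L])
      dam <- c(dam, parents[2L]); gen <- c(gen, "F1")
      if (selfing_generations > 0L) {
        for (t in seq_len(selfing_generations)) {
          cur <- sprintf("L%05d_F%d", j, t + 1L)
          id <- c(id, cur); sire <- c(sire, prev); dam <- c(dam, prev)
          gen <- c(gen, sprintf("F%d", t + 1L))
          prev <- cur
        }
      }
      line_ids[j] <- prev
    }
    ped <- as_pedigree(data.frame(id = id, sire = sire, dam = dam,
                                  generation = gen,
                                  stringsAsFactors = FALSE))
    attr(ped, "line_ids") <- line_ids
    ped
  })
}
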