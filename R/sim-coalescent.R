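#' Neutral coalescent sample under the infinite-sites model
#'
#' Simulates a Hudson coalescent genealogy for \code{n} lineages (no
#' recombination) and drops infinite-sites mutations on it at rate
#' \code{theta/2} per lineage per coalescent time unit: the number of
#' mutations is Poisson with mean \code{theta/2} times the total branch
#' length, and each mutation lands on a branch with probability proportional
#' to its length, deriving every descendant leaf. Under this model the
#' expected number of segregating sites is Watterson's
#' \code{theta * a1(n)} with \code{a1(n) = sum(1/(1:(n-1)))}.
#'
#' @param n Number of sampled sequences (>= 2).
#' @param theta Per-locus population mutation parameter (>= 0).
#' @param locus_length Locus length; mutated sites get distinct positions in
#'   1..locus_length.
#' @param seed Optional RNG seed.
#' @return A \code{\link{seq_matrix}} with one column per segregating site
#'   (ancestral and derived nucleotides drawn at random). With
#'   \code{theta = 0} the matrix has zero columns.
#' @examples
#' m <- simulate_neutral_sample(10, theta = 5, seed = 1)
#' dim(m)
#' @export
simulate_neutral_sample <- function(n, theta, locus_length = 25000L,
                                    seed = NULL) {
  assert_that(n >= 2, "need at least two lineages")
  assert_that(theta >= 0, "theta must be non-negative")
  with_seed(seed, {
    # branches: leaf set and accumulated length for every lineage that has
    # been closed off by a coalescence (the root lineage carries no mutations
    # that segregate, and is dropped)
    active_sets <- lapply(seq_len(n), identity)
    active_len <- numeric(n)
    branch_sets <- list()
    branch_len <- numeric(0)
    k <- n
    while (k > 1) {
      t <- rexp(1, rate = k * (k - 1) / 2)
      active_len <- active_len + t
      pick <- sample.int(k, 2)
      i <- min(pick); j <- max(pick)
      branch_sets <- c(branch_sets, active_sets[c(i, j)])
      branch_len <- c(branch_len, active_len[c(i, j)])
      merged <- sort(c(active_sets[[i]], active_sets[[j]]))
      active_sets <- c(active_sets[-c(i, j)], list(merged))
      active_len <- c(active_len[-c(i, j)], 0)
      k <- k - 1
    }
    total_len <- sum(branch_len)
    n_mut <- if (theta > 0) rpois(1, theta / 2 * total_len) else 0L
    n_mut <- min(n_mut, locus_length)  # infinite sites needs distinct positions
    if (n_mut == 0) {
      mat <- matrix(character(0), nrow = n, ncol = 0)
      rownames(mat) <- paste0("s", seq_len(n))
      return(seq_matrix(mat, integer(0)))
    }
    which_branch <- sample.int(length(branch_len), n_mut, replace = TRUE,
                               prob = branch_len)
    positions <- sort(sample.int(locus_length, n_mut))
    bases <- c("A", "C", "G", "T")
    mat <- matrix("", nrow = n, ncol = n_mut)
    for (s in seq_len(n_mut)) {
      anc_der <- sample(bases, 2)
      col <- rep(anc_der[1], n)
      col[branch_sets[[which_branch[s]]]] <- anc_der[2]
      mat[, s] <- col
    }
    rownames(mat) <- paste0("s", seq_len(n))
    seq_matrix(mat, positions)
  })
}
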