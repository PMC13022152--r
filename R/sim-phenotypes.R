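#' Simulate plant-height phenotypes for a cohort
#'
#' Heights (culm length at heading, cm) are drawn from a normal distribution
#' around each accession's haplotype-group mean, emulating the published
#' pattern: tall wild-type (GR) and ER accessions, intermediate EQ, and
#' semi-dwarf loss-of-function groups.
#'
#' @param truth Tibble with columns \code{accession} and \code{type_id}
#'   (the TruthSet of a simulated cohort).
#' @param config A \code{\link{sim_config}} supplying \code{height_means}
#'   (named by type id) and \code{height_sd}.
#' @param seed Optional RNG seed (default derived from the config seed).
#' @return Tibble with columns \code{accession}, \code{type_id},
#'   \code{height_cm}.
#' @export
simulate_phenotypes <- function(truth, config,
                                seed = derive_seed(config$seed, "phenotypes")) {
  ids <- as.character(truth$type_id)
  missing_mean <- setdiff(unique(ids), names(config$height_means))
  assert_that(length(missing_mean) == 0,
              paste0("no height mean configured for haplotype(s): ",
                     paste(missing_mean, collapse = ", ")))
  mu <- unname(config$height_means[ids])
  with_seed(seed, {
    tibble(accession = truth$accession,
           type_id = truth$type_id,
           height_cm = rnorm(nrow(truth), mu, config$height_sd))
  })
}
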