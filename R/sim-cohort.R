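# Whole-cohort simulation: reference, haplotype-edited accessions, genotype
# calls, read pairs, metadata, phenotypes, and the recorded TruthSet.

# plausible subpopulation tendencies per haplotype, reflecting the published
# distribution (GR mostly indica, EQ mostly japonica, japonica-specific
# types 3-6, indica types 7-10, ER scattered)
default_subpop_for_type <- function(type_id) {
  switch(as.character(type_id),
         `1` = "indica", `2` = "japonica", `3` = "japonica", `4` = "japonica",
         `5` = "japonica", `6` = "japonica", `7` = "indica", `8` = "indica",
         `9` = "indica", `10` = "indica", `11` = "indica", `12` = "aromatic",
         "admix")
}

#' Simulate a full synthetic cohort
#'
#' Builds the reference locus, edits accessions to carry the requested
#' haplotypes, assembles per-accession genotype calls (homozygous alternate
#' at every edited site, depth and alt-fraction recorded), simulates read
#' pairs for every accession, and attaches metadata and plant-height
#' phenotypes. Heterozygous accessions (optional) carry their combination
#' edits in 0/1 state with alt fraction 0.5 and truth label
#' \code{"heterozygous"}.
#'
#' @param config A \code{\link{sim_config}}.
#' @param n_per_type Accessions per haplotype type (single value or vector
#'   named by type id).
#' @param types Haplotype type ids to include (default 1..12).
#' @param n_het Number of additional heterozygous (EQ/GR-style) accessions.
#' @param definitions Haplotype definition table.
#' @param depth Simulated genotype depth (default 30).
#' @param with_pairs Simulate read pairs (default TRUE; required for
#'   structural typing).
#' @return List of class \code{sd1_cohort}: \code{reference}, \code{truth}
#'   (accession, type_id, label), \code{calls}, \code{pairs},
#'   \code{metadata}, \code{phenotypes}, \code{sequences} (named list of
#'   accession sequences), \code{deletions} (truth deletion intervals per
#'   accession).
#' @export
simulate_cohort <- function(config = sim_config(), n_per_type = 10L,
                            types = 1:12, n_het = 0L,
                            definitions = sd1_haplotypes(),
                            depth = 30, with_pairs = TRUE) {
  ref <- make_reference(config)
  if (length(n_per_type) == 1) {
    n_per_type <- setNames(rep(n_per_type, length(types)), types)
  }
  acc_rows <- list(); call_rows <- list(); pair_rows <- list()
  meta_rows <- list(); del_rows <- list(); seqs <- list()

  add_accession <- function(name, type_id, label, edits, deletions, sequence,
                            gt, af) {
    acc_rows[[length(acc_rows) + 1]] <<- tibble(
      accession = name, type_id = type_id, label = label)
    if (nrow(edits) > 0) {
      call_rows[[length(call_rows) + 1]] <<- edits |>
        mutate(sample = name, gt = gt, depth = depth, alt_fraction = af,
               allele = .data$alt)
    }
    if (nrow(deletions) > 0) {
      del_rows[[length(del_rows) + 1]] <<- mutate(deletions, accession = name)
    }
    seqs[[name]] <<- sequence
    meta_rows[[length(meta_rows) + 1]] <<- tibble(
      accession = name,
      subpopulation = default_subpop_for_type(type_id %||% 1L),
      category = if ((length(meta_rows) %% 3) == 0) "modern" else "landrace")
    if (with_pairs) {
      pair_rows[[length(pair_rows) + 1]] <<- simulate_read_pairs(
        sequence, config, deletions = if (nrow(deletions) > 0) deletions,
        accession = name)
    }
  }

  for (t in types) {
    edited <- apply_haplotype(ref, t, definitions)
    for (i in seq_len(n_per_type[[as.character(t)]])) {
      name <- sprintf("t%02d_acc%02d", t, i)
      add_accession(name, t, as.character(t), edited$edits, edited$deletions,
                    edited$sequence, gt = "1/1", af = 1.0)
    }
  }
  if (n_het > 0) {
    edited <- apply_haplotype(ref, 2L, definitions)  # EQ/GR heterozygote
    for (i in seq_len(n_het)) {
      name <- sprintf("het_acc%02d", i)
      # reads come from the reference haplotype; genotypes are 0/1
      add_accession(name, NA_integer_, "heterozygous", edited$edits,
                    edited$deletions[0, ], ref$sequence, gt = "0/1", af = 0.5)
    }
  }

  truth <- bind_rows(acc_rows)
  calls <- bind_rows(call_rows)
  # add homozygous-reference rows so every accession appears at every site
  if (nrow(calls) > 0) {
    sites <- calls |> distinct(.data$chrom, .data$pos, .data$ref, .data$alt)
    full <- tidyr::crossing(sites, sample = truth$accession) |>
      dplyr::anti_join(calls, by = c("chrom", "pos", "sample"))
    calls <- bind_rows(
      calls,
      full |> mutate(gt = "0/0", depth = depth, alt_fraction = 0,
                     allele = NA_character_)) |>
      arrange(.data$pos, .data$sample)
  }
  phen_truth <- dplyr::filter(truth, !is.na(.data$type_id))
  structure(list(
    reference = ref,
    truth = truth,
    calls = calls,
    pairs = if (with_pairs) bind_rows(pair_rows) else NULL,
    metadata = bind_rows(meta_rows),
    phenotypes = simulate_phenotypes(phen_truth, config),
    sequences = seqs,
    deletions = if (length(del_rows)) bind_rows(del_rows) else
      tibble(start = integer(), end = integer(), accession = character())
  ), class = "sd1_cohort")
}

#' @export
print.sd1_cohort <- function(x, ...) {
  cat("<sd1_cohort> ", nrow(x$truth), " accessions, ",
      length(unique(x$truth$label)), " truth labels\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits reference FASTA, accession FASTA, truth VCF, pairs TSV, metadata
#' TSV and phenotype TSV into a directory. Output is byte-identical for a
#' fixed configuration seed.
#'
#' @param cohort An \code{sd1_cohort}.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named list of written paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    reference = file.path(out_dir, "reference.fasta"),
    accessions = file.path(out_dir, "accessions.fasta"),
    vcf = file.path(out_dir, "truth.vcf"),
    pairs = file.path(out_dir, "pairs.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    definitions = file.path(out_dir, "haplotype_definitions.tsv")
  )
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(c(locus = cohort$reference$sequence)),
    paths$reference)
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(unlist(cohort$sequences)), paths$accessions)
  write_vcf(cohort$calls, paths$vcf,
            contig_length = cohort$reference$config$locus_length)
  if (!is.null(cohort$pairs)) write_pairs_tsv(cohort$pairs, paths$pairs)
  write_metadata(cohort$metadata, paths$metadata)
  readr::write_tsv(cohort$phenotypes, paths$phenotypes)
  write_haplotype_definitions(sd1_haplotypes(), paths$definitions)
  invisible(paths)
}
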