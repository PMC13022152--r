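#' Pipeline run configuration
#'
#' Paths plus thresholds for an end-to-end run. Referenced files must exist
#' at construction time, so misconfiguration fails before any stage runs.
#'
#' @param vcf,pairs,metadata,reference,definitions Input file paths
#'   (\code{pairs} may be NULL to skip deletion detection).
#' @param accessions Optional accession FASTA (enables the tandem-repeat
#'   stage).
#' @param out_dir Output directory.
#' @param policy Genotype \code{\link{filter_policy}}.
#' @param k_sigma,min_support Deletion-detector thresholds.
#' @param read_length Read length in bp.
#' @param flanks Diversity window flanks in bp.
#' @param bootstrap_replicates,collapse_below Phylogeny bootstrap settings.
#' @param alpha ANOVA significance level.
#' @param min_reciprocal_overlap Structural-match threshold.
#' @param coord_offset Chromosome-1 to locus offset.
#' @param seed RNG seed for the bootstrap stage.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(vcf, metadata, reference, definitions,
                       pairs = NULL, accessions = NULL,
                       out_dir = tempfile("sd1hap_run_"),
                       policy = filter_policy(),
                       k_sigma = 4, min_support = 3L, read_length = 150L,
                       flanks = c(1000, 10000),
                       bootstrap_replicates = 1000L, collapse_below = 60,
                       alpha = 0.05, min_reciprocal_overlap = 0.9,
                       coord_offset = sd1_coord_offset(), seed = 1L) {
  paths <- c(vcf = vcf, metadata = metadata, reference = reference,
             definitions = definitions,
             if (!is.null(pairs)) c(pairs = pairs),
             if (!is.null(accessions)) c(accessions = accessions))
  missing <- paths[!file.exists(paths)]
  assert_that(length(missing) == 0,
              paste0("missing input file(s): ",
                     paste(names(missing), "=", missing, collapse = ", ")))
  assert_that(k_sigma > 0 && min_support >= 1 && all(flanks >= 0) &&
                alpha > 0 && alpha < 1 &&
                min_reciprocal_overlap > 0 && min_reciprocal_overlap <= 1,
              "threshold outside its documented range")
  structure(list(vcf = vcf, pairs = pairs, metadata = metadata,
                 reference = reference, definitions = definitions,
                 accessions = accessions, out_dir = out_dir, policy = policy,
                 k_sigma = k_sigma, min_support = min_support,
                 read_length = read_length, flanks = flanks,
                 bootstrap_replicates = bootstrap_replicates,
                 collapse_below = collapse_below, alpha = alpha,
                 min_reciprocal_overlap = min_reciprocal_overlap,
                 coord_offset = coord_offset, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes filter, annotation, deletion detection, haplotype
#' classification, frequency tabulation, windowed diversity, NJ phylogeny
#' with bootstrap, and (when accession sequences are supplied)
#' tandem-repeat comparison, writing TSV/newick/BED outputs and a manifest
#' into \code{config$out_dir}. Identical configuration and inputs give
#' identical outputs.
#'
#' @param config A \code{\link{run_config}}.
#' @param gene_model Optional gene model tibble; defaults to the standard
#'   synthetic-locus model.
#' @return List of class \code{sd1_run}: per-stage results plus
#'   \code{manifest}.
#' @export
run_pipeline <- function(config, gene_model = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  manifest <- list(package_version = as.character(utils::packageVersion("sd1hap")),
                   seed = config$seed,
                   thresholds = list(
                     min_depth = config$policy$min_depth_exclusive,
                     min_alt_fraction = config$policy$min_alt_fraction_exclusive,
                     k_sigma = config$k_sigma,
                     min_support = config$min_support,
                     min_reciprocal_overlap = config$min_reciprocal_overlap,
                     collapse_below = config$collapse_below,
                     alpha = config$alpha),
                   counts = list())

  calls <- stage("read_vcf", read_vcf(config$vcf))
  metadata <- stage("read_metadata", read_metadata(config$metadata))
  definitions <- stage("read_definitions",
                       read_haplotype_definitions(config$definitions))
  ref_seq <- stage("read_reference", {
    ss <- Biostrings::readBStringSet(config$reference)
    as.character(ss[[1]])
  })
  gm <- gene_model %||% gene_model_from_config(sim_config())
  manifest$counts$calls <- nrow(calls)

  filtered <- stage("filter", filter_variants(calls, config$policy))
  manifest$counts$filtered_calls <- nrow(filtered)

  annotated <- stage("annotate", {
    sites <- filtered |>
      dplyr::filter(!is.na(.data$allele)) |>
      distinct(.data$pos, .data$ref, alt = .data$allele)
    if (nrow(sites) > 0) annotate_variants(sites, gm, ref_seq) else
      mutate(sites, class = character(0), detail = character(0))
  })

  pairs <- if (!is.null(config$pairs)) stage("read_pairs",
                                             read_pairs_tsv(config$pairs))
  haplotype_calls <- stage("classify", classify_cohort(
    calls, pairs, definitions, config$coord_offset, config$policy,
    config$min_reciprocal_overlap, config$read_length, config$min_support,
    config$k_sigma))
  manifest$counts$accessions <- nrow(haplotype_calls)

  frequencies <- stage("frequencies",
                       tabulate_frequencies(haplotype_calls, metadata))

  m <- stage("seq_matrix", vcf_to_seq_matrix(
    dplyr::filter(calls, !is.na(.data$depth),
                  .data$depth > config$policy$min_depth_exclusive)))
  cfg0 <- sim_config()
  diversity <- stage("diversity", if (ncol(m$states) > 0 && nrow(m$states) >= 2)
    window_scan(m, cfg0$gene_start, cfg0$gene_end, config$flanks) else NULL)

  phylogeny <- stage("phylogeny", {
    if (ncol(m$states) >= 1 && nrow(m$states) >= 3) {
      dmat <- tn93_distance_matrix(m)
      if (!any(is.na(dmat))) {
        bootstrap_support(m, replicates = config$bootstrap_replicates,
                          seed = config$seed,
                          collapse_below = config$collapse_below)
      } else NULL
    } else NULL
  })

  trs <- stage("tandem_repeats", {
    if (!is.null(config$accessions)) {
      acc_seqs <- Biostrings::readBStringSet(config$accessions)
      ref_loci <- scan_trs(ref_seq)
      purrr::map(setNames(names(acc_seqs), names(acc_seqs)), function(nm) {
        compare_trs(scan_trs(as.character(acc_seqs[[nm]])), ref_loci)
      })
    } else NULL
  })

  # outputs
  readr::write_tsv(haplotype_calls, file.path(config$out_dir, "haplotype_calls.tsv"))
  readr::write_tsv(frequencies, file.path(config$out_dir, "frequencies.tsv"))
  readr::write_tsv(annotated, file.path(config$out_dir, "annotations.tsv"))
  if (!is.null(diversity)) {
    readr::write_tsv(diversity, file.path(config$out_dir, "diversity_windows.tsv"))
  }
  if (!is.null(phylogeny)) {
    write_tree_newick(phylogeny, file.path(config$out_dir, "tree.nwk"))
  }
  if (!is.null(trs)) {
    tr_summary <- purrr::imap(trs, function(cmp, nm) {
      mutate(cmp$summary, accession = nm, .before = 1)
    }) |> bind_rows()
    readr::write_tsv(tr_summary, file.path(config$out_dir, "tr_comparison.tsv"))
  }
  manifest$counts$frequencies_rows <- nrow(frequencies)
  manifest_df <- tibble(key = c("package_version", "seed",
                                names(unlist(manifest$thresholds)),
                                names(unlist(manifest$counts))),
                        value = as.character(c(manifest$package_version,
                                               manifest$seed,
                                               unlist(manifest$thresholds),
                                               unlist(manifest$counts))))
  readr::write_tsv(manifest_df, file.path(config$out_dir, "manifest.tsv"))

  structure(list(calls = calls, filtered = filtered, annotated = annotated,
                 haplotype_calls = haplotype_calls, frequencies = frequencies,
                 diversity = diversity, phylogeny = phylogeny, trs = trs,
                 manifest = manifest, out_dir = config$out_dir),
            class = "sd1_run")
}

#' @export
print.sd1_run <- function(x, ...) {
  cat("<sd1_run> ", x$manifest$counts$accessions, " accessions; outputs in ",
      x$out_dir, "\n", sep = "")
  invisible(x)
}
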