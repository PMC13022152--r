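# Haplotype assignment.
#
# Evaluation follows the catalogue's precedence rule: accessions carrying a
# long-deletion (structural) diagnostic are typed first, then point
# loss-of-function alleles, and only accessions with neither are typed by
# their residue-100/340 states -- because a LOF accession may share the
# 100/340 substitutions of the combination types.

#' Classify one accession's SD1 haplotype
#'
#' @param variants Genotype-call tibble for a single accession (locus
#'   coordinates; typically depth-filtered).
#' @param deletion_calls Deletion-call tibble for the accession (may be
#'   empty).
#' @param definitions Haplotype definition table.
#' @param coord_offset Chromosome-1 to locus offset for the definition
#'   coordinates.
#' @param min_reciprocal_overlap Minimum reciprocal overlap between a
#'   deletion call and a defined interval (default 0.9; insert-size
#'   breakpoints are imprecise).
#' @param accession Accession id for the output (default taken from
#'   \code{variants$sample}).
#' @return One-row tibble: \code{accession}, \code{type_id} (NA for special
#'   labels), \code{label} (\code{"1"}..\code{"12"}, \code{"GQ_unobserved"},
#'   \code{"heterozygous"} or \code{"unclassified"}), \code{zygosity},
#'   \code{evidence} (semicolon-joined matched diagnostics).
#' @export
classify_accession <- function(variants, deletion_calls = NULL,
                               definitions = sd1_haplotypes(),
                               coord_offset = sd1_coord_offset(),
                               min_reciprocal_overlap = 0.9,
                               accession = NULL) {
  accession <- accession %||%
    (if (nrow(variants) > 0 && "sample" %in% names(variants))
      variants$sample[1] else NA_character_)
  result <- function(type_id, label, zygosity, evidence) {
    tibble(accession = accession, type_id = type_id, label = label,
           zygosity = zygosity, evidence = paste(evidence, collapse = "; "))
  }

  # 1. structural types from deletion calls
  dels <- dplyr::filter(definitions, .data$class == "long_deletion")
  if (!is.null(deletion_calls) && nrow(deletion_calls) > 0 && nrow(dels) > 0) {
    matched <- purrr::map_lgl(seq_len(nrow(dels)), function(i) {
      ds <- dels$pos[i] - coord_offset; de <- dels$end[i] - coord_offset
      any(reciprocal_overlap(deletion_calls$start, deletion_calls$end, ds, de) >=
            min_reciprocal_overlap)
    })
    if (sum(matched) > 1) {
      abort(paste0("accession ", accession, ": deletion calls match ",
                   "multiple structural haplotypes (types ",
                   paste(dels$type_id[matched], collapse = ", "),
                   ") - possible sample-purity problem"))
    }
    if (sum(matched) == 1) {
      hit <- dels[matched, ]
      return(result(hit$type_id, as.character(hit$type_id), "homozygous",
                    paste0("deletion ", hit$pos, "-", hit$end,
                           " (", hit$allele_name, ")")))
    }
  }

  has_site <- function(pos) {
    dplyr::filter(variants, .data$pos == !!pos)
  }
  saw_het <- FALSE

  # 2. point loss-of-function diagnostics (homozygous)
  lof <- dplyr::filter(definitions, .data$precedence == 2L) |>
    arrange(.data$type_id)
  for (i in seq_len(nrow(lof))) {
    d <- lof[i, ]
    lp <- d$pos - coord_offset
    if (d$class == "point_snp") {
      v <- has_site(lp)
      v <- dplyr::filter(v, !is.na(.data$allele), .data$allele == d$alt)
      if (nrow(v) > 0) {
        if (any(is_hom_alt(v$gt))) {
          return(result(d$type_id, as.character(d$type_id), "homozygous",
                        paste0(d$aa_detail, " at ", d$pos)))
        }
        if (any(is_het(v$gt))) saw_het <- TRUE
      }
    } else if (d$class == "indel") {
      le <- d$end - coord_offset
      want_del <- !identical(d$indel_kind, "insertion")
      v <- variants |>
        dplyr::filter(!is.na(.data$allele),
                      if (want_del) nchar(.data$ref) > nchar(.data$allele)
                      else nchar(.data$allele) > nchar(.data$ref),
                      abs(nchar(.data$ref) - nchar(.data$allele)) ==
                        le - lp + 1L,
                      .data$pos >= lp - 2L, .data$pos <= le)
      if (nrow(v) > 0) {
        if (any(is_hom_alt(v$gt))) {
          return(result(d$type_id, as.character(d$type_id), "homozygous",
                        paste0(d$aa_detail, " indel at ", d$pos, "-", d$end)))
        }
        if (any(is_het(v$gt))) saw_het <- TRUE
      }
    }
  }

  # 3. residue-100/340 combination
  sites <- sd1_diagnostic_sites() - coord_offset
  state_at <- function(lp, ref_state, alt_state) {
    v <- has_site(lp)
    if (nrow(v) == 0) return(ref_state)
    v <- v[1, ]
    if (is_het(v$gt)) return("het")
    if (is_hom_alt(v$gt) && !is.na(v$allele) && v$allele == "A") return(alt_state)
    ref_state
  }
  s100 <- state_at(sites[["res100"]], "G", "E")
  s340 <- state_at(sites[["res340"]], "R", "Q")
  if (saw_het || s100 == "het" || s340 == "het") {
    return(result(NA_integer_, "heterozygous", "heterozygous",
                  "heterozygous genotype at a deciding site"))
  }
  combo <- paste0(s100, s340)
  combo_map <- c(GR = 1L, EQ = 2L, ER = 11L)
  if (combo %in% names(combo_map)) {
    tid <- combo_map[[combo]]
    return(result(tid, as.character(tid), "homozygous",
                  paste0(s100, "100/", s340, "340")))
  }
  if (combo == "GQ") {
    return(result(NA_integer_, "GQ_unobserved", "homozygous", "G100/Q340"))
  }
  result(NA_integer_, "unclassified", NA_character_, "")
}

#' Classify every accession of a cohort
#'
#' Applies the depth filter to all calls and the alternate-fraction filter to
#' homozygous-alternate calls only, so heterozygous genotypes (alt fraction
#' near 0.5) remain visible to the classifier; heterozygous accessions are
#' then excluded by the homozygous-only frequency tabulation, mirroring the
#' convention that only homozygous alleles are counted.
#'
#' @param calls Multi-sample genotype-call tibble.
#' @param pairs Optional pairs tibble covering all accessions (deletion
#'   evidence); the insert model is fitted on the pooled concordant pairs.
#' @param definitions,coord_offset,min_reciprocal_overlap As in
#'   \code{\link{classify_accession}}.
#' @param policy Filter policy for the quality filter.
#' @param read_length Read length for inner-span computation.
#' @param min_support,k_sigma Deletion-detector thresholds.
#' @return Tibble with one row per accession (see
#'   \code{\link{classify_accession}}).
#' @export
classify_cohort <- function(calls, pairs = NULL,
                            definitions = sd1_haplotypes(),
                            coord_offset = sd1_coord_offset(),
                            policy = filter_policy(),
                            min_reciprocal_overlap = 0.9,
                            read_length = 150L, min_support = 3L,
                            k_sigma = 4) {
  kept <- calls |>
    dplyr::filter(!is.na(.data$depth),
                  .data$depth > policy$min_depth_exclusive) |>
    dplyr::filter(is_het(.data$gt) |
                    is.na(.data$alt_fraction) |
                    .data$alt_fraction > policy$min_alt_fraction_exclusive |
                    !is_hom_alt(.data$gt))
  model <- if (!is.null(pairs) && nrow(pairs) >= 2) fit_insert_model(pairs) else NULL
  samples <- sort(unique(c(calls$sample,
                           if (!is.null(pairs)) pairs$accession)))
  purrr::map(samples, function(s) {
    v <- dplyr::filter(kept, .data$sample == s)
    dc <- NULL
    if (!is.null(model)) {
      p <- dplyr::filter(pairs, .data$accession == s)
      if (nrow(p) > 0) {
        dc <- detect_deletions(p, model, read_length = read_length,
                               min_support = min_support, k_sigma = k_sigma)
      }
    }
    classify_accession(v, dc, definitions, coord_offset,
                       min_reciprocal_overlap, accession = s)
  }) |> bind_rows()
}

#' Tabulate haplotype frequencies by subpopulation
#'
#' Counts and percentages of each haplotype label per subpopulation (or any
#' metadata column). With \code{homozygous_only = TRUE} (the default,
#' matching the convention that only homozygous alleles are counted),
#' heterozygous calls are excluded from both numerator and denominator.
#' Accessions without metadata are dropped and reported in the
#' \code{"excluded"} attribute.
#'
#' @param haplotype_calls Classification tibble from
#'   \code{\link{classify_cohort}}.
#' @param metadata Metadata tibble (accession, subpopulation, category).
#' @param by Metadata column to tabulate against (default
#'   \code{"subpopulation"}).
#' @param homozygous_only Exclude heterozygous calls (default TRUE).
#' @return Tibble with \code{label}, the grouping column, \code{n} and
#'   \code{pct} (percentage within the group, 1 decimal).
#' @export
tabulate_frequencies <- function(haplotype_calls, metadata,
                                 by = "subpopulation",
                                 homozygous_only = TRUE) {
  joined <- left_join(haplotype_calls, metadata, by = "accession")
  missing_meta <- joined$accession[is.na(joined[[by]])]
  if (length(missing_meta) > 0) {
    warn(paste0(length(missing_meta),
                " accession(s) without metadata excluded from the table"))
    joined <- joined[!is.na(joined[[by]]), ]
  }
  if (homozygous_only) {
    joined <- dplyr::filter(joined, .data$label != "heterozygous")
  }
  out <- joined |>
    count(.data$label, .data[[by]], name = "n") |>
    group_by(.data[[by]]) |>
    mutate(pct = round(100 * .data$n / sum(.data$n), 1)) |>
    ungroup() |>
    arrange(.data[[by]], .data$label)
  attr(out, "excluded") <- unique(missing_meta)
  out
}

#' Pivot a frequency table to classes-by-groups layout
#'
#' @param freq Output of \code{\link{tabulate_frequencies}}.
#' @param values \code{"n"} or \code{"pct"}.
#' @return Wide tibble, one row per label.
#' @export
frequency_table_wide <- function(freq, values = c("pct", "n")) {
  values <- match.arg(values)
  grp <- setdiff(names(freq), c("label", "n", "pct"))[1]
  tidyr::pivot_wider(freq, id_cols = "label", names_from = all_of(grp),
                     values_from = all_of(values), values_fill = 0)
}
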