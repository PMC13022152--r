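#' Site-level quality filter policy
#'
#' The per-genotype quality rule applied before haplotype counting: a call
#' survives only with read depth strictly greater than 5 and alternate-allele
#' read fraction strictly greater than 0.8. "SNP frequency" is interpreted as
#' the per-sample alternate-read fraction (not a population allele
#' frequency); both thresholds are exclusive, matching the ">" rule.
#'
#' @param min_depth_exclusive Depth threshold (call kept iff depth > this).
#' @param min_alt_fraction_exclusive Alt-fraction threshold (call kept iff
#'   fraction > this).
#' @return A list of class \code{filter_policy}.
#' @export
filter_policy <- function(min_depth_exclusive = 5,
                          min_alt_fraction_exclusive = 0.8) {
  assert_that(min_depth_exclusive >= 0 && min_alt_fraction_exclusive >= 0,
              "thresholds must be non-negative")
  structure(list(min_depth_exclusive = min_depth_exclusive,
                 min_alt_fraction_exclusive = min_alt_fraction_exclusive),
            class = "filter_policy")
}

#' Apply the genotype quality filter
#'
#' Keeps a call iff \code{depth > min_depth_exclusive} AND
#' \code{alt_fraction > min_alt_fraction_exclusive} (strict inequalities).
#' Calls are never modified, only removed, so the filter is idempotent and
#' its output is a subset of its input.
#'
#' @param calls Genotype-call tibble (see \code{\link{read_vcf}}).
#' @param policy A \code{\link{filter_policy}}.
#' @return The surviving rows of \code{calls}.
#' @examples
#' calls <- tibble::tibble(chrom = "locus", pos = 1L, ref = "A", alt = "G",
#'                         sample = "x", gt = "1/1", depth = 6,
#'                         alt_fraction = 0.9)
#' nrow(filter_variants(calls, filter_policy()))
#' @export
filter_variants <- function(calls, policy = filter_policy()) {
  dplyr::filter(calls,
                !is.na(.data$depth) & .data$depth > policy$min_depth_exclusive,
                !is.na(.data$alt_fraction) &
                  .data$alt_fraction > policy$min_alt_fraction_exclusive)
}

#' Read a VCF into a tidy genotype-call table
#'
#' One row per sample per site with genotype, depth and alternate-read
#' fraction (computed from the AD field as alt depth over total depth when
#' present). Multi-allelic sites are preserved; \code{allele} is the sample's
#' non-reference allele (first ALT allele its genotype carries).
#'
#' @param path VCF (v4.x) file path.
#' @return Tibble with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} (comma-joined site ALT list), \code{sample}, \code{gt},
#'   \code{depth}, \code{alt_fraction}, \code{allele}.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path, n = 1L)
  if (length(lines) == 0 || !startsWith(lines[1], "##fileformat=VCF")) {
    abort(paste0("malformed VCF header at line 1 of ", path,
                 ": missing ##fileformat"))
  }
  body <- sum(!startsWith(readLines(path), "#"))
  if (body == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), sample = character(), gt = character(),
                  depth = double(), alt_fraction = double(),
                  allele = character()))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) {
    fixm <- matrix(fixm, nrow = 1, dimnames = list(NULL, names(fixm)))
  }
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(gt)
  n_site <- nrow(fix)

  per_sample <- lapply(samples, function(s) {
    gts <- unname(gt[, s])
    ads <- if (!is.null(ad)) unname(ad[, s]) else rep(NA_character_, n_site)
    af <- vapply(unname(ads), function(a) {
      if (is.na(a)) return(NA_real_)
      d <- suppressWarnings(as.numeric(strsplit(a, ",", fixed = TRUE)[[1]]))
      tot <- sum(d)
      if (!is.finite(tot) || tot == 0) return(NA_real_)
      sum(d[-1]) / tot
    }, 1.0, USE.NAMES = FALSE)
    alts <- strsplit(fix$ALT, ",", fixed = TRUE)
    allele <- vapply(seq_len(n_site), function(i) {
      g <- gts[i]
      if (is.na(g)) return(NA_character_)
      idx <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
      idx <- idx[!is.na(idx) & idx > 0]
      if (length(idx) == 0) return(NA_character_)
      alts[[i]][idx[1]]
    }, "")
    tibble(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
           alt = fix$ALT, sample = s, gt = gts,
           depth = if (!is.null(dp)) as.numeric(dp[, s]) else NA_real_,
           alt_fraction = af, allele = allele)
  })
  bind_rows(per_sample)
}

#' Write genotype calls as a VCF v4.2 file
#'
#' Inverse of \code{\link{read_vcf}} for the fields this pipeline uses
#' (CHROM/POS/REF/ALT and per-sample GT:DP:AD); round-trips with the reader.
#'
#' @param calls Genotype-call tibble.
#' @param path Output path.
#' @param contig Contig name/length for the header.
#' @param contig_length Contig length.
#' @export
write_vcf <- function(calls, path, contig = "locus", contig_length = 25000L) {
  sites <- calls |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    arrange(.data$chrom, .data$pos)
  # one ALT list per site
  sites <- sites |>
    group_by(.data$chrom, .data$pos, .data$ref) |>
    summarise(alt = paste(unique(unlist(strsplit(.data$alt, ",", fixed = TRUE))),
                          collapse = ","), .groups = "drop") |>
    arrange(.data$chrom, .data$pos)
  samples <- sort(unique(calls$sample))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", contig, ",length=", contig_length, ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- vapply(seq_len(nrow(sites)), function(i) {
    st <- sites[i, ]
    alt_list <- strsplit(st$alt, ",", fixed = TRUE)[[1]]
    cells <- vapply(samples, function(s) {
      row <- calls[calls$chrom == st$chrom & calls$pos == st$pos &
                     calls$sample == s, ]
      if (nrow(row) == 0) return("./.:.:.")
      row <- row[1, ]
      g <- row$gt
      if (is.na(g)) g <- "./."
      # renumber the sample's allele into the site ALT list
      if (!is.na(row$allele) && row$allele %in% alt_list) {
        idx <- match(row$allele, alt_list)
        g <- gsub("1", as.character(idx), g, fixed = TRUE)
      }
      d <- row$depth
      if (is.na(d)) return(paste0(g, ":.:."))
      af <- row$alt_fraction
      alt_d <- if (is.na(af)) 0L else as.integer(round(d * af))
      ads <- rep(0L, length(alt_list) + 1L)
      ads[1] <- as.integer(d) - alt_d
      if (!is.na(row$allele) && row$allele %in% alt_list) {
        ads[match(row$allele, alt_list) + 1L] <- alt_d
      }
      paste0(g, ":", as.integer(d), ":", paste(ads, collapse = ","))
    }, "")
    paste(c(st$chrom, st$pos, ".", st$ref, st$alt, ".", "PASS", ".",
            "GT:DP:AD", cells), collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read or write the accession metadata TSV
#'
#' Columns: accession, subpopulation (indica, japonica, aus, aromatic,
#' admix), category (landrace, modern).
#'
#' @param path File path.
#' @return \code{read_metadata} returns the metadata tibble.
#' @export
read_metadata <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(accession = "c", subpopulation = "c",
                                          category = "c"))
}

#' @rdname read_metadata
#' @param metadata Metadata tibble.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path)
  invisible(path)
}
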