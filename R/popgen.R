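# Windowed diversity and neutrality statistics.
#
# Conventions follow the classical estimators: S counts polymorphic columns,
# eta counts total mutations ((distinct alleles - 1) per column, so
# eta >= S at multi-allelic columns), k is the mean pairwise difference,
# pi = k / L_used, theta per sequence = eta / a1(n), and Watterson's theta
# per site = theta_per_seq / L_used. Columns containing any gap or missing
# state are removed first (complete deletion), matching the usual
# alignment-based workflow.

VALID_BASES <- c("A", "C", "G", "T")

#' Diversity statistics for an aligned sample
#'
#' @param m A \code{\link{seq_matrix}}.
#' @param deletion_mode \code{"complete"} (default: drop any column with a
#'   gap/missing/ambiguous state before computing) -- the convention used for
#'   all statistics here.
#' @return One-row tibble: \code{n}, \code{L_used}, \code{S}, \code{eta},
#'   \code{k}, \code{pi}, \code{theta_per_seq}, \code{theta_w_site},
#'   \code{tajima_D}, \code{tajima_p}, \code{note}. All statistics are NA
#'   (with a note) when no analyzable sites remain; \code{tajima_D} is NA
#'   unless \code{S > 0} and \code{n >= 4}.
#' @examples
#' m <- seq_matrix(rbind(c("A","A","A","A"), c("A","A","A","T")))
#' diversity_stats(m)  # S = 1, k = 1, pi = 0.25
#' @export
diversity_stats <- function(m, deletion_mode = "complete") {
  stopifnot(inherits(m, "seq_matrix"))
  x <- m$states
  n <- nrow(x)
  assert_that(n >= 2, "need at least two sequences")
  keep <- apply(x, 2, function(col) all(col %in% VALID_BASES))
  x <- x[, keep, drop = FALSE]
  L_used <- ncol(x)
  if (L_used == 0) {
    return(tibble(n = n, L_used = 0L, S = NA_integer_, eta = NA_integer_,
                  k = NA_real_, pi = NA_real_, theta_per_seq = NA_real_,
                  theta_w_site = NA_real_, tajima_D = NA_real_,
                  tajima_p = NA_real_, note = "no analyzable sites"))
  }
  n_alleles <- apply(x, 2, function(col) length(unique(col)))
  S <- sum(n_alleles > 1)
  eta <- sum(n_alleles - 1)
  n_pairs <- choose(n, 2)
  # per-column pairwise differences via allele counts
  diffs <- apply(x, 2, function(col) {
    cnt <- table(col)
    n_pairs - sum(choose(cnt, 2))
  })
  k <- sum(diffs) / n_pairs
  a1 <- harmonic_a1(n)
  pi <- k / L_used
  theta_per_seq <- eta / a1
  theta_w_site <- theta_per_seq / L_used
  td <- tajima_d(n = n, S = S, k = k)
  tibble(n = n, L_used = L_used, S = as.integer(S), eta = as.integer(eta),
         k = k, pi = pi, theta_per_seq = theta_per_seq,
         theta_w_site = theta_w_site,
         tajima_D = td$D, tajima_p = td$p_value, note = td$note)
}

#' Tajima's D with beta-approximation significance
#'
#' \code{D = (k - S/a1) / sqrt(e1 S + e2 S (S - 1))} with the 1989 constants
#' derived from the sample size. Negative values indicate an excess of
#' low-frequency polymorphism (the discrepancy between the pairwise and
#' segregating-site theta estimates). Two-sided significance uses the
#' scaled-beta approximation of the null density of D with mean 0 and
#' variance 1 over its theoretical range.
#'
#' @param n Sample size (>= 4 for a defined D).
#' @param S Number of segregating sites.
#' @param k Mean pairwise differences.
#' @return One-row tibble: \code{D}, \code{p_value}, \code{note}.
#' @export
tajima_d <- function(n, S, k) {
  if (is.na(S) || S == 0) {
    return(tibble(D = NA_real_, p_value = NA_real_, note = "S = 0"))
  }
  if (n < 4) {
    return(tibble(D = NA_real_, p_value = NA_real_, note = "n < 4"))
  }
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  # beta approximation over [Dmin, Dmax], matched to mean 0 / variance 1
  kmax <- if (n %% 2 == 0) n / (2 * (n - 1)) else (n + 1) / (2 * n)
  Dmin <- (2 / n - 1 / a1) / sqrt(e2)
  Dmax <- (kmax - 1 / a1) / sqrt(e2)
  rng <- Dmax - Dmin
  shape1 <- Dmin * (1 + Dmin * Dmax) / rng       # l(1+lu)/(u-l) > 0
  shape2 <- -Dmax * (1 + Dmin * Dmax) / rng
  p <- if (shape1 > 0 && shape2 > 0 && D > Dmin && D < Dmax) {
    z <- (D - Dmin) / rng
    2 * min(pbeta(z, shape1, shape2), 1 - pbeta(z, shape1, shape2))
  } else if (!is.finite(D)) NA_real_ else {
    0  # observed outside the theoretical null range
  }
  tibble(D = D, p_value = p, note = NA_character_)
}

#' Windowed diversity scan around the gene
#'
#' Computes \code{\link{diversity_stats}} on the sites falling within
#' \code{[gene_start - flank, gene_end + flank]} for each requested flank
#' (the catalogue analyses use 1-kb and 10-kb flanks).
#'
#' @param m A \code{\link{seq_matrix}} with reference positions.
#' @param gene_start,gene_end 1-based inclusive gene interval.
#' @param flanks Numeric vector of flank widths in bp.
#' @return Tibble with one row per flank: \code{flank}, \code{win_start},
#'   \code{win_end} plus the diversity columns.
#' @export
window_scan <- function(m, gene_start, gene_end, flanks = c(1000, 10000)) {
  assert_that(all(flanks >= 0), "flanks must be non-negative")
  purrr::map(flanks, function(fl) {
    lo <- gene_start - fl; hi <- gene_end + fl
    sub <- subset_sites(m, lo, hi)
    stats <- if (ncol(sub$states) == 0) {
      tibble(n = nrow(m$states), L_used = 0L, S = NA_integer_,
             eta = NA_integer_, k = NA_real_, pi = NA_real_,
             theta_per_seq = NA_real_, theta_w_site = NA_real_,
             tajima_D = NA_real_, tajima_p = NA_real_, note = "empty window")
    } else diversity_stats(sub)
    mutate(stats, flank = fl, win_start = lo, win_end = hi, .before = 1)
  }) |> bind_rows()
}

#' One-way ANOVA with Tukey compact letter display
#'
#' Fits a one-way ANOVA of \code{value ~ group}, runs all-pairs Tukey HSD at
#' \code{alpha}, and assigns letters so that two groups share a letter iff
#' they are not significantly different -- the usual letters-above-bars
#' summary for group comparisons such as plant height by haplotype.
#'
#' @param data Tibble with the response and grouping columns.
#' @param value,group Column names (strings).
#' @param alpha Significance level (default 0.05).
#' @return Object of class \code{group_anova}: list with \code{anova}
#'   (one-row tibble: F, p, df), \code{letters} (tibble: group, n, mean,
#'   letter) and the fitted \code{aov}. Groups with fewer than 2 values are
#'   excluded with a warning.
#' @export
anova_letters <- function(data, value, group, alpha = 0.05) {
  d <- tibble(y = data[[value]], g = as.character(data[[group]]))
  d <- d[complete.cases(d), ]
  sizes <- d |> count(.data$g)
  small <- sizes$g[sizes$n < 2]
  if (length(small) > 0) {
    warn(paste0("excluding group(s) with fewer than 2 values: ",
                paste(small, collapse = ", ")))
    d <- dplyr::filter(d, !.data$g %in% small)
  }
  assert_that(length(unique(d$g)) >= 2, "need at least two groups")
  d$g <- factor(d$g)
  fit <- aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
  letters <- multcomp::cld(glht_fit, level = alpha)$mcletters$Letters
  lt <- tibble(group = names(letters), letter = unname(letters)) |>
    left_join(d |> group_by(.data$g) |>
                summarise(n = dplyr::n(), mean = mean(.data$y)),
              by = c(group = "g"))
  structure(list(
    anova = tibble(F_value = an$`F value`[1], p_value = an$`Pr(>F)`[1],
                   df_between = an$Df[1], df_within = an$Df[2]),
    letters = lt |> select("group", "n", "mean", "letter"),
    fit = fit, alpha = alpha
  ), class = "group_anova")
}

#' @export
print.group_anova <- function(x, ...) {
  cat("<group_anova> F =", format(x$anova$F_value, digits = 4),
      ", p =", format(x$anova$p_value, digits = 3), "\n")
  print(x$letters)
  invisible(x)
}

#' @export
tidy.group_anova <- function(x, ...) x$letters

#' @export
glance.group_anova <- function(x, ...) x$anova

#' Venn-partition counts of shared SNP sets
#'
#' For 2-5 accession SNP sets, counts every one of the 2^k - 1 membership
#' patterns (sites private to each set, each pairwise intersection, and so
#' on); the counts sum to the size of the union.
#'
#' @param sets Named list of 2 to 5 vectors (SNP identifiers).
#' @return Tibble with one logical column per set plus \code{count}, one row
#'   per non-empty membership pattern (including zero-count patterns).
#' @examples
#' snp_sharing(list(A = c(1, 2), B = c(2, 3)))
#' @export
snp_sharing <- function(sets) {
  k <- length(sets)
  assert_that(k >= 2 && k <= 5, "snp_sharing needs between 2 and 5 sets")
  nm <- names(sets) %||% LETTERS[seq_len(k)]
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(patterns) <- nm
  counts <- apply(patterns, 1, function(p) {
    if (length(universe) == 0) return(0L)
    sum(apply(membership, 1, function(row) all(row == p)))
  })
  out <- as_tibble(patterns)
  out$count <- as.integer(counts)
  out
}
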