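# Distance-based phylogeny reconstruction: SNP-matrix extraction from VCF
# genotypes, TN93-family distances with pooled base frequencies and pairwise
# deletion, Saitou-Nei neighbor joining with a deterministic tie-break, and
# column-resampling bootstrap with support-based collapsing.

IUPAC2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

iupac_het <- function(a, b) {
  key <- paste(sort(c(a, b)), collapse = "")
  unname(IUPAC2[key]) %||% "N"
}

#' Convert genotype calls to an aligned SNP matrix
#'
#' One column per SNP site: homozygous genotypes become the allele base,
#' heterozygous genotypes the IUPAC ambiguity code, and missing genotypes
#' (or samples absent from a record) N. Indel sites are skipped.
#'
#' @param calls Multi-sample genotype-call tibble (see \code{\link{read_vcf}}).
#' @param samples Sample ids to include (default: all present).
#' @return A \code{\link{seq_matrix}} with the site positions.
#' @export
vcf_to_seq_matrix <- function(calls, samples = NULL) {
  samples <- samples %||% sort(unique(calls$sample))
  snp_sites <- calls |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::filter(nchar(.data$ref) == 1,
                  !grepl(",", .data$alt) | TRUE) |>
    dplyr::filter(purrr::map_lgl(strsplit(.data$alt, ",", fixed = TRUE),
                                 function(a) all(nchar(a) == 1))) |>
    arrange(.data$pos)
  mat <- matrix("N", nrow = length(samples), ncol = nrow(snp_sites),
                dimnames = list(samples, NULL))
  for (i in seq_len(nrow(snp_sites))) {
    st <- snp_sites[i, ]
    alleles <- c(st$ref, strsplit(st$alt, ",", fixed = TRUE)[[1]])
    rows <- calls |>
      dplyr::filter(.data$pos == st$pos, .data$ref == st$ref,
                    .data$sample %in% samples)
    for (j in seq_len(nrow(rows))) {
      r <- rows[j, ]
      g <- r$gt
      if (is.na(g)) next
      idx <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
      if (any(is.na(idx))) next
      b <- alleles[idx + 1L]
      if (any(is.na(b))) next
      mat[r$sample, i] <- if (length(unique(b)) == 1) b[1]
      else iupac_het(b[1], b[2])
    }
  }
  seq_matrix(mat, snp_sites$pos)
}

#' Tamura-Nei (TN93) distance matrix with pooled base frequencies
#'
#' Distances in substitutions per site under the TN93 model with base
#' frequencies pooled across all sequences (composite-likelihood-style
#' sharing, approximating the usual maximum-composite-likelihood distances).
#' With \code{deletion_mode = "pairwise"} (default), sites carrying a gap,
#' missing or ambiguous state in either member of a pair are skipped for
#' that pair only. Saturated pairs (a log argument reaching zero) and pairs
#' with no comparable sites are returned as NA (inestimable).
#'
#' In the equal-frequency, uniform-substitution limit the formula reduces to
#' Jukes-Cantor: d = -(3/4) log(1 - (4/3) p).
#'
#' @param m A \code{\link{seq_matrix}}.
#' @param deletion_mode \code{"pairwise"} (default) or \code{"complete"}.
#' @return Symmetric numeric matrix with zero diagonal and sequence labels.
#' @export
tn93_distance_matrix <- function(m, deletion_mode = c("pairwise", "complete")) {
  deletion_mode <- match.arg(deletion_mode)
  x <- m$states
  n <- nrow(x)
  assert_that(n >= 2, "need at least two sequences")
  if (deletion_mode == "complete") {
    keep <- apply(x, 2, function(col) all(col %in% VALID_BASES))
    x <- x[, keep, drop = FALSE]
  }
  # pooled base frequencies over all unambiguous states
  all_states <- as.vector(x)
  cnt <- table(factor(all_states[all_states %in% VALID_BASES],
                      levels = VALID_BASES))
  g <- as.numeric(cnt) / sum(cnt)
  names(g) <- VALID_BASES
  gR <- g[["A"]] + g[["G"]]; gY <- g[["C"]] + g[["T"]]
  k1 <- if (gR > 0) 2 * g[["A"]] * g[["G"]] / gR else 0
  k2 <- if (gY > 0) 2 * g[["C"]] * g[["T"]] / gY else 0
  k3 <- if (gR > 0 && gY > 0) {
    2 * (gR * gY - g[["A"]] * g[["G"]] * gY / gR -
           g[["C"]] * g[["T"]] * gR / gY)
  } else 0
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- x[i, ] %in% VALID_BASES & x[j, ] %in% VALID_BASES
      L <- sum(ok)
      if (L == 0) { d[i, j] <- d[j, i] <- NA_real_; next }
      a <- x[i, ok]; b <- x[j, ok]
      diffp <- a != b
      ts1 <- sum(diffp & ((a == "A" & b == "G") | (a == "G" & b == "A"))) / L
      ts2 <- sum(diffp & ((a == "C" & b == "T") | (a == "T" & b == "C"))) / L
      q <- sum(diffp) / L - ts1 - ts2
      # each term only contributes where its pooled-frequency coefficient is
      # positive (a zero coefficient with observed changes of that kind means
      # the model cannot fit the pair: inestimable)
      dist_ij <- 0
      bad <- FALSE
      if (k1 > 0) {
        w1 <- 1 - ts1 / k1 - q / (2 * gR)
        if (w1 <= 0) bad <- TRUE else dist_ij <- dist_ij - k1 * log(w1)
      } else if (ts1 > 0) bad <- TRUE
      if (k2 > 0) {
        w2 <- 1 - ts2 / k2 - q / (2 * gY)
        if (w2 <= 0) bad <- TRUE else dist_ij <- dist_ij - k2 * log(w2)
      } else if (ts2 > 0) bad <- TRUE
      if (k3 > 0) {
        w3 <- 1 - q / (2 * gR * gY)
        if (w3 <= 0) bad <- TRUE else dist_ij <- dist_ij - k3 * log(w3)
      } else if (q > 0) bad <- TRUE
      d[i, j] <- d[j, i] <- if (bad) NA_real_ else dist_ij
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration on a distance matrix: at each step the
#' pair minimising Q(i, j) = (N - 2) d(i, j) - r(i) - r(j) is joined, with
#' ties broken deterministically in favour of the lexicographically smallest
#' label pair (internal nodes inherit the smaller label of their children
#' for this purpose). Negative branch lengths are clamped to zero with the
#' deficit moved to the sister branch, preserving the pair's summed length.
#'
#' @param d Symmetric distance matrix with labels (no NA entries).
#' @return An unrooted \code{ape::phylo} tree with branch lengths.
#' @export
nj_tree <- function(d) {
  labels <- rownames(d)
  assert_that(!is.null(labels), "distance matrix must have labels")
  assert_that(nrow(d) >= 3, "need at least three taxa")
  if (any(is.na(d))) {
    bad <- which(is.na(d), arr.ind = TRUE)[1, ]
    abort(paste0("inestimable distance between ", labels[bad[1]], " and ",
                 labels[bad[2]]))
  }
  frags <- labels          # newick fragments
  reps <- labels           # tie-break representative labels
  dm <- d

  clamp <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    c(max(bi, 0), max(bj, 0))
  }
  fmt <- function(x) sprintf("%.10g", x)

  while (nrow(dm) > 3) {
    N <- nrow(dm)
    r <- rowSums(dm)
    Q <- (N - 2) * dm - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(t) {
      pr <- sort(c(reps[cand[t, 1]], reps[cand[t, 2]]))
      paste(pr, collapse = "\r")
    }, "")
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- dm[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (N - 2))
    bj <- dij - bi
    bb <- clamp(bi, bj)
    new_frag <- paste0("(", frags[i], ":", fmt(bb[1]), ",",
                       frags[j], ":", fmt(bb[2]), ")")
    new_rep <- min(reps[i], reps[j])
    dk <- (dm[i, ] + dm[j, ] - dij) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    dm2 <- rbind(cbind(dm[keep, keep, drop = FALSE], dk[keep]),
                 c(dk[keep], 0))
    frags <- c(frags[keep], new_frag)
    reps <- c(reps[keep], new_rep)
    nn <- length(frags)
    rownames(dm2) <- colnames(dm2) <- paste0("x", seq_len(nn))
    dm <- dm2
  }
  # final three-point resolution
  b1 <- (dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2
  b2 <- (dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2
  b3 <- (dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2
  b1 <- max(b1, 0); b2 <- max(b2, 0); b3 <- max(b3, 0)
  nwk <- paste0("(", frags[1], ":", fmt(b1), ",", frags[2], ":", fmt(b2),
                ",", frags[3], ":", fmt(b3), ");")
  ape::read.tree(text = nwk)
}

#' Bootstrap support with collapsing of weak edges
#'
#' Resamples alignment columns with replacement, rebuilds the
#' distance-plus-NJ tree per replicate, and scores each internal bipartition
#' of the point-estimate tree by the percentage of replicates containing it.
#' Internal edges with support below \code{collapse_below} are contracted
#' into polytomies. Replicates yielding an inestimable pair are dropped and
#' counted.
#'
#' @param m A \code{\link{seq_matrix}}.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed RNG seed for reproducible resampling.
#' @param collapse_below Support percentage below which internal edges are
#'   collapsed (default 60; 0 keeps the binary tree).
#' @param deletion_mode Passed to \code{\link{tn93_distance_matrix}}.
#' @return List of class \code{bootstrap_phylo}: \code{tree} (collapsed,
#'   node labels = support), \code{point_tree} (uncollapsed, labelled),
#'   \code{support} (numeric per internal node), \code{n_valid},
#'   \code{n_dropped}.
#' @export
bootstrap_support <- function(m, replicates = 1000L, seed = NULL,
                              collapse_below = 60,
                              deletion_mode = "pairwise") {
  point <- nj_tree(tn93_distance_matrix(m, deletion_mode))
  n_col <- ncol(m$states)
  assert_that(n_col >= 1, "alignment has no columns")
  with_seed(seed, {
    trees <- list()
    dropped <- 0L
    for (b in seq_len(replicates)) {
      idx <- sample.int(n_col, n_col, replace = TRUE)
      mb <- seq_matrix(m$states[, idx, drop = FALSE], seq_len(n_col))
      tb <- tryCatch(nj_tree(tn93_distance_matrix(mb, deletion_mode)),
                     error = function(e) NULL)
      if (is.null(tb)) dropped <- dropped + 1L else trees <- c(trees, list(tb))
    }
    n_valid <- length(trees)
    assert_that(n_valid > 0, "every bootstrap replicate failed")
    counts <- ape::prop.clades(point, trees, rooted = FALSE)
    counts[is.na(counts)] <- 0
    support <- 100 * counts / n_valid
    labelled <- point
    labelled$node.label <- round(support, 1)
    collapsed <- if (collapse_below > 0) {
      phangorn::pruneTree(labelled, collapse_below)
    } else labelled
    structure(list(tree = collapsed, point_tree = labelled,
                   support = support, n_valid = n_valid,
                   n_dropped = dropped, collapse_below = collapse_below),
              class = "bootstrap_phylo")
  })
}

#' @export
print.bootstrap_phylo <- function(x, ...) {
  cat("<bootstrap_phylo> ", x$n_valid, " replicates (", x$n_dropped,
      " dropped); edges below ", x$collapse_below, "% collapsed\n", sep = "")
  print(x$tree)
  invisible(x)
}

#' @export
glance.bootstrap_phylo <- function(x, ...) {
  tibble(n_valid = x$n_valid, n_dropped = x$n_dropped,
         min_support = min(x$support), max_support = max(x$support),
         collapse_below = x$collapse_below)
}

#' Write a tree with support labels as newick
#'
#' @param tree An \code{ape::phylo} or \code{bootstrap_phylo}.
#' @param path Output path.
#' @export
write_tree_newick <- function(tree, path) {
  if (inherits(tree, "bootstrap_phylo")) tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}
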