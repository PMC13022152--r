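# SNP-matrix extraction, TN93 distances, NJ, bootstrap

test_that("genotypes convert to bases, IUPAC codes and N", {
  calls <- dplyr::bind_rows(
    tibble::tibble(chrom = "locus", pos = 10L, ref = "A", alt = "G",
                   sample = "s1", gt = "0/0", depth = 30, alt_fraction = 0,
                   allele = NA_character_),
    tibble::tibble(chrom = "locus", pos = 10L, ref = "A", alt = "G",
                   sample = "s2", gt = "1/1", depth = 30, alt_fraction = 1,
                   allele = "G"),
    tibble::tibble(chrom = "locus", pos = 10L, ref = "A", alt = "G",
                   sample = "s3", gt = "0/1", depth = 30, alt_fraction = 0.5,
                   allele = "G"))
  m <- vcf_to_seq_matrix(calls)
  expect_equal(unname(m$states["s1", 1]), "A")
  expect_equal(unname(m$states["s2", 1]), "G")
  expect_equal(unname(m$states["s3", 1]), "R")
  # a sample absent from the record is N
  m2 <- vcf_to_seq_matrix(calls, samples = c("s1", "s2", "s4"))
  expect_equal(unname(m2$states["s4", 1]), "N")
})

test_that("SNP matrix matches direct sequence extraction on a cohort", {
  sim <- small_cohort()
  snp_calls <- dplyr::filter(sim$calls, nchar(ref) == 1, nchar(alt) == 1)
  m <- vcf_to_seq_matrix(snp_calls)
  hom <- dplyr::filter(sim$truth, label != "heterozygous")
  for (acc in hom$accession[seq(1, nrow(hom), by = 5)]) {
    seq_acc <- sim$sequences[[acc]]
    dels <- dplyr::filter(sim$deletions, accession == acc)
    for (ci in seq_along(m$positions)) {
      ref_pos <- m$positions[ci]
      # positions inside a deletion are not comparable; skip
      if (nrow(dels) > 0 &&
          any(ref_pos >= dels$start & ref_pos <= dels$end)) next
      shift <- if (nrow(dels) > 0)
        sum(dels$end[dels$end < ref_pos] - dels$start[dels$end < ref_pos] + 1)
      else 0
      expect_equal(unname(m$states[acc, ci]),
                   substr(seq_acc, ref_pos - shift, ref_pos - shift),
                   info = paste(acc, ref_pos))
    }
  }
})

test_that("TN93 reduces to the JC69 closed form in the uniform limit", {
  # equal base frequencies, mismatches spread over all 12 ordered pairs
  n_sites <- 1200
  s1 <- rep(c("A", "C", "G", "T"), n_sites / 4)
  s2 <- s1
  mism <- data.frame(from = c("A","A","A","C","C","C","G","G","G","T","T","T"),
                     to   = c("C","G","T","A","G","T","A","C","T","A","C","G"))
  # 120 mismatch sites (p = 0.1), 10 per ordered pair
  slot <- 1
  for (r in seq_len(nrow(mism))) {
    hits <- 0
    while (hits < 10) {
      if (s1[slot] == mism$from[r]) {
        s2[slot] <- mism$to[r]; hits <- hits + 1
      }
      slot <- slot + 1
    }
  }
  p <- mean(s1 != s2)
  expect_equal(p, 0.1)
  d <- tn93_distance_matrix(seq_matrix(rbind(a = s1, b = s2)))
  jc <- -3 / 4 * log(1 - 4 / 3 * p)
  expect_lt(abs(d["a", "b"] - jc), 1e-3)
})

test_that("distances are symmetric, non-negative, zero iff identical", {
  set.seed(10)
  for (rep in 1:10) {
    mat <- matrix(sample(c("A", "C", "G", "T", "N"), 5 * 60, replace = TRUE,
                         prob = c(rep(0.235, 4), 0.06)), nrow = 5)
    rownames(mat) <- paste0("s", 1:5)
    d <- tn93_distance_matrix(seq_matrix(mat))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d[!is.na(d)] >= 0))
  }
  row <- rep(c("A", "C", "G", "T"), length.out = 50)
  same <- rbind(x = row, y = row)
  d <- tn93_distance_matrix(seq_matrix(same))
  expect_equal(unname(d["x", "y"]), 0)
})

test_that("pairwise deletion skips ambiguous sites per pair", {
  mat <- rbind(a = c("A", "A", "A", "A"),
               b = c("A", "N", "A", "A"),
               c = c("T", "T", "N", "T"))
  rownames(mat) <- c("a", "b", "c")
  d <- tn93_distance_matrix(seq_matrix(mat))
  expect_equal(d["a", "b"], 0)      # the N column is skipped for this pair
  expect_true(is.finite(d["a", "c"]) || is.na(d["a", "c"]))
  # a pair with no comparable sites is inestimable
  mat2 <- rbind(a = c("A", "N"), b = c("N", "A"))
  d2 <- tn93_distance_matrix(seq_matrix(mat2))
  expect_true(is.na(d2["a", "b"]))
})

test_that("four-taxon additive matrix gives the known tree exactly", {
  labs <- c("A", "B", "C", "D")
  d <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4, dimnames = list(labs, labs))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  # topology AB | CD with internal branch 2, leaf branches 1
  truth <- ape::read.tree(text = "((A:1,B:1):2,C:1,D:1);")
  expect_equal(as.numeric(ape::dist.topo(tr, truth)), 0)
  expect_equal(sort(tr$edge.length), c(1, 1, 1, 1, 2))
  # recomputed path distances reproduce the input (additivity)
  expect_equal(cophenetic(tr)[labs, labs], d)
})

test_that("three taxa resolve with the closed-form branch lengths", {
  labs <- c("x", "y", "z")
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3, dimnames = list(labs, labs))
  tr <- nj_tree(d)
  expect_equal(cophenetic(tr)[labs, labs], d)
  # (d_xy + d_xz - d_yz) / 2 = 1 for x
  bx <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "x")]
  expect_equal(bx, 1)
})

test_that("NJ recovers random additive trees and matches an independent NJ", {
  set.seed(20)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    case <- random_additive_case(n)
    tr <- nj_tree(case$d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), case$tree)), 0)
    # cross-check against the reference implementation's topology
    tr_ape <- ape::nj(as.dist(case$d))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                           ape::unroot(tr_ape))), 0)
  }
})

test_that("NJ rejects inestimable distances naming the pair", {
  d <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_error(nj_tree(d), "a and c|c and a")
})

test_that("bootstrap supports a clean split at 100 and is reproducible", {
  const <- matrix(rep(rep(c("A", "C", "G", "T"), 10), each = 4), nrow = 4)
  split <- matrix(rep(c("A", "A", "G", "G"), 10), nrow = 4)
  mat <- cbind(const, split)
  rownames(mat) <- c("a", "b", "c", "d")
  m <- seq_matrix(mat)
  bs <- bootstrap_support(m, replicates = 100, seed = 5)
  expect_true(all(bs$support >= 0 & bs$support <= 100))
  expect_true(any(bs$support == 100))
  # internal edges never exceed n - 3 after collapsing trivial ones
  expect_lte(ape::Nnode(bs$point_tree) - 1, 4 - 3 + 1)
  bs2 <- bootstrap_support(m, replicates = 100, seed = 5)
  expect_identical(bs$support, bs2$support)
  # collapse_below = 0 keeps the binary tree
  bs0 <- bootstrap_support(m, replicates = 50, seed = 5, collapse_below = 0)
  expect_true(ape::is.binary(ape::unroot(bs0$tree)))
})

test_that("edges below the support threshold collapse into polytomies", {
  set.seed(30)
  base <- sample(c("A", "C", "G", "T"), 40, replace = TRUE)
  mat <- matrix(rep(base, 6), nrow = 6, byrow = TRUE)
  rownames(mat) <- paste0("t", 1:6)
  # one strong split (t1,t2 | rest) plus a couple of private mutations
  mat[1:2, 1:10] <- "G"; mat[3:6, 1:10] <- "A"
  mat[3, 11] <- "T"; mat[4, 12] <- "T"
  m <- seq_matrix(mat)
  bs_keep <- bootstrap_support(m, replicates = 100, seed = 2,
                               collapse_below = 0)
  # a threshold above every support level collapses all internal structure
  bs_all <- bootstrap_support(m, replicates = 100, seed = 2,
                              collapse_below = 101)
  expect_lt(ape::Nnode(bs_all$tree), ape::Nnode(bs_keep$tree))
  # at the standard 60% threshold the strong split survives
  bs60 <- bootstrap_support(m, replicates = 100, seed = 2,
                            collapse_below = 60)
  parts <- ape::prop.part(bs60$tree)
  tipsets <- lapply(parts, function(p) sort(bs60$tree$tip.label[p]))
  expect_true(any(vapply(tipsets, identical, TRUE, y = c("t1", "t2"))) ||
                any(vapply(tipsets, identical, TRUE,
                           y = c("t3", "t4", "t5", "t6"))))
})

test_that("PHYLIP and FASTA round trips preserve the matrix", {
  sim <- small_cohort()
  snp_calls <- dplyr::filter(sim$calls, nchar(ref) == 1, nchar(alt) == 1)
  m <- vcf_to_seq_matrix(snp_calls)
  fp <- withr::local_tempfile(fileext = ".phy")
  write_phylip(m, fp)
  m2 <- read_phylip(fp)
  expect_equal(m2$states, m$states)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_matrix(m, fa)
  m3 <- read_fasta_matrix(fa)
  expect_equal(m3$states, m$states)
})
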