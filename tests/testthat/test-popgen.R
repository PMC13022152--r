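# diversity statistics, Tajima's D, windows, ANOVA letters, SNP sharing

test_that("hand-computed diversity values are reproduced", {
  # identical sequences: everything zero
  m <- seq_matrix(matrix("A", 5, 10))
  s <- diversity_stats(m)
  expect_equal(s$S, 0L); expect_equal(s$eta, 0L)
  expect_equal(s$k, 0); expect_equal(s$pi, 0)
  # n = 2, L = 4, one difference: S=1, eta=1, k=1, pi=0.25, thetaw=0.25
  m2 <- seq_matrix(rbind(c("A", "A", "A", "A"), c("A", "A", "A", "T")))
  s2 <- diversity_stats(m2)
  expect_equal(s2$S, 1L); expect_equal(s2$eta, 1L)
  expect_equal(s2$k, 1); expect_equal(s2$pi, 0.25)
  expect_equal(s2$theta_w_site, 0.25)  # a1(2) = 1
  expect_equal(s2$L_used, 4L)
})

test_that("diversity matches the brute-force oracle on random matrices", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(2:12, 1); L <- sample(5:100, 1)
    states <- matrix(sample(c("A", "C", "G", "T", "-", "N"), n * L,
                            replace = TRUE,
                            prob = c(rep(0.23, 4), 0.04, 0.04)),
                     nrow = n)
    s <- diversity_stats(seq_matrix(states))
    o <- oracle_diversity(states)
    if (o$L_used == 0) {
      expect_equal(s$L_used, 0L)
      next
    }
    expect_equal(s$S, o$S)
    expect_equal(s$eta, o$eta)
    expect_equal(s$k, o$k)
    expect_equal(s$pi, o$pi)
    expect_equal(s$theta_per_seq, o$theta_per_seq)
    expect_equal(s$theta_w_site, o$theta_w_site)
    # structural invariants
    expect_gte(s$eta, s$S)
    expect_equal(s$k, s$pi * s$L_used)
  }
})

test_that("Tajima's D is undefined for S = 0 or tiny samples", {
  expect_true(is.na(tajima_d(10, 0, 0)$D))
  expect_equal(tajima_d(10, 0, 0)$note, "S = 0")
  expect_true(is.na(tajima_d(3, 5, 2)$D))
  expect_equal(tajima_d(3, 5, 2)$note, "n < 4")
})

test_that("singleton-heavy matrices give negative D, balanced give positive", {
  n <- 20; L <- 40
  mat <- matrix("A", n, L)
  for (j in seq_len(L)) mat[(j - 1) %% n + 1, j] <- "T"
  d_single <- diversity_stats(seq_matrix(mat))$tajima_D
  expect_lt(d_single, 0)
  mat2 <- matrix("A", n, L)
  for (j in seq_len(L)) mat2[seq_len(n / 2), j] <- "T"
  d_balanced <- diversity_stats(seq_matrix(mat2))$tajima_D
  expect_gt(d_balanced, 0)
})

test_that("neutral simulations recover theta and have D near zero", {
  set.seed(101)
  reps <- 400
  res <- t(replicate(reps, {
    m <- simulate_neutral_sample(20, 5)
    if (ncol(m$states) == 0) return(c(0, NA))
    s <- diversity_stats(m)
    c(s$theta_per_seq, s$tajima_D)
  }))
  th <- res[, 1]
  expect_lt(abs(mean(th) - 5), 3 * sd(th) / sqrt(reps))
  D <- res[, 2][!is.na(res[, 2])]
  expect_lt(abs(mean(D)), 3 * sd(D) / sqrt(length(D)))
})

test_that("window scan restricts to gene +/- flank and nests monotonically", {
  set.seed(55)
  m <- simulate_neutral_sample(10, 20, locus_length = 25000)
  win <- window_scan(m, gene_start = 10001, gene_end = 12743,
                     flanks = c(0, 1000, 10000))
  expect_equal(win$win_start, c(10001, 9001, 1))
  expect_equal(win$win_end, c(12743, 13743, 22743))
  S <- win$S
  expect_true(all(diff(S) >= 0))  # nested windows: S can only grow
  # flank 0 equals direct subsetting to the gene span
  direct <- diversity_stats(subset_sites(m, 10001, 12743))
  expect_equal(win$S[1], direct$S)
  # the 10-kb window corresponds to the published chr1 anchor positions
  off <- sd1_coord_offset()
  expect_equal(win$win_start[3] + off, 38372466)
  expect_equal(win$win_end[3] + off, 38395208)
})

test_that("ANOVA letters separate distinct groups and join identical ones", {
  set.seed(8)
  d <- tibble::tibble(
    g = rep(c("wild", "dwarf", "dwarf2"), each = 30),
    y = c(rnorm(30, 150, 5), rnorm(30, 60, 5), rnorm(30, 60, 5)))
  res <- anova_letters(d, "y", "g")
  lt <- tidy(res)
  expect_lt(glance(res)$p_value, 1e-10)
  expect_false(lt$letter[lt$group == "wild"] %in%
                 lt$letter[lt$group != "wild"])
  expect_equal(lt$letter[lt$group == "dwarf"],
               lt$letter[lt$group == "dwarf2"])
})

test_that("textbook three-group ANOVA arithmetic is reproduced", {
  d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 3),
                      y = c(1, 2, 3, 2, 3, 4, 6, 7, 8))
  res <- anova_letters(d, "y", "g")
  # hand computation: group means 2,3,7; grand 4; SSB = 3*(4+1+9) = 42
  # SSW = 2+2+2 = 6; F = (42/2)/(6/6) = 21
  expect_equal(glance(res)$F_value, 21)
  expect_equal(glance(res)$df_between, 2)
  expect_equal(glance(res)$df_within, 6)
  # undersized groups are dropped with a warning
  d2 <- dplyr::bind_rows(d, tibble::tibble(g = "tiny", y = 5))
  expect_warning(anova_letters(d2, "y", "g"), "fewer than 2")
})

test_that("SNP-sharing counts match brute-force membership tallies", {
  out <- snp_sharing(list(A = c(1, 2), B = c(2, 3)))
  expect_equal(out$count[out$A & !out$B], 1)
  expect_equal(out$count[!out$A & out$B], 1)
  expect_equal(out$count[out$A & out$B], 1)
  # identical sets: only the all-sets region is occupied
  same <- snp_sharing(list(A = 1:5, B = 1:5, C = 1:5))
  expect_equal(same$count[same$A & same$B & same$C], 5)
  expect_equal(sum(same$count), 5)
  # 5 random sets against an explicit oracle
  set.seed(3)
  sets <- lapply(1:5, function(i) sample(1:50, sample(5:30, 1)))
  names(sets) <- LETTERS[1:5]
  out5 <- snp_sharing(sets)
  expect_equal(nrow(out5), 2^5 - 1)
  expect_equal(sum(out5$count), length(unique(unlist(sets))))
  for (r in sample(nrow(out5), 8)) {
    pat <- unlist(out5[r, LETTERS[1:5]])
    oracle <- sum(vapply(unique(unlist(sets)), function(el) {
      all(vapply(LETTERS[1:5],
                 function(s) (el %in% sets[[s]]) == pat[[s]], TRUE))
    }, TRUE))
    expect_equal(out5$count[r], oracle)
  }
  expect_error(snp_sharing(list(A = 1)), "between 2 and 5")
})
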