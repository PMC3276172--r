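test_that("pairwise F_st behaves at the extremes and keeps its invariants", {
  ## two samples from one panmictic population -> ~0 (may be negative)
  set.seed(19)
  fsts <- sapply(1:8, function(i) {
    a <- simulate_coalescent(coalescent_params(24, 8, 400))
    pm <- population_map(setNames(
      as.list(rep(c("P1", "P2"), length.out = 24)), a$strains))
    pairwise_fst(a, pm)["P1", "P2"]
  })
  expect_lt(abs(mean(fsts)), 0.05)

  m <- matrix(sample(c("A", "C", "G", "T"), 8 * 30, replace = TRUE), 8, 30)
  aln <- locus_alignment(m, strains = c(paste0("p1_", 1:4),
                                        paste0("p2_", 1:4)))
  pm <- population_map(setNames(as.list(rep(c("P1", "P2"), each = 4)),
                                aln$strains))
  f <- pairwise_fst(aln, pm)
  expect_equal(unname(diag(unclass(f))), c(0, 0))
  expect_equal(unclass(f), t(unclass(f)))

  ## populations fixed for sequences differing at every site -> 1
  s1 <- matrix("A", 3, 20); s2 <- matrix("C", 3, 20)
  aln2 <- locus_alignment(rbind(s1, s2),
                          strains = c(paste0("a", 1:3), paste0("b", 1:3)))
  pm2 <- population_map(setNames(as.list(rep(c("A", "B"), each = 3)),
                                 aln2$strains))
  expect_equal(unname(pairwise_fst(aln2, pm2)["A", "B"]), 1)

  ## permuting sequence order changes nothing
  perm <- sample(aln2$strains)
  aln2p <- locus_alignment(aln2$mat[match(perm, aln2$strains), ],
                           strains = perm)
  expect_equal(unclass(pairwise_fst(aln2p, pm2)), unclass(pairwise_fst(aln2, pm2)))

  ## undersized population excluded with warning
  pm3 <- population_map(c(setNames(as.list(rep("A", 3)), paste0("a", 1:3)),
                          setNames(as.list(rep("B", 2)), paste0("b", 1:2)),
                          list(b3 = "C")))
  expect_warning(f3 <- pairwise_fst(aln2, pm3), "excluding")
  expect_equal(rownames(f3), c("A", "B"))

  ## Weir-Cockerham option agrees qualitatively
  expect_equal(unname(pairwise_fst(aln2, pm2,
                                   method = "weir-cockerham")["A", "B"]), 1)
})

test_that("multiply-assigned haplotypes enter each assigned population", {
  m <- matrix(sample(c("A", "C"), 6 * 10, replace = TRUE), 6, 10)
  aln <- locus_alignment(m, strains = paste0("h", 1:6))
  asg <- list(h1 = "A", h2 = "A", h3 = "B", h4 = "B", h5 = c("A", "B"),
              h6 = "B")
  pm <- population_map(asg)
  expect_equal(unname(pm$sizes), c(3L, 4L))   # sums past the strain count
  f <- pairwise_fst(aln, pm)
  expect_true(is.finite(f["A", "B"]))
})

test_that("informative SNPs are biallelic with minor count >= 2", {
  m <- rbind(
    s1 = c("A", "A", "A", "C", "A", "T"),
    s2 = c("A", "C", "A", "C", "G", "T"),
    s3 = c("A", "C", "A", "A", "A", "C"),
    s4 = c("A", "A", "A", "A", "A", "C"),
    s5 = c("A", "A", "T", "A", "A", "C"))
  ## col1 monomorphic; col2 informative (C x2); col3 singleton T;
  ## col4 informative (C x2); col5 singleton G; col6 informative (T x2)
  snps <- informative_snps(locus_alignment(m))
  expect_equal(snps$column, c(2L, 4L, 6L))

  ## three-allele columns are excluded
  m3 <- rbind(a = c("A", "A"), b = c("C", "A"), c = c("G", "A"),
              d = c("C", "A"), e = c("G", "A"))
  expect_equal(nrow(informative_snps(locus_alignment(m3))), 0L)

  ## positions follow genome coordinates via the locus offset
  ld <- locus_def("x", "II", 1000, 1006)
  snps2 <- informative_snps(locus_alignment(m, locus = ld))
  expect_equal(snps2$position, c(1001, 1003, 1005))
})

test_that("LD statistics satisfy the classical identities", {
  set.seed(30)
  for (rep_i in 1:20) {
    n <- 40
    a <- rbinom(n, 1, 0.5); b <- ifelse(rbinom(n, 1, 0.3) == 1, a, rbinom(n, 1, 0.5))
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    ld <- ld_statistics(rbind(a, b))
    ## chi2 = n * r^2 equals the direct uncorrected Pearson chi-square
    tab <- table(factor(a, 0:1), factor(b, 0:1))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    chi_direct <- suppressWarnings(
      chisq.test(tab, correct = FALSE)$statistic)
    expect_equal(unname(ld$chi2["a", "b"]), unname(chi_direct),
                 tolerance = 1e-10)
    expect_equal(ld$chi2["a", "b"], ld$n["a", "b"] * ld$r["a", "b"]^2)
    expect_lte(abs(ld$Dprime["a", "b"]), 1 + 1e-12)
    expect_lte(abs(ld$r["a", "b"]), 1 + 1e-12)
    ## |D'| = 1 iff at most three gametic types
    types <- length(unique(paste0(a, b)))
    expect_equal(abs(ld$Dprime["a", "b"]) > 1 - 1e-9, types <= 3)
    if (abs(ld$Dprime["a", "b"]) > 1 - 1e-9)
      expect_false(ld$four_gamete["a", "b"])
  }
})

test_that("independent and perfectly associated pairs give textbook values", {
  a <- rep(c(0, 1), each = 20)
  ld_perfect <- ld_statistics(rbind(m1 = a, m2 = a))
  expect_equal(unname(ld_perfect$chi2[1, 2]), 40)
  expect_equal(unname(ld_perfect$r[1, 2]), 1)
  expect_equal(ld_perfect$stars[1, 2], "***")

  b <- rep(c(0, 1), times = 20)   # orthogonal: D = 0
  ld_indep <- ld_statistics(rbind(m1 = a, m2 = b))
  expect_equal(unname(ld_indep$D[1, 2]), 0)
  expect_equal(unname(ld_indep$Dprime[1, 2]), 0)
  expect_equal(unname(ld_indep$chi2[1, 2]), 0)

  ## missing genotypes are excluded pairwise
  a2 <- a; a2[1:4] <- NA
  ld_na <- ld_statistics(rbind(m1 = a2, m2 = a))
  expect_equal(unname(ld_na$n[1, 2]), 36)
})

test_that("four-gamete test and Rm follow the interval rule", {
  three <- rbind(m1 = c(0, 0, 1, 1, 1), m2 = c(0, 1, 1, 1, 1))
  fg3 <- four_gamete_test(three)
  expect_false(fg3$four_gamete[1, 2])
  expect_equal(fg3$rm, 0L)

  four <- rbind(m1 = c(0, 0, 1, 1), m2 = c(0, 1, 0, 1))
  fg4 <- four_gamete_test(four)
  expect_true(fg4$four_gamete[1, 2])
  expect_equal(fg4$rm, 1L)

  ## perfect LD across a whole region: no pair informative, Rm = 0
  h <- rep(c(0, 1), each = 10)
  region <- rbind(m1 = h, m2 = h, m3 = h, m4 = h)
  expect_equal(four_gamete_test(region)$rm, 0L)

  ## two well-separated incompatibilities need two recombinations
  g <- rbind(m1 = c(0, 0, 1, 1, 0, 0, 1, 1),
             m2 = c(0, 1, 0, 1, 0, 1, 0, 1),
             m3 = c(0, 0, 0, 0, 1, 1, 1, 1),
             m4 = c(0, 1, 1, 0, 0, 1, 1, 0))
  expect_gte(four_gamete_test(g)$rm, 2L)
})
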