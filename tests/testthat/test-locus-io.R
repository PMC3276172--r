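test_that("locus definitions use end-exclusive spans that sum correctly", {
  expect_equal(total_locus_span(pombe_loci()), 5777L)
  cen2 <- locus_def("cen2_core", "II", 1621085, 1621800, "centromere-core")
  expect_equal(locus_span(cen2), 715L)
  expect_equal(total_locus_span(list()), 0L)
  expect_error(locus_def("bad", "I", 10, 10), "end")
})

test_that("FASTA reading preserves order, uppercases, and rejects bad input", {
  p <- write_tmp_fasta(c("acgtacgtaa", "ACGTACGTAC", "ACGTTCGTAA"),
                       c("z_strain", "a_strain", "m_strain"))
  aln <- read_locus_fasta(p)
  expect_equal(dim(aln), c(3L, 10L))
  expect_equal(aln$strains, c("z_strain", "a_strain", "m_strain"))
  expect_true(all(aln$mat %in% c("A", "C", "G", "T")))

  ragged <- write_tmp_fasta(c("ACGT", "ACGTA"))
  expect_error(read_locus_fasta(ragged), "ragged|length")

  empty <- tempfile(fileext = ".fasta"); file.create(empty)
  expect_error(read_locus_fasta(empty))

  dup <- write_tmp_fasta(c("ACGT", "ACGA"), c("s1", "s1"))
  expect_error(read_locus_fasta(dup), "duplicate")

  gap <- read_locus_fasta(write_tmp_fasta(c("AC-T", "ACGT")))
  expect_true("-" %in% gap$mat)  # gaps retained until filtering
})

test_that("site filtering drops gap columns, masked ranges and N columns", {
  m <- rbind(s1 = strsplit("ACGTACGTAC", "")[[1]],
             s2 = strsplit("AC-TACGTAC", "")[[1]],
             s3 = strsplit("ACGTAC-TAC", "")[[1]])
  aln <- locus_alignment(m)
  f1 <- apply_site_filter(aln, site_filter())
  expect_equal(n_sites(f1), 8L)       # 2 gapped columns of 10 dropped

  f2 <- apply_site_filter(aln, site_filter(drop_indel_columns = FALSE,
                                           masked_ranges = list(c(1, 4))))
  expect_equal(n_sites(f2), 6L)

  clean <- random_alignment(4, 12)
  expect_equal(apply_site_filter(clean, site_filter())$mat, clean$mat)

  expect_warning(
    apply_site_filter(clean, site_filter(masked_ranges = list(c(1, 12)))),
    "no columns")
  expect_error(
    apply_site_filter(clean, site_filter(masked_ranges = list(c(5, 20)))),
    "outside")

  nmat <- rbind(a = c("A", "N", "G"), b = c("A", "C", "G"))
  expect_equal(n_sites(apply_site_filter(locus_alignment(nmat),
                                         site_filter())), 2L)
})

test_that("haplotype collapse groups by exact concatenated identity", {
  m1 <- rbind(a = c("A", "C"), b = c("A", "C"), c = c("A", "G"))
  m2 <- rbind(a = c("T", "T"), b = c("T", "T"), c = c("T", "T"))
  ht <- collapse_haplotypes(list(locus_alignment(m1), locus_alignment(m2)))
  expect_equal(ht$n_groups, 2L)
  expect_equal(unname(ht$strain_to_group[c("a", "b", "c")]), c(1L, 1L, 2L))

  allsame <- locus_alignment(rbind(a = c("A", "A"), b = c("A", "A")))
  expect_equal(collapse_haplotypes(list(allsame))$n_groups, 1L)

  alldiff <- random_alignment(6, 30)
  expect_equal(collapse_haplotypes(list(alldiff))$n_groups, 6L)

  ## mismatched strain sets across loci are an input error
  m3 <- rbind(a = c("A", "C"), z = c("A", "C"))
  expect_error(collapse_haplotypes(list(locus_alignment(m1),
                                        locus_alignment(m3))),
               "strain sets differ")
})

test_that("collapse is invariant to strain order and refines per-locus groups", {
  set.seed(11)
  fx <- sim_strain_collection(seq_fraction = 0.05)
  ht <- collapse_haplotypes(fx$alignments)

  perm <- sample(fx$metadata$strain)
  alns_p <- lapply(fx$alignments, function(a)
    locus_alignment(a$mat[match(perm, a$strains), , drop = FALSE],
                    strains = perm, locus = a$locus))
  ht_p <- collapse_haplotypes(alns_p)
  expect_equal(ht_p$n_groups, ht$n_groups)
  ## same partition up to relabelling
  for (g in ht$groups) {
    ids <- unique(ht_p$strain_to_group[g])
    expect_length(ids, 1L)
    expect_equal(sum(ht_p$strain_to_group == ids), length(g))
  }

  ## compound groups are intersections of per-locus groups: within one
  ## compound group every per-locus id is constant
  for (loc in names(ht$per_locus)) {
    for (g in ht$groups)
      expect_length(unique(ht$per_locus[[loc]][g]), 1L)
  }
})

test_that("filtering commutes with concatenation column-wise", {
  set.seed(5)
  mk <- function() {
    m <- matrix(sample(c("A", "C", "G", "-"), 4 * 15, replace = TRUE,
                       prob = c(.4, .3, .2, .1)), nrow = 4)
    rownames(m) <- paste0("s", 1:4)
    locus_alignment(m)
  }
  a1 <- mk(); a2 <- mk()
  f <- site_filter()
  filt_then_cat <- cbind(apply_site_filter(a1, f)$mat,
                         apply_site_filter(a2, f)$mat)
  cat_then_filt <- apply_site_filter(
    locus_alignment(cbind(a1$mat, a2$mat)), f)$mat
  expect_equal(filt_then_cat, cat_then_filt)
})

test_that("the synthetic 84-strain collection reproduces the published partition", {
  fx <- sim_strain_collection(seq_fraction = 0.1)
  expect_equal(nrow(fx$metadata), 84L)
  ht <- collapse_haplotypes(fx$alignments)
  expect_equal(ht$n_groups, 40L)

  ## each strain in exactly one group
  expect_equal(sort(unlist(ht$groups, use.names = FALSE)),
               sort(fx$metadata$strain))

  ## recovered partition matches the published group memberships
  for (g in split(fx$metadata$strain, fx$metadata$haplotype_group)) {
    ids <- unique(ht$strain_to_group[g])
    expect_length(ids, 1L)
    expect_equal(sum(ht$strain_to_group == ids), length(g))
  }

  ## the Japanese trio shares one group of size 3
  trio <- c("CBS 2775", "CBS 2776", "CBS 2777")
  gid <- unique(ht$strain_to_group[trio])
  expect_length(gid, 1L)
  expect_length(ht$groups[[as.character(gid)]], 3L)
})
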