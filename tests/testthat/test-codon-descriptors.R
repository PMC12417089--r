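# RSCU, codon-usage distance, CAI, Fop, within-family bias E.

test_that("codon table has 61 sense codons partitioned into families", {
  tab <- codon_table()
  expect_identical(nrow(tab), 61L)
  expect_false(any(c("TAA", "TAG", "TGA") %in% tab$codon))
  expect_identical(tab$codon, sort(tab$codon)) # lexicographic A<C<G<T
  fam <- table(tab$amino_acid)
  expect_identical(sum(fam), 61L)
  expect_identical(as.integer(fam[c("M", "W")]), c(1L, 1L))
  expect_identical(tab$family_size, as.integer(fam[tab$amino_acid]))
})

test_that("RSCU matches hand cases and the family-sum property", {
  r <- compute_rscu("TTTTTC")
  expect_equal(unname(r[c("TTT", "TTC")]), c(1, 1))
  expect_equal(sum(r), 2) # every other family unobserved, fill 0
  r2 <- compute_rscu("TTTTTT")
  expect_equal(unname(r2[["TTT"]]), 2)
  expect_equal(unname(r2[["TTC"]]), 0)
  expect_equal(unname(compute_rscu("ATG")[["ATG"]]), 1)
  # neutral fill option
  r3 <- compute_rscu("ATG", fill = 1)
  expect_equal(unname(r3[["TTT"]]), 1)
  # property: within every observed family, values sum to the family size
  tab <- codon_table()
  set.seed(13)
  for (i in 1:20) {
    cds <- random_cds(sample(5:60, 1L))
    r <- compute_rscu(cds)
    counts <- table(factor(nifstack:::codons_of(cds), levels = tab$codon))
    for (aa in unique(tab$amino_acid)) {
      rows <- tab$codon[tab$amino_acid == aa]
      if (sum(counts[rows]) > 0) {
        expect_equal(sum(r[rows]), length(rows), tolerance = 1e-9)
      }
    }
  }
})

test_that("codon distance satisfies Eq-style closed forms", {
  expect_equal(euclidean_codon_distance(rep(1, 61)), 0)
  v <- rep(1, 61); v[17] <- 2
  expect_equal(euclidean_codon_distance(v), 1.0)
  expect_equal(euclidean_codon_distance(rep(0, 61)), sqrt(61))
  expect_error(euclidean_codon_distance(rep(1, 60)), "61")
  # permutation invariance
  set.seed(2)
  x <- runif(61, 0, 3)
  expect_equal(euclidean_codon_distance(x),
               euclidean_codon_distance(sample(x)))
})

test_that("CAI is the geometric mean of weights over eligible codons", {
  ref <- default_reference_usage()
  # gene built from preferred codons only -> CAI exactly 1
  opt_phe <- ref$codon[ref$optimal & ref$amino_acid == "F"]
  gene_opt <- strrep(opt_phe, 12)
  expect_equal(compute_cai(gene_opt, ref), 1.0, tolerance = 1e-12)
  expect_equal(compute_fop(gene_opt, ref), 1.0)
  # two-codon gene with weights 1 and w -> sqrt(w)
  phe <- c("TTT", "TTC")
  w <- setNames(ref$weight[match(phe, ref$codon)], phe)
  gene2 <- paste0(phe[1], phe[2])
  expect_equal(compute_cai(gene2, ref), sqrt(prod(w)), tolerance = 1e-12)
  # singleton-family-only gene is ineligible
  expect_error(compute_cai("ATGTGG", ref), "no codons")
  expect_error(compute_fop("ATGTGG", ref), "no codons")
})

test_that("synthetic two-weight reference gives CAI 0.5 on a 1/0.25 pair", {
  # construct a reference where TTC has weight 1 and TTT weight 0.25
  tab <- codon_table()
  ref_df <- tibble::tibble(codon = tab$codon, weight = 1)
  ref_df$weight[ref_df$codon == "TTT"] <- 0.25
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(ref_df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ref <- read_reference_usage(path)
  expect_equal(compute_cai("TTCTTT", ref), 0.5, tolerance = 1e-12)
  expect_equal(compute_fop("TTCTTT", ref), 0.5)
  expect_equal(compute_fop("TTTTTT", ref), 0.0)
})

test_that("reference usage validation requires family maxima of 1", {
  tab <- codon_table()
  bad <- tibble::tibble(codon = tab$codon, weight = 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_reference_usage(path), "maximum weight")
})

test_that("bias statistic E measures within-family non-uniformity", {
  # only eligible codons are 3 x TTT (Phe family of size 2):
  # |1 - 0.5| + |0 - 0.5| = 1
  expect_equal(compute_bias_e(strrep("TTT", 3)), 1.0)
  # perfectly uniform families -> 0
  expect_equal(compute_bias_e("TTTTTC"), 0.0)
  # invariant to gene length at fixed proportions
  g <- "TTTTTCGGG" # Phe 1/1, Gly single codon of 4-family
  expect_equal(compute_bias_e(g), compute_bias_e(strrep(g, 5)),
               tolerance = 1e-12)
  # strictly positive when a used family deviates from uniform
  expect_gt(compute_bias_e("TTTTTTTTC"), 0)
})

test_that("expression block has fixed 24-dim layout with missing-gene policy", {
  ref <- default_reference_usage()
  data <- tiny_dataset(4L)
  cds <- data$cds[[1L]]
  eb <- expression_block(cds, ref)
  expect_length(eb, 24L)
  expect_true(all(is.finite(eb)))
  expect_identical(names(eb)[1:3], c("EXPR_nifA_CAI", "EXPR_nifA_E",
                                     "EXPR_nifA_Fop"))
  # identical CDS -> identical blocks
  expect_identical(expression_block(cds, ref), eb)
  # missing nifX -> trailing triple is zero, with warning
  expect_warning(eb2 <- expression_block(cds[names(cds) != "nifX"], ref),
                 "nifX")
  expect_equal(unname(eb2[22:24]), c(0, 0, 0))
  expect_equal(eb2[1:21], eb[1:21])
  expect_error(expression_block(list(), ref), "all 8")
})
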