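# The synthetic nif-operon generator and its planted-signal guarantees.

test_that("generated datasets have the full per-sample structure", {
  d <- generate_dataset(generator_config(n_samples = 15L, seed = 1L,
                                         protein_length = c(40L, 80L)))
  expect_identical(nrow(d), 15L)
  expect_true(all(c("sample_id", "activity", "proteins", "cds", "coords",
                    "copy_numbers", "label", "target") %in% names(d)))
  for (i in seq_len(15L)) {
    expect_setequal(names(d$proteins[[i]]),
                    c("nifH", "nifD", "nifK"))
    expect_setequal(names(d$cds[[i]]), nifstack:::EXPRESSION_GENES)
    expect_identical(nrow(d$coords[[i]]), 3L)
    expect_identical(length(d$copy_numbers[[i]]), 34L)
  }
  expect_true(all(d$activity >= 0))
  expect_identical(d$label, binarize_activity(d$activity))
  expect_equal(d$target, transform_activity(d$activity), tolerance = 1e-12)
  gt <- attr(d, "ground_truth")
  expect_length(gt$latent, 15L)
})

test_that("generated CDS translate cleanly back to their proteins", {
  d <- generate_dataset(generator_config(n_samples = 10L, seed = 3L,
                                         protein_length = c(40L, 60L)))
  for (i in 1:10) {
    for (g in names(d$cds[[i]])) {
      cds <- d$cds[[i]][[g]]
      expect_identical(nchar(cds) %% 3L, 0L)
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                         no.init.codon = TRUE))
      expect_false(grepl("*", aa, fixed = TRUE)) # no internal stops
      if (g %in% c("nifH", "nifD", "nifK")) {
        expect_identical(aa, d$proteins[[i]][[g]])
      }
    }
  }
})

test_that("generation is a deterministic function of the config", {
  cfg <- generator_config(n_samples = 12L, seed = 7L,
                          protein_length = c(40L, 60L))
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_fixture_bundle(d1, dir1, embedding_width = 8L)
  write_fixture_bundle(d2, dir2, embedding_width = 8L)
  for (f in c("manifest.tsv", "proteins.fasta", "cds.fasta", "coords.tsv",
              "embeddings.tsv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), info = f)
  }
  d3 <- generate_dataset(generator_config(n_samples = 12L, seed = 8L,
                                          protein_length = c(40L, 60L)))
  expect_false(identical(d1$activity, d3$activity))
})

test_that("label balance tracks the configured target", {
  d <- generate_dataset(generator_config(n_samples = 100L, seed = 5L,
                                         protein_length = c(40L, 60L)))
  expect_gte(mean(d$label), 0.35)
  expect_lte(mean(d$label), 0.65)
  d2 <- generate_dataset(generator_config(n_samples = 100L, seed = 5L,
                                          balance = 0.3,
                                          protein_length = c(40L, 60L)))
  expect_lt(abs(mean(d2$label) - 0.3), 0.15)
})

test_that("with only the copy-number effect the label is a step function", {
  d <- generate_dataset(generator_config(
    n_samples = 60L, seed = 9L, sigma = 0, beta_cn = 1, beta_emb = 0,
    beta_cb = 0, protein_length = c(40L, 60L)))
  cn <- vapply(d$copy_numbers, function(x) x[["nifH"]], integer(1L))
  # every positive sample has strictly more nifH copies than every negative
  expect_gt(min(cn[d$label == 1L]), max(cn[d$label == 0L]) - 1L)
  agg <- tapply(d$label, cn, mean)
  expect_true(all(agg %in% c(0, 1)))
})

test_that("fixture bundles round-trip through the standard readers", {
  d <- generate_dataset(generator_config(n_samples = 10L, seed = 11L,
                                         protein_length = c(40L, 60L)))
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(d, dir, embedding_width = 8L,
                                embedding_seed = 2L)
  back <- read_manifest(paths$manifest)
  expect_identical(back$proteins, d$proteins)
  emb <- load_embedding_table(paths$embeddings)
  expect_identical(emb$sample_id, d$sample_id)
  expect_identical(ncol(emb), 9L)
  # the bundled embeddings equal a fresh pseudo-backend run
  fresh <- pseudo_embedding_block(d, width = 8L, seed = 2L)
  expect_equal(as.matrix(emb[, -1L]), as.matrix(fresh[, -1L]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(write_dataset(d[0L, ], withr::local_tempdir()), "empty")
})

test_that("planted single-group signals are recovered by IFS downstream", {
  # cross-module recovery: sigma = 0, one nonzero effect weight; the
  # corresponding feature group must win round 1 of IFS
  hits <- 0L
  n_seeds <- 20L
  for (seed in seq_len(n_seeds)) {
    d <- generate_dataset(generator_config(
      n_samples = 60L, seed = seed, sigma = 0,
      beta_cn = 1, beta_emb = 0, beta_cb = 0,
      protein_length = c(40L, 60L)))
    blocks <- build_feature_groups(
      d, groups = c("Copy_number", "Gene_distance", "Euclidean_distance"))
    trace <- ifs_search(blocks, d$label, cheap_classifier(seed), seed = seed)
    round1 <- trace$rounds[trace$rounds$round == 1L, ]
    if (identical(round1$set[[which.max(round1$score)]], "Copy_number")) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 18L)
})
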