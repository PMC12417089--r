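# Labels, activity transform, stratified splits, manifest round trip.

test_that("activity binarisation is strict at the threshold", {
  expect_identical(binarize_activity(c(51, 0, 50)), c(1L, 0L, 0L))
  expect_identical(binarize_activity(50 + 1e-9), 1L)
  expect_error(binarize_activity(-1), "non-negative")
  expect_identical(binarize_activity(c(5, 15), threshold = 10), c(0L, 1L))
})

test_that("log-activity transform matches closed forms and round-trips", {
  expect_equal(transform_activity(0), log10(2), tolerance = 1e-12)
  expect_equal(transform_activity(8), 1.0, tolerance = 1e-12)
  expect_equal(transform_activity(98), 2.0, tolerance = 1e-12)
  x <- c(0, 0.5, 50, 999.9)
  expect_equal(inverse_transform_activity(transform_activity(x)), x,
               tolerance = 1e-9)
  # strictly monotone increasing
  xs <- sort(runif(50, 0, 1000))
  expect_true(all(diff(transform_activity(xs)) > 0))
  expect_error(transform_activity(-3), "invalid")
})

test_that("stratified split reproduces per-class floor allocation", {
  df <- tibble::tibble(.id = seq_len(402),
                       label = rep(c(0L, 1L), c(209L, 193L)))
  parts <- stratified_split(df, split_spec(0.8, seed = 11L))
  expect_identical(sum(parts$a$label == 0L), 167L)
  expect_identical(sum(parts$a$label == 1L), 154L)
  expect_identical(sum(parts$b$label == 0L), 42L)
  expect_identical(sum(parts$b$label == 1L), 39L)
  # disjoint and exhaustive, for several seeds and fractions
  for (seed in 1:5) {
    for (fr in c(0.3, 0.6, 0.8)) {
      p <- stratified_split(df, split_spec(fr, seed = seed))
      expect_length(intersect(p$a$.id, p$b$.id), 0L)
      expect_setequal(c(p$a$.id, p$b$.id), df$.id)
    }
  }
})

test_that("splits are reproducible under a fixed seed", {
  df <- tibble::tibble(.id = 1:40, label = rep(c(0L, 1L), 20L))
  p1 <- stratified_split(df, split_spec(0.8, seed = 3L))
  p2 <- stratified_split(df, split_spec(0.8, seed = 3L))
  expect_identical(p1$a$.id, p2$a$.id)
  p3 <- stratified_split(df, split_spec(0.8, seed = 4L))
  expect_false(identical(p1$a$.id, p3$a$.id))
})

test_that("split errors on degenerate classes", {
  df <- tibble::tibble(label = c(0L, 0L, 0L, 1L))
  expect_error(stratified_split(df, split_spec(0.8, seed = 1L)), "class")
  df2 <- tibble::tibble(x = 1:5)
  expect_error(stratified_split(df2, split_spec(0.5, seed = 1L)),
               "label")
  p <- stratified_split(df2, split_spec(0.5, stratified = FALSE, seed = 1L))
  expect_identical(nrow(p$a), 2L)
})

test_that("protein and CDS validation enforce the alphabets", {
  expect_identical(validate_protein("acdef"), "ACDEF")
  expect_error(validate_protein("ACXDE"), "non-canonical")
  expect_warning(out <- validate_protein("ACXDE", ambiguity = "drop"),
                 "dropped")
  expect_identical(out, "ACDE")
  expect_error(validate_cds("ATGAA"), "divisible")
  expect_error(validate_cds("ATGTAAGGG"), "internal stop")
  # terminal stop is stripped
  expect_identical(validate_cds("ATGGGGTAA"), "ATGGGG")
  expect_error(validate_cds("ATGNGG"), "outside")
})

test_that("manifest bundle round-trips a generated dataset", {
  data <- generate_dataset(generator_config(n_samples = 12L, seed = 21L,
                                            protein_length = c(40L, 60L)))
  dir <- withr::local_tempdir()
  write_dataset(data, dir)
  back <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_identical(back$sample_id, data$sample_id)
  expect_equal(back$activity, data$activity, tolerance = 1e-12)
  expect_identical(back$proteins, data$proteins)
  expect_identical(back$cds, data$cds)
  expect_identical(back$copy_numbers, data$copy_numbers)
  for (i in seq_len(nrow(data))) {
    expect_equal(as.data.frame(back$coords[[i]]),
                 as.data.frame(data$coords[[i]]))
  }
  # byte-stable: write -> read -> write reproduces the manifest file
  dir2 <- withr::local_tempdir()
  write_dataset(back, dir2)
  expect_identical(readLines(file.path(dir2, "manifest.tsv")),
                   readLines(file.path(dir, "manifest.tsv")))
})

test_that("manifest ingestion reports missing records and duplicates", {
  data <- generate_dataset(generator_config(n_samples = 10L, seed = 5L,
                                            protein_length = c(40L, 60L)))
  dir <- withr::local_tempdir()
  write_dataset(data, dir)
  # drop one sample's nifD protein record
  fa <- Biostrings::readAAStringSet(file.path(dir, "proteins.fasta"))
  fa <- fa[names(fa) != paste0(data$sample_id[2], "|nifD")]
  Biostrings::writeXStringSet(fa, file.path(dir, "proteins.fasta"))
  expect_error(read_manifest(file.path(dir, "manifest.tsv")),
               paste0(data$sample_id[2], ".*nifD"))
  # duplicate sample id
  man <- readLines(file.path(dir, "manifest.tsv"))
  writeLines(c(man, man[2]), file.path(dir, "manifest.tsv"))
  expect_error(read_manifest(file.path(dir, "manifest.tsv")), "duplicate")
  # missing required column
  man2 <- gsub("^sample_id", "id", man)
  writeLines(man2, file.path(dir, "manifest.tsv"))
  expect_error(read_manifest(file.path(dir, "manifest.tsv")),
               "missing required column")
})

test_that("label_dataset refuses missing activity unless allowed", {
  d <- tibble::tibble(activity = c(10, NA))
  expect_error(label_dataset(d), "missing activity")
  out <- label_dataset(d, allow_missing = TRUE)
  expect_identical(out$label, c(0L, NA_integer_))
})
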