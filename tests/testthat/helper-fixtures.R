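# Shared fixtures: tiny in-code datasets, feature blocks built from plain
# matrices, planted-signal designs, and brute-force oracles.

# wrap a numeric matrix as a feature-block tibble
as_block <- function(mat, ids = sprintf("S%03d", seq_len(nrow(mat))),
                     prefix = "X") {
  if (is.null(colnames(mat))) {
    colnames(mat) <- paste0(prefix, seq_len(ncol(mat)))
  }
  dplyr::bind_cols(tibble::tibble(sample_id = ids), tibble::as_tibble(mat))
}

# planted-signal classification design: one informative group among noise
# groups. The signal group's first column equals the label plus slight noise.
planted_classification <- function(n = 120L, n_noise_groups = 3L, seed = 1L,
                                   signal_sd = 0.1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)[sample.int(n)]
  ids <- sprintf("S%03d", seq_len(n))
  groups <- list(signal = as_block(
    cbind(s1 = y + rnorm(n, 0, signal_sd), s2 = rnorm(n)), ids))
  for (g in seq_len(n_noise_groups)) {
    groups[[paste0("noise", g)]] <-
      as_block(matrix(rnorm(n * 3L), n, 3L), ids)
  }
  list(groups = groups, y = y)
}

# additive two-group regression design: each informative group carries half
# the signal
planted_regression <- function(n = 150L, seed = 1L, noise_sd = 0.05) {
  set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n))
  a <- rnorm(n)
  b <- rnorm(n)
  y <- a + b + rnorm(n, 0, noise_sd)
  list(groups = list(
    partA = as_block(cbind(a = a), ids),
    partB = as_block(cbind(b = b), ids),
    noise = as_block(matrix(rnorm(n * 2L), n, 2L), ids)
  ), y = y)
}

# cheap deterministic evaluator for selection tests
cheap_classifier <- function(seed = 1L) learner_spec("logistic", seed = seed)
cheap_regressor <- function(seed = 1L) learner_spec("lm", seed = seed)

# brute-force conjoint-triad oracle: enumerate windows directly
brute_ct <- function(seq, classes = nifstack:::CT_CLASSES) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  out <- setNames(numeric(343), nifstack:::ct_feature_names())
  for (i in seq_len(L - 2L)) {
    key <- paste0("CT_", classes[ch[i]], classes[ch[i + 1L]],
                  classes[ch[i + 2L]])
    out[key] <- out[key] + 1
  }
  out / (L - 2L)
}

# brute-force dipeptide oracle
brute_dpc <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  out <- setNames(numeric(400), nifstack:::dpc_feature_names())
  for (i in seq_len(L - 1L)) {
    key <- paste0("DPC_", ch[i], ch[i + 1L])
    out[key] <- out[key] + 1
  }
  out / (L - 1L)
}

# brute-force pairwise AUC (ties count 1/2)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# random valid protein / CDS strings
random_aa <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(nifstack:::AA_ALPHABET, n, replace = TRUE), collapse = "")
}
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- codon_table()
  paste(sample(tab$codon, n_codons, replace = TRUE), collapse = "")
}

# tiny complete nif dataset without going through the generator
tiny_dataset <- function(n = 4L, seed = 42L) {
  generate_dataset(generator_config(n_samples = max(n, 10L), seed = seed,
                                    protein_length = c(40L, 60L)))[
                                      seq_len(max(n, 10L)), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
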