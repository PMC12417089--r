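# Deterministic generator of synthetic nif-operon datasets with planted,
# configurable signal. Emulates the structure of the real training data: three
# structural proteins (~250-550 residues), coding sequences for the eight
# expression genes (back-translated with a per-sample codon bias), gene
# coordinates on one replicon, 34 copy counts, and a continuous activity value
# whose log-scale target is near-linear in the latent score.

#' Synthetic dataset generator configuration
#'
#' The latent activity score of a sample is
#' `s = beta_cn * z(nifH copies) + beta_emb * z(embedding projection) +
#' beta_cb * z(CAI of nifH) + Normal(0, sigma)`, where `z` denotes
#' standardisation across the cohort; activity is `activity_scale * 10^s`
#' shifted so that the configured class balance holds at the 50-unit label
#' threshold. Setting a single nonzero effect weight plants the signal in the
#' corresponding feature group.
#'
#' @param n_samples Number of strains (>= 10).
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the config.
#' @param protein_length Length range of the structural proteins.
#' @param balance Target positive-class fraction at the 50-unit threshold.
#' @param beta_cn,beta_emb,beta_cb Effect weights of the copy-number,
#'   embedding-direction and codon-bias components.
#' @param sigma Sd of the latent noise (>= 0).
#' @param activity_scale Activity at latent score 0; the label threshold (50)
#'   by default, putting the class boundary at `s = 0`.
#' @param embedding_width Width of the pseudo-embedding used for the planted
#'   embedding direction.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_samples = 100L, seed = 1L,
                             protein_length = c(250L, 550L),
                             balance = 0.5,
                             beta_cn = 1, beta_emb = 1, beta_cb = 1,
                             sigma = 0.3, activity_scale = 50,
                             embedding_width = 32L) {
  stopifnot(n_samples >= 10L, sigma >= 0, length(protein_length) == 2L,
            protein_length[1L] >= 35L,
            protein_length[1L] <= protein_length[2L],
            balance > 0, balance < 1, activity_scale > 0,
            embedding_width >= 1L)
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 protein_length = as.integer(protein_length),
                 balance = balance, beta_cn = beta_cn, beta_emb = beta_emb,
                 beta_cb = beta_cb, sigma = sigma,
                 activity_scale = activity_scale,
                 embedding_width = as.integer(embedding_width)),
            class = "generator_config")
}

# optimal codon per amino acid used by the generator's back-translation:
# the alphabetically first codon of each synonymous family
generator_optimal_codons <- function() {
  tab <- codon_table_cached()
  vapply(split(tab$codon, tab$amino_acid), min, character(1L))
}

# back-translate a protein: each residue takes its family's preferred codon
# with probability rho, otherwise a uniform draw from the family
back_translate <- function(protein, rho) {
  tab <- codon_table_cached()
  fam <- split(tab$codon, tab$amino_acid)
  opt <- generator_optimal_codons()
  letters_in <- strsplit(protein, "", fixed = TRUE)[[1]]
  use_opt <- stats::runif(length(letters_in)) < rho
  cods <- character(length(letters_in))
  cods[use_opt] <- opt[letters_in[use_opt]]
  for (i in which(!use_opt)) {
    f <- fam[[letters_in[i]]]
    cods[i] <- f[sample.int(length(f), 1L)]
  }
  paste(cods, collapse = "")
}

random_protein <- function(length, probs) {
  paste(sample(AA_ALPHABET, length, replace = TRUE, prob = probs),
        collapse = "")
}

#' Generate a synthetic labelled dataset
#'
#' Produces a complete dataset (proteins, coding sequences, coordinates, copy
#' numbers, activity, labels and regression targets) plus a ground-truth
#' record of the latent scores and effect components, attached as the
#' `"ground_truth"` attribute.
#'
#' @param cfg A [generator_config()].
#' @return A labelled nif dataset tibble (see [label_dataset()]) with the
#'   ground-truth attribute.
#' @export
generate_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n_samples
  local_rng(cfg$seed)

  # phase 1: draw every random quantity (fixed draw order = determinism)
  copy_numbers <- lapply(seq_len(n), function(i) {
    cn <- stats::setNames(stats::rpois(34L, 1), COPY_NUMBER_GENES)
    cn["nifH"] <- sample(1:4, 1L)
    cn[c("nifD", "nifK")] <- pmax(cn[c("nifD", "nifK")], 1L)
    cn
  })
  rho <- stats::runif(n, 0.15, 0.95)        # per-sample codon bias
  tilt <- stats::runif(n, -1, 1)            # residue-composition tilt
  tilt_mask <- rep(c(1, -1), each = 10L)    # first vs last half of alphabet
  aa_probs <- lapply(tilt, function(t) {
    w <- 1 + 0.35 * t * tilt_mask
    w / sum(w)
  })
  struct_len <- matrix(sample(seq(cfg$protein_length[1L],
                                  cfg$protein_length[2L]),
                              3L * n, replace = TRUE), ncol = 3L)
  aux_genes <- setdiff(EXPRESSION_GENES, NIF_STRUCTURAL_GENES)
  aux_len <- matrix(sample(150:250, length(aux_genes) * n, replace = TRUE),
                    ncol = length(aux_genes))
  proteins <- lapply(seq_len(n), function(i) {
    p <- vapply(struct_len[i, ], random_protein, character(1L),
                probs = aa_probs[[i]])
    stats::setNames(p, NIF_STRUCTURAL_GENES)
  })
  aux_proteins <- lapply(seq_len(n), function(i) {
    p <- vapply(aux_len[i, ], random_protein, character(1L),
                probs = aa_probs[[i]])
    stats::setNames(p, aux_genes)
  })
  cds <- lapply(seq_len(n), function(i) {
    all_prot <- c(proteins[[i]], aux_proteins[[i]])[EXPRESSION_GENES]
    vapply(all_prot, back_translate, character(1L), rho = rho[i])
  })
  coords <- lapply(seq_len(n), function(i) {
    start_h <- sample(1000:5000, 1L)
    gap1 <- sample(50:2000, 1L)
    gap2 <- sample(50:2000, 1L)
    len <- struct_len[i, ] * 3L
    s_h <- start_h
    s_d <- s_h + len[1L] + gap1
    s_k <- s_d + len[2L] + gap2
    tibble::tibble(
      gene = NIF_STRUCTURAL_GENES,
      replicon = "rep1",
      start = c(s_h, s_d, s_k),
      end = c(s_h + len[1L] - 1L, s_d + len[2L] - 1L, s_k + len[3L] - 1L),
      strand = "+"
    )
  })
  noise <- stats::rnorm(n, 0, cfg$sigma)

  # phase 2: deterministic transforms (embedding projection, CAI)
  zscale <- function(v) if (stats::sd(v) == 0) rep(0, length(v)) else
    (v - mean(v)) / stats::sd(v)
  emb_proj <- if (cfg$beta_emb != 0) {
    dir_seed <- (string_hash("planted-direction") + cfg$embedding_width) %%
      2147483647L
    set.seed(dir_seed)
    direction <- stats::rnorm(cfg$embedding_width)
    direction <- direction / sqrt(sum(direction^2))
    vapply(proteins, function(prots) {
      pooled <- lapply(prots, function(p) {
        mean_pool(pseudo_embedding(p, width = cfg$embedding_width,
                                   seed = cfg$seed))
      })
      sum(aggregate_sample_embedding(pooled) * direction)
    }, numeric(1L))
  } else numeric(n)
  ref <- default_reference_usage()
  cai_h <- if (cfg$beta_cb != 0) {
    vapply(cds, function(s) compute_cai(s[["nifH"]], ref), numeric(1L))
  } else numeric(n)
  cn_h <- vapply(copy_numbers, function(cn) as.numeric(cn[["nifH"]]),
                 numeric(1L))

  s <- cfg$beta_cn * zscale(cn_h) + cfg$beta_emb * zscale(emb_proj) +
    cfg$beta_cb * zscale(cai_h) + noise
  # centre the latent score so the configured class balance holds at the
  # 50-unit threshold (the boundary sits at s = 0 when activity_scale = 50)
  shift <- stats::quantile(s, 1 - cfg$balance, names = FALSE, type = 1L)
  s <- s - shift
  activity <- pmax(cfg$activity_scale * 10^s, 0)

  data <- tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    activity = activity,
    proteins = proteins,
    cds = cds,
    coords = coords,
    copy_numbers = copy_numbers
  )
  data <- label_dataset(data, threshold = 50)
  if (min(table(data$label)) < 2L) {
    stop("infeasible class balance for requested n", call. = FALSE)
  }
  attr(data, "ground_truth") <- list(
    latent = s, noise = noise, rho = rho, tilt = tilt,
    embedding_projection = emb_proj, cai_nifH = cai_h, copies_nifH = cn_h,
    betas = c(cn = cfg$beta_cn, emb = cfg$beta_emb, cb = cfg$beta_cb),
    sigma = cfg$sigma, seed = cfg$seed
  )
  data
}

#' Write a fixture bundle
#'
#' Serialises a dataset in the exact manifest/FASTA/coordinate dialects of
#' the readers, plus a sample-level pseudo-embedding table, so the bundle
#' round-trips through [read_manifest()] and [load_embedding_table()].
#'
#' @param data A nif dataset tibble.
#' @param dir Output directory.
#' @param embedding_width,embedding_seed Pseudo-embedding parameters for the
#'   bundled `embeddings.tsv`.
#' @return Invisibly, a named list of the file paths written.
#' @export
write_fixture_bundle <- function(data, dir, embedding_width = 32L,
                                 embedding_seed = 1L) {
  manifest <- write_dataset(data, dir)
  emb <- pseudo_embedding_block(data, width = embedding_width,
                                seed = embedding_seed)
  emb_path <- file.path(dir, "embeddings.tsv")
  write_embedding_table(emb, emb_path)
  invisible(list(manifest = manifest, embeddings = emb_path,
                 proteins = file.path(dir, "proteins.fasta"),
                 cds = file.path(dir, "cds.fasta"),
                 coords = file.path(dir, "coords.tsv")))
}
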