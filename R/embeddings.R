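# Protein embedding ingestion and pooling. Language-model inference itself is
# out of scope: per-residue or per-protein matrices computed elsewhere are
# read from TSV, mean-pooled along the sequence axis and averaged over the
# three structural proteins. A deterministic pseudo-embedding backend with the
# same interface supports testing and simulation.

#' Mean-pool a per-residue embedding matrix
#'
#' Column-wise arithmetic mean over the residue rows, collapsing an L x D
#' matrix to a length-D global vector. Pooling runs over residue rows only
#' (no special or padding tokens).
#'
#' @param mat Numeric matrix, residues in rows.
#' @return Numeric vector of length `ncol(mat)`.
#' @export
mean_pool <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (nrow(mat) < 1L) stop("empty embedding matrix", call. = FALSE)
  if (!all(is.finite(mat))) stop("non-finite embedding entries", call. = FALSE)
  colMeans(mat)
}

#' Average pooled embeddings over the three structural proteins
#'
#' Element-wise mean of the pooled nifH/nifD/nifK embedding vectors; the
#' embedding width is preserved.
#'
#' @inheritParams aggregate_protein_block
#' @export
aggregate_sample_embedding <- function(vectors, permissive = FALSE) {
  aggregate_protein_block(vectors, permissive = permissive)
}

#' Validate an embedding width against its source tag
#'
#' Known sources (ProtT5 1024, ProteinBERT 512, Ankh 1536, ESMC_300M 960,
#' ESMC_600M 1152, ESMC_6B 2560) must match their declared width; unknown
#' tags accept any width.
#'
#' @param width Integer embedding width.
#' @param source Source tag string.
#' @return `width`, invisibly; errors on mismatch.
#' @export
check_embedding_width <- function(width, source) {
  if (source %in% names(EMBEDDING_WIDTHS) &&
      width != EMBEDDING_WIDTHS[[source]]) {
    stop("source ", source, " declares width ", EMBEDDING_WIDTHS[[source]],
         ", got ", width, call. = FALSE)
  }
  invisible(width)
}

#' Deterministic pseudo-embedding backend
#'
#' Stands in for a protein language model in tests and simulations: each
#' residue's row is a deterministic function of the residue identity, its
#' +/-1 sequence context window, and the seed (a seeded hash keys a fixed
#' random row), so identical sequences give bit-identical matrices and
#' similar sequences give correlated ones.
#'
#' @param seq Protein sequence.
#' @param width Embedding width D (default 64).
#' @param seed Integer seed.
#' @return L x D numeric matrix with source tag attribute `"pseudo"`.
#' @export
pseudo_embedding <- function(seq, width = 64L, seed = 1L) {
  seq <- validate_protein(seq)
  stopifnot(width >= 1L)
  letters_in <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(letters_in)
  ctx <- paste0(c("^", letters_in[-L]), letters_in,
                c(letters_in[-1L], "$"))
  keys <- unique(ctx)
  rows <- matrix(0, length(keys), width)
  for (i in seq_along(keys)) {
    set.seed((string_hash(keys[i]) + as.integer(seed) * 7919L) %% 2147483647L)
    rows[i, ] <- stats::rnorm(width)
  }
  out <- rows[match(ctx, keys), , drop = FALSE]
  attr(out, "source") <- "pseudo"
  out
}

# deterministic 31-bit string hash (polynomial rolling, platform independent)
string_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 131 + x) %% 2147483647
  as.integer(h)
}

#' Read an embedding table
#'
#' TSV whose first column is `sampleID` (sample-level vectors) or
#' `sampleID|gene` (gene-level vectors, which are averaged over the three
#' structural proteins per sample); remaining columns are numeric. Widths
#' must be consistent across rows.
#'
#' @param path Path to the TSV.
#' @param source Optional source tag; known tags have their width validated.
#' @return Tibble with `sample_id` and numeric columns `EMB_1` ... `EMB_D`.
#' @export
load_embedding_table <- function(path, source = "unknown") {
  if (!file.exists(path)) stop("embedding table not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("embedding table is empty", call. = FALSE)
  }
  ids <- as.character(df[[1L]])
  num <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(num) || anyNA(num)) {
    stop("embedding table has non-numeric or missing entries (ragged rows?)",
         call. = FALSE)
  }
  check_embedding_width(ncol(num), source)
  if (any(grepl("|", ids, fixed = TRUE))) {
    sample_id <- sub("\\|.*$", "", ids)
    pooled <- rowsum(num, sample_id) / as.vector(table(sample_id)[
      sort(unique(sample_id))])
    sample_id <- rownames(pooled)
    num <- pooled
  } else {
    sample_id <- ids
  }
  colnames(num) <- paste0("EMB_", seq_len(ncol(num)))
  dplyr::bind_cols(tibble::tibble(sample_id = sample_id),
                   tibble::as_tibble(num))
}

#' Write an embedding table
#'
#' @param emb Tibble as returned by [load_embedding_table()] (column
#'   `sample_id` + numeric columns).
#' @param path Output TSV path.
#' @export
write_embedding_table <- function(emb, path) {
  stopifnot(is.data.frame(emb), "sample_id" %in% names(emb))
  df <- as.data.frame(emb)
  names(df)[names(df) == "sample_id"] <- "sampleID"
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pooled pseudo-embedding block for a dataset
#'
#' Runs the pseudo backend over each sample's three structural proteins,
#' mean-pools per protein and averages across proteins.
#'
#' @param data A nif dataset tibble.
#' @param width Embedding width.
#' @param seed Integer seed for the pseudo backend.
#' @return Tibble `sample_id` + `EMB_1` ... `EMB_width`.
#' @export
pseudo_embedding_block <- function(data, width = 64L, seed = 1L) {
  rows <- purrr::map2(data$sample_id, data$proteins, function(id, prots) {
    pooled <- lapply(prots[NIF_STRUCTURAL_GENES], function(p) {
      mean_pool(pseudo_embedding(p, width = width, seed = seed))
    })
    aggregate_sample_embedding(pooled)
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- paste0("EMB_", seq_len(width))
  dplyr::bind_cols(tibble::tibble(sample_id = data$sample_id),
                   tibble::as_tibble(mat))
}
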