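# Assembly of the nine named feature groups for a dataset, plus feature-block
# serialisation. A feature block is a tibble with a sample_id column followed
# by fixed-width named numeric columns; blocks in a set are row-aligned.

#' Build the feature-group set for a dataset
#'
#' Computes the handcrafted feature groups — CT (343), DPC (400), PAAC (50),
#' RSCU (61), Euclidean_distance (1), Expression (24), Gene_distance (1),
#' Copy_number (34) — and attaches an embedding block (`Embedding`): either a
#' supplied table (e.g. language-model output loaded with
#' [load_embedding_table()]) or the deterministic pseudo backend.
#'
#' @param data A nif dataset tibble.
#' @param ref Reference usage for CAI/Fop (default: bundled synthetic table).
#' @param embedding Optional embedding tibble (`sample_id` + numeric columns);
#'   `NULL` uses the pseudo backend.
#' @param embedding_width,embedding_seed Pseudo-backend parameters, used only
#'   when `embedding` is `NULL`.
#' @param groups Which groups to build (default all nine).
#' @param paac_cfg A [paac_config()].
#' @return Named list of feature-block tibbles, row-aligned to `data`.
#' @export
build_feature_groups <- function(data,
                                 ref = default_reference_usage(),
                                 embedding = NULL,
                                 embedding_width = 64L,
                                 embedding_seed = 1L,
                                 groups = NULL,
                                 paac_cfg = paac_config()) {
  all_groups <- c("CT", "DPC", "PAAC", "RSCU", "Euclidean_distance",
                  "Expression", "Gene_distance", "Copy_number", "Embedding")
  groups <- groups %||% all_groups
  stopifnot(all(groups %in% all_groups))
  ids <- data$sample_id

  per_protein <- function(encode) {
    rows <- purrr::map(data$proteins, function(prots) {
      aggregate_protein_block(lapply(prots[NIF_STRUCTURAL_GENES], encode))
    })
    block_from_rows(ids, rows)
  }
  per_structural_cds <- function(encode) {
    rows <- purrr::map(data$cds, function(cds) {
      aggregate_codon_block(lapply(cds[NIF_STRUCTURAL_GENES], encode))
    })
    block_from_rows(ids, rows)
  }

  out <- list()
  if ("CT" %in% groups) out$CT <- per_protein(encode_ct)
  if ("DPC" %in% groups) out$DPC <- per_protein(encode_dpc)
  if ("PAAC" %in% groups) {
    out$PAAC <- per_protein(function(s) encode_paac(s, paac_cfg))
  }
  rscu_needed <- any(c("RSCU", "Euclidean_distance") %in% groups)
  if (rscu_needed) {
    rscu_rows <- purrr::map(data$cds, function(cds) {
      lapply(cds[NIF_STRUCTURAL_GENES], compute_rscu)
    })
  }
  if ("RSCU" %in% groups) {
    rows <- purrr::map(rscu_rows, aggregate_codon_block)
    out$RSCU <- block_from_rows(ids, purrr::map(rows, function(r) {
      stats::setNames(r, paste0("RSCU_", names(r)))
    }))
  }
  if ("Euclidean_distance" %in% groups) {
    rows <- purrr::map(rscu_rows, function(r) {
      c(ECD = aggregate_codon_block(lapply(r, euclidean_codon_distance)))
    })
    out$Euclidean_distance <- block_from_rows(ids, rows)
  }
  if ("Expression" %in% groups) {
    rows <- purrr::map(data$cds, expression_block, ref = ref)
    out$Expression <- block_from_rows(ids, rows)
  }
  if ("Gene_distance" %in% groups) {
    rows <- purrr::map(data$coords, function(crd) {
      c(GDIST = gene_distance(crd))
    })
    out$Gene_distance <- block_from_rows(ids, rows)
  }
  if ("Copy_number" %in% groups) {
    rows <- purrr::map(data$copy_numbers, copy_number_vector, quiet = TRUE)
    out$Copy_number <- block_from_rows(ids, rows)
  }
  if ("Embedding" %in% groups) {
    if (is.null(embedding)) {
      out$Embedding <- pseudo_embedding_block(data, width = embedding_width,
                                              seed = embedding_seed)
    } else {
      m <- match(ids, embedding$sample_id)
      if (anyNA(m)) {
        stop("embedding table is missing sample(s): ",
             paste(utils::head(ids[is.na(m)], 5L), collapse = ", "),
             call. = FALSE)
      }
      out$Embedding <- embedding[m, , drop = FALSE]
    }
  }
  out[intersect(all_groups, groups)]
}

block_from_rows <- function(ids, rows) {
  mat <- do.call(rbind, rows)
  dplyr::bind_cols(tibble::tibble(sample_id = ids), tibble::as_tibble(mat))
}

#' Serialise / read a feature block
#'
#' Feature blocks are TSV files: first column `sample_id`, then labelled
#' numeric columns.
#'
#' @param block Feature-block tibble.
#' @param path File path.
#' @return The path (write) or the tibble (read).
#' @export
write_feature_block <- function(block, path) {
  stopifnot(is.data.frame(block), names(block)[1L] == "sample_id")
  utils::write.table(block, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_block
#' @export
read_feature_block <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  df$sample_id <- as.character(df$sample_id)
  tibble::as_tibble(df)
}

#' Bind feature groups into a design matrix
#'
#' Concatenates the numeric columns of the named blocks (in the given order)
#' into one numeric matrix, checking row alignment on `sample_id`.
#'
#' @param blocks Named list of feature-block tibbles.
#' @param groups Character vector of group names to include (default all).
#' @return Numeric matrix, rownames = sample ids.
#' @export
design_matrix <- function(blocks, groups = names(blocks)) {
  stopifnot(length(groups) >= 1L, all(groups %in% names(blocks)))
  ids <- blocks[[groups[1L]]]$sample_id
  mats <- lapply(groups, function(g) {
    b <- blocks[[g]]
    if (!identical(b$sample_id, ids)) {
      stop("feature blocks are not row-aligned (group ", g, ")",
           call. = FALSE)
    }
    as.matrix(b[, -1L, drop = FALSE])
  })
  out <- do.call(cbind, mats)
  rownames(out) <- ids
  out
}
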