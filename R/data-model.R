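#' @importFrom rlang .data %||%
#' @importFrom stats predict rnorm runif setNames var
#' @importFrom utils head modifyList
NULL

# ---- sequence validation ------------------------------------------------

#' Validate a protein sequence
#'
#' Checks a one-letter amino acid string against the 20-letter canonical
#' alphabet. Ambiguous or non-standard letters (B, Z, X, U, O, J) are rejected
#' by default; in `ambiguity = "drop"` mode they are removed with a warning.
#'
#' @param seq Character scalar, one-letter amino acid codes.
#' @param ambiguity `"reject"` (default) or `"drop"`.
#' @return The validated (possibly cleaned) sequence string.
#' @export
validate_protein <- function(seq, ambiguity = c("reject", "drop")) {
  ambiguity <- match.arg(ambiguity)
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("protein sequence is empty", call. = FALSE)
  letters_in <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- !(letters_in %in% AA_ALPHABET)
  if (any(bad)) {
    if (ambiguity == "reject") {
      stop("protein sequence contains non-canonical residues: ",
           paste(unique(letters_in[bad]), collapse = ", "), call. = FALSE)
    }
    warning(sum(bad), " non-canonical residue(s) dropped", call. = FALSE)
    seq <- paste(letters_in[!bad], collapse = "")
    if (!nzchar(seq)) stop("no canonical residues left after dropping",
                           call. = FALSE)
  }
  seq
}

#' Validate a coding sequence
#'
#' Checks a DNA string over {A,C,G,T}: length divisible by 3 and no internal
#' stop codon under the standard genetic code. A terminal stop codon is
#' stripped before validation (GenBank CDS records usually carry one).
#'
#' @param bases Character scalar of DNA bases.
#' @return The validated CDS string, terminal stop removed.
#' @export
validate_cds <- function(bases) {
  stopifnot(is.character(bases), length(bases) == 1L, !is.na(bases))
  bases <- toupper(bases)
  if (grepl("[^ACGT]", bases)) {
    stop("coding sequence contains characters outside {A,C,G,T}",
         call. = FALSE)
  }
  if (nchar(bases) %% 3L != 0L) {
    stop("coding sequence length not divisible by 3", call. = FALSE)
  }
  cods <- codons_of(bases)
  n <- length(cods)
  if (n == 0L) stop("coding sequence is empty", call. = FALSE)
  if (cods[n] %in% STOP_CODONS) {
    cods <- cods[-n]
    bases <- paste(cods, collapse = "")
    if (length(cods) == 0L) stop("coding sequence is a bare stop codon",
                                 call. = FALSE)
  }
  if (any(cods %in% STOP_CODONS)) {
    stop("internal stop codon in coding sequence", call. = FALSE)
  }
  bases
}

codons_of <- function(bases) {
  n <- nchar(bases)
  if (n == 0L) return(character(0))
  substring(bases, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# ---- labels -------------------------------------------------------------

#' Binarise a nitrogenase activity value
#'
#' A strain is labelled positive (1) when its measured activity strictly
#' exceeds the threshold, by default 50 nmol C2H4/mg protein/hour; an activity
#' exactly at the threshold is negative.
#'
#' @param x Numeric vector of activity values (>= 0).
#' @param threshold Activity threshold, same units as `x`.
#' @return Integer vector of 0/1 labels.
#' @examples
#' binarize_activity(c(0, 50, 51))
#' @export
binarize_activity <- function(x, threshold = 50) {
  stopifnot(is.numeric(x), is.numeric(threshold), length(threshold) == 1L)
  if (any(x < 0, na.rm = TRUE)) stop("activity must be non-negative",
                                     call. = FALSE)
  as.integer(x > threshold)
}

#' Log-transform activity for regression
#'
#' The regression target is `y = log10(x + 2)` where `x` is the activity in
#' nmol C2H4/mg protein/hour; the +2 offset keeps zero activities finite while
#' compressing the heavy right tail.
#'
#' @param x Numeric activity values (>= 0).
#' @return Transformed targets.
#' @seealso [inverse_transform_activity()]
#' @export
transform_activity <- function(x) {
  stopifnot(is.numeric(x))
  if (any(x < -2, na.rm = TRUE)) stop("activity below -2 is invalid",
                                      call. = FALSE)
  if (any(x < 0, na.rm = TRUE)) stop("activity must be non-negative",
                                     call. = FALSE)
  log10(x + 2)
}

#' @rdname transform_activity
#' @param y Transformed targets.
#' @export
inverse_transform_activity <- function(y) {
  stopifnot(is.numeric(y))
  10^y - 2
}

#' Attach labels and regression targets to a dataset
#'
#' Adds `label` (0/1 at the activity threshold) and `target`
#' (log10(activity + 2)) columns. Samples with missing activity are allowed
#' only when `allow_missing = TRUE` (prediction mode).
#'
#' @param data A nif dataset tibble with an `activity` column.
#' @param threshold Activity threshold for the binary label.
#' @param allow_missing Allow NA activities (prediction-only samples).
#' @return The dataset with `label` and `target` columns.
#' @export
label_dataset <- function(data, threshold = 50, allow_missing = FALSE) {
  stopifnot(is.data.frame(data), "activity" %in% names(data))
  if (!allow_missing && anyNA(data$activity)) {
    stop("missing activity values; training requires complete labels",
         call. = FALSE)
  }
  data$label <- binarize_activity(data$activity, threshold)
  data$target <- transform_activity(data$activity)
  data
}

# ---- splits -------------------------------------------------------------

#' Split specification
#'
#' @param fraction Proportion of samples allocated to the first partition
#'   (0 < fraction < 1).
#' @param stratified Preserve class proportions (requires a `label` column).
#' @param seed Integer seed making the split reproducible.
#' @return A `split_spec` list.
#' @export
split_spec <- function(fraction, stratified = TRUE, seed = 1L) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            fraction > 0, fraction < 1)
  structure(list(fraction = fraction, stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified dataset split
#'
#' Splits sample rows into two disjoint partitions. In stratified mode each
#' class contributes exactly `floor(fraction * class size)` samples to
#' partition A and the remainder to partition B, so an 80% split of a 209/193
#' dataset yields 167/154 and 42/39. Membership is randomised under the
#' spec's seed and reproducible.
#'
#' @param data A tibble (one row per sample); needs a `label` column for
#'   stratified splits.
#' @param spec A [split_spec()].
#' @return A list with tibbles `a` and `b`.
#' @export
stratified_split <- function(data, spec) {
  stopifnot(is.data.frame(data), inherits(spec, "split_spec"))
  n <- nrow(data)
  if (n < 2L) stop("need at least 2 samples to split", call. = FALSE)
  rng <- local_rng(spec$seed)
  if (spec$stratified) {
    if (!"label" %in% names(data)) {
      stop("stratified split requires a 'label' column", call. = FALSE)
    }
    idx_a <- integer(0)
    for (cl in sort(unique(data$label))) {
      rows <- which(data$label == cl)
      if (length(rows) < 2L) {
        stop("class ", cl, " has fewer than 2 members", call. = FALSE)
      }
      k <- floor(spec$fraction * length(rows))
      if (k == 0L || k == length(rows)) {
        stop("class ", cl, " would receive 0 members in one partition",
             call. = FALSE)
      }
      idx_a <- c(idx_a, sample(rows, k))
    }
  } else {
    k <- floor(spec$fraction * n)
    if (k == 0L || k == n) stop("a partition would be empty", call. = FALSE)
    idx_a <- sample.int(n, k)
  }
  idx_a <- sort(idx_a)
  list(a = data[idx_a, , drop = FALSE],
       b = data[setdiff(seq_len(n), idx_a), , drop = FALSE])
}

# Evaluate expr-free seeded RNG scope: set the seed locally, restore on exit.
local_rng <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = envir)
  set.seed(as.integer(seed))
  invisible(seed)
}

# ---- manifest / FASTA ingestion ----------------------------------------

MANIFEST_COLUMNS <- c("sample_id", "activity", "protein_fasta", "cds_fasta",
                      "coords_tsv", "copy_numbers")

#' Read a sample manifest into a nif dataset
#'
#' The manifest is a UTF-8 TSV with header columns `sample_id`, `activity`,
#' `protein_fasta`, `cds_fasta`, `coords_tsv`, `copy_numbers` (34
#' comma-separated integers in the canonical gene order). File paths are
#' resolved relative to the manifest's directory; FASTA records are matched by
#' `sampleID|gene` identifiers. Sample order follows manifest row order.
#'
#' @param path Path to the manifest TSV.
#' @param ambiguity Protein ambiguity policy, see [validate_protein()].
#' @return A tibble with one row per sample: `sample_id`, `activity`, and
#'   list-columns `proteins`, `cds`, `coords`, `copy_numbers`.
#' @export
read_manifest <- function(path, ambiguity = c("reject", "drop")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  man <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(man))
  if (length(missing_cols)) {
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(man$sample_id)) {
    stop("duplicate sample_id in manifest: ",
         paste(unique(man$sample_id[duplicated(man$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base_dir, p))

  prot_sets <- read_fasta_map(unique(resolve(man$protein_fasta)), type = "AA")
  cds_sets <- read_fasta_map(unique(resolve(man$cds_fasta)), type = "DNA")
  coords_all <- dplyr::bind_rows(lapply(unique(resolve(man$coords_tsv)),
                                        read_coords_tsv))

  samples <- purrr::pmap(man, function(sample_id, activity, protein_fasta,
                                       cds_fasta, coords_tsv, copy_numbers,
                                       ...) {
    prot <- extract_records(prot_sets[[resolve(protein_fasta)]], sample_id,
                            NIF_STRUCTURAL_GENES, "protein")
    prot <- vapply(prot, validate_protein, character(1L),
                   ambiguity = ambiguity)
    cds <- extract_records(cds_sets[[resolve(cds_fasta)]], sample_id,
                           EXPRESSION_GENES, "CDS")
    cds <- vapply(cds, validate_cds, character(1L))
    crd <- coords_all[coords_all$sample_id == sample_id &
                        coords_all$gene %in% NIF_STRUCTURAL_GENES, ]
    if (nrow(crd) != 3L) {
      stop("sample ", sample_id, ": expected coordinates for nifH/nifD/nifK, ",
           "found ", nrow(crd), call. = FALSE)
    }
    cn <- parse_copy_numbers(copy_numbers, sample_id)
    list(proteins = prot, cds = cds,
         coords = crd[, c("gene", "replicon", "start", "end", "strand")],
         copy_numbers = cn)
  })

  tibble::tibble(
    sample_id = man$sample_id,
    activity = as.numeric(man$activity),
    proteins = purrr::map(samples, "proteins"),
    cds = purrr::map(samples, "cds"),
    coords = purrr::map(samples, "coords"),
    copy_numbers = purrr::map(samples, "copy_numbers")
  )
}

read_fasta_map <- function(paths, type) {
  out <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("FASTA file not found: ", p, call. = FALSE)
    set <- if (type == "AA") Biostrings::readAAStringSet(p)
           else Biostrings::readDNAStringSet(p)
    stats::setNames(as.character(set), names(set))
  })
  stats::setNames(out, paths)
}

extract_records <- function(recs, sample_id, genes, what) {
  ids <- paste(sample_id, genes, sep = "|")
  missing <- ids[!ids %in% names(recs)]
  if (length(missing)) {
    stop("sample ", sample_id, ": missing ", what, " record(s) for gene(s) ",
         paste(sub(".*\\|", "", missing), collapse = ", "), call. = FALSE)
  }
  stats::setNames(unname(recs[ids]), genes)
}

read_coords_tsv <- function(path) {
  if (!file.exists(path)) stop("coordinates file not found: ", path,
                               call. = FALSE)
  crd <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "replicon", "start", "end", "strand")
  missing_cols <- setdiff(need, names(crd))
  if (length(missing_cols)) {
    stop("coordinates file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  crd$start <- as.integer(crd$start)
  crd$end <- as.integer(crd$end)
  if (any(crd$start < 1L) || any(crd$start > crd$end)) {
    stop("invalid coordinates: need 1 <= start <= end", call. = FALSE)
  }
  if (!all(crd$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  tibble::as_tibble(crd[, need])
}

parse_copy_numbers <- function(field, sample_id) {
  vals <- suppressWarnings(as.integer(strsplit(field, ",", fixed = TRUE)[[1]]))
  if (length(vals) != 34L || anyNA(vals) || any(vals < 0L)) {
    stop("sample ", sample_id,
         ": copy_numbers must be 34 comma-separated non-negative integers",
         call. = FALSE)
  }
  stats::setNames(vals, COPY_NUMBER_GENES)
}

#' Write a nif dataset to a manifest bundle
#'
#' Writes `manifest.tsv`, `proteins.fasta`, `cds.fasta` and `coords.tsv` in
#' the dialects read back by [read_manifest()]; the write/read round trip
#' preserves every field.
#'
#' @param data A nif dataset tibble (as returned by [read_manifest()] or
#'   [generate_dataset()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  prot <- unlist(lapply(seq_len(nrow(data)), function(i) {
    stats::setNames(data$proteins[[i]],
                    paste(data$sample_id[i], names(data$proteins[[i]]),
                          sep = "|"))
  }))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(prot),
                              file.path(dir, "proteins.fasta"))
  cds <- unlist(lapply(seq_len(nrow(data)), function(i) {
    stats::setNames(data$cds[[i]],
                    paste(data$sample_id[i], names(data$cds[[i]]), sep = "|"))
  }))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds),
                              file.path(dir, "cds.fasta"))

  coords <- dplyr::bind_rows(lapply(seq_len(nrow(data)), function(i) {
    dplyr::mutate(data$coords[[i]], sample_id = data$sample_id[i],
                  .before = 1L)
  }))
  utils::write.table(coords, file.path(dir, "coords.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  man <- data.frame(
    sample_id = data$sample_id,
    activity = format_activity(data$activity),
    protein_fasta = "proteins.fasta",
    cds_fasta = "cds.fasta",
    coords_tsv = "coords.tsv",
    copy_numbers = vapply(data$copy_numbers, function(v) {
      paste(v[COPY_NUMBER_GENES], collapse = ",")
    }, character(1L))
  )
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# full-precision, locale-independent numeric formatting for manifests
format_activity <- function(x) {
  ifelse(is.na(x), "NA", vapply(x, function(v) {
    format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1L)))
}
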