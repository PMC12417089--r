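# Sequence-level protein encoders: conjoint triad (CT), dipeptide
# composition (DPC), pseudo-amino-acid composition (PAAC), plus the
# per-sample average over the three nitrogenase structural proteins.

#' Conjoint triad encoding
#'
#' Groups the 20 amino acids into 7 physicochemical classes (side-chain
#' dipole moment and volume) and counts every consecutive residue triplet by
#' its class signature, yielding a 343-dimensional (7 x 7 x 7) vector of
#' relative triplet frequencies (count / (L - 2)). Index order is a-major:
#' entry (a,b,c) sits at position (a-1)*49 + (b-1)*7 + c.
#'
#' @param seq Protein sequence (validated one-letter string).
#' @param classes Named integer vector mapping each amino acid to a class in
#'   1..7; defaults to the standard conjoint-triad grouping.
#' @param rescale If `TRUE`, apply the original min-max rescaling
#'   `(f - min) / max` instead of relative frequencies.
#' @return Named numeric vector of length 343 (`CT_111` ... `CT_777`).
#' @export
encode_ct <- function(seq, classes = CT_CLASSES, rescale = FALSE) {
  seq <- validate_protein(seq)
  check_class_map(classes)
  L <- nchar(seq)
  if (L < 3L) stop("conjoint triad needs length >= 3", call. = FALSE)
  cl <- unname(classes[strsplit(seq, "", fixed = TRUE)[[1]]])
  idx <- (cl[1:(L - 2L)] - 1L) * 49L + (cl[2:(L - 1L)] - 1L) * 7L +
    cl[3:L]
  counts <- tabulate(idx, nbins = 343L)
  out <- if (rescale) {
    f <- counts
    if (max(f) == 0) f else (f - min(f)) / max(f)
  } else {
    counts / (L - 2L)
  }
  names(out) <- ct_feature_names()
  out
}

ct_feature_names <- function() {
  g <- expand.grid(c = 1:7, b = 1:7, a = 1:7)
  paste0("CT_", g$a, g$b, g$c)
}

check_class_map <- function(classes) {
  if (!all(AA_ALPHABET %in% names(classes))) {
    stop("class map must cover the 20-letter alphabet", call. = FALSE)
  }
  if (length(unique(classes[AA_ALPHABET])) != 7L) {
    stop("class map must use exactly 7 non-empty classes", call. = FALSE)
  }
  invisible(classes)
}

#' Dipeptide composition
#'
#' Relative frequency of each ordered residue pair: entry (a,b) is the count
#' of dipeptide `ab` divided by (L - 1). Amino acids in alphabetical
#' one-letter order, row-major flatten to length 400.
#'
#' @param seq Protein sequence.
#' @return Named numeric vector of length 400 (`DPC_AA` ... `DPC_YY`).
#' @export
encode_dpc <- function(seq) {
  seq <- validate_protein(seq)
  L <- nchar(seq)
  if (L < 2L) stop("dipeptide composition needs length >= 2", call. = FALSE)
  aa_idx <- stats::setNames(seq_along(AA_ALPHABET), AA_ALPHABET)
  r <- unname(aa_idx[strsplit(seq, "", fixed = TRUE)[[1]]])
  idx <- (r[1:(L - 1L)] - 1L) * 20L + r[2:L]
  out <- tabulate(idx, nbins = 400L) / (L - 1L)
  names(out) <- dpc_feature_names()
  out
}

dpc_feature_names <- function() {
  g <- expand.grid(b = AA_ALPHABET, a = AA_ALPHABET)
  paste0("DPC_", g$a, g$b)
}

#' Pseudo-amino-acid composition configuration
#'
#' @param lambda Number of sequence-order correlation tiers (default 30,
#'   giving 20 + 30 = 50 components).
#' @param w Pseudo-component weight (default 0.05).
#' @param properties List of three named numeric property tables over the 20
#'   amino acids (hydrophobicity, hydrophilicity, side-chain mass by
#'   default); each is standardised to mean 0, population sd 1 before use.
#' @return A `paac_config` list.
#' @export
paac_config <- function(lambda = 30L, w = 0.05,
                        properties = list(PAAC_HYDROPHOBICITY,
                                          PAAC_HYDROPHILICITY,
                                          PAAC_SIDECHAIN_MASS)) {
  stopifnot(lambda >= 1L, w > 0, length(properties) >= 1L)
  std <- lapply(properties, function(p) {
    p <- p[AA_ALPHABET]
    if (anyNA(p)) stop("property table must cover the 20 amino acids",
                       call. = FALSE)
    (p - mean(p)) / sqrt(mean((p - mean(p))^2))
  })
  structure(list(lambda = as.integer(lambda), w = w, properties = std),
            class = "paac_config")
}

#' Pseudo-amino-acid composition
#'
#' The first 20 components are the amino-acid composition, damped by the
#' pseudo-component mass; components 21..(20 + lambda) carry sequence-order
#' information: tier j is `w * tau_j / (1 + w * sum(tau))`, where `tau_j` is
#' the mean over positions of the squared-difference correlation of the three
#' standardised physicochemical properties at lag j. All components sum to 1.
#'
#' @param seq Protein sequence of length > lambda.
#' @param cfg A [paac_config()].
#' @return Named numeric vector of length 20 + lambda (default 50).
#' @export
encode_paac <- function(seq, cfg = paac_config()) {
  seq <- validate_protein(seq)
  stopifnot(inherits(cfg, "paac_config"))
  L <- nchar(seq)
  if (L <= cfg$lambda) {
    stop("PAAC needs sequence length > lambda (", cfg$lambda, ")",
         call. = FALSE)
  }
  letters_in <- strsplit(seq, "", fixed = TRUE)[[1]]
  props <- vapply(cfg$properties, function(p) unname(p[letters_in]),
                  numeric(L)) # L x 3
  tau <- vapply(seq_len(cfg$lambda), function(j) {
    d <- props[1:(L - j), , drop = FALSE] - props[(1 + j):L, , drop = FALSE]
    mean(rowMeans(d^2))
  }, numeric(1L))
  f <- tabulate(match(letters_in, AA_ALPHABET), nbins = 20L) / L
  denom <- 1 + cfg$w * sum(tau)
  out <- c(f / denom, cfg$w * tau / denom)
  names(out) <- c(paste0("PAAC_", AA_ALPHABET),
                  paste0("PAAC_lam", seq_len(cfg$lambda)))
  out
}

#' Average a descriptor over the three structural proteins
#'
#' Element-wise arithmetic mean of the nifH, nifD and nifK descriptor
#' vectors. With `permissive = TRUE` a missing gene is skipped (mean over the
#' available vectors) with a warning; otherwise it is an error.
#'
#' @param vectors Named list of up to three equal-length numeric vectors
#'   (names nifH, nifD, nifK).
#' @param permissive Tolerate missing genes.
#' @return Numeric vector, the element-wise mean.
#' @export
aggregate_protein_block <- function(vectors, permissive = FALSE) {
  stopifnot(is.list(vectors))
  present <- !vapply(vectors, is.null, logical(1L))
  if (!all(present)) {
    if (!permissive) {
      stop("missing gene vector(s): ",
           paste(names(vectors)[!present], collapse = ", "), call. = FALSE)
    }
    warning("averaging over available genes only: ",
            paste(names(vectors)[present], collapse = ", "), call. = FALSE)
    vectors <- vectors[present]
  }
  if (length(vectors) == 0L) stop("no vectors to aggregate", call. = FALSE)
  lens <- vapply(vectors, length, integer(1L))
  if (length(unique(lens)) != 1L) {
    stop("vectors have mismatched lengths", call. = FALSE)
  }
  Reduce(`+`, vectors) / length(vectors)
}
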