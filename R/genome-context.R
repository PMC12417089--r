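# Genome-organisation features: the nifHDK gene distance and the 34-gene
# copy-number vector.

#' Genomic span of the nifHDK genes
#'
#' Operationalises "how far apart the three structural genes lie" as the
#' genomic span: `max(end) - min(start)` over nifH, nifD, nifK (1-based
#' inclusive coordinates). Invariant to gene order and strand. In
#' `mode = "pairwise_sum"` the sum of the three pairwise midpoint distances is
#' returned instead. Genes on different replicons are an error unless a
#' `sentinel` value is supplied. Circular replicons are treated as linear.
#'
#' @param coords Data frame with columns `gene`, `replicon`, `start`, `end`
#'   (and `strand`), one row per structural gene.
#' @param mode `"span"` (default) or `"pairwise_sum"`.
#' @param sentinel Optional value returned when genes sit on different
#'   replicons (default: error).
#' @return Non-negative scalar distance in bp.
#' @export
gene_distance <- function(coords, mode = c("span", "pairwise_sum"),
                          sentinel = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(coords),
            all(c("gene", "replicon", "start", "end") %in% names(coords)))
  coords <- coords[coords$gene %in% NIF_STRUCTURAL_GENES, ]
  if (nrow(coords) != 3L || !setequal(coords$gene, NIF_STRUCTURAL_GENES)) {
    stop("need coordinates for exactly nifH, nifD and nifK", call. = FALSE)
  }
  if (any(coords$start < 1L) || any(coords$start > coords$end)) {
    stop("invalid coordinates: need 1 <= start <= end", call. = FALSE)
  }
  if (length(unique(coords$replicon)) != 1L) {
    if (!is.null(sentinel)) return(sentinel)
    stop("nifH/nifD/nifK lie on different replicons: ",
         paste(unique(coords$replicon), collapse = ", "), call. = FALSE)
  }
  if (mode == "span") {
    max(coords$end) - min(coords$start)
  } else {
    mid <- (coords$start + coords$end) / 2
    sum(stats::dist(mid))
  }
}

#' Canonical 34-gene copy-number vector
#'
#' Arranges per-gene copy counts into the fixed 34-gene order (nifD, nifH,
#' nifK, amtB, fix/gln/nif/rnf accessory genes). Absent genes are 0 with a
#' warning; unknown gene keys are ignored with a warning.
#'
#' @param counts Named non-negative integer vector/list of gene copy counts.
#' @param quiet Suppress the absent-gene warning (used when zeros are
#'   intentional).
#' @return Named integer vector of length 34 in canonical order.
#' @export
copy_number_vector <- function(counts, quiet = FALSE) {
  counts <- unlist(counts)
  if (is.null(names(counts)) && length(counts) > 0L) {
    stop("counts must be named by gene", call. = FALSE)
  }
  if (any(counts < 0)) stop("copy counts must be non-negative", call. = FALSE)
  unknown <- setdiff(names(counts), COPY_NUMBER_GENES)
  if (length(unknown)) {
    warning("ignoring unknown gene key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- stats::setNames(integer(34L), COPY_NUMBER_GENES)
  known <- intersect(names(counts), COPY_NUMBER_GENES)
  out[known] <- as.integer(counts[known])
  absent <- setdiff(COPY_NUMBER_GENES, known)
  if (length(absent) && !quiet) {
    warning(length(absent), " gene(s) absent from counts, set to 0",
            call. = FALSE)
  }
  names(out) <- paste0("CN_", COPY_NUMBER_GENES)
  out
}
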