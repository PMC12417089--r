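# Codon-usage statistics over coding sequences: RSCU, Euclidean distance
# from neutral usage, CAI, Fop, the within-family bias statistic E, and the
# 24-dimensional expression block.

#' Relative synonymous codon usage
#'
#' For codon c in a synonymous family of size n_f with total family count
#' N_f > 0, `RSCU_c = count_c * n_f / N_f`; within an observed family the
#' values sum to the family size, and 1 means neutral usage. Codons of
#' families never observed in the gene take the `fill` value.
#'
#' @param cds Coding sequence (validated DNA string; a terminal stop codon is
#'   stripped).
#' @param fill Value assigned to codons of unobserved families (default 0; use
#'   1 for a neutral fill).
#' @return Named numeric vector of length 61 in canonical codon order.
#' @export
compute_rscu <- function(cds, fill = 0) {
  cds <- validate_cds(cds)
  tab <- codon_table_cached()
  counts <- tabulate(match(codons_of(cds), tab$codon), nbins = 61L)
  fam_tot <- tapply(counts, tab$amino_acid, sum)[tab$amino_acid]
  rscu <- ifelse(fam_tot > 0, counts * tab$family_size / fam_tot, fill)
  stats::setNames(as.numeric(rscu), tab$codon)
}

#' Euclidean distance from neutral codon usage
#'
#' `ECD = sqrt(sum_i (x_i - 1)^2)` over the 61 RSCU values, where the neutral
#' reference has RSCU 1 for every codon. All 61 entries enter the sum,
#' including fill values for unobserved families.
#'
#' @param rscu Length-61 RSCU vector.
#' @return Non-negative scalar.
#' @export
euclidean_codon_distance <- function(rscu) {
  if (length(rscu) != 61L) stop("RSCU vector must have length 61",
                                call. = FALSE)
  sqrt(sum((rscu - 1)^2))
}

#' Reference codon-usage weights
#'
#' Builds per-codon relative adaptiveness weights from a reference
#' (highly-expressed) gene set: within each synonymous family,
#' `w_c = RSCU_c / max(RSCU)` so the family's preferred codon has weight 1.
#' Codons unobserved in the reference get the floor weight.
#'
#' @param cds_list Character vector/list of reference coding sequences.
#' @param floor Minimum weight (default 1e-4), avoiding log(0) in CAI.
#' @return A `reference_usage` object: tibble with `codon`, `amino_acid`,
#'   `weight`, `optimal` (logical, the family argmax).
#' @export
reference_usage_from_cds <- function(cds_list, floor = 1e-4) {
  stopifnot(length(cds_list) >= 1L)
  tab <- codon_table_cached()
  counts <- Reduce(`+`, lapply(cds_list, function(cds) {
    tabulate(match(codons_of(validate_cds(cds)), tab$codon), nbins = 61L)
  }))
  fam_tot <- tapply(counts, tab$amino_acid, sum)[tab$amino_acid]
  rscu <- ifelse(fam_tot > 0, counts * tab$family_size / fam_tot, 0)
  fam_max <- tapply(rscu, tab$amino_acid, max)[tab$amino_acid]
  w <- ifelse(fam_max > 0, rscu / fam_max, 1)
  w <- pmax(w, floor)
  new_reference_usage(tibble::tibble(
    codon = tab$codon, amino_acid = tab$amino_acid, weight = as.numeric(w)
  ))
}

new_reference_usage <- function(df) {
  stopifnot(all(c("codon", "amino_acid", "weight") %in% names(df)))
  fam_max <- tapply(df$weight, df$amino_acid, max)
  if (any(abs(fam_max - 1) > 1e-9)) {
    stop("every synonymous family's maximum weight must be 1", call. = FALSE)
  }
  opt <- stats::ave(df$weight, df$amino_acid,
                    FUN = function(w) seq_along(w) == which.max(w))
  df$optimal <- as.logical(opt)
  structure(df, class = c("reference_usage", class(tibble::as_tibble(df))))
}

#' Read / write a reference usage table
#'
#' TSV with columns `codon` and `weight`; validated so every synonymous
#' family's maximum weight is 1.
#'
#' @param path File path.
#' @return A `reference_usage` object.
#' @export
read_reference_usage <- function(path) {
  if (!file.exists(path)) stop("reference usage file not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("codon", "weight") %in% names(df))) {
    stop("reference usage needs 'codon' and 'weight' columns", call. = FALSE)
  }
  tab <- codon_table_cached()
  m <- match(tab$codon, df$codon)
  if (anyNA(m)) stop("reference usage must cover all 61 sense codons",
                     call. = FALSE)
  new_reference_usage(tibble::tibble(
    codon = tab$codon, amino_acid = tab$amino_acid,
    weight = as.numeric(df$weight[m])
  ))
}

#' @rdname read_reference_usage
#' @param ref A `reference_usage` object.
#' @export
write_reference_usage <- function(ref, path) {
  stopifnot(inherits(ref, "reference_usage"))
  utils::write.table(ref[, c("codon", "weight")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled synthetic reference usage
#'
#' The default relative-adaptiveness table shipped with the package. It is
#' synthetic: derived once, deterministically, from the package's own
#' simulated highly-expressed gene set (it is not an organism's measured
#' usage) so that CAI/Fop are computable without external downloads.
#'
#' @return A `reference_usage` object.
#' @export
default_reference_usage <- function() {
  read_reference_usage(system.file("extdata", "reference_usage.tsv",
                                   package = "nifstack", mustWork = TRUE))
}

# codons eligible for CAI/Fop/E: members of multi-codon families
eligible_mask <- function() {
  tab <- codon_table_cached()
  tab$family_size > 1L
}

#' Codon adaptation index
#'
#' Geometric mean of the reference relative-adaptiveness weights over the
#' gene's codons, excluding the singleton families (Met, Trp). Weights are
#' floored at 1e-4 so unobserved reference codons do not force log(0).
#'
#' @param cds Coding sequence.
#' @param ref A `reference_usage` object.
#' @return Scalar in (0, 1]; 1 iff only preferred codons are used.
#' @export
compute_cai <- function(cds, ref) {
  stopifnot(inherits(ref, "reference_usage"))
  cds <- validate_cds(cds)
  tab <- codon_table_cached()
  idx <- match(codons_of(cds), tab$codon)
  idx <- idx[eligible_mask()[idx]]
  if (length(idx) == 0L) {
    stop("no codons from multi-codon families; CAI undefined", call. = FALSE)
  }
  w <- pmax(ref$weight[idx], 1e-4)
  exp(mean(log(w)))
}

#' Frequency of optimal codons
#'
#' Proportion of the gene's codons (within multi-codon families) that equal
#' their family's preferred codon in the reference set.
#'
#' @inheritParams compute_cai
#' @return Scalar in \[0, 1\].
#' @export
compute_fop <- function(cds, ref) {
  stopifnot(inherits(ref, "reference_usage"))
  cds <- validate_cds(cds)
  tab <- codon_table_cached()
  idx <- match(codons_of(cds), tab$codon)
  idx <- idx[eligible_mask()[idx]]
  if (length(idx) == 0L) {
    stop("no codons from multi-codon families; Fop undefined", call. = FALSE)
  }
  mean(ref$optimal[idx])
}

#' Within-family codon bias statistic E
#'
#' Measures deviation from uniform usage within synonymous families:
#' `E = sum_a p_a * sum_{c in a} |q_{c|a} - 1/n_a|`, where the sum runs over
#' multi-codon families observed in the gene, `p_a` is family a's share of the
#' gene's eligible codons and `q_{c|a}` the within-family codon frequency.
#' Zero iff every used family is used uniformly. This definition is specific
#' to this package (a family-share-weighted mean absolute deviation).
#'
#' @param cds Coding sequence.
#' @return Non-negative scalar, invariant to gene length at fixed within-family
#'   proportions.
#' @export
compute_bias_e <- function(cds) {
  cds <- validate_cds(cds)
  tab <- codon_table_cached()
  counts <- tabulate(match(codons_of(cds), tab$codon), nbins = 61L)
  elig <- eligible_mask()
  n_elig <- sum(counts[elig])
  if (n_elig == 0L) {
    stop("no codons from multi-codon families; E undefined", call. = FALSE)
  }
  total <- 0
  for (aa in unique(tab$amino_acid[elig])) {
    rows <- which(tab$amino_acid == aa)
    N_a <- sum(counts[rows])
    if (N_a == 0L) next
    q <- counts[rows] / N_a
    total <- total + (N_a / n_elig) * sum(abs(q - 1 / length(rows)))
  }
  total
}

#' Per-sample expression block (CAI, E, Fop for 8 genes)
#'
#' For each expression gene in the fixed order nifA, nifB, nifD, nifE, nifH,
#' nifK, nifN, nifX, computes the triple (CAI, E, Fop), giving a length-24
#' vector. A missing gene contributes (0, 0, 0) with a warning.
#'
#' @param cds Named list/character vector of coding sequences (names are gene
#'   symbols).
#' @param ref A `reference_usage` object.
#' @return Named numeric vector of length 24.
#' @export
expression_block <- function(cds, ref) {
  present <- EXPRESSION_GENES %in% names(cds)
  if (!any(present)) stop("all 8 expression genes missing", call. = FALSE)
  if (!all(present)) {
    warning("missing expression gene(s) scored as 0: ",
            paste(EXPRESSION_GENES[!present], collapse = ", "),
            call. = FALSE)
  }
  vals <- lapply(EXPRESSION_GENES, function(g) {
    if (!g %in% names(cds)) return(c(0, 0, 0))
    c(compute_cai(cds[[g]], ref), compute_bias_e(cds[[g]]),
      compute_fop(cds[[g]], ref))
  })
  out <- unlist(vals)
  names(out) <- paste0("EXPR_", rep(EXPRESSION_GENES, each = 3L), "_",
                       c("CAI", "E", "Fop"))
  out
}

#' Average a codon descriptor over the three structural genes
#'
#' Element-wise mean of nifH/nifD/nifK codon-level descriptors (RSCU vectors
#' or scalar distances); same contract as [aggregate_protein_block()].
#'
#' @inheritParams aggregate_protein_block
#' @export
aggregate_codon_block <- function(vectors, permissive = FALSE) {
  aggregate_protein_block(vectors, permissive = permissive)
}
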