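#' Canonical alphabets and gene rosters
#'
#' Internal constants shared across the feature encoders: the 20-letter amino
#' acid alphabet (alphabetical one-letter order), the conjoint-triad residue
#' classes, the 61 sense codons of the standard genetic code, the eight
#' expression genes scored with CAI/E/Fop, and the 34-gene copy-number roster.
#'
#' @name nifstack-constants
#' @keywords internal
NULL

# 20 canonical amino acids, alphabetical one-letter order (Ala ... Tyr)
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguous / non-standard residue letters rejected by default
AA_AMBIGUOUS <- c("B", "Z", "X", "U", "O", "J")

# Conjoint-triad grouping of the 20 amino acids into 7 classes by side-chain
# dipole moment and volume. Shipped as the default ResidueClassMap; any map
# covering the alphabet with 7 non-empty classes can be swapped in.
CT_CLASSES <- c(
  A = 1L, G = 1L, V = 1L,
  I = 2L, L = 2L, F = 2L, P = 2L,
  Y = 3L, M = 3L, T = 3L, S = 3L,
  H = 4L, N = 4L, Q = 4L, W = 4L,
  R = 5L, K = 5L,
  D = 6L, E = 6L,
  C = 7L
)[AA_ALPHABET]

# Classical physicochemical property tables used by the pseudo-amino-acid
# composition: hydrophobicity, hydrophilicity (Hopp-Woods), side-chain mass.
# Standardised (mean 0, population sd 1 over the 20 residues) before use.
PAAC_HYDROPHOBICITY <- c(
  A =  0.62, C =  0.29, D = -0.90, E = -0.74, F =  1.19,
  G =  0.48, H = -0.40, I =  1.38, K = -1.50, L =  1.06,
  M =  0.64, N = -0.78, P =  0.12, Q = -0.85, R = -2.53,
  S = -0.18, T = -0.05, V =  1.08, W =  0.81, Y =  0.26
)
PAAC_HYDROPHILICITY <- c(
  A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5,
  G =  0.0, H = -0.5, I = -1.8, K =  3.0, L = -1.8,
  M = -1.3, N =  0.2, P =  0.0, Q =  0.2, R =  3.0,
  S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3
)
PAAC_SIDECHAIN_MASS <- c(
  A =  15.0, C =  47.0, D =  59.0, E =  73.0, F =  91.0,
  G =   1.0, H =  82.0, I =  57.0, K =  73.0, L =  57.0,
  M =  75.0, N =  58.0, P =  42.0, Q =  72.0, R = 101.0,
  S =  31.0, T =  45.0, V =  43.0, W = 130.0, Y = 107.0
)

# Structural genes of molybdenum nitrogenase (protein features)
NIF_STRUCTURAL_GENES <- c("nifH", "nifD", "nifK")

# The eight genes scored with CAI / E / Fop expression indices, fixed order
EXPRESSION_GENES <- c("nifA", "nifB", "nifD", "nifE",
                      "nifH", "nifK", "nifN", "nifX")

# Canonical 34-gene roster for the copy-number feature, fixed order
COPY_NUMBER_GENES <- c(
  "nifD", "nifH", "nifK", "amtB", "fixA", "fixB", "fixC", "fixX",
  "glnK", "glnA", "nifA", "nifB", "nifE", "nifF", "nifJ", "nifL",
  "nifM", "nifN", "nifP", "nifQ", "nifS", "nifT", "nifU", "nifV",
  "nifW", "nifX", "nifY", "nifZ", "rnfA", "rnfB", "rnfC", "rnfD",
  "rnfE", "rnfG"
)

# Declared widths of supported protein language-model embedding sources;
# unknown source tags accept any width.
EMBEDDING_WIDTHS <- c(
  ProtT5      = 1024L,
  ProteinBERT = 512L,
  Ankh        = 1536L,
  ESMC_300M   = 960L,
  ESMC_600M   = 1152L,
  ESMC_6B     = 2560L
)

#' Standard genetic code codon table
#'
#' The 61 sense codons of the standard genetic code (NCBI transl_table=1),
#' ordered lexicographically over A < C < G < T with the three stop codons
#' (TAA, TAG, TGA) excluded, together with the encoded amino acid and the
#' synonymous-family size. GTG/TTG bacterial start codons are counted as their
#' standard amino acids (Val, Leu).
#'
#' @return A tibble with columns `codon`, `amino_acid`, and `family_size`,
#'   one row per sense codon in canonical order.
#' @examples
#' tab <- codon_table()
#' nrow(tab) # 61
#' @export
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- sort(names(gc)[gc != "*"]) # lexicographic, A<C<G<T
  aa <- unname(gc[codons])
  fam <- table(aa)
  tibble::tibble(
    codon = codons,
    amino_acid = aa,
    family_size = as.integer(fam[aa])
  )
}

# cached codon table (built lazily; Biostrings load order safe)
.codon_env <- new.env(parent = emptyenv())
codon_table_cached <- function() {
  if (is.null(.codon_env$tab)) .codon_env$tab <- codon_table()
  .codon_env$tab
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Feature group widths
#'
#' Fixed dimensionalities of the handcrafted feature groups: conjoint triad
#' 343 (7^3), dipeptide composition 400 (20^2), pseudo-amino-acid composition
#' 50 (20 + 30), relative synonymous codon usage 61, codon-usage Euclidean
#' distance 1, expression indices 24 (8 genes x CAI/E/Fop), gene distance 1,
#' copy number 34. The embedding group width depends on its source.
#'
#' @return Named integer vector of widths.
#' @export
feature_group_widths <- function() {
  c(CT = 343L, DPC = 400L, PAAC = 50L, RSCU = 61L,
    Euclidean_distance = 1L, Expression = 24L,
    Gene_distance = 1L, Copy_number = 34L)
}
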