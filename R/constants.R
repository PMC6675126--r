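# Amino-acid alphabet and embedded constant scales.

#' The 20 standard amino acids
#'
#' One-letter codes in alphabetical order. All frequency profiles in the
#' package are indexed by this vector, in this order.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Residues tolerated in input sequences but excluded from frequency counting
# (ambiguity codes and rare translated residues). They still count towards
# protein length.
.nonstandard_residues <- c("X", "B", "Z", "U", "O")

# TOP-IDP disorder-propensity scale (Campen et al. 2008, published constants).
# Higher values = more disorder-promoting; proline is the extreme promoter,
# tryptophan the extreme order promoter.
.topidp <- c(
  A =  0.060, C =  0.020, D =  0.192, E =  0.736, F = -0.697,
  G =  0.166, H =  0.303, I = -0.486, K =  0.586, L = -0.326,
  M = -0.397, N =  0.007, P =  0.987, Q =  0.318, R =  0.180,
  S =  0.341, T =  0.059, V = -0.121, W = -0.884, Y = -0.510
)

#' TOP-IDP disorder-propensity scale
#'
#' Published per-amino-acid disorder propensities. The scale is used for mean
#' disorder propensities of sequences and profiles, for the built-in window
#' predictor, and as the weights of the per-amino-acid contribution
#' decomposition.
#'
#' @return Named numeric vector of length 20 (names are one-letter codes in
#'   the order of [amino_acids()]).
#' @export
#' @examples
#' topidp_scale()[["P"]] # proline, the strongest disorder promoter
topidp_scale <- function() {
  .topidp[amino_acids()]
}

# Reference amino-acid frequencies (percent) per kingdom x region type, from
# large-scale proteome surveys of shared-domain proteins. Rows are three-letter
# coded residues in the conventional presentation order; used as the planted
# default compositions of the synthetic-proteome generator. Columns do not sum
# to exactly 100 because of presentation rounding; consumers renormalize.
.reference_pct <- matrix(
  c(
    # euk: shared, specific, linker | bac: shared, specific, linker
    # | arc: shared, specific, linker
    1.5, 1.3, 1.1, 1.0, 1.0, 1.1, 1.0, 0.8, 1.1,  # Trp (W)
    4.6, 4.3, 3.6, 4.3, 4.2, 4.2, 4.0, 3.8, 3.9,  # Phe (F)
    3.4, 3.3, 2.7, 3.4, 3.5, 3.4, 3.6, 3.6, 3.8,  # Tyr (Y)
    6.3, 5.8, 4.9, 7.5, 7.2, 6.9, 8.1, 7.9, 7.8,  # Ile (I)
    2.3, 2.1, 2.2, 2.4, 2.1, 2.9, 2.3, 2.0, 3.0,  # Met (M)
    9.8, 9.8, 8.8, 9.8, 9.9, 9.7, 9.5, 9.5, 9.5,  # Leu (L)
    7.1, 6.5, 5.8, 7.2, 7.0, 6.2, 7.9, 7.8, 7.1,  # Val (V)
    4.2, 4.4, 4.5, 4.2, 4.6, 4.8, 3.9, 4.5, 4.4,  # Asn (N)
    1.8, 2.2, 1.5, 1.0, 1.0, 0.8, 1.1, 1.2, 0.9,  # Cys (C)
    5.5, 5.4, 5.7, 5.3, 5.4, 5.5, 5.0, 4.8, 4.9,  # Thr (T)
    7.6, 7.4, 7.5, 8.4, 8.2, 7.5, 7.8, 7.5, 6.4,  # Ala (A)
    7.3, 6.1, 6.0, 7.6, 7.2, 6.0, 7.9, 7.7, 6.5,  # Gly (G)
    5.0, 5.5, 5.8, 4.7, 4.6, 4.9, 5.1, 5.4, 5.6,  # Arg (R)
    5.4, 5.5, 5.6, 5.4, 5.7, 5.4, 5.4, 5.8, 5.4,  # Asp (D)
    2.5, 2.6, 2.4, 2.1, 1.9, 1.8, 1.8, 1.7, 1.6,  # His (H)
    3.4, 3.9, 4.2, 3.5, 3.8, 4.0, 2.2, 2.2, 2.4,  # Gln (Q)
    6.8, 7.1, 8.9, 5.9, 6.1, 6.5, 5.9, 5.9, 6.3,  # Ser (S)
    5.3, 6.0, 5.8, 6.0, 6.3, 7.2, 6.2, 6.7, 7.3,  # Lys (K)
    5.7, 6.5, 6.7, 6.4, 6.6, 7.0, 7.0, 7.5, 7.9,  # Glu (E)
    4.4, 4.2, 5.9, 3.9, 3.6, 4.0, 4.2, 3.7, 4.3   # Pro (P)
  ),
  nrow = 20, byrow = TRUE,
  dimnames = list(
    c("W", "F", "Y", "I", "M", "L", "V", "N", "C", "T",
      "A", "G", "R", "D", "H", "Q", "S", "K", "E", "P"),
    c("eukaryote.shared_domain", "eukaryote.specific_domain",
      "eukaryote.linker",
      "bacterium.shared_domain", "bacterium.specific_domain",
      "bacterium.linker",
      "archaeon.shared_domain", "archaeon.specific_domain",
      "archaeon.linker")
  )
)

#' Reference kingdom-by-region amino-acid compositions
#'
#' Frequencies (fractions summing to 1 per column) of the 20 amino acids in
#' shared domains, specific domains and linker regions of shared-domain
#' proteins from the three kingdoms, as observed in large-scale proteome
#' surveys. These are the default compositions planted by
#' [synthetic_spec()]: the generator emits each region's residues i.i.d. from
#' the matching column, so pipeline estimates can be compared back to them.
#'
#' @param normalize Renormalize each column to sum to exactly 1 (default).
#'   With `FALSE` the columns are the printed percentages divided by 100,
#'   which sum to 1 only up to presentation rounding.
#' @return 20 x 9 numeric matrix; rows ordered as [amino_acids()], columns
#'   named `<kingdom>.<region_type>`.
#' @export
reference_compositions <- function(normalize = TRUE) {
  m <- .reference_pct[amino_acids(), ] / 100
  if (normalize)
    m <- sweep(m, 2, colSums(m), "/")
  m
}

.kingdoms <- c("eukaryote", "bacterium", "archaeon")
.region_types <- c("shared_domain", "specific_domain", "linker")
.protein_groups <- c("shared_protein", "kingdom_specific_protein",
                     "no_domain_protein")
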