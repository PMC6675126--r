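# GC-parameterized codon-usage null model for amino-acid frequencies.
#
# Under the null, the three codon positions are filled i.i.d. with
# P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2; stop codons are excluded
# and the 61 sense-codon probabilities renormalized, giving the expected
# amino-acid frequencies from codon structure alone (one GC parameter, no
# positional GC).

# Standard genetic code, named by codon; "*" marks stops.
.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

# Per-codon occurrence probability at a given GC. Internal.
.codon_probs <- function(gc) {
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  codons <- names(.genetic_code())
  m <- matrix(unlist(strsplit(codons, "", fixed = TRUE)),
              ncol = 3, byrow = TRUE)
  stats::setNames(base_p[m[, 1]] * base_p[m[, 2]] * base_p[m[, 3]], codons)
}

#' Expected amino-acid frequencies from codon usage alone
#'
#' @param gc Genomic GC fraction in `[0, 1]` (the closed limits are handled:
#'   at `gc = 1` only the eight G/C-only sense codons survive, giving
#'   Ala = Gly = Pro = Arg = 0.25).
#' @return Named numeric vector of 20 expected frequencies summing to 1,
#'   ordered as [amino_acids()].
#' @export
#' @examples
#' expected_aa_freq(0.5)[["S"]] # 6/61: serine has six codons
expected_aa_freq <- function(gc) {
  if (!is.numeric(gc) || length(gc) != 1 || is.na(gc) || gc < 0 || gc > 1)
    stop("gc must be a single value in [0, 1]")
  code <- .genetic_code()
  p <- .codon_probs(gc)
  sense <- code != "*"
  p <- p[sense] / sum(p[sense])
  freq <- tapply(p, code[sense], sum)
  out <- stats::setNames(numeric(20), amino_acids())
  out[names(freq)] <- freq
  out
}

#' Base composition of an amino acid's codon set
#'
#' Fraction of one nucleotide among all positions of all codons of an amino
#' acid, e.g. the adenosine fraction of the isoleucine codons
#' (ATT, ATC, ATA) is 4/9, printing as 44%.
#'
#' @param amino_acid One-letter code of a standard amino acid.
#' @param base One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' codon_base_fraction("I", "A") # 4/9
codon_base_fraction <- function(amino_acid, base) {
  if (!is.character(amino_acid) || length(amino_acid) != 1 ||
      !amino_acid %in% amino_acids())
    stop("unknown amino acid: ", amino_acid)
  if (!is.character(base) || length(base) != 1 ||
      !base %in% c("A", "C", "G", "T"))
    stop("unknown base: ", base)
  code <- .genetic_code()
  codons <- names(code)[code == amino_acid]
  chars <- unlist(strsplit(codons, "", fixed = TRUE))
  sum(chars == base) / length(chars)
}

#' Observed vs codon-null expected frequencies across genomes
#'
#' For each amino acid, pairs every genome's observed frequency with its GC,
#' fits an ordinary least-squares line per kingdom (omitted, with a message
#' in the output, for kingdoms with fewer than two genomes), and samples the
#' codon-usage null curve on a GC grid.
#'
#' @param genome_freqs Data frame with columns `genome_id`, `kingdom`, `gc`
#'   and one column per amino acid (one-letter codes) holding observed
#'   frequencies.
#' @param gc_grid Numeric vector of GC values for the null curve.
#' @return List with `points` (the input, long format: genome_id, kingdom,
#'   gc, aa, observed), `fits` (kingdom, aa, slope, intercept, n), and
#'   `null_curve` (gc, aa, expected).
#' @export
observed_vs_expected <- function(genome_freqs,
                                 gc_grid = seq(0.2, 0.6, by = 0.01)) {
  aa <- amino_acids()
  missing_aa <- setdiff(aa, names(genome_freqs))
  if (length(missing_aa))
    stop("genome_freqs lacks amino-acid column(s): ",
         paste(missing_aa, collapse = ", "))
  pts <- do.call(rbind, lapply(aa, function(a)
    data.frame(genome_id = genome_freqs$genome_id,
               kingdom = genome_freqs$kingdom,
               gc = genome_freqs$gc, aa = a,
               observed = genome_freqs[[a]],
               stringsAsFactors = FALSE)))
  fits <- list()
  for (k in sort(unique(genome_freqs$kingdom))) {
    sub <- genome_freqs[genome_freqs$kingdom == k, , drop = FALSE]
    if (nrow(sub) < 2) next
    for (a in aa) {
      co <- stats::coef(stats::lm(sub[[a]] ~ sub$gc))
      fits[[length(fits) + 1]] <- data.frame(
        kingdom = k, aa = a, slope = unname(co[2]),
        intercept = unname(co[1]), n = nrow(sub),
        stringsAsFactors = FALSE)
    }
  }
  fits <- if (length(fits)) do.call(rbind, fits) else
    data.frame(kingdom = character(0), aa = character(0),
               slope = numeric(0), intercept = numeric(0), n = integer(0))
  null_curve <- do.call(rbind, lapply(gc_grid, function(g) {
    e <- expected_aa_freq(g)
    data.frame(gc = g, aa = names(e), expected = unname(e),
               stringsAsFactors = FALSE)
  }))
  list(points = pts, fits = fits, null_curve = null_curve)
}
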