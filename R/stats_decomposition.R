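# Statistical layer: propensity-contribution decomposition, leave-out
# comparisons, t-tests, standard errors, and the GC-adjusted kingdom ANOVA.

#' Per-amino-acid disorder-propensity contributions
#'
#' Decomposes the difference in mean TOP-IDP propensity between two
#' compositions into per-amino-acid contributions
#' `c_aa = s_aa * (f_other,aa - f_baseline,aa)` with `s_aa` the TOP-IDP
#' value and the deltas on the fractional scale. The contributions are
#' exactly additive: their sum equals
#' `topidp_mean(other) - topidp_mean(baseline)`.
#'
#' @param baseline,other Profiles, named frequency vectors or sequences
#'   (`baseline` conventionally eukaryotic).
#' @return Data frame with one row per amino acid (`aa`, `scale`, `delta`,
#'   `contribution`), sorted by ascending TOP-IDP propensity (the
#'   conventional axis order for this decomposition).
#' @export
propensity_contribution <- function(baseline, other) {
  s <- topidp_scale()
  d <- frequency_difference(baseline, other, percentage = FALSE)
  out <- data.frame(aa = names(s), scale = unname(s),
                    delta = unname(d[names(s)]),
                    contribution = unname(s * d[names(s)]),
                    stringsAsFactors = FALSE)
  out[order(out$scale), , drop = FALSE]
}

#' Propensity difference with amino acids left out
#'
#' Restricts both compositions to the amino acids not in `excluded`,
#' renormalizes each to sum to 1, and returns the difference of mean TOP-IDP
#' propensities (`other - baseline`). Used to ask whether a disorder gap
#' survives once the headline shifted residues (by default Ser, Pro, Ile)
#' are ignored.
#'
#' @param baseline,other Profiles, named frequency vectors or sequences.
#' @param excluded Character vector of one-letter codes (default
#'   `c("S", "P", "I")`); must leave at least one amino acid.
#' @return Single numeric difference.
#' @export
leave_out_propensity_diff <- function(baseline, other,
                                      excluded = c("S", "P", "I")) {
  excluded <- unique(excluded)
  bad <- setdiff(excluded, amino_acids())
  if (length(bad)) stop("unknown amino acid(s): ", paste(bad, collapse = ", "))
  keep <- setdiff(amino_acids(), excluded)
  if (!length(keep)) stop("cannot exclude all 20 amino acids")
  s <- topidp_scale()[keep]
  restrict <- function(x) {
    f <- .as_freqs(x)[keep]
    if (sum(f) <= 0) stop("profile has no mass outside the excluded set")
    f / sum(f)
  }
  sum(restrict(other) * s) - sum(restrict(baseline) * s)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Classic equal-variance two-sample t with a two-sided P-value, via
#' [stats::t.test()]. Degenerate inputs are resolved before the call: zero
#' pooled variance gives `t = 0, P = 1` when the means agree and an infinite
#' t with `P = 0` when they differ.
#'
#' @param a,b Numeric vectors, each of length at least 2.
#' @return List with `t`, `df`, `p`.
#' @export
students_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least two observations")
  df <- length(a) + length(b) - 2
  pooled <- ((length(a) - 1) * stats::var(a) +
             (length(b) - 1) * stats::var(b)) / df
  if (pooled == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by `sqrt(n)`.
#'
#' @param x Numeric vector, length at least 2.
#' @return Single numeric value.
#' @export
standard_error <- function(x) {
  if (length(x) < 2) stop("need at least two observations")
  stats::sd(x) / sqrt(length(x))
}

#' GC-adjusted kingdom effect on per-genome amino-acid frequencies
#'
#' For each amino acid, fits `freq ~ gc + kingdom` by least squares and
#' tests the kingdom factor with the extra-sum-of-squares F-test against the
#' GC-only model — a covariate-adjusted reading of a two-factor analysis
#' with genomic GC. Optionally GC can be binned into a factor
#' (`gc_bins > 0`) for a classical two-factor layout.
#'
#' @param freqs Matrix or data frame of per-genome frequencies, one column
#'   per amino acid (one-letter names), one row per genome.
#' @param kingdom Character/factor vector of kingdom labels per genome; at
#'   least two distinct values.
#' @param gc Numeric GC fraction per genome.
#' @param gc_bins If positive, cut `gc` into that many equal-width bins and
#'   use the bin factor instead of the continuous covariate.
#' @return Data frame with one row per amino acid: `aa`, `F`, `p`, `df1`,
#'   `df2`.
#' @export
anova_kingdom_gc <- function(freqs, kingdom, gc, gc_bins = 0) {
  freqs <- as.data.frame(freqs)
  if (length(kingdom) != nrow(freqs) || length(gc) != nrow(freqs))
    stop("kingdom and gc must have one entry per genome row")
  kingdom <- factor(kingdom)
  if (nlevels(kingdom) < 2)
    stop("need at least two kingdoms for the kingdom effect")
  if (nrow(freqs) < 3) stop("need at least three genomes")
  gcv <- if (gc_bins > 0) cut(gc, breaks = gc_bins) else gc
  aa <- intersect(amino_acids(), names(freqs))
  if (!length(aa)) stop("no amino-acid columns found")
  rows <- lapply(aa, function(a) {
    y <- freqs[[a]]
    full <- stats::lm(y ~ gcv + kingdom)
    reduced <- stats::lm(y ~ gcv)
    cmp <- stats::anova(reduced, full)
    data.frame(aa = a, F = cmp$F[2], p = cmp$`Pr(>F)`[2],
               df1 = cmp$Df[2], df2 = cmp$Res.Df[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
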