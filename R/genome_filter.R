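# Dataset hygiene: GC computation, extreme-GC genome exclusion, and
# alternative-codon-usage taxon exclusion.

#' GC fraction of a nucleotide sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; `N` is excluded from both counts.
#'
#' @param sequence Nucleotide sequence over `A/C/G/T/N` (single string,
#'   case-insensitive).
#' @return Fraction in `[0, 1]`.
#' @export
compute_gc <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1)
    stop("sequence must be a single string")
  s <- toupper(sequence)
  bad <- gsub("[ACGTN]", "", s)
  if (nzchar(bad))
    stop("non-nucleotide character(s): ",
         paste(unique(strsplit(bad, "", fixed = TRUE)[[1]]), collapse = ", "))
  dna <- Biostrings::DNAString(s)
  cnt <- Biostrings::letterFrequency(dna, letters = c("A", "C", "G", "T"))
  total <- sum(cnt)
  if (total == 0) stop("no informative bases: GC undefined")
  unname((cnt[["C"]] + cnt[["G"]]) / total)
}

#' Filter genomes by GC bounds and excluded genera
#'
#' Retains genomes with GC in `[min_gc, max_gc]` (inclusive bounds — the
#' exclusion targets genomes with *more* than the upper or *less* than the
#' lower bound) whose genus is not in the exclusion list of
#' alternative-codon-usage clades.
#'
#' @param genomes Genome metadata data frame (`genome_id`, `kingdom`,
#'   `phylum`, `genus`, `gc`).
#' @param min_gc,max_gc Inclusive GC bounds (defaults 0.20, 0.60).
#' @param excluded_genera Genera dropped regardless of GC (defaults:
#'   Mycoplasma, Spiroplasma, Ureaplasma, Mesoplasma — clades with
#'   non-standard codon usage).
#' @return List with `retained`, `excluded` (data frames partitioning the
#'   input) and `report`: one row per kingdom with `n_total`,
#'   `n_excluded_gc`, `n_excluded_taxon`, `pct_excluded` (rounded to the
#'   nearest integer percent).
#' @export
filter_genomes <- function(genomes, min_gc = 0.20, max_gc = 0.60,
                           excluded_genera = c("Mycoplasma", "Spiroplasma",
                                               "Ureaplasma", "Mesoplasma")) {
  if (any(is.na(genomes$gc)))
    stop("gc must be populated for every genome")
  taxon_out <- genomes$genus %in% excluded_genera
  gc_out <- !taxon_out & (genomes$gc < min_gc | genomes$gc > max_gc)
  excluded <- genomes[taxon_out | gc_out, , drop = FALSE]
  retained <- genomes[!(taxon_out | gc_out), , drop = FALSE]
  report <- do.call(rbind, lapply(.kingdoms, function(k) {
    sel <- genomes$kingdom == k
    n <- sum(sel)
    data.frame(kingdom = k, n_total = n,
               n_excluded_gc = sum(gc_out & sel),
               n_excluded_taxon = sum(taxon_out & sel),
               pct_excluded = if (n > 0)
                 round(100 * sum((gc_out | taxon_out) & sel) / n) else 0,
               stringsAsFactors = FALSE)
  }))
  list(retained = retained, excluded = excluded, report = report)
}
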