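# Per-region disorder quantification: TOP-IDP propensity means,
# threshold-based disorder fractions from score tracks, and group/region
# disorder summaries.

#' Mean TOP-IDP disorder propensity
#'
#' For a sequence, the mean of the per-residue scale values (non-standard
#' residues excluded); for a frequency profile, the dot product of the
#' frequencies with the scale. The two forms agree exactly on the same
#' composition.
#'
#' @param x An amino-acid sequence (character scalar or vector, pooled), an
#'   [aa_profile()], or a named 20-vector of frequencies.
#' @return Single numeric propensity.
#' @export
#' @examples
#' topidp_mean("P") == topidp_scale()[["P"]]
topidp_mean <- function(x) {
  f <- .as_freqs(x)
  sum(f * topidp_scale())
}

#' Disorder fraction of a score track over intervals
#'
#' Fraction of residues whose predictor score is strictly above the
#' threshold (a score of exactly 0.4 counts as ordered, following the
#' "higher than 0.4" convention).
#'
#' @param scores Numeric per-residue scores.
#' @param intervals Optional two-column matrix/data frame of 1-based
#'   inclusive `start`, `end` intervals; default is the whole track.
#' @param threshold Binarization threshold (default 0.4).
#' @return Fraction in `[0, 1]`.
#' @export
disorder_fraction <- function(scores, intervals = NULL, threshold = 0.4) {
  idx <- .interval_indices(intervals, length(scores))
  if (!length(idx)) stop("empty interval set")
  mean(scores[idx] > threshold)
}

# Residue indices covered by an interval table (or the whole 1:L). Internal.
.interval_indices <- function(intervals, L) {
  if (is.null(intervals)) return(seq_len(L))
  intervals <- as.data.frame(intervals)
  if (!nrow(intervals)) return(integer(0))
  st <- intervals[[intersect(c("start", 1), names(intervals))[1]]]
  en <- intervals[[intersect(c("end", 2), names(intervals))[1]]]
  if (any(st < 1) || any(en > L) || any(en < st))
    stop("intervals must satisfy 1 <= start <= end <= track length")
  unlist(mapply(seq.int, st, en, SIMPLIFY = FALSE))
}

#' Built-in window-smoothed propensity predictor
#'
#' A self-contained per-residue disorder score: the TOP-IDP value of each
#' residue is averaged over a centred window (truncated at the termini) and
#' min-max normalized to `[0, 1]` using the scale's own extreme values, so a
#' poly-proline stretch scores 1 and a poly-tryptophan stretch 0. It is a
#' simple composition-based smoother intended for self-contained runs and
#' testing; it is not an energy-based predictor, and runs consuming it are
#' flagged as such in output metadata. Non-standard residues are excluded
#' from the window average.
#'
#' @param sequence Amino-acid sequence (single string).
#' @param window Odd window width >= 1 (default 21).
#' @return Numeric vector of per-residue scores in `[0, 1]`.
#' @export
builtin_window_predictor <- function(sequence, window = 21) {
  if (window < 1 || window %% 2 == 0)
    stop("window must be odd and >= 1")
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(res)
  if (!L) stop("empty sequence")
  s <- topidp_scale()[res]           # NA for non-standard residues
  half <- (window - 1) / 2
  val <- ifelse(is.na(s), 0, s)
  cnt <- as.numeric(!is.na(s))
  cv <- cumsum(c(0, val))
  cc <- cumsum(c(0, cnt))
  lo <- pmax(seq_len(L) - half, 1)
  hi <- pmin(seq_len(L) + half, L)
  sums <- cv[hi + 1] - cv[lo]
  ns <- cc[hi + 1] - cc[lo]
  m <- ifelse(ns > 0, sums / ns, NA_real_)
  rng <- range(topidp_scale())
  out <- (m - rng[1]) / (rng[2] - rng[1])
  # windows with no standard residue: no information, midpoint score
  out[is.na(out)] <- 0.5
  unname(pmin(pmax(out, 0), 1))
}

#' Disorder summary per kingdom and region type / protein group
#'
#' Computes, for each (kingdom, region type) over shared proteins and each
#' (kingdom, protein group) over all proteins: the pooled residue-weighted
#' disorder fraction, the per-protein mean number of disordered residues
#' with its standard error, and the per-protein mean region length with its
#' standard error. Proteins without a score track are skipped with a
#' warning and counted.
#'
#' @param regions Region table from [segment_regions()].
#' @param groups Protein-group table from [assign_groups()].
#' @param proteins,genomes Protein and genome tables.
#' @param tracks Named list of per-residue score vectors.
#' @param threshold Disorder threshold (default 0.4).
#' @return List with `by_region` and `by_group` data frames (columns:
#'   `kingdom`, `region_type`/`group`, `n_proteins`, `mean_length`,
#'   `se_length`, `pooled_disorder_fraction`, `mean_disordered`,
#'   `se_disordered`) and `n_missing_tracks`.
#' @export
regional_disorder_summary <- function(regions, groups, proteins, genomes,
                                      tracks, threshold = 0.4) {
  kingdom <- .kingdom_of(proteins, genomes)
  len_by_id <- stats::setNames(nchar(proteins$sequence), proteins$protein_id)
  have <- names(tracks)

  missing_region <- setdiff(unique(regions$protein_id), have)
  missing_group <- setdiff(unique(groups$protein_id), have)
  n_missing <- length(unique(c(missing_region, missing_group)))
  if (n_missing)
    warning(n_missing, " protein(s) lack disorder tracks and were skipped")

  reg <- regions[regions$protein_id %in% have, , drop = FALSE]
  dis_cnt <- numeric(nrow(reg))
  for (i in seq_len(nrow(reg))) {
    sc <- tracks[[reg$protein_id[i]]]
    dis_cnt[i] <- sum(sc[reg$start[i]:reg$end[i]] > threshold)
  }
  reg_len <- reg$end - reg$start + 1

  # collapse multiple intervals of one type within a protein
  key <- paste(reg$protein_id, reg$region_type, sep = "\r")
  agg_len <- tapply(reg_len, key, sum)
  agg_dis <- tapply(dis_cnt, key, sum)
  per <- data.frame(
    protein_id = sub("\r.*", "", names(agg_len)),
    region_type = sub(".*\r", "", names(agg_len)),
    length = as.numeric(agg_len),
    disordered = as.numeric(agg_dis),
    stringsAsFactors = FALSE)
  per$kingdom <- kingdom[per$protein_id]

  summarize <- function(d, label_col) {
    out <- list()
    for (k in .kingdoms) for (v in unique(d[[label_col]])) {
      sub <- d[d$kingdom == k & d[[label_col]] == v, , drop = FALSE]
      if (!nrow(sub)) next
      frac <- sub$disordered / sub$length
      out[[length(out) + 1]] <- data.frame(
        kingdom = k, label = v, n_proteins = nrow(sub),
        mean_length = mean(sub$length),
        se_length = if (nrow(sub) > 1) standard_error(sub$length) else NA_real_,
        pooled_disorder_fraction = sum(sub$disordered) / sum(sub$length),
        mean_disorder_fraction = mean(frac),
        se_disorder_fraction = if (nrow(sub) > 1) standard_error(frac)
                               else NA_real_,
        mean_disordered = mean(sub$disordered),
        se_disordered = if (nrow(sub) > 1) standard_error(sub$disordered)
                        else NA_real_,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  by_region <- summarize(per, "region_type")
  if (!is.null(by_region)) names(by_region)[2] <- "region_type"

  grp <- groups[groups$protein_id %in% have, , drop = FALSE]
  gl <- len_by_id[grp$protein_id]
  gd <- vapply(grp$protein_id,
               function(p) sum(tracks[[p]] > threshold), numeric(1))
  gdat <- data.frame(protein_id = grp$protein_id, group = grp$group,
                     length = as.numeric(gl), disordered = as.numeric(gd),
                     kingdom = kingdom[grp$protein_id],
                     stringsAsFactors = FALSE)
  by_group <- summarize(gdat, "group")
  if (!is.null(by_group)) names(by_group)[2] <- "group"

  list(by_region = by_region, by_group = by_group,
       n_missing_tracks = n_missing)
}
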