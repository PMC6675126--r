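# Amino-acid frequency profiles and composition comparisons.

#' Construct an amino-acid frequency profile
#'
#' @param counts Named integer vector of residue counts over the 20 standard
#'   amino acids (missing names are zero-filled).
#' @return An `aa_profile`: list with `counts`, `freqs` (counts/n) and `n`.
#' @export
aa_profile <- function(counts) {
  aa <- amino_acids()
  full <- stats::setNames(numeric(20), aa)
  if (length(counts)) {
    if (is.null(names(counts)))
      stop("counts must be named by one-letter amino-acid codes")
    bad <- setdiff(names(counts), aa)
    if (length(bad))
      stop("unknown amino acid(s) in counts: ", paste(bad, collapse = ", "))
    if (any(counts < 0)) stop("counts must be non-negative")
    full[names(counts)] <- counts
  }
  n <- sum(full)
  structure(
    list(counts = full, freqs = if (n > 0) full / n else full, n = n),
    class = "aa_profile"
  )
}

#' @export
print.aa_profile <- function(x, ...) {
  cat("Amino-acid frequency profile (n =", format(x$n, big.mark = ","),
      "residues)\n")
  print(round(x$freqs, 4))
  invisible(x)
}

# Coerce sequences / profiles / named frequency vectors to a frequency vector
# over amino_acids(). Internal.
.as_freqs <- function(x) {
  if (inherits(x, "aa_profile")) return(x$freqs)
  if (is.numeric(x)) {
    if (is.null(names(x)) && length(x) == 20) names(x) <- amino_acids()
    if (!setequal(names(x), amino_acids()))
      stop("frequency vector must be named by the 20 standard amino acids")
    x <- x[amino_acids()]
    s <- sum(x)
    if (s <= 0) stop("frequencies must have positive sum")
    if (abs(s - 1) > 1e-6) x <- x / s
    return(x)
  }
  if (is.character(x)) return(aa_frequencies(x)$freqs)
  stop("cannot interpret input as an amino-acid frequency profile")
}

# Pooled counts of the 20 standard residues over a character vector of
# sequences. Non-standard residues (X, B, Z, U, O) are excluded from both
# numerator and denominator. Internal workhorse; uses Biostrings.
.aa_counts <- function(seqs) {
  seqs <- seqs[nzchar(seqs)]
  if (!length(seqs)) return(stats::setNames(numeric(20), amino_acids()))
  set <- Biostrings::AAStringSet(seqs)
  cnt <- Biostrings::letterFrequency(set, letters = amino_acids(),
                                     collapse = TRUE)
  stats::setNames(as.numeric(cnt), amino_acids())
}

#' Pooled amino-acid frequencies of a set of sequences
#'
#' Counts are pooled over all residues in scope, so concatenating the inputs
#' would give the same profile. Non-standard residues (X, B, Z, U, O) are
#' excluded from both the numerator and the denominator: frequencies are over
#' the 20-letter alphabet and sum to 1.
#'
#' @param seqs Character vector of amino-acid sequences (possibly region
#'   slices).
#' @return An [aa_profile()].
#' @export
#' @examples
#' aa_frequencies("SSPP")$freqs[c("S", "P")]
aa_frequencies <- function(seqs) {
  cnt <- .aa_counts(seqs)
  if (sum(cnt) == 0)
    stop("no countable residues (all empty or non-standard)")
  aa_profile(cnt)
}

#' Count-weighted merge of frequency profiles
#'
#' Exactly reproduces the pooled profile of the union of the underlying
#' residue sets.
#'
#' @param ... `aa_profile` objects (or a single list of them).
#' @return An [aa_profile()].
#' @export
merge_profiles <- function(...) {
  ps <- list(...)
  if (length(ps) == 1 && !inherits(ps[[1]], "aa_profile")) ps <- ps[[1]]
  stopifnot(all(vapply(ps, inherits, logical(1), "aa_profile")))
  aa_profile(Reduce(`+`, lapply(ps, `[[`, "counts")))
}

#' Signed frequency differences against a eukaryote baseline
#'
#' Computes `100 * (f_other - f_baseline)` per amino acid, i.e. percentage
#' points, with the eukaryotic profile as baseline: an amino acid more
#' abundant in eukaryotes shows a negative ("downward") shift, matching the
#' presentation convention of kingdom-comparison figures.
#'
#' @param baseline,other Profiles ([aa_profile()]), named frequency vectors
#'   or sequences; `baseline` is conventionally the eukaryotic profile.
#' @param percentage Return percentage points (default) or fractions.
#' @return Named numeric vector of 20 signed deltas; sums to 0.
#' @export
frequency_difference <- function(baseline, other, percentage = TRUE) {
  d <- .as_freqs(other) - .as_freqs(baseline)
  if (percentage) d <- 100 * d
  d
}

#' Pearson similarity of frequency profiles with clustering order
#'
#' Pairwise Pearson correlation over the 20 frequency values of each profile,
#' plus an average-linkage hierarchical clustering (distance `1 - r`) that
#' provides the display order for heat maps.
#'
#' @param profiles Named list of profiles (see [frequency_difference()] for
#'   accepted forms); at least two.
#' @return List with `r` (symmetric correlation matrix, unit diagonal),
#'   `order` (labels in dendrogram order), and `hclust`.
#' @export
profile_similarity <- function(profiles) {
  if (length(profiles) < 2) stop("need at least two profiles")
  if (is.null(names(profiles)))
    names(profiles) <- paste0("profile", seq_along(profiles))
  m <- vapply(profiles, .as_freqs, numeric(20))
  if (any(apply(m, 2, stats::sd) == 0))
    stop("zero-variance profile: Pearson correlation undefined")
  r <- stats::cor(m)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  list(r = r, order = colnames(r)[hc$order], hclust = hc)
}

# Extract region subsequences for a region/hit table with start/end columns.
# Internal; seq_by_id is a named character vector of protein sequences.
.slice_sequences <- function(tab, seq_by_id) {
  seqs <- seq_by_id[tab$protein_id]
  if (anyNA(seqs))
    stop("unknown protein id(s): ",
         paste(utils::head(unique(tab$protein_id[is.na(seqs)]), 3),
               collapse = ", "))
  substring(seqs, tab$start, tab$end)
}

#' Pooled frequency profiles per kingdom and region type
#'
#' @param regions Region table from [segment_regions()].
#' @param proteins Protein table (`protein_id`, `genome_id`, `sequence`).
#' @param genomes Genome metadata (`genome_id`, `kingdom`).
#' @return Named list of [aa_profile()]s, names `<kingdom>.<region_type>`, in
#'   deterministic kingdom-major order; combinations with zero residues are
#'   omitted.
#' @export
region_profiles <- function(regions, proteins, genomes) {
  seq_by_id <- stats::setNames(proteins$sequence, proteins$protein_id)
  kingdom <- .kingdom_of(proteins, genomes)[regions$protein_id]
  slices <- .slice_sequences(regions, seq_by_id)
  keys <- paste(kingdom, regions$region_type, sep = ".")
  wanted <- as.vector(outer(.kingdoms, .region_types, paste, sep = "."))
  out <- list()
  for (k in wanted) {
    s <- slices[keys == k]
    if (length(s) && sum(.aa_counts(s)) > 0) out[[k]] <- aa_frequencies(s)
  }
  out
}

# kingdom lookup: named vector protein_id -> kingdom. Internal.
.kingdom_of <- function(proteins, genomes) {
  kg <- stats::setNames(genomes$kingdom, genomes$genome_id)
  k <- kg[proteins$genome_id]
  if (anyNA(k))
    stop("protein(s) reference unknown genome(s): ",
         paste(utils::head(unique(proteins$genome_id[is.na(k)]), 3),
               collapse = ", "))
  stats::setNames(as.character(k), proteins$protein_id)
}

#' Per-group frequency profiles by an arbitrary metadata key
#'
#' Groups linker (or any) region slices by `kingdom`, `phylum`,
#' `region_type` or `protein_group` and returns one pooled profile per group
#' value, in deterministic (sorted) order.
#'
#' @param regions Region table; rows define the residues in scope.
#' @param proteins,genomes Protein and genome tables.
#' @param by One of `"kingdom"`, `"phylum"`, `"region_type"`; or
#'   `"protein_group"` together with `groups`.
#' @param groups Optional protein-group table from [assign_groups()]
#'   (required for `by = "protein_group"`).
#' @return Named list of [aa_profile()]s.
#' @export
group_profiles <- function(regions, proteins, genomes,
                           by = c("kingdom", "phylum", "region_type",
                                  "protein_group"),
                           groups = NULL) {
  by <- match.arg(by)
  seq_by_id <- stats::setNames(proteins$sequence, proteins$protein_id)
  slices <- .slice_sequences(regions, seq_by_id)
  key <- switch(by,
    kingdom = .kingdom_of(proteins, genomes)[regions$protein_id],
    phylum = {
      ph <- stats::setNames(genomes$phylum, genomes$genome_id)
      gid <- stats::setNames(proteins$genome_id, proteins$protein_id)
      as.character(ph[gid[regions$protein_id]])
    },
    region_type = regions$region_type,
    protein_group = {
      if (is.null(groups)) stop("groups table required for protein_group")
      gg <- stats::setNames(groups$group, groups$protein_id)
      as.character(gg[regions$protein_id])
    })
  out <- list()
  for (k in sort(unique(key))) {
    s <- slices[key == k]
    if (length(s) && sum(.aa_counts(s)) > 0) out[[k]] <- aa_frequencies(s)
  }
  out
}

#' Per-family kingdom composition shifts
#'
#' For every shared domain family with at least `min_members` instances in
#' both bacteria and eukaryotes (archaea are ignored by the membership
#' filter), computes the per-amino-acid frequency difference between the
#' family's prokaryotic and eukaryotic instance residues, with the eukaryotic
#' frequencies as baseline. The summary gives, per amino acid, the fraction
#' of families in which the eukaryotic members are enriched (positive
#' eukaryotic excess).
#'
#' @param hits Resolved domain-hit table.
#' @param proteins,genomes Protein and genome tables.
#' @param families Family classification from [classify_families()]; only
#'   families labelled `shared` are considered.
#' @param min_members Minimum instances required in bacteria and in
#'   eukaryotes (default 100).
#' @return List with `deltas` (family x 20 matrix per comparison kingdom, as
#'   a named list of matrices, percentage points, eukaryote baseline),
#'   `euk_excess_fraction` (per-comparison named list of 20-vectors),
#'   `n_families_used`, `n_families_excluded`.
#' @export
per_family_shift <- function(hits, proteins, genomes, families,
                             min_members = 100) {
  shared <- families$family_acc[families$label == "shared"]
  h <- hits[hits$family_acc %in% shared, , drop = FALSE]
  kingdom <- .kingdom_of(proteins, genomes)[h$protein_id]
  seq_by_id <- stats::setNames(proteins$sequence, proteins$protein_id)
  slices <- .slice_sequences(h, seq_by_id)

  inst <- table(h$family_acc, kingdom)
  ok_cols <- intersect(c("eukaryote", "bacterium"), colnames(inst))
  eligible <- if (length(ok_cols) == 2)
    rownames(inst)[inst[, "eukaryote"] >= min_members &
                   inst[, "bacterium"] >= min_members]
  else character(0)
  n_excluded <- length(unique(h$family_acc)) - length(eligible)

  comparisons <- c(bacterium = "bacterium", archaeon = "archaeon")
  deltas <- list()
  excess <- list()
  for (cmp in names(comparisons)) {
    rows <- lapply(eligible, function(fam) {
      sel <- h$family_acc == fam
      fe <- slices[sel & kingdom == "eukaryote"]
      fo <- slices[sel & kingdom == cmp]
      if (!length(fe) || !length(fo)) return(NULL)
      ce <- .aa_counts(fe); co <- .aa_counts(fo)
      if (sum(ce) == 0 || sum(co) == 0) return(NULL)
      frequency_difference(ce / sum(ce), co / sum(co))
    })
    names(rows) <- eligible
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) {
      m <- do.call(rbind, rows)
      deltas[[cmp]] <- m
      # eukaryote baseline: negative delta = eukaryotic excess
      excess[[cmp]] <- colMeans(m < 0)
    }
  }
  list(deltas = deltas, euk_excess_fraction = excess,
       n_families_used = length(eligible),
       n_families_excluded = n_excluded)
}

#' Majority secondary-structure label of an alignment column
#'
#' Majority rule over the observed structural labels (`H`, `E`, `C`) of a
#' column. Ties between the top labels are broken to `C` (coil); a column
#' with no structural observation is `unassigned` (treated downstream as
#' disordered).
#'
#' @param labels Character vector of per-sequence labels for the column;
#'   values outside `H`/`E`/`C` are ignored.
#' @return One of `"H"`, `"E"`, `"C"`, `"unassigned"`.
#' @export
majority_ss <- function(labels) {
  labels <- labels[labels %in% c("H", "E", "C")]
  if (!length(labels)) return("unassigned")
  tab <- table(factor(labels, levels = c("H", "E", "C")))
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) "C" else top
}

#' Secondary-structure-stratified amino-acid frequencies
#'
#' Every residue of a domain instance inherits the consensus label of its
#' family alignment column (instances are assumed ungapped, so instance
#' position i maps to column i); `unassigned` columns are reported as the
#' `disordered` class. Returns one pooled profile per class.
#'
#' @param hits Resolved domain-hit table.
#' @param proteins Protein table.
#' @param ss Secondary-structure annotation table with columns `family_acc`,
#'   `column` (1-based) and `label` in `H`/`E`/`C`/`unassigned`.
#' @return List with `profiles` (named list over `H`, `E`, `C`,
#'   `disordered`; classes with no residues omitted) and
#'   `n_families_excluded` (hit families without annotation).
#' @export
ss_stratified_frequencies <- function(hits, proteins, ss) {
  seq_by_id <- stats::setNames(proteins$sequence, proteins$protein_id)
  annotated <- unique(ss$family_acc)
  keep <- hits$family_acc %in% annotated
  n_fam_excl <- length(setdiff(unique(hits$family_acc), annotated))
  h <- hits[keep, , drop = FALSE]
  labels_by_fam <- lapply(split(ss, ss$family_acc), function(d) {
    out <- character(max(d$column))
    out[d$column] <- d$label
    out
  })
  class_chars <- list(H = character(0), E = character(0), C = character(0),
                      disordered = character(0))
  if (nrow(h)) {
    slices <- .slice_sequences(h, seq_by_id)
    for (i in seq_len(nrow(h))) {
      lab <- labels_by_fam[[h$family_acc[i]]]
      res <- strsplit(slices[i], "", fixed = TRUE)[[1]]
      ncol_used <- min(length(res), length(lab))
      if (ncol_used == 0) next
      cls <- lab[seq_len(ncol_used)]
      cls[!cls %in% c("H", "E", "C")] <- "disordered"
      for (cl in unique(cls)) {
        class_chars[[cl]] <- c(class_chars[[cl]],
                               paste(res[seq_len(ncol_used)][cls == cl],
                                     collapse = ""))
      }
    }
  }
  profiles <- list()
  for (cl in names(class_chars)) {
    cnt <- .aa_counts(class_chars[[cl]])
    if (sum(cnt) > 0) profiles[[cl]] <- aa_profile(cnt)
  }
  list(profiles = profiles, n_families_excluded = n_fam_excl)
}
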