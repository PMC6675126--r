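# File-format boundary: FASTA, TSV (genomes, domain hits, disorder tracks,
# secondary-structure annotations) and the summary-table writers. All
# coordinates are 1-based inclusive throughout.

#' Read a protein FASTA file
#'
#' Headers carry the protein and genome identifiers separated by a
#' configurable delimiter (`proteinid|genomeid` by default). Sequences are
#' upper-cased; input order is preserved.
#'
#' @param path FASTA file.
#' @param delim Header delimiter between protein id and genome id.
#' @param policy `"strict"` (default) errors on residues outside the
#'   20-letter alphabet plus `X/B/Z/U/O`; `"mask"` replaces them with `X`.
#' @return Data frame `protein_id`, `genome_id`, `sequence`, `length`.
#' @export
read_fasta <- function(path, delim = "|", policy = c("strict", "mask")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(data.frame(protein_id = character(0), genome_id = character(0),
                      sequence = character(0), length = integer(0),
                      stringsAsFactors = FALSE))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  parts <- strsplit(headers, delim, fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2)
  if (length(bad))
    stop("malformed FASTA header (expected 'protein", delim,
         "genome') in entry ", bad[1], ": '", headers[bad[1]], "'")
  seqs <- toupper(as.character(set))
  allowed <- paste0(c(amino_acids(), .nonstandard_residues), collapse = "")
  stray <- gsub(paste0("[", allowed, "]"), "", seqs)
  if (any(nzchar(stray))) {
    i <- which(nzchar(stray))[1]
    offender <- substring(stray[i], 1, 1)
    if (policy == "strict")
      stop("residue '", offender, "' outside the amino-acid alphabet in ",
           "entry ", i, " ('", headers[i], "')")
    seqs <- vapply(seqs, function(s)
      gsub(paste0("[^", allowed, "]"), "X", s), character(1),
      USE.NAMES = FALSE)
  }
  out <- data.frame(
    protein_id = vapply(parts, `[`, character(1), 1),
    genome_id = vapply(parts, function(p)
      paste(p[-1], collapse = delim), character(1)),
    sequence = seqs, length = nchar(seqs), stringsAsFactors = FALSE)
  if (anyDuplicated(out$protein_id))
    stop("duplicate protein_id: ",
         out$protein_id[duplicated(out$protein_id)][1])
  row.names(out) <- NULL
  out
}

#' Write a protein FASTA file
#'
#' Inverse of [read_fasta()]; headers are `protein_id<delim>genome_id`.
#'
#' @param proteins Protein table.
#' @param path Output file.
#' @param delim Header delimiter.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, delim = "|") {
  set <- Biostrings::BStringSet(proteins$sequence)
  names(set) <- paste0(proteins$protein_id, delim, proteins$genome_id)
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Read genome metadata TSV
#'
#' Expects columns `genome_id`, `kingdom`, `phylum`, `genus` and `gc` (or
#' `gc_fraction`). Kingdoms must come from
#' eukaryote/bacterium/archaeon; GC must lie in `[0, 1]`; genome ids must be
#' unique.
#'
#' @param path TSV file.
#' @return Data frame with a `gc` column.
#' @export
read_genome_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("gc_fraction" %in% names(d) && !"gc" %in% names(d))
    names(d)[names(d) == "gc_fraction"] <- "gc"
  need <- c("genome_id", "kingdom", "phylum", "genus", "gc")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("genome TSV lacks column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(d$kingdom), .kingdoms)
  if (length(bad))
    stop("unknown kingdom(s): ", paste(bad, collapse = ", "))
  if (any(is.na(d$gc) | d$gc < 0 | d$gc > 1))
    stop("gc outside [0, 1]")
  if (anyDuplicated(d$genome_id))
    stop("duplicate genome_id: ", d$genome_id[duplicated(d$genome_id)][1])
  d[need]
}

#' @rdname read_genome_tsv
#' @param genomes Genome table to write.
#' @export
write_genome_tsv <- function(genomes, path) {
  utils::write.table(genomes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read domain-hit TSV
#'
#' Columns `protein_id`, `family_acc`, `start`, `end` and optionally
#' `score`; coordinates are 1-based inclusive. When a protein table is
#' supplied, hits are validated against it (existing protein, end within
#' length).
#'
#' @param path TSV file.
#' @param proteins Optional protein table for validation.
#' @return Data frame of hits.
#' @export
read_domain_tsv <- function(path, proteins = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "family_acc", "start", "end")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("domain TSV lacks column(s): ", paste(miss, collapse = ", "))
  if (!"score" %in% names(d)) d$score <- NA_real_
  if (any(d$start < 1))
    stop("coordinates are 1-based: start must be >= 1")
  if (any(d$end < d$start))
    stop("end < start in domain TSV")
  if (!is.null(proteins)) {
    len <- stats::setNames(nchar(proteins$sequence), proteins$protein_id)
    unknown <- setdiff(d$protein_id, names(len))
    if (length(unknown))
      stop("hit references unknown protein: ", unknown[1])
    over <- d$end > len[d$protein_id]
    if (any(over))
      stop("hit beyond protein length for: ", d$protein_id[over][1])
  }
  d[c(need, "score")]
}

#' @rdname read_domain_tsv
#' @param hits Hit table to write.
#' @export
write_domain_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-residue disorder-score tracks
#'
#' Accepts either a long-format TSV with columns `protein_id`, `position`,
#' `score`, or a block format: a `>protein_id` line followed by one score
#' per line. When a protein table is supplied, each track's length must
#' equal the protein length. Scores outside `[0, 1]` are clamped with a
#' warning.
#'
#' @param path Track file.
#' @param proteins Optional protein table for validation.
#' @return Named list of numeric score vectors.
#' @export
read_disorder_tracks <- function(path, proteins = NULL) {
  first <- readLines(path, n = 1)
  if (length(first) && startsWith(first, ">")) {
    lines <- readLines(path)
    idx <- cumsum(startsWith(lines, ">"))
    blocks <- split(lines, idx)
    tracks <- lapply(blocks, function(b)
      as.numeric(b[-1]))
    names(tracks) <- vapply(blocks, function(b)
      sub("^>", "", b[1]), character(1))
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("protein_id", "position", "score")
    miss <- setdiff(need, names(d))
    if (length(miss))
      stop("disorder TSV lacks column(s): ", paste(miss, collapse = ", "))
    d <- d[order(d$protein_id, d$position), ]
    tracks <- lapply(split(d, d$protein_id), function(b) {
      if (!identical(as.integer(b$position), seq_len(nrow(b))))
        stop("positions of protein ", b$protein_id[1],
             " are not 1..L without gaps")
      b$score
    })
  }
  if (any(vapply(tracks, anyNA, logical(1))))
    stop("non-numeric score in disorder tracks")
  oob <- vapply(tracks, function(s) any(s < 0 | s > 1), logical(1))
  if (any(oob)) {
    warning("scores outside [0, 1] clamped for: ",
            paste(utils::head(names(tracks)[oob], 3), collapse = ", "))
    tracks[oob] <- lapply(tracks[oob], function(s) pmin(pmax(s, 0), 1))
  }
  if (!is.null(proteins)) {
    len <- stats::setNames(nchar(proteins$sequence), proteins$protein_id)
    common <- intersect(names(tracks), names(len))
    mism <- common[lengths(tracks[common]) != len[common]]
    if (length(mism))
      stop("track length differs from protein length for: ", mism[1])
  }
  tracks
}

#' @rdname read_disorder_tracks
#' @param tracks Named list of score vectors to write (block format).
#' @param digits Decimal places written per score.
#' @export
write_disorder_tracks <- function(tracks, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(tracks)) {
    writeLines(paste0(">", id), con)
    writeLines(formatC(tracks[[id]], digits = digits, format = "f"), con)
  }
  invisible(path)
}

#' Read / write secondary-structure column annotations
#'
#' TSV with columns `family_acc`, `column` (1-based alignment column) and
#' `label` in `H`/`E`/`C`/`unassigned`.
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_ss_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family_acc", "column", "label")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("SS TSV lacks column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(d$label), c("H", "E", "C", "unassigned"))
  if (length(bad))
    stop("unknown SS label(s): ", paste(bad, collapse = ", "))
  d[need]
}

#' @rdname read_ss_tsv
#' @param ss Annotation table to write.
#' @export
write_ss_tsv <- function(ss, path) {
  utils::write.table(ss, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write protein-level and region-level summary tables
#'
#' Emits two TSV files, `summary_proteins.tsv` (one row per kingdom and
#' protein group) and `summary_regions.tsv` (one row per kingdom and region
#' type), each with `n`, mean length and SE, pooled disorder fraction, mean
#' disordered residues and SE, and the 20 amino-acid frequencies. Rows for
#' empty classes are present with `n = 0` and empty statistics. Column
#' order is fixed and values are written at fixed precision, so reruns on
#' the same input are byte-identical.
#'
#' @param results A [run_pipeline()] result (or any list with
#'   `disorder_summary` and profile lists of the same shape).
#' @param out_dir Output directory (created if needed).
#' @param digits Decimal places for real-valued columns.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_summary_tables <- function(results, out_dir, digits = 6) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  fmt <- function(x) ifelse(is.na(x), "",
                            formatC(x, digits = digits, format = "f"))
  build <- function(summary_df, label_col, labels, profiles, prefix) {
    rows <- list()
    for (k in .kingdoms) for (v in labels) {
      sub <- summary_df[summary_df$kingdom == k &
                          summary_df[[label_col]] == v, , drop = FALSE]
      prof <- profiles[[paste(k, v, sep = ".")]]
      freqs <- if (!is.null(prof)) prof$freqs else
        stats::setNames(rep(NA_real_, 20), amino_acids())
      base <- if (nrow(sub)) sub else
        data.frame(kingdom = k, label = v, n_proteins = 0,
                   mean_length = NA, se_length = NA,
                   pooled_disorder_fraction = NA,
                   mean_disorder_fraction = NA, se_disorder_fraction = NA,
                   mean_disordered = NA, se_disordered = NA)
      rows[[length(rows) + 1]] <- data.frame(
        kingdom = k, class = v, n = base$n_proteins[1],
        mean_length = fmt(base$mean_length[1]),
        se_length = fmt(base$se_length[1]),
        disorder_fraction = fmt(base$pooled_disorder_fraction[1]),
        se_disorder_fraction = fmt(base$se_disorder_fraction[1]),
        mean_disordered = fmt(base$mean_disordered[1]),
        se_disordered = fmt(base$se_disordered[1]),
        t(vapply(freqs, fmt, character(1))),
        stringsAsFactors = FALSE, check.names = FALSE)
    }
    do.call(rbind, rows)
  }
  ds <- results$disorder_summary
  prot_tab <- build(ds$by_group, "group", .protein_groups,
                    results$protein_group_profiles, "group")
  reg_tab <- build(ds$by_region, "region_type", .region_types,
                   results$region_profiles, "region")
  paths <- file.path(out_dir, c("summary_proteins.tsv",
                                "summary_regions.tsv"))
  utils::write.table(prot_tab, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(reg_tab, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
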