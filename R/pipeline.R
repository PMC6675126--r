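# Orchestration: filter -> classify -> partition -> disorder -> composition
# -> decomposition -> codon null, as one reproducible run.

#' Default pipeline configuration
#'
#' All analysis thresholds in one list: GC retention bounds (0.20-0.60),
#' excluded genera, the 10-genome shared-family presence rule, the 99.9%
#' single-kingdom instance-share cap, the 0.4 disorder threshold, the
#' 100-member per-family filter, and the built-in predictor window.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_gc = 0.20, max_gc = 0.60,
    excluded_genera = c("Mycoplasma", "Spiroplasma", "Ureaplasma",
                        "Mesoplasma"),
    min_genomes = 10, max_share = 0.999,
    disorder_threshold = 0.4,
    min_family_members = 100,
    builtin_window = 21,
    use_builtin = FALSE,
    gc_grid = seq(0.2, 0.6, by = 0.01))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes every stage on in-memory tables (or a [generate_proteomes()]
#' bundle): genome filtering, overlap resolution, family classification,
#' protein grouping, region segmentation, disorder summaries, composition
#' profiles and kingdom deltas, Pearson similarity with clustering,
#' per-family shifts, optional secondary-structure stratification, the
#' propensity-contribution decomposition with Ser/Pro/Ile leave-out, the
#' GC-adjusted kingdom ANOVA on per-genome linker frequencies, and the
#' codon-usage null comparison. Stage outputs equal those of calling the
#' stage functions individually with the same configuration.
#'
#' @param proteins Protein table, or a `synthetic_bundle` (then the other
#'   table arguments are taken from it).
#' @param genomes,hits Genome metadata and domain hits.
#' @param tracks Named list of per-residue disorder scores; if `NULL` and
#'   `config$use_builtin` is `TRUE`, the built-in window predictor supplies
#'   scores (flagged in the manifest); otherwise an error.
#' @param ss Optional secondary-structure annotation table.
#' @param config A [pipeline_config()].
#' @return Object of class `idp_pipeline`.
#' @export
run_pipeline <- function(proteins, genomes = NULL, hits = NULL,
                         tracks = NULL, ss = NULL,
                         config = pipeline_config()) {
  if (inherits(proteins, "synthetic_bundle")) {
    bundle <- proteins
    proteins <- bundle$proteins
    if (is.null(genomes)) genomes <- bundle$genomes
    if (is.null(hits)) hits <- bundle$hits
    if (is.null(tracks)) tracks <- bundle$tracks
    if (is.null(ss)) ss <- bundle$ss
  }
  if (is.null(genomes) || is.null(hits))
    stop("genomes and hits are required")

  n_genomes_in <- nrow(genomes)
  filt <- filter_genomes(genomes, config$min_gc, config$max_gc,
                         config$excluded_genera)
  genomes <- filt$retained
  keep_prot <- proteins$genome_id %in% genomes$genome_id
  proteins <- proteins[keep_prot, , drop = FALSE]
  hits <- hits[hits$protein_id %in% proteins$protein_id, , drop = FALSE]

  if (is.null(tracks)) {
    if (!config$use_builtin)
      stop("no disorder tracks supplied and use_builtin is FALSE: ",
           "provide predictor output or enable the built-in predictor")
    tracks <- lapply(stats::setNames(proteins$sequence,
                                     proteins$protein_id),
                     builtin_window_predictor,
                     window = config$builtin_window)
    predictor <- "builtin_window_predictor (composition smoother, not an
energy-based predictor)"
  } else {
    tracks <- tracks[intersect(names(tracks), proteins$protein_id)]
    predictor <- "external score tracks"
  }

  hits <- resolve_overlaps(hits)
  families <- classify_families(hits, proteins, genomes,
                                config$min_genomes, config$max_share)
  groups <- assign_groups(proteins, hits, families)
  regions <- segment_regions(proteins, hits, families, groups)
  linker_split <- linker_location_summary(regions, proteins, genomes)
  disorder <- regional_disorder_summary(regions, groups, proteins, genomes,
                                        tracks, config$disorder_threshold)

  reg_prof <- region_profiles(regions, proteins, genomes)
  kingdom <- .kingdom_of(proteins, genomes)
  grp_prof <- list()
  gkey <- paste(kingdom[proteins$protein_id],
                stats::setNames(groups$group,
                                groups$protein_id)[proteins$protein_id],
                sep = ".")
  for (k in sort(unique(gkey))) {
    s <- proteins$sequence[gkey == k]
    if (length(s) && sum(.aa_counts(s)) > 0)
      grp_prof[[k]] <- aa_frequencies(s)
  }

  similarity <- if (length(reg_prof) >= 2) profile_similarity(reg_prof)
                else NULL

  deltas <- list(); contributions <- list(); leave_out <- list()
  for (rt in c("linker", "shared_domain")) {
    base <- reg_prof[[paste0("eukaryote.", rt)]]
    if (is.null(base)) next
    for (k in c("bacterium", "archaeon")) {
      other <- reg_prof[[paste0(k, ".", rt)]]
      if (is.null(other)) next
      key <- paste(rt, k, sep = ".")
      deltas[[key]] <- frequency_difference(base, other)
      if (rt == "linker") {
        contributions[[k]] <- propensity_contribution(base, other)
        leave_out[[k]] <- leave_out_propensity_diff(base, other)
      }
    }
  }

  fam_shift <- per_family_shift(hits, proteins, genomes, families,
                                config$min_family_members)
  ss_strat <- if (!is.null(ss) && nrow(ss))
    ss_stratified_frequencies(hits, proteins, ss) else NULL

  # per-genome linker profiles for the GC-adjusted kingdom test
  lk <- regions[regions$region_type == "linker", , drop = FALSE]
  gid_of <- stats::setNames(proteins$genome_id, proteins$protein_id)
  anova <- NULL
  genome_linker_freqs <- NULL
  if (nrow(lk)) {
    slices <- .slice_sequences(lk, stats::setNames(proteins$sequence,
                                                   proteins$protein_id))
    by_gen <- split(slices, gid_of[lk$protein_id])
    cnts <- t(vapply(by_gen, .aa_counts, numeric(20)))
    ok <- rowSums(cnts) > 0
    freqs <- cnts[ok, , drop = FALSE] / rowSums(cnts)[ok]
    meta <- genomes[match(rownames(freqs), genomes$genome_id), ]
    genome_linker_freqs <- data.frame(genome_id = rownames(freqs),
                                      kingdom = meta$kingdom,
                                      gc = meta$gc, freqs,
                                      stringsAsFactors = FALSE,
                                      check.names = FALSE)
    if (length(unique(meta$kingdom)) >= 2 && nrow(freqs) >= 3)
      anova <- anova_kingdom_gc(freqs, meta$kingdom, meta$gc)
  }

  # whole-proteome per-genome frequencies vs the codon null
  by_gen_all <- split(proteins$sequence, proteins$genome_id)
  cnts_all <- t(vapply(by_gen_all, .aa_counts, numeric(20)))
  ok <- rowSums(cnts_all) > 0
  freqs_all <- cnts_all[ok, , drop = FALSE] / rowSums(cnts_all)[ok]
  meta_all <- genomes[match(rownames(freqs_all), genomes$genome_id), ]
  genome_freqs <- data.frame(genome_id = rownames(freqs_all),
                             kingdom = meta_all$kingdom, gc = meta_all$gc,
                             freqs_all, stringsAsFactors = FALSE,
                             check.names = FALSE)
  codon <- observed_vs_expected(genome_freqs, config$gc_grid)

  manifest <- list(
    package_version = as.character(utils::packageVersion("linkerscape")),
    config = config[setdiff(names(config), "gc_grid")],
    predictor = predictor,
    counts = list(
      genomes_in = n_genomes_in, genomes_retained = nrow(genomes),
      proteins = nrow(proteins), hits = nrow(hits),
      families = nrow(families),
      shared_families = sum(families$label == "shared"),
      shared_families_all_kingdoms = sum(
        families$label == "shared" & families$n_genomes_eukaryote > 0 &
          families$n_genomes_bacterium > 0 &
          families$n_genomes_archaeon > 0),
      proteins_per_group = as.list(table(groups$group)),
      regions = nrow(regions),
      linker_residues = if (nrow(lk)) sum(lk$end - lk$start + 1) else 0,
      proteins_missing_tracks = disorder$n_missing_tracks))

  structure(list(
    genomes = genomes, filter_report = filt$report, proteins = proteins,
    hits = hits, families = families, groups = groups, regions = regions,
    linker_location = linker_split, disorder_summary = disorder,
    region_profiles = reg_prof, protein_group_profiles = grp_prof,
    similarity = similarity, deltas = deltas,
    contributions = contributions, leave_out = leave_out,
    family_shift = fam_shift, ss_stratified = ss_strat,
    genome_linker_freqs = genome_linker_freqs, anova = anova,
    codon_null = codon, manifest = manifest, config = config),
    class = "idp_pipeline")
}

#' @export
print.idp_pipeline <- function(x, ...) {
  cn <- x$manifest$counts
  cat("Kingdom disorder/composition pipeline run\n")
  cat(sprintf("  genomes: %d retained of %d\n", cn$genomes_retained,
              cn$genomes_in))
  cat(sprintf("  proteins: %d (%s)\n", cn$proteins,
              paste(names(cn$proteins_per_group),
                    unlist(cn$proteins_per_group),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  domain families: %d (%d shared)\n", cn$families,
              cn$shared_families))
  cat(sprintf("  regions: %d (%d linker residues)\n", cn$regions,
              cn$linker_residues))
  cat("  predictor:", x$manifest$predictor, "\n")
  invisible(x)
}

#' @export
summary.idp_pipeline <- function(object, ...) {
  ds <- object$disorder_summary
  br <- ds$by_region
  if (is.null(br)) {
    cat("No segmented regions in this run.\n")
    return(invisible(object))
  }
  cat("Pooled disorder fraction by kingdom and region type:\n")
  wide <- tapply(br$pooled_disorder_fraction,
                 list(factor(br$kingdom, levels = .kingdoms),
                      br$region_type), identity)
  print(round(wide, 4))
  if (length(object$contributions)) {
    cat("\nTop |propensity x delta-frequency| contributions",
        "(eukaryote baseline):\n")
    for (k in names(object$contributions)) {
      co <- object$contributions[[k]]
      co <- co[order(-abs(co$contribution)), ]
      cat(" vs", k, ":",
          paste(utils::head(co$aa, 5), collapse = ", "), "\n")
    }
  }
  invisible(object)
}

#' Plot pipeline results
#'
#' `which = "similarity"` draws the clustered Pearson heat map of region
#' profiles; `which = "contributions"` the per-amino-acid propensity
#' contribution bars (one panel per prokaryote comparison);
#' `which = "gc"` observed per-genome frequencies of a chosen amino acid
#' against GC with the codon-null curve.
#'
#' @param x An `idp_pipeline` object.
#' @param which One of `"similarity"`, `"contributions"`, `"gc"`.
#' @param aa Amino acid for `which = "gc"` (default `"S"`).
#' @param ... Ignored.
#' @export
plot.idp_pipeline <- function(x, which = c("similarity", "contributions",
                                           "gc"), aa = "S", ...) {
  which <- match.arg(which)
  if (which == "similarity") {
    if (is.null(x$similarity)) stop("no similarity matrix in this run")
    r <- x$similarity$r
    ord <- x$similarity$order
    graphics::image(seq_along(ord), seq_along(ord),
                    r[ord, ord][, rev(seq_along(ord))],
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    axes = FALSE, xlab = "", ylab = "",
                    main = "Pearson similarity of region profiles")
    graphics::axis(1, seq_along(ord), ord, las = 2, cex.axis = 0.7)
    graphics::axis(2, seq_along(ord), rev(ord), las = 2, cex.axis = 0.7)
  } else if (which == "contributions") {
    if (!length(x$contributions)) stop("no contributions in this run")
    old <- graphics::par(mfrow = c(length(x$contributions), 1))
    on.exit(graphics::par(old))
    for (k in names(x$contributions)) {
      co <- x$contributions[[k]]
      graphics::barplot(co$contribution, names.arg = co$aa,
                        main = paste("Propensity contributions: eukaryote vs",
                                     k),
                        ylab = "s_aa * delta f_aa")
    }
  } else {
    pts <- x$codon_null$points
    pts <- pts[pts$aa == aa, ]
    nc <- x$codon_null$null_curve
    nc <- nc[nc$aa == aa, ]
    graphics::plot(pts$gc, pts$observed,
                   col = factor(pts$kingdom, levels = .kingdoms),
                   pch = 16, cex = 0.5, xlab = "genomic GC",
                   ylab = paste("frequency of", aa))
    graphics::lines(nc$gc, nc$expected, lwd = 2)
    graphics::legend("topright", legend = .kingdoms, col = 1:3, pch = 16,
                     cex = 0.8)
  }
  invisible(x)
}
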