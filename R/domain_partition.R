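# Domain-family classification (shared vs kingdom-restricted), protein
# grouping, and exact segmentation of shared proteins into shared-domain /
# specific-domain / linker region tracks.

#' Resolve overlapping domain hits within proteins
#'
#' Greedy by descending score: any hit overlapping an already accepted hit
#' by at least one residue is dropped whole. Ties broken by longer hit, then
#' smaller start, then lexicographic family accession. Applied per protein.
#'
#' @param hits Domain-hit table (`protein_id`, `family_acc`, `start`, `end`,
#'   optional `score`; missing scores are treated as 0).
#' @return The non-overlapping subset of `hits`, sorted by protein and
#'   start.
#' @export
resolve_overlaps <- function(hits) {
  if (!nrow(hits)) return(hits)
  score <- if ("score" %in% names(hits)) {
    s <- hits$score
    s[is.na(s)] <- 0
    s
  } else rep(0, nrow(hits))
  len <- hits$end - hits$start + 1
  keep <- logical(nrow(hits))
  for (idx in split(seq_len(nrow(hits)), hits$protein_id)) {
    o <- idx[order(-score[idx], -len[idx], hits$start[idx],
                   hits$family_acc[idx])]
    acc <- integer(0)
    for (i in o) {
      if (!length(acc) ||
          all(hits$start[i] > hits$end[acc] | hits$end[i] < hits$start[acc]))
        acc <- c(acc, i)
    }
    keep[acc] <- TRUE
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$protein_id, out$start), , drop = FALSE]
}

#' Classify domain families as shared or non-shared between kingdoms
#'
#' A family is `shared` when it is present (at least one instance) in at
#' least `min_genomes` eukaryotic genomes and at least `min_genomes`
#' prokaryotic genomes (bacteria and archaea combined), and no single
#' kingdom holds more than `max_share` of the family's instances.
#'
#' @param hits Domain-hit table.
#' @param proteins,genomes Protein and genome tables (to resolve each hit's
#'   kingdom).
#' @param min_genomes Genome-presence threshold (default 10).
#' @param max_share Maximum tolerated single-kingdom instance share
#'   (default 0.999).
#' @return Data frame with one row per family: `family_acc`, per-kingdom
#'   genome and instance counts, `label` (`shared`/`nonshared`).
#' @export
classify_families <- function(hits, proteins, genomes,
                              min_genomes = 10, max_share = 0.999) {
  kingdom <- .kingdom_of(proteins, genomes)
  gid <- stats::setNames(proteins$genome_id, proteins$protein_id)
  hk <- kingdom[hits$protein_id]
  if (anyNA(hk))
    stop("hit(s) reference unknown protein(s): ",
         paste(utils::head(unique(hits$protein_id[is.na(hk)]), 3),
               collapse = ", "))
  hg <- gid[hits$protein_id]

  inst <- table(factor(hits$family_acc),
                factor(hk, levels = .kingdoms))
  pg <- unique(data.frame(family_acc = hits$family_acc, genome = hg,
                          kingdom = hk, stringsAsFactors = FALSE))
  gen <- table(factor(pg$family_acc, levels = rownames(inst)),
               factor(pg$kingdom, levels = .kingdoms))

  total <- rowSums(inst)
  share_max <- apply(inst, 1, max) / total
  shared <- gen[, "eukaryote"] >= min_genomes &
    (gen[, "bacterium"] + gen[, "archaeon"]) >= min_genomes &
    share_max <= max_share
  data.frame(
    family_acc = rownames(inst),
    n_genomes_eukaryote = as.integer(gen[, "eukaryote"]),
    n_genomes_bacterium = as.integer(gen[, "bacterium"]),
    n_genomes_archaeon = as.integer(gen[, "archaeon"]),
    n_instances_eukaryote = as.integer(inst[, "eukaryote"]),
    n_instances_bacterium = as.integer(inst[, "bacterium"]),
    n_instances_archaeon = as.integer(inst[, "archaeon"]),
    label = ifelse(shared, "shared", "nonshared"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign proteins to shared / kingdom-specific / no-domain groups
#'
#' A protein with at least one hit to a shared family is a
#' `shared_protein`; a protein with hits only to non-shared families is a
#' `kingdom_specific_protein`; a protein without hits is a
#' `no_domain_protein`. The assignment is invariant to hit order.
#'
#' @param proteins Protein table.
#' @param hits Domain-hit table.
#' @param families Output of [classify_families()].
#' @return Data frame `protein_id`, `group`.
#' @export
assign_groups <- function(proteins, hits, families) {
  shared_fams <- families$family_acc[families$label == "shared"]
  has_hit <- proteins$protein_id %in% hits$protein_id
  has_shared <- proteins$protein_id %in%
    hits$protein_id[hits$family_acc %in% shared_fams]
  data.frame(
    protein_id = proteins$protein_id,
    group = ifelse(has_shared, "shared_protein",
                   ifelse(has_hit, "kingdom_specific_protein",
                          "no_domain_protein")),
    stringsAsFactors = FALSE)
}

#' Segment shared proteins into region tracks
#'
#' For every shared protein, labels each residue exactly once: resolved hits
#' to shared families become `shared_domain` intervals, hits to other
#' families `specific_domain` intervals, and maximal unannotated runs become
#' `linker` intervals located `n_terminal` (before the first hit),
#' `c_terminal` (after the last hit) or `central`. The intervals of a
#' protein partition `[1, L]` exactly; per-protein region lengths are sums
#' over all intervals of a type.
#'
#' @param proteins Protein table.
#' @param hits Non-overlapping hits (see [resolve_overlaps()]).
#' @param families Output of [classify_families()].
#' @param groups Optional precomputed [assign_groups()] output.
#' @return Region table: `protein_id`, `region_type`, `location`
#'   (`NA` for domains), `start`, `end`.
#' @export
segment_regions <- function(proteins, hits, families, groups = NULL) {
  if (is.null(groups)) groups <- assign_groups(proteins, hits, families)
  shared_ids <- groups$protein_id[groups$group == "shared_protein"]
  if (!length(shared_ids))
    return(data.frame(protein_id = character(0), region_type = character(0),
                      location = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  shared_fams <- families$family_acc[families$label == "shared"]
  len_by_id <- stats::setNames(nchar(proteins$sequence), proteins$protein_id)
  h <- hits[hits$protein_id %in% shared_ids, , drop = FALSE]
  if (any(h$end > len_by_id[h$protein_id]))
    stop("hit extends beyond protein length")
  hsplit <- split(h, h$protein_id)
  out <- vector("list", length(shared_ids))
  for (j in seq_along(shared_ids)) {
    pid <- shared_ids[j]
    L <- len_by_id[[pid]]
    ph <- hsplit[[pid]]
    if (is.null(ph) || !nrow(ph))
      stop("shared protein without hits: ", pid)  # contract violation
    ph <- ph[order(ph$start), , drop = FALSE]
    if (any(ph$start[-1] <= ph$end[-nrow(ph)]))
      stop("overlapping hits for protein ", pid,
           "; run resolve_overlaps() first")
    dom_type <- ifelse(ph$family_acc %in% shared_fams,
                       "shared_domain", "specific_domain")
    starts <- integer(0); ends <- integer(0)
    types <- character(0); locs <- character(0)
    pos <- 1L
    for (i in seq_len(nrow(ph))) {
      if (ph$start[i] > pos) {
        starts <- c(starts, pos); ends <- c(ends, ph$start[i] - 1L)
        types <- c(types, "linker")
        locs <- c(locs, if (pos == 1L) "n_terminal" else "central")
      }
      starts <- c(starts, ph$start[i]); ends <- c(ends, ph$end[i])
      types <- c(types, dom_type[i]); locs <- c(locs, NA_character_)
      pos <- ph$end[i] + 1L
    }
    if (pos <= L) {
      starts <- c(starts, pos); ends <- c(ends, L)
      types <- c(types, "linker"); locs <- c(locs, "c_terminal")
    }
    out[[j]] <- data.frame(protein_id = pid, region_type = types,
                           location = locs, start = starts, end = ends,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

#' Distribution of linker residues over locations, per kingdom
#'
#' @param regions Region table from [segment_regions()].
#' @param proteins,genomes Protein and genome tables.
#' @return Data frame `kingdom`, `n_terminal`, `central`, `c_terminal`
#'   (fractions of linker residues summing to 1); kingdoms without linker
#'   residues are absent.
#' @export
linker_location_summary <- function(regions, proteins, genomes) {
  lk <- regions[regions$region_type == "linker", , drop = FALSE]
  if (!nrow(lk))
    return(data.frame(kingdom = character(0), n_terminal = numeric(0),
                      central = numeric(0), c_terminal = numeric(0)))
  kingdom <- .kingdom_of(proteins, genomes)[lk$protein_id]
  len <- lk$end - lk$start + 1
  out <- list()
  for (k in .kingdoms) {
    sel <- kingdom == k
    if (!any(sel)) next
    tot <- sum(len[sel])
    out[[length(out) + 1]] <- data.frame(
      kingdom = k,
      n_terminal = sum(len[sel & lk$location == "n_terminal"]) / tot,
      central = sum(len[sel & lk$location == "central"]) / tot,
      c_terminal = sum(len[sel & lk$location == "c_terminal"]) / tot,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
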