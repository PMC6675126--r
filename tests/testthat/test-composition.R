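# Frequency profiles, kingdom deltas, similarity clustering, per-family
# shifts and secondary-structure stratification.

test_that("profiles count residues and exclude non-standard letters", {
  p <- aa_frequencies("SSPP")
  expect_equal(p$freqs[["S"]], 0.5)
  expect_equal(p$freqs[["P"]], 0.5)
  expect_equal(sum(p$freqs), 1)

  px <- aa_frequencies("SSXP")
  expect_equal(px$n, 3)
  expect_equal(px$freqs[["S"]], 2 / 3)
  expect_equal(px$freqs[["P"]], 1 / 3)
  expect_error(aa_frequencies("XXX"), "no countable")
})

test_that("merging profiles equals profiling the concatenation", {
  set.seed(31)
  a <- paste(sample(amino_acids(), 200, TRUE), collapse = "")
  b <- paste(sample(amino_acids(), 77, TRUE), collapse = "")
  merged <- merge_profiles(aa_frequencies(a), aa_frequencies(b))
  pooled <- aa_frequencies(paste0(a, b))
  expect_equal(merged$counts, pooled$counts)
  expect_equal(merged$freqs, pooled$freqs)
})

test_that("kingdom deltas use the eukaryote baseline sign convention", {
  ref <- reference_compositions()
  d <- frequency_difference(ref[, "eukaryote.linker"],
                            ref[, "bacterium.linker"])
  # serine more abundant in eukaryotic linkers: downward (negative) shift
  expect_equal(d[["S"]], -2.422717, tolerance = 1e-5)
  expect_lt(d[["P"]], 0)
  expect_gt(d[["I"]], 0)
  expect_equal(sum(d), 0, tolerance = 1e-9)
  expect_equal(frequency_difference(ref[, 1], ref[, 1]),
               setNames(rep(0, 20), amino_acids()))
})

test_that("profile similarity is a clustered symmetric Pearson matrix", {
  ref <- reference_compositions()
  profs <- as.list(as.data.frame(ref))
  profs <- lapply(profs, setNames, rownames(ref))
  sim <- profile_similarity(profs)
  expect_true(isSymmetric(sim$r))
  expect_equal(unname(diag(sim$r)), rep(1, ncol(ref)))
  expect_true(all(sim$r >= -1 & sim$r <= 1))
  expect_setequal(sim$order, colnames(ref))

  # exact anticorrelation for affinely reversed profiles
  f1 <- (1:20) / 210
  f2 <- (21 - (1:20)) / 210
  s2 <- profile_similarity(list(up = setNames(f1, amino_acids()),
                                down = setNames(f2, amino_acids())))
  expect_equal(s2$r["up", "down"], -1)

  dup <- profile_similarity(list(a = f1, b = f1, c = f2))
  expect_equal(dup$r["a", "b"], 1)
  expect_error(profile_similarity(list(a = rep(0.05, 20),
                                       b = rep(0.05, 20))),
               "zero-variance")
})

test_that("the eukaryotic linker profile is the clustering outlier", {
  # on the planted reference compositions (the generator's truth) the
  # eukaryotic-linker column has the largest mean 1 - r distance
  ref <- reference_compositions()
  sim <- profile_similarity(lapply(as.data.frame(ref), setNames,
                                   rownames(ref)))
  d <- 1 - sim$r
  mean_dist <- rowMeans(d)
  expect_equal(names(which.max(mean_dist)), "eukaryote.linker")
})

test_that("per-family shifts apply the 100-member filter", {
  b <- small_bundle(seed = 37)
  res <- run_pipeline(b)
  fam <- res$families
  inst_e <- setNames(fam$n_instances_eukaryote, fam$family_acc)
  inst_b <- setNames(fam$n_instances_bacterium, fam$family_acc)
  fs <- per_family_shift(res$hits, res$proteins, res$genomes, fam,
                         min_members = 12)
  used <- rownames(fs$deltas$bacterium)
  shared <- fam$family_acc[fam$label == "shared"]
  expect_setequal(used,
                  shared[inst_e[shared] >= 12 & inst_b[shared] >= 12])
  expect_gt(length(used), 0)
  # raising the threshold beyond any family's membership excludes all
  fs2 <- per_family_shift(res$hits, res$proteins, res$genomes, fam,
                          min_members = 10^6)
  expect_equal(fs2$n_families_used, 0)
})

test_that("planted Ser/Pro/Ile family shifts appear in most families", {
  b <- small_bundle(seed = 41, genomes_per_kingdom = 15,
                    proteins_per_genome = 40)
  res <- run_pipeline(b)
  fs <- per_family_shift(res$hits, res$proteins, res$genomes,
                         res$families, min_members = 20)
  expect_gt(fs$n_families_used, 5)
  ex <- fs$euk_excess_fraction$bacterium
  # planted: eukaryotic domains richer in Ser, poorer in Ile
  expect_gt(ex[["S"]], 0.5)
  expect_lt(ex[["I"]], 0.5)
  expect_true(all(unlist(fs$euk_excess_fraction) >= 0 &
                    unlist(fs$euk_excess_fraction) <= 1))
})

test_that("identical kingdom compositions give zero family deltas", {
  fx <- presence_fixture()
  fam <- classify_families(fx$hits, fx$proteins, fx$genomes)
  fs <- per_family_shift(fx$hits, fx$proteins, fx$genomes, fam,
                         min_members = 10)
  expect_equal(unname(fs$deltas$bacterium[1, ]),
               rep(0, 20))  # all instances share one sequence
})

test_that("majority SS labels follow the stated tie and fallback rules", {
  expect_equal(majority_ss(c("H", "H", "E")), "H")
  expect_equal(majority_ss(character(0)), "unassigned")
  expect_equal(majority_ss(c("H", "E")), "C")
  expect_equal(majority_ss(c("E", "E", "C")), "E")
  expect_equal(majority_ss(c("x", "y")), "unassigned")
})

test_that("SS stratification pools residues by column class", {
  p <- data.frame(protein_id = "P1", genome_id = "g",
                  sequence = "WWHHSS", stringsAsFactors = FALSE)
  hits <- data.frame(protein_id = "P1", family_acc = "F1", start = 1,
                     end = 6, score = 1, stringsAsFactors = FALSE)
  ss <- data.frame(family_acc = "F1", column = 1:6,
                   label = c("H", "H", "E", "E", "unassigned", "unassigned"),
                   stringsAsFactors = FALSE)
  out <- ss_stratified_frequencies(hits, p, ss)
  expect_equal(out$profiles$H$freqs[["W"]], 1)
  expect_equal(out$profiles$E$freqs[["H"]], 1)
  expect_equal(out$profiles$disordered$freqs[["S"]], 1)
  # unannotated families are excluded and reported
  hits2 <- rbind(hits, data.frame(protein_id = "P1", family_acc = "F2",
                                  start = 1, end = 3, score = 1))
  out2 <- ss_stratified_frequencies(hits2, p, ss)
  expect_equal(out2$n_families_excluded, 1)
})

test_that("grouping by kingdom reproduces pooled region profiles", {
  b <- small_bundle(seed = 43)
  res <- run_pipeline(b)
  lk <- res$regions[res$regions$region_type == "linker", ]
  by_k <- group_profiles(lk, res$proteins, res$genomes, by = "kingdom")
  for (k in names(by_k)) {
    expect_equal(by_k[[k]]$counts,
                 res$region_profiles[[paste0(k, ".linker")]]$counts)
  }
  # per-phylum counts partition the kingdom counts
  by_ph <- group_profiles(lk, res$proteins, res$genomes, by = "phylum")
  ph_of <- unique(res$genomes[c("phylum", "kingdom")])
  for (k in names(by_k)) {
    phyla <- ph_of$phylum[ph_of$kingdom == k]
    phyla <- intersect(phyla, names(by_ph))
    summed <- Reduce(`+`, lapply(by_ph[phyla], `[[`, "counts"))
    expect_equal(summed, by_k[[k]]$counts)
  }
})
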