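# Family classification, protein grouping, overlap resolution and region
# segmentation.

test_that("families shared across kingdoms satisfy both presence rules", {
  fx <- presence_fixture(n_euk = 12, n_bac = 11)
  fam <- classify_families(fx$hits, fx$proteins, fx$genomes)
  expect_equal(fam$label, "shared")
  expect_equal(fam$n_genomes_eukaryote, 12)
  expect_equal(fam$n_genomes_bacterium, 11)

  # family only in bacteria fails eukaryote presence
  bac_only <- fx
  bac_only$hits <- fx$hits[grepl("^p_b", fx$hits$protein_id), , drop = FALSE]
  fam2 <- classify_families(bac_only$hits, fx$proteins, fx$genomes)
  expect_equal(fam2$label, "nonshared")
})

test_that("prokaryote presence pools bacterial and archaeal genomes", {
  fx <- presence_fixture(n_euk = 12, n_bac = 6)
  # add 5 archaeal genomes: 6 + 5 = 11 prokaryotes jointly
  arc <- data.frame(genome_id = sprintf("a%02d", 1:5), kingdom = "archaeon",
                    phylum = "ph", genus = "gen", gc = 0.45,
                    stringsAsFactors = FALSE)
  genomes <- rbind(fx$genomes, arc)
  prot_a <- data.frame(protein_id = paste0("p_", arc$genome_id),
                       genome_id = arc$genome_id,
                       sequence = strrep("ACDEFGHIKLMNPQRSTVWY", 6),
                       stringsAsFactors = FALSE)
  proteins <- rbind(fx$proteins, prot_a)
  hits <- rbind(fx$hits,
                data.frame(protein_id = prot_a$protein_id,
                           family_acc = "SFx", start = 11, end = 60,
                           score = 50, stringsAsFactors = FALSE))
  fam <- classify_families(hits, proteins, genomes)
  expect_equal(fam$label, "shared")
})

test_that("a 99.9%+ single-kingdom instance share vetoes sharing", {
  # 10 euk genomes (one with 20,000 instances) + 10 bacterial genomes with
  # one instance each: presence rule passes, share rule fails
  n_inst <- 20000
  genomes <- data.frame(
    genome_id = c(sprintf("e%02d", 1:10), sprintf("b%02d", 1:10)),
    kingdom = rep(c("eukaryote", "bacterium"), each = 10),
    phylum = "ph", genus = "gen", gc = 0.45, stringsAsFactors = FALSE)
  proteins <- data.frame(
    protein_id = paste0("p_", genomes$genome_id),
    genome_id = genomes$genome_id,
    sequence = strrep("ACDEFGHIKLMNPQRSTVWY", 6),
    stringsAsFactors = FALSE)
  hits <- data.frame(
    protein_id = c(rep("p_e01", n_inst - 9),          # heavy eukaryote load
                   paste0("p_", sprintf("e%02d", 2:10)),
                   paste0("p_", sprintf("b%02d", 1:10))),
    family_acc = "SFx", start = 1, end = 10, score = 1,
    stringsAsFactors = FALSE)
  fam <- classify_families(hits, proteins, genomes)
  share <- fam$n_instances_eukaryote /
    (fam$n_instances_eukaryote + fam$n_instances_bacterium)
  expect_gt(share, 0.999)
  expect_equal(fam$label, "nonshared")
})

test_that("classification matches a brute-force recount", {
  b <- small_bundle(seed = 13)
  fam <- classify_families(b$hits, b$proteins, b$genomes)
  # independent tabulation straight from the hit rows
  gid <- setNames(b$proteins$genome_id, b$proteins$protein_id)
  kg <- setNames(b$genomes$kingdom, b$genomes$genome_id)
  for (f in fam$family_acc) {
    rows <- b$hits[b$hits$family_acc == f, ]
    ks <- kg[gid[rows$protein_id]]
    gs <- gid[rows$protein_id]
    n_gen <- c(eukaryote = length(unique(gs[ks == "eukaryote"])),
               bacterium = length(unique(gs[ks == "bacterium"])),
               archaeon = length(unique(gs[ks == "archaeon"])))
    n_inst <- c(eukaryote = sum(ks == "eukaryote"),
                bacterium = sum(ks == "bacterium"),
                archaeon = sum(ks == "archaeon"))
    expected <- if (n_gen[["eukaryote"]] >= 10 &&
                    n_gen[["bacterium"]] + n_gen[["archaeon"]] >= 10 &&
                    max(n_inst) / sum(n_inst) <= 0.999) "shared" else
                      "nonshared"
    row <- fam[fam$family_acc == f, ]
    expect_equal(unname(unlist(
      row[c("n_genomes_eukaryote", "n_genomes_bacterium",
            "n_genomes_archaeon")])), unname(n_gen))
    expect_equal(row$label, expected)
  }
})

test_that("protein grouping is a trichotomy invariant to hit order", {
  fx <- presence_fixture()
  fam <- classify_families(fx$hits, fx$proteins, fx$genomes)
  # protein with one shared + one nonshared hit is a shared protein
  extra <- data.frame(protein_id = c("p_e01", "p_e01"),
                      family_acc = c("LONER", "LONER"),
                      start = c(61, 71), end = c(70, 80), score = 1,
                      stringsAsFactors = FALSE)
  hits <- rbind(fx$hits, extra)
  fam <- classify_families(hits, fx$proteins, fx$genomes)
  proteins <- rbind(fx$proteins,
                    data.frame(protein_id = "naked", genome_id = "e01",
                               sequence = "ACDEFGHIKL",
                               stringsAsFactors = FALSE),
                    data.frame(protein_id = "loner_only", genome_id = "e02",
                               sequence = strrep("ACDEFGHIKL", 10),
                               stringsAsFactors = FALSE))
  hits <- rbind(hits, data.frame(protein_id = "loner_only",
                                 family_acc = "LONER", start = 1, end = 10,
                                 score = 1, stringsAsFactors = FALSE))
  fam <- classify_families(hits, proteins, fx$genomes)
  g1 <- assign_groups(proteins, hits, fam)
  grp <- setNames(g1$group, g1$protein_id)
  expect_equal(grp[["p_e01"]], "shared_protein")
  expect_equal(grp[["naked"]], "no_domain_protein")
  expect_equal(grp[["loner_only"]], "kingdom_specific_protein")
  # shuffled hits give the identical assignment
  set.seed(5)
  g2 <- assign_groups(proteins, hits[sample(nrow(hits)), ], fam)
  expect_equal(g2[order(g2$protein_id), ], g1[order(g1$protein_id), ],
               ignore_attr = TRUE)
})

test_that("overlap resolution is greedy by score with stated tie-breaks", {
  h <- data.frame(protein_id = "P", family_acc = c("A", "B"),
                  start = c(1, 60), end = c(50, 90), score = c(30, 20),
                  stringsAsFactors = FALSE)
  expect_equal(nrow(resolve_overlaps(h)), 2)  # disjoint: unchanged

  h2 <- data.frame(protein_id = "P", family_acc = c("A", "B"),
                   start = c(1, 40), end = c(50, 90), score = c(30, 20),
                   stringsAsFactors = FALSE)
  out <- resolve_overlaps(h2)
  expect_equal(out$family_acc, "A")  # higher score wins, overlap dropped

  # equal score and length: smaller start wins
  h3 <- data.frame(protein_id = "P", family_acc = c("B", "A"),
                   start = c(15, 10), end = c(25, 20), score = c(5, 5),
                   stringsAsFactors = FALSE)
  out3 <- resolve_overlaps(h3)
  expect_equal(out3$start, 10)

  # equal score: longer hit wins
  h4 <- data.frame(protein_id = "P", family_acc = c("A", "B"),
                   start = c(10, 5), end = c(20, 25), score = c(5, 5),
                   stringsAsFactors = FALSE)
  expect_equal(resolve_overlaps(h4)$family_acc, "B")
})

test_that("segmentation labels every residue exactly once", {
  fx <- presence_fixture()
  fam <- classify_families(fx$hits, fx$proteins, fx$genomes)
  groups <- assign_groups(fx$proteins, fx$hits, fam)
  reg <- segment_regions(fx$proteins, fx$hits, fam, groups)
  one <- reg[reg$protein_id == "p_e01", ]
  expect_equal(one$region_type, c("linker", "shared_domain", "linker"))
  expect_equal(one$location[c(1, 3)], c("n_terminal", "c_terminal"))
  expect_equal(one$start, c(1, 11, 61))
  expect_equal(one$end, c(10, 60, 120))
})

test_that("mixed shared/specific architectures get central linkers", {
  fx <- presence_fixture()
  proteins <- fx$proteins
  proteins$sequence[1] <- strrep("ACDEFGHIKL", 10)  # L = 100
  hits <- rbind(fx$hits[-1, ],
                data.frame(protein_id = "p_e01", family_acc = "SFx",
                           start = 1, end = 40, score = 9,
                           stringsAsFactors = FALSE),
                data.frame(protein_id = "p_e01", family_acc = "ONLYME",
                           start = 61, end = 100, score = 9,
                           stringsAsFactors = FALSE))
  fam <- classify_families(hits, proteins, fx$genomes)
  reg <- segment_regions(proteins, hits, fam)
  one <- reg[reg$protein_id == "p_e01", ]
  expect_equal(one$region_type,
               c("shared_domain", "linker", "specific_domain"))
  expect_equal(one$location[2], "central")
  expect_equal(one$start[one$region_type == "linker"], 41)
  expect_equal(one$end[one$region_type == "linker"], 60)
})

test_that("hits tiling the whole protein leave no linker", {
  fx <- presence_fixture(min_len = 100)
  hits <- fx$hits
  hits$start <- 1
  hits$end <- nchar(fx$proteins$sequence[1])
  fam <- classify_families(hits, fx$proteins, fx$genomes)
  reg <- segment_regions(fx$proteins, hits, fam)
  expect_gt(nrow(reg), 0)
  expect_false(any(reg$region_type == "linker"))
})

test_that("regions exactly partition [1, L] on synthetic shared proteins", {
  b <- small_bundle(seed = 17)
  res <- run_pipeline(b)
  reg <- res$regions
  len <- setNames(nchar(res$proteins$sequence), res$proteins$protein_id)
  by_prot <- split(reg$end - reg$start + 1, reg$protein_id)
  sums <- vapply(by_prot, sum, numeric(1))
  expect_equal(unname(sums), unname(len[names(by_prot)]))
  # intervals sorted and non-overlapping within each protein
  for (pid in sample(names(by_prot), 50)) {
    r <- reg[reg$protein_id == pid, ]
    r <- r[order(r$start), ]
    expect_true(all(r$start[-1] == r$end[-nrow(r)] + 1))
    expect_equal(r$start[1], 1)
  }
})

test_that("linker locations summarize as planted fractions", {
  # one protein with 10-residue linkers around a central domain: 0.5/0/0.5
  g <- toy_genomes()
  p <- data.frame(protein_id = "P1", genome_id = "ge1",
                  sequence = strrep("ACDEFGHIKL", 10),
                  stringsAsFactors = FALSE)
  fam <- data.frame(family_acc = "F", label = "shared",
                    stringsAsFactors = FALSE)
  reg <- data.frame(protein_id = "P1",
                    region_type = c("linker", "shared_domain", "linker"),
                    location = c("n_terminal", NA, "c_terminal"),
                    start = c(1, 11, 91), end = c(10, 90, 100),
                    stringsAsFactors = FALSE)
  ls <- linker_location_summary(reg, p, g)
  expect_equal(ls$n_terminal, 0.5)
  expect_equal(ls$central, 0)
  expect_equal(ls$c_terminal, 0.5)
  expect_true(all(abs(rowSums(ls[, -1]) - 1) < 1e-12))
})

test_that("the planted 40/20/40 linker split is recovered", {
  b <- small_bundle(seed = 19, genomes_per_kingdom = 10,
                    proteins_per_genome = 40)
  res <- run_pipeline(b)
  ls <- res$linker_location
  truth <- b$truth$linker_split_expected
  for (k in ls$kingdom) {
    exp_split <- truth[[k]]
    got <- unlist(ls[ls$kingdom == k, c("n_terminal", "central",
                                        "c_terminal")])
    # generous binomial-style bound at this sample size
    expect_true(all(abs(got - exp_split) < 0.03),
                info = paste(k, paste(round(got, 3), collapse = "/")))
  }
})
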