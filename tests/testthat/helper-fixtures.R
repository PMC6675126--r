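# Small in-code fixtures shared across test files.

toy_genomes <- function() {
  data.frame(
    genome_id = c("ge1", "ge2", "gb1", "gb2", "ga1"),
    kingdom = c("eukaryote", "eukaryote", "bacterium", "bacterium",
                "archaeon"),
    phylum = c("Chordata", "Ascomycota", "Proteobacteria", "Firmicutes",
               "Euryarchaeota"),
    genus = c("Homo", "Saccharomyces", "Escherichia", "Bacillus",
              "Methanococcus"),
    gc = c(0.41, 0.38, 0.50, 0.44, 0.45),
    stringsAsFactors = FALSE)
}

toy_proteins <- function() {
  data.frame(
    protein_id = c("P1", "P2", "P3"),
    genome_id = c("ge1", "gb1", "ga1"),
    sequence = c(strrep("ACDEFGHIKL", 10),   # L = 100
                 strrep("MNPQRSTVWY", 8),    # L = 80
                 strrep("ACDEFGHIKL", 6)),   # L = 60
    stringsAsFactors = FALSE)
}

# Genomes/proteins/hits where family SFx is present in >= min_genomes
# eukaryotic and prokaryotic genomes; used by partition tests.
presence_fixture <- function(n_euk = 12, n_bac = 11, min_len = 120) {
  genomes <- data.frame(
    genome_id = c(sprintf("e%02d", seq_len(n_euk)),
                  sprintf("b%02d", seq_len(n_bac))),
    kingdom = c(rep("eukaryote", n_euk), rep("bacterium", n_bac)),
    phylum = "ph", genus = "gen", gc = 0.45, stringsAsFactors = FALSE)
  proteins <- data.frame(
    protein_id = paste0("p_", genomes$genome_id),
    genome_id = genomes$genome_id,
    sequence = strrep("ACDEFGHIKLMNPQRSTVWY", ceiling(min_len / 20)),
    stringsAsFactors = FALSE)
  hits <- data.frame(protein_id = proteins$protein_id,
                     family_acc = "SFx", start = 11, end = 60,
                     score = 50, stringsAsFactors = FALSE)
  list(genomes = genomes, proteins = proteins, hits = hits)
}

# i.i.d. codon probabilities at a given GC, enumerated independently of the
# package internals (used as an oracle)
.codon_probs_for_test <- function(gc, code) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  codons <- names(code)
  vapply(strsplit(codons, "", fixed = TRUE),
         function(ch) prod(p[ch]), numeric(1)) |>
    stats::setNames(codons)
}

# Uniform random frequency profile (Dirichlet(1) via normalized exponentials)
random_profile <- function() {
  x <- stats::rexp(20)
  stats::setNames(x / sum(x), amino_acids())
}

small_bundle <- function(seed = 7, genomes_per_kingdom = 12,
                         proteins_per_genome = 30) {
  n <- genomes_per_kingdom
  # tight GC spread keeps every genome inside the filter window, so the
  # fixture never drops below the 10-genome family-presence threshold
  spec <- synthetic_spec(
    n_genomes = c(eukaryote = n, bacterium = n, archaeon = n),
    proteins_per_genome = proteins_per_genome,
    n_shared_families = 8,
    gc_sd = c(eukaryote = 0.03, bacterium = 0.03, archaeon = 0.03))
  generate_proteomes(spec, seed = seed)
}
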