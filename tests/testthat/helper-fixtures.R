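# shared fixtures: tiny simulated screens and brute-force set oracles

# a controls-only 384-format layout (no library genes)
controls_layout <- function(scheme = c(siCTL = 72, siMARK4 = 16), seed = 1) {
  layout_plates(build_kinome_library(0), 384, scheme, seed = seed)
}

# one simulated localization screen line; returns list(lib, zs, hits, ...)
simulate_loc_screen <- function(seed, n_genes = 720, n_inh = 20,
                                effect = 3, well_sd = 1, mark4 = 6,
                                n_replicates = 2) {
  lib <- build_kinome_library(n_genes, n_loc_inhibitors = n_inh,
                              effect_magnitude = effect, seed = seed)
  lay <- layout_plates(lib, 384, c(siCTL = 72, siMARK4 = 16), seed = seed)
  wells <- simulate_localization_wells(
    lay, lib, mark4_effect = mark4,
    noise = noise_model(well_sd = well_sd, seed = seed),
    n_replicates = n_replicates)
  zs <- compute_zscores(normalize_to_controls(wells))
  list(lib = lib, layout = lay, wells = wells, zs = zs,
       hits = call_cytoplasmic_hits(top_fraction(zs, 0.25)),
       spiked = lib$gene_id[lib$loc_class == "inhibitor"])
}

# element-by-element membership enumeration, independent of venn_counts()
brute_force_regions <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  k <- length(sets)
  counts <- integer(0)
  for (pattern in seq_len(2^k - 1)) {
    inset <- as.logical(bitwAnd(pattern, 2^(seq_len(k) - 1)))
    n <- 0L
    for (el in universe) {
      memb <- vapply(sets, function(s) el %in% s, logical(1))
      if (all(memb == inset)) n <- n + 1L
    }
    counts[paste(names(sets)[inset], collapse = "&")] <- n
  }
  counts
}

random_gene_sets <- function(k, universe_size, sizes, seed) {
  set.seed(seed)
  universe <- sprintf("G%04d", seq_len(universe_size))
  sets <- lapply(sizes, function(n) sample(universe, n))
  names(sets) <- LETTERS[seq_len(k)]
  sets
}
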