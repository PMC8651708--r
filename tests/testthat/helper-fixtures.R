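# Heavy shared fixtures, built once per test run. The default panel matches
# the study conditions: 190 tetraploid individuals, 3 weakly separated
# subpopulations, 3262 biallelic dosage SNPs.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_panel <- function() {
  fixture("panel", function() simulate_panel(sim_config(), seed = 20260925))
}

default_A <- function() {
  fixture("A", function() vanraden_A(default_panel()))
}

default_similarity <- function() {
  fixture("S", function() to_similarity(euclidean_distance(default_panel())))
}

# tuber-length-like trait: high heritability, moderately sparse architecture
default_trait <- function() {
  fixture("trait", function() {
    simulate_trait(default_panel(), n_qtl = 50, h2 = 0.91,
                   trait_name = "length", seed = 31)
  })
}
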