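# Shared fixtures: printed notation strings, reduced rule sets and toy
# models used across test files.

MAN5_STR <- "GlcNAc4.1GlcNAc4.1Man(3.1Man:)_m6.1Man(3.1Man:)_m6.1Man:@"
COMPLEX_STR <- paste0("GlcNAc4.1GlcNAc4.1Man(3.1Man2.1GlcNAc4.1Gal:)",
                      "_m6.1Man2.1GlcNAc4.1Gal6.2Sia:@")

# Rule set restricted to a subset of enzymes.
restrict_rules <- function(enzymes, base = default_mammalian_rules()) {
  base$rules <- Filter(function(r) r$enzyme %in% enzymes, base$rules)
  base
}

# Single-reaction toy: Man5 + MGAT1 only (A -> B at rate k).
toy_single_model <- function(k, cisternae = 1L, residence = 10) {
  rates <- matrix(k, 1L, cisternae, dimnames = list("MGAT1", NULL))
  golgi_model(rates, residence_time = residence,
              input_distribution = c(Man5 = 1))
}

toy_single_ruleset <- function() restrict_rules("MGAT1")

# Three-way competition from Man5: first antenna (MGAT1), core fucose on
# Man5 (FUT8 at its scale factor), quench.
toy_competing_model <- function(k_mgat1, k_fut8, k_quench, residence = 10) {
  rates <- matrix(c(k_mgat1, k_fut8, k_quench), 3L, 1L,
                  dimnames = list(c("MGAT1", "FUT8", "OMquench"), NULL))
  golgi_model(rates, residence_time = residence,
              input_distribution = c(Man5 = 1))
}

toy_competing_ruleset <- function() restrict_rules(c("MGAT1", "FUT8", "OMquench"))

# Random valid glycan trees for property tests: random pathway states
# reached by random rule applications from a random input species.
random_reachable_glycan <- function(ruleset = default_mammalian_rules(),
                                    max_steps = 25L) {
  g <- pathway_glycan(sample(c("Man8", "Man9", "Man9Glc"), 1L))
  for (i in seq_len(sample.int(max_steps, 1L))) {
    hits <- list()
    for (rule in ruleset$rules) {
      sites <- match_sites(rule, g)
      for (s in sites) hits[[length(hits) + 1L]] <- list(rule = rule, site = s)
    }
    if (!length(hits)) break
    h <- hits[[sample.int(length(hits), 1L)]]
    g <- apply_rule(h$rule, g, h$site)
  }
  g
}

# Fully random residue trees (not pathway-constrained) for parser/canonical
# property tests.
random_tree_glycan <- function(max_children = 3L, depth = 3L) {
  build <- function(d, linkage) {
    sugar <- sample(c("GlcNAc", "Man", "Gal", "Fuc", "NeuAc", "Glc"), 1L)
    node <- list(sugar = sugar, linkage = linkage, children = list())
    if (d > 0L) {
      for (j in seq_len(sample.int(max_children + 1L, 1L) - 1L)) {
        lk <- paste0(sample(2:6, 1L), ".", sample(1:2, 1L))
        node$children[[length(node$children) + 1L]] <- build(d - 1L, lk)
      }
    }
    node
  }
  glycan(build(depth, ""))
}
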