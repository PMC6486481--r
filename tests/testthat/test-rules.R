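# Enzyme rule matching, application, propensities and the default
# mammalian rule set.

rs <- default_mammalian_rules()
rule_by_name <- function(name, set = rs)
  set$rules[[which(vapply(set$rules, `[[`, "", "name") == name)]]

# count Man residues directly from the serialization
count_man <- function(g) {
  s <- glycan_serialize(g)
  length(gregexpr("Man", s, fixed = TRUE)[[1L]])
}

test_that("MGAT1 matches exactly the 3-arm core mannose of Man5", {
  sites <- match_sites(rule_by_name("MGAT1_first_antenna"),
                       pathway_glycan("Man5"))
  expect_length(sites, 1L)
  # and nothing on Man9 (guard man_eq = 5) or on hybrids (antenna guard)
  expect_length(match_sites(rule_by_name("MGAT1_first_antenna"),
                            pathway_glycan("Man9")), 0L)
  hybrid <- apply_rule(rule_by_name("MGAT1_first_antenna"),
                       pathway_glycan("Man5"), sites[[1L]])
  expect_length(match_sites(rule_by_name("MGAT1_first_antenna"), hybrid), 0L)
})

test_that("GalT site multiplicity counts ungalactosylated antennae", {
  expect_length(match_sites(rule_by_name("GalT_antenna"),
                            pathway_glycan("Man5")), 0L)
  # bi-antennary complex with two open antennae
  bi <- glycan_parse(paste0("GlcNAc4.1GlcNAc4.1Man(3.1Man2.1GlcNAc:)",
                            "_m6.1Man2.1GlcNAc:@"))
  sites <- match_sites(rule_by_name("GalT_antenna"), bi)
  expect_length(sites, 2L)
  g1 <- apply_rule(rule_by_name("GalT_antenna"), bi, sites[[1L]])
  expect_length(match_sites(rule_by_name("GalT_antenna"), g1), 1L)
  # the galactosylated antenna terminates in a 4.1 Gal
  expect_equal(glycan_composition(g1)[["Hex"]] -
                 glycan_composition(bi)[["Hex"]], 1L)
})

test_that("MAN2 applied twice to the MGAT1 product leaves a Man3 core", {
  g <- pathway_glycan("Man5")
  g <- apply_rule(rule_by_name("MGAT1_first_antenna"), g,
                  match_sites(rule_by_name("MGAT1_first_antenna"), g)[[1L]])
  expect_equal(glycan_class(g), "hybrid")
  man2 <- rule_by_name("MAN2_trim")
  sites <- match_sites(man2, g)
  expect_length(sites, 2L)
  g <- apply_rule(man2, g, sites[[1L]])
  g <- apply_rule(man2, g, match_sites(man2, g)[[1L]])
  expect_equal(count_man(g), 3L)
  expect_equal(glycan_class(g), "complex")
  expect_length(match_sites(man2, g), 0L)
})

test_that("rule application changes composition by exactly the rule's unit", {
  set.seed(13)
  for (i in 1:80) {
    g <- random_reachable_glycan()
    for (rule in rs$rules) {
      sites <- match_sites(rule, g)
      if (!length(sites)) next
      s <- sites[[sample.int(length(sites), 1L)]]
      g2 <- apply_rule(rule, g, s)
      d <- glycan_composition(g2) - glycan_composition(g)
      if (rule$action == "add") {
        expect_equal(sum(abs(d)), 1L, info = rule$name)
      } else if (rule$action == "remove") {
        expect_equal(sum(abs(d)), 1L, info = rule$name)
      } else if (rule$action == "remove_subtree") {
        expect_equal(d[["Glc"]], -1L, info = rule$name)  # endo-mannosidase unit
        expect_equal(d[["Hex"]], -1L, info = rule$name)
      } else {
        expect_equal(sum(abs(d)), 0L)
        expect_true(golgisim:::is_quenched(g2))
      }
      # serialization of the product is a valid parseable structure
      expect_s3_class(glycan_parse(glycan_serialize(g2)), "glycan")
    }
  }
})

test_that("quenched glycans match no rule and enumerate no reactions", {
  g <- pathway_glycan("Man5")
  q <- apply_rule(rule_by_name("OM_quench"), g, integer())
  expect_true(golgisim:::is_quenched(q))
  for (rule in rs$rules) expect_length(match_sites(rule, q), 0L)
  rates <- setNames(rep(1, length(rule_enzymes(rs$rules))),
                    rule_enzymes(rs$rules))
  expect_length(enumerate_reactions(q, rs$rules, rs$scales, rates), 0L)
})

test_that("applying at a non-matching site is a precondition error", {
  g <- pathway_glycan("Man9")
  expect_error(apply_rule(rule_by_name("MGAT1_first_antenna"), g, c(1L, 1L)),
               "does not match")
})

test_that("propensities combine rate, multiplicity and scale factors", {
  enz <- rule_enzymes(rs$rules)
  rates <- setNames(rep(0, length(enz)), enz)
  # single site, unit scale: Man5 + MGAT1 at rate k
  rates["MGAT1"] <- 0.3
  inst <- enumerate_reactions(pathway_glycan("Man5"), rs$rules, rs$scales, rates)
  expect_length(inst, 1L)
  expect_equal(inst[[1L]]$propensity, 0.3)
  # bi-antennary with 2 open antennae at >= 3 antennae the branched GalT
  # scale applies; at 2 antennae it does not
  bi <- glycan_parse(paste0("GlcNAc4.1GlcNAc4.1Man(3.1Man2.1GlcNAc:)",
                            "_m6.1Man2.1GlcNAc:@"))
  rates[] <- 0; rates["GalT"] <- 2
  inst <- enumerate_reactions(bi, rs$rules, rs$scales, rates)
  expect_length(inst, 2L)
  expect_equal(attr(inst, "total"), 2 * 2 * 1)
  tri <- apply_rule(rule_by_name("MGAT4_third_antenna"), bi,
                    match_sites(rule_by_name("MGAT4_third_antenna"), bi)[[1L]])
  inst3 <- enumerate_reactions(tri, rs$rules, rs$scales, rates)
  expect_length(inst3, 3L)
  expect_equal(attr(inst3, "total"), 3 * 2 * 0.5)  # branched scale factor
  # linearity: doubling the rate doubles every propensity
  rates2 <- rates; rates2["GalT"] <- 4
  inst6 <- enumerate_reactions(tri, rs$rules, rs$scales, rates2)
  expect_equal(vapply(inst6, `[[`, 0, "propensity"),
               2 * vapply(inst3, `[[`, 0, "propensity"))
})

test_that("unknown enzymes in the rate map are a configuration error", {
  expect_error(enumerate_reactions(pathway_glycan("Man5"), rs$rules,
                                   rs$scales, c(MGAT1 = 1)),
               "no rate given")
})

test_that("FUT8 needs an antenna unless the Man5 context applies", {
  enz <- rule_enzymes(rs$rules)
  rates <- setNames(rep(0, length(enz)), enz); rates["FUT8"] <- 1
  # bare Man5: only via the Man5 rule, at the 0.1 scale factor
  inst <- enumerate_reactions(pathway_glycan("Man5"), rs$rules, rs$scales, rates)
  expect_length(inst, 1L)
  expect_equal(inst[[1L]]$propensity, 0.1)
  # Man9 (no antenna, not Man5): no FUT8 reaction at all
  expect_length(enumerate_reactions(pathway_glycan("Man9"), rs$rules,
                                    rs$scales, rates), 0L)
})

test_that("reachability closure is finite with capped antennae and >=3 Man", {
  net <- compile_network(rs$rules, rs$scales, c("Man8", "Man9", "Man9Glc"))
  expect_true(nrow(net$states) < 10000L)
  expect_true(max(net$states$antennae) <= 4L)
  man_counts <- vapply(strsplit(net$states$structure, "Man"), length, 0L) - 1L
  expect_true(min(man_counts) >= 3L)
  # the printed complex glycan is reachable from the ER inputs
  target <- glycan_serialize(glycan_parse(COMPLEX_STR))
  expect_true(target %in% net$states$structure)
})

test_that("the shipped rules file reproduces the in-code default set", {
  shipped <- read_rules_config(default_rules_path())
  expect_identical(lapply(shipped$rules, unclass),
                   lapply(rs$rules, unclass))
  expect_identical(unclass(shipped$scales), unclass(rs$scales))
})
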