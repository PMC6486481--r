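# Rule-based enzyme reactions over glycan trees.
#
# A rule is a declarative record: an enzyme name, an action (add / remove /
# remove_subtree / quench), the residue added (for "add"), a target-residue
# pattern and whole-glycan guards.  Patterns and guards are conjunctions of
# simple named predicates so the shipped YAML rules file can express the
# default rule set exactly.

#' Define an enzyme rule
#'
#' @param name unique rule identifier.
#' @param enzyme enzyme (parameter) name; several rules may share an enzyme.
#' @param action one of `"add"`, `"remove"`, `"remove_subtree"`, `"quench"`.
#' @param sugar,linkage residue added for `action = "add"`.
#' @param target named list of target-residue predicates: `sugar`,
#'   `linkage` (allowed linkage codes), `leaf`, `is_root`, `parent_sugar`,
#'   `parent_is_core` (parent is the core beta-mannose), `parent_arm6`
#'   (parent is the 6.1-arm mannose), `lacks_child_sugar`, `lacks_child_at`,
#'   `has_bare_gn_child` (a 2.1 GlcNAc leaf child is present),
#'   `glc_cap_unit` (a 2.1 mannose whose only child is a Glc leaf),
#'   `no_sia_in_subtree`.
#' @param guards named list of whole-glycan guards: `man_eq`, `man_min`,
#'   `man_max`, `antennae_min`, `antennae_max`, `glc_eq`, `class_in`.
#' @param scale_factor_id optional id into the scale-factor table.
#' @return An object of class `"enzyme_rule"`.
#' @export
enzyme_rule <- function(name, enzyme, action, sugar = NULL, linkage = NULL,
                        target = list(), guards = list(),
                        scale_factor_id = NULL) {
  action <- match.arg(action, c("add", "remove", "remove_subtree", "quench"))
  if (action == "add" && (is.null(sugar) || is.null(linkage)))
    stop("add rule needs sugar and linkage")
  structure(list(name = name, enzyme = enzyme, action = action,
                 sugar = sugar, linkage = linkage, target = target,
                 guards = guards, scale_factor_id = scale_factor_id),
            class = "enzyme_rule")
}

#' Scale-factor table constructor
#'
#' Context-dependent multipliers on an enzyme's effective rate.  Context
#' fields (`man_eq`, `antennae_min`, `arm`) are NA when unconstrained; for a
#' given enzyme at most one entry may match any (glycan, site).
#'
#' @param id,enzyme,multiplier,man_eq,antennae_min,arm vectors of equal length.
#' @return A `data.frame` with class `"scale_factor_table"`.
#' @export
scale_factor_table <- function(id = character(), enzyme = character(),
                               multiplier = numeric(), man_eq = NA_integer_,
                               antennae_min = NA_integer_, arm = NA_character_) {
  stopifnot(all(multiplier > 0))
  structure(data.frame(id = id, enzyme = enzyme, multiplier = multiplier,
                       man_eq = man_eq, antennae_min = antennae_min, arm = arm,
                       stringsAsFactors = FALSE),
            class = c("scale_factor_table", "data.frame"))
}

glycan_meta <- function(g) {
  list(man = n_sugar(g, "Man"), glc = n_sugar(g, "Glc"),
       antennae = n_antennae(g), class = glycan_class(g),
       quenched = is_quenched(g))
}

.check_guards <- function(gd, meta) {
  if (!is.null(gd$man_eq) && meta$man != gd$man_eq) return(FALSE)
  if (!is.null(gd$man_min) && meta$man < gd$man_min) return(FALSE)
  if (!is.null(gd$man_max) && meta$man > gd$man_max) return(FALSE)
  if (!is.null(gd$antennae_min) && meta$antennae < gd$antennae_min) return(FALSE)
  if (!is.null(gd$antennae_max) && meta$antennae > gd$antennae_max) return(FALSE)
  if (!is.null(gd$glc_eq) && meta$glc != gd$glc_eq) return(FALSE)
  if (!is.null(gd$class_in) && !(meta$class %in% gd$class_in)) return(FALSE)
  TRUE
}

.check_target <- function(t, node, ancestors) {
  parent <- if (length(ancestors)) ancestors[[length(ancestors)]] else NULL
  gparent <- if (length(ancestors) > 1L) ancestors[[length(ancestors) - 1L]] else NULL
  ggparent <- if (length(ancestors) > 2L) ancestors[[length(ancestors) - 2L]] else NULL
  if (!is.null(t$sugar) && node$sugar != t$sugar) return(FALSE)
  if (!is.null(t$linkage) && !(node$linkage %in% t$linkage)) return(FALSE)
  if (isTRUE(t$leaf) && length(node$children) > 0L) return(FALSE)
  if (isTRUE(t$is_root) && !is.null(parent)) return(FALSE)
  if (!is.null(t$parent_sugar) &&
      (is.null(parent) || parent$sugar != t$parent_sugar)) return(FALSE)
  if (isTRUE(t$parent_is_core)) {
    ok <- !is.null(parent) && parent$sugar == "Man" &&
      !is.null(gparent) && gparent$sugar == "GlcNAc"
    if (!ok) return(FALSE)
  }
  if (isTRUE(t$parent_arm6)) {
    ok <- !is.null(parent) && parent$sugar == "Man" && parent$linkage == "6.1" &&
      !is.null(gparent) && gparent$sugar == "Man" &&
      !is.null(ggparent) && ggparent$sugar == "GlcNAc"
    if (!ok) return(FALSE)
  }
  if (!is.null(t$lacks_child_sugar)) {
    kid_sugars <- vapply(node$children, `[[`, "", "sugar")
    if (any(kid_sugars %in% t$lacks_child_sugar)) return(FALSE)
  }
  if (!is.null(t$lacks_child_at)) {
    kid_lk <- vapply(node$children, `[[`, "", "linkage")
    if (t$lacks_child_at %in% kid_lk) return(FALSE)
  }
  if (isTRUE(t$has_bare_gn_child)) {
    ok <- any(vapply(node$children, function(ch)
      ch$sugar == "GlcNAc" && ch$linkage == "2.1" && length(ch$children) == 0L,
      logical(1)))
    if (!ok) return(FALSE)
  }
  if (isTRUE(t$glc_cap_unit)) {
    ok <- node$sugar == "Man" && node$linkage == "2.1" &&
      length(node$children) == 1L &&
      node$children[[1L]]$sugar == "Glc" &&
      length(node$children[[1L]]$children) == 0L
    if (!ok) return(FALSE)
  }
  if (isTRUE(t$no_sia_in_subtree)) {
    if (.subtree_has_sugar(node, "NeuAc")) return(FALSE)
  }
  TRUE
}

.subtree_has_sugar <- function(node, sugar) {
  if (node$sugar == sugar) return(TRUE)
  for (ch in node$children) if (.subtree_has_sugar(ch, sugar)) return(TRUE)
  FALSE
}

# Depth-first preorder site search; returns list of integer paths plus the
# Golgi arm ("3.1"/"6.1"/NA) each site descends from.
.match_walk <- function(node, ancestors, path, arm, t, acc) {
  if (.check_target(t, node, ancestors)) {
    acc$sites[[length(acc$sites) + 1L]] <- path
    acc$arms[[length(acc$arms) + 1L]] <- arm
  }
  is_core <- node$sugar == "Man" && length(ancestors) &&
    ancestors[[length(ancestors)]]$sugar == "GlcNAc"
  anc2 <- c(ancestors, list(node))
  for (j in seq_along(node$children)) {
    ch <- node$children[[j]]
    .match_walk(ch, anc2, c(path, j), if (is_core) ch$linkage else arm, t, acc)
  }
}

#' Enumerate sites in a glycan matching a rule
#'
#' @param rule an [enzyme_rule()].
#' @param g a [glycan()] (canonicalized internally).
#' @return List of integer child-index paths (root = empty path), in
#'   deterministic depth-first canonical order; empty when no site matches
#'   or the glycan is quenched or fails a whole-glycan guard.
#' @export
match_sites <- function(rule, g) {
  g <- glycan_canonical(g)
  meta <- glycan_meta(g)
  if (meta$quenched) return(list())
  if (!.check_guards(rule$guards, meta)) return(list())
  if (rule$action == "quench") return(list(integer()))
  acc <- new.env(); acc$sites <- list(); acc$arms <- list()
  .match_walk(unclass(g), list(), integer(), NA_character_, rule$target, acc)
  attr(acc$sites, "arms") <- unlist(acc$arms, use.names = FALSE)
  acc$sites
}

.node_at <- function(node, path) {
  for (j in path) node <- node$children[[j]]
  node
}

.modify_at <- function(node, path, fun) {
  if (length(path) == 0L) return(fun(node))
  j <- path[[1L]]
  node$children[[j]] <- .modify_at(node$children[[j]], path[-1L], fun)
  node
}

#' Apply an enzyme rule at a site
#'
#' Returns a new canonical glycan with the rule's substitution applied; the
#' input is unmodified.  The site must be one returned by [match_sites()].
#'
#' @param rule an [enzyme_rule()].
#' @param g a [glycan()].
#' @param site integer path from [match_sites()].
#' @return The product [glycan()].
#' @export
apply_rule <- function(rule, g, site) {
  g <- glycan_canonical(g)
  sites <- match_sites(rule, g)
  if (!any(vapply(sites, identical, logical(1), as.integer(site))))
    stop("site does not match rule '", rule$name, "'")
  .apply_rule_at(rule, g, site)
}

# Same as apply_rule but trusts that `site` came from match_sites on the
# already-canonical `g` (used by the network compiler).
.apply_rule_at <- function(rule, g, site) {
  if (rule$action == "quench")
    return(glycan(unclass(g), quenched = TRUE))
  node <- unclass(g)
  if (rule$action == "add") {
    node <- .modify_at(node, site, function(nd) {
      nd$children[[length(nd$children) + 1L]] <-
        glycan_node(rule$sugar, rule$linkage)
      nd
    })
  } else { # remove / remove_subtree
    if (length(site) == 0L) stop("cannot remove the root residue")
    tgt <- .node_at(node, site)
    if (rule$action == "remove" && length(tgt$children) > 0L)
      stop("remove rule matched a non-leaf site")
    j <- site[[length(site)]]
    node <- .modify_at(node, site[-length(site)], function(nd) {
      nd$children[[j]] <- NULL
      nd
    })
  }
  glycan_canonical(glycan(node, quenched = is_quenched(g)))
}

#' Enumerate applicable reactions with propensities
#'
#' One reaction instance per (rule, site) pair.  The propensity of an
#' instance is the enzyme's effective rate in the current cisterna times the
#' applicable scale factor (1 when no table entry matches).
#'
#' @param g a [glycan()].
#' @param rules list of [enzyme_rule()]s.
#' @param scales a [scale_factor_table()].
#' @param rates named numeric vector of effective rates (min^-1) for the
#'   current cisterna; must name every enzyme used by `rules`.
#' @return A list of instances, each `list(rule, site, enzyme, propensity)`,
#'   with attribute `total` (the total propensity).
#' @export
enumerate_reactions <- function(g, rules, scales, rates) {
  enz <- unique(vapply(rules, `[[`, "", "enzyme"))
  missing <- setdiff(enz, names(rates))
  if (length(missing))
    stop("no rate given for enzyme(s): ", paste(missing, collapse = ", "))
  if (any(rates < 0)) stop("rates must be >= 0")
  g <- glycan_canonical(g)
  meta <- glycan_meta(g)
  out <- list()
  for (rule in rules) {
    k <- rates[[rule$enzyme]]
    if (k == 0) next
    sites <- match_sites(rule, g)
    arms <- attr(sites, "arms")
    for (i in seq_along(sites)) {
      s <- scale_factor_for(scales, rule$enzyme, meta,
                            if (is.null(arms)) NA_character_ else arms[[i]])
      out[[length(out) + 1L]] <- list(rule = rule, site = sites[[i]],
                                      enzyme = rule$enzyme,
                                      propensity = k * s)
    }
  }
  attr(out, "total") <- sum(vapply(out, `[[`, 0, "propensity"))
  out
}

#' Look up the scale factor for an enzyme in a glycan context
#'
#' @param scales a [scale_factor_table()].
#' @param enzyme enzyme name.
#' @param meta result of the internal glycan metadata computation (list with
#'   `man`, `antennae`); a [glycan()] is also accepted.
#' @param arm the Golgi arm ("3.1"/"6.1") the site descends from, or NA.
#' @return The multiplier (1 when no entry matches).
#' @export
scale_factor_for <- function(scales, enzyme, meta, arm = NA_character_) {
  if (inherits(meta, "glycan")) meta <- glycan_meta(meta)
  hit <- scales$enzyme == enzyme &
    (is.na(scales$man_eq) | scales$man_eq == meta$man) &
    (is.na(scales$antennae_min) | scales$antennae_min <= meta$antennae) &
    (is.na(scales$arm) | (!is.na(arm) & scales$arm == arm))
  if (!any(hit)) return(1)
  if (sum(hit) > 1L) stop("scale-factor table ambiguous for enzyme ", enzyme)
  scales$multiplier[hit]
}

#' Default mammalian enzyme rule set
#'
#' The documented default rule set for mammalian Golgi N-glycan processing:
#' MAN1 (stepwise alpha-1,2 mannose trimming, Man9 to Man5, with a scale
#' factor on the Man6 to Man5 step), endo-mannosidase (removal of the
#' Glc-bearing terminal unit of glucosylated species), MGAT1/MGAT2/MGAT4/
#' MGAT5 (first to fourth GlcNAc antennae; the branching transferases
#' require their arm's 2.1 antenna to be an unextended leaf), MAN2 (removal
#' of the two 6-arm mannoses of hybrid glycans), GalT (antenna
#' galactosylation, scale factor for tri/tetra-antennary substrates), SiaT
#' (antenna sialylation, 6.2 linkage, scale factor for 6-arm antennae), FUT8
#' (core fucosylation; a scale factor permits slow fucosylation of Man5
#' substrates), antFUT (grouped antenna fucosyltransferases, complex glycans,
#' non-sialylated antennae) and the OM-quench pseudo-enzyme that marks
#' oligomannose glycans as terminally unprocessable.
#'
#' @param antenna_cap maximum number of GlcNAc antennae (default 4; rules
#'   for additional antennae are not generated).
#' @return `list(rules = <list of enzyme_rule>, scales = <scale_factor_table>)`.
#' @export
default_mammalian_rules <- function(antenna_cap = 4L) {
  rules <- list(
    enzyme_rule("MAN1_trim", "MAN1", "remove",
                target = list(sugar = "Man", linkage = "2.1", leaf = TRUE),
                guards = list(antennae_max = 0L),
                scale_factor_id = "MAN1_man6"),
    enzyme_rule("EndoMan_deglc", "EndoMan", "remove_subtree",
                target = list(glc_cap_unit = TRUE),
                guards = list(antennae_max = 0L)),
    enzyme_rule("MGAT1_first_antenna", "MGAT1", "add", "GlcNAc", "2.1",
                target = list(sugar = "Man", linkage = "3.1", leaf = TRUE,
                              parent_is_core = TRUE),
                guards = list(man_eq = 5L, glc_eq = 0L, antennae_max = 0L)),
    enzyme_rule("MAN2_trim", "MAN2", "remove",
                target = list(sugar = "Man", linkage = c("3.1", "6.1"),
                              leaf = TRUE, parent_arm6 = TRUE),
                guards = list(antennae_min = 1L)),
    enzyme_rule("MGAT2_second_antenna", "MGAT2", "add", "GlcNAc", "2.1",
                target = list(sugar = "Man", linkage = "6.1", leaf = TRUE,
                              parent_is_core = TRUE),
                guards = list(man_eq = 3L, antennae_min = 1L)),
    if (antenna_cap >= 3L)
      enzyme_rule("MGAT4_third_antenna", "MGAT4", "add", "GlcNAc", "4.1",
                  target = list(sugar = "Man", linkage = "3.1",
                                parent_is_core = TRUE,
                                has_bare_gn_child = TRUE,
                                lacks_child_at = "4.1"),
                  guards = list(man_eq = 3L, antennae_min = 2L)),
    if (antenna_cap >= 4L)
      enzyme_rule("MGAT5_fourth_antenna", "MGAT5", "add", "GlcNAc", "6.1",
                  target = list(sugar = "Man", linkage = "6.1",
                                parent_is_core = TRUE,
                                has_bare_gn_child = TRUE,
                                lacks_child_at = "6.1"),
                  guards = list(man_eq = 3L, antennae_min = 2L)),
    enzyme_rule("GalT_antenna", "GalT", "add", "Gal", "4.1",
                target = list(sugar = "GlcNAc", parent_sugar = "Man",
                              lacks_child_sugar = "Gal"),
                guards = list(antennae_min = 1L),
                scale_factor_id = "GalT_branched"),
    enzyme_rule("SiaT_cap", "SiaT", "add", "NeuAc", "6.2",
                target = list(sugar = "Gal", lacks_child_sugar = "NeuAc"),
                guards = list(antennae_min = 1L),
                scale_factor_id = "SiaT_arm6"),
    enzyme_rule("FUT8_core", "FUT8", "add", "Fuc", "6.1",
                target = list(is_root = TRUE, lacks_child_sugar = "Fuc"),
                guards = list(antennae_min = 1L),
                scale_factor_id = "FUT8_man5"),
    enzyme_rule("FUT8_core_man5", "FUT8", "add", "Fuc", "6.1",
                target = list(is_root = TRUE, lacks_child_sugar = "Fuc"),
                guards = list(man_eq = 5L, antennae_max = 0L, glc_eq = 0L),
                scale_factor_id = "FUT8_man5"),
    enzyme_rule("antFUT_antenna", "antFUT", "add", "Fuc", "3.1",
                target = list(sugar = "GlcNAc", parent_sugar = "Man",
                              lacks_child_sugar = "Fuc",
                              no_sia_in_subtree = TRUE),
                guards = list(man_eq = 3L)),
    enzyme_rule("OM_quench", "OMquench", "quench",
                guards = list(class_in = "oligomannose"))
  )
  rules <- rules[!vapply(rules, is.null, logical(1))]
  scales <- scale_factor_table(
    id = c("MAN1_man6", "FUT8_man5", "GalT_branched", "SiaT_arm6"),
    enzyme = c("MAN1", "FUT8", "GalT", "SiaT"),
    multiplier = c(0.2, 0.1, 0.5, 0.5),
    man_eq = c(6L, 5L, NA, NA),
    antennae_min = c(NA, NA, 3L, NA),
    arm = c(NA, NA, NA, "6.1"))
  list(rules = rules, scales = scales)
}

#' Enzymes referenced by a rule set
#' @param rules list of [enzyme_rule()]s.
#' @return Character vector of unique enzyme names, in rule order.
#' @export
rule_enzymes <- function(rules) unique(vapply(rules, `[[`, "", "enzyme"))
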