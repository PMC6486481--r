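# Reaction-network compilation.
#
# The set of glycans reachable from the ER-exit species under a rule set is
# finite (antenna cap, one decoration of each kind per antenna, removals
# only shrink).  Compiling the reachable state graph once lets the
# stochastic simulation run on integer state ids in compiled code; rates
# enter only through per-edge propensities (rate x scale factor), so one
# compiled network serves every parameter set over the same rules.

.network_cache <- new.env(parent = emptyenv())

resolve_input_glycan <- function(name) {
  if (name %in% names(.PATHWAY_NOTATION)) pathway_glycan(name) else glycan_parse(name)
}

state_key <- function(g) {
  paste0(if (is_quenched(g)) "Q|" else "", glycan_serialize(g))
}

#' Compile the reachable reaction network
#'
#' Breadth-first closure of the rule set over the input species.  States are
#' canonical glycans (quenched twins are distinct absorbing states); edges
#' are (substrate, product, enzyme) with their scale-factor multiplier.
#'
#' @param rules list of [enzyme_rule()]s.
#' @param scales a [scale_factor_table()].
#' @param input_names names of the ER-exit species (see [golgi_model()]).
#' @param cache reuse a previously compiled network for identical inputs.
#' @return An object of class `"glycan_network"`: state table (serialization,
#'   composition key, class, antenna count, quenched flag), edge table
#'   (from, to, enzyme, scale; CSR-sorted by substrate state) and input ids.
#' @export
compile_network <- function(rules, scales, input_names, cache = TRUE) {
  key <- paste(paste(vapply(rules, function(r) paste(deparse(unclass(r)), collapse = ""), ""),
                     collapse = ";"),
               paste(deparse(unclass(scales)), collapse = ""),
               paste(sort(input_names), collapse = ","), sep = "##")
  if (cache && !is.null(.network_cache[[key]])) return(.network_cache[[key]])

  ids <- new.env(parent = emptyenv())
  glycans <- list()
  add_state <- function(g) {
    k <- state_key(g)
    id <- ids[[k]]
    if (is.null(id)) {
      id <- length(glycans) + 1L
      ids[[k]] <- id
      glycans[[id]] <<- g
    }
    id
  }
  input_ids <- vapply(input_names,
                      function(nm) add_state(resolve_input_glycan(nm)), 0L)
  per_state <- list()
  i <- 1L
  while (i <= length(glycans)) {
    g <- glycans[[i]]
    if (!is_quenched(g)) {
      meta <- glycan_meta(g)
      to <- integer(); enz <- character(); sc <- numeric()
      for (rule in rules) {
        sites <- match_sites(rule, g)
        arms <- attr(sites, "arms")
        for (j in seq_along(sites)) {
          prod <- .apply_rule_at(rule, g, sites[[j]])
          to[length(to) + 1L] <- add_state(prod)
          enz[length(enz) + 1L] <- rule$enzyme
          sc[length(sc) + 1L] <- scale_factor_for(
            scales, rule$enzyme, meta,
            if (is.null(arms)) NA_character_ else arms[[j]])
        }
      }
      per_state[[i]] <- list(to = to, enz = enz, sc = sc)
    }
    i <- i + 1L
  }
  ef <- rep.int(seq_along(per_state),
                vapply(per_state, function(x) length(x$to), 0L))
  et <- unlist(lapply(per_state, `[[`, "to"), use.names = FALSE)
  ee <- unlist(lapply(per_state, `[[`, "enz"), use.names = FALSE)
  es <- unlist(lapply(per_state, `[[`, "sc"), use.names = FALSE)
  if (is.null(et)) { et <- integer(); ee <- character(); es <- numeric() }
  enzymes <- rule_enzymes(rules)
  ord <- order(ef, et, match(ee, enzymes))
  edges <- data.frame(from = ef[ord], to = et[ord],
                      enzyme = ee[ord], scale = es[ord],
                      stringsAsFactors = FALSE)
  states <- data.frame(
    structure = vapply(glycans, glycan_serialize, ""),
    composition = vapply(glycans, composition_key, ""),
    class = vapply(glycans, glycan_class, ""),
    antennae = vapply(glycans, n_antennae, 0L),
    quenched = vapply(glycans, is_quenched, logical(1)),
    stringsAsFactors = FALSE)
  # CSR pointer: edge rows for state s are edge_ptr[s]..edge_ptr[s+1]-1 (0-based)
  n <- nrow(states)
  cnt <- tabulate(edges$from, nbins = n)
  net <- structure(list(states = states, edges = edges,
                        edge_ptr = c(0L, cumsum(cnt)),
                        enzymes = enzymes, input_ids = input_ids),
                   class = "glycan_network")
  if (cache) .network_cache[[key]] <- net
  net
}

#' @export
print.glycan_network <- function(x, ...) {
  cat("<glycan_network> ", nrow(x$states), " states, ", nrow(x$edges),
      " reactions, ", length(x$enzymes), " enzymes\n", sep = "")
  invisible(x)
}

network_for_model <- function(model, ruleset) {
  compile_network(ruleset$rules, ruleset$scales,
                  names(model$input_distribution))
}
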