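# Reaction flux maps: directed multigraphs of (substrate, product, enzyme)
# edges weighted by event counts from a simulation.

#' Construct a flux map
#'
#' Edges are keyed at composition level by default (isoforms collated, as in
#' profile output); self-edges produced by the quench pseudo-reaction are
#' retained.  Node annotations carry the final-profile abundance.
#'
#' @param substrate,product composition keys per edge.
#' @param enzyme enzyme name per edge.
#' @param count event count per edge; rows with zero count are dropped.
#' @param profile optional [glycan_profile()] for node abundances.
#' @return A `data.frame` of class `"flux_map"` with columns substrate,
#'   product, enzyme, count, aggregated over duplicate edges.
#' @export
flux_map <- function(substrate, product, enzyme, count, profile = NULL) {
  df <- data.frame(substrate = substrate, product = product, enzyme = enzyme,
                   count = as.numeric(count), stringsAsFactors = FALSE)
  key <- paste(df$substrate, df$product, df$enzyme, sep = "\r")
  agg <- rowsum(df$count, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(substrate = vapply(parts, `[[`, "", 1L),
                    product = vapply(parts, `[[`, "", 2L),
                    enzyme = vapply(parts, `[[`, "", 3L),
                    count = agg[, 1L], stringsAsFactors = FALSE)
  out <- out[out$count > 0, , drop = FALSE]
  out <- out[order(out$substrate, out$product, out$enzyme, method = "radix"), ]
  rownames(out) <- NULL
  if (!is.null(profile)) {
    ab <- setNames(profile$abundance_pct, profile$composition)
    attr(out, "node_abundance") <- ab
  }
  class(out) <- c("flux_map", "data.frame")
  out
}

#' @export
print.flux_map <- function(x, ...) {
  cat("<flux_map> ", nrow(x), " edges, total flux ", sum(x$count), "\n", sep = "")
  print.data.frame(head(as.data.frame(x), 20L), row.names = FALSE)
  if (nrow(x) > 20L) cat("  ...\n")
  invisible(x)
}

#' Build a flux map from a reaction-event log
#'
#' Tallies one edge per distinct (substrate key, product key, enzyme)
#' triple.  [simulate_profile()] already returns the equivalent map built
#' from aggregated counts; this entry point works from an explicit event
#' log (e.g. read back from disk).
#'
#' @param events data.frame with columns `substrate_key`, `product_key`,
#'   `enzyme` (as produced with `record_events = TRUE`).
#' @param profile optional [glycan_profile()] for node annotations.
#' @return A [flux_map()].
#' @export
build_flux_map <- function(events, profile = NULL) {
  if (nrow(events) == 0L)
    return(flux_map(character(), character(), character(), numeric(), profile))
  flux_map(events$substrate_key, events$product_key, events$enzyme,
           rep(1, nrow(events)), profile)
}

#' Highest-flux reactions of an enzyme
#'
#' @param map a [flux_map()].
#' @param enzyme enzyme name (default FUT8, the core fucosyltransferase).
#' @param k number of reactions (default 6).
#' @return The k highest-count edges of that enzyme, count-descending,
#'   ties broken by substrate key; empty when the enzyme is absent.
#' @export
top_reactions <- function(map, enzyme = "FUT8", k = 6L) {
  stopifnot(k >= 1L)
  sub <- map[map$enzyme == enzyme, , drop = FALSE]
  sub <- sub[order(-sub$count, sub$substrate, sub$product, method = "radix"), ]
  sub <- head(sub, k)
  rownames(sub) <- NULL
  sub
}

#' Normalized condition-versus-control flux ratios
#'
#' For every edge with nonzero control flux, the ratio of condition to
#' control flux divided by the ratio of the total flux of the normalizing
#' enzyme (default FUT8, i.e. total core-fucosylation flux) in the two
#' maps:  (f_cond / f_ctl) / (F_cond / F_ctl).  Values above 1 indicate a
#' preference for that pathway in the condition.  `variant = "multiply"`
#' multiplies by the total-flux ratio instead of dividing.
#'
#' @param condition,control [flux_map()]s from matched simulations (same
#'   `n_glycans`; counts are compared raw since the ratio cancels n).
#' @param normalizing_enzyme enzyme whose total flux normalizes the ratios.
#' @param variant `"divide"` (default) or `"multiply"`.
#' @return A `data.frame` (class `"flux_ratio_report"`) with one row per
#'   edge (substrate, product, enzyme, ratio) and attributes
#'   `normalizer` (the two total fluxes) and `omitted` (edges with zero
#'   control flux).
#' @export
normalized_flux_ratio <- function(condition, control,
                                  normalizing_enzyme = "FUT8",
                                  variant = c("divide", "multiply")) {
  variant <- match.arg(variant)
  F_cond <- sum(condition$count[condition$enzyme == normalizing_enzyme])
  F_ctl <- sum(control$count[control$enzyme == normalizing_enzyme])
  if (F_cond <= 0 || F_ctl <= 0)
    stop("total flux of the normalizing enzyme must be > 0 in both maps")
  key <- function(m) paste(m$substrate, m$product, m$enzyme, sep = "\r")
  idx <- match(key(control), key(condition))
  f_cond <- ifelse(is.na(idx), 0, condition$count[idx])
  norm <- F_cond / F_ctl
  raw <- (f_cond / control$count)
  ratio <- if (variant == "divide") raw / norm else raw * norm
  out <- data.frame(substrate = control$substrate, product = control$product,
                    enzyme = control$enzyme, ratio = ratio,
                    stringsAsFactors = FALSE)
  omitted <- condition[is.na(match(key(condition), key(control))), , drop = FALSE]
  attr(out, "normalizer") <- c(condition = F_cond, control = F_ctl)
  attr(out, "omitted") <- omitted
  class(out) <- c("flux_ratio_report", "data.frame")
  out
}

#' Flux ratios restricted to an enzyme's top substrates
#'
#' Convenience wrapper reproducing the usual report structure: the
#' normalized condition/control ratios for all reactions consuming the
#' substrates of the control map's top-k reactions of the given enzyme.
#'
#' @inheritParams normalized_flux_ratio
#' @param k number of top reactions (default 6).
#' @return A `"flux_ratio_report"` restricted to those substrates.
#' @export
top_substrate_flux_report <- function(condition, control, enzyme = "FUT8",
                                      k = 6L, variant = "divide") {
  top <- top_reactions(control, enzyme, k)
  rep <- normalized_flux_ratio(condition, control, enzyme, variant)
  out <- rep[rep$substrate %in% top$substrate, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GalT branching titration
#'
#' Scales all cisternal GalT rates by each multiplier, simulates, and
#' reports the summed relative abundance of tri- and tetra-antennary
#' complex glycans.  Galactosylation competes with the branching
#' transferases (MGAT4/MGAT5 require an unextended 2.1 antenna), so raising
#' GalT activity suppresses higher branching.
#'
#' @param model a [golgi_model()] containing a GalT row.
#' @param galt_multipliers non-negative multipliers (>= 1 value).
#' @param n_glycans glycans per run.
#' @param seed seed shared across runs (paired comparison).
#' @param ruleset rule set as in [simulate_profile()].
#' @return data.frame(multiplier, tri_pct, tetra_pct).
#' @export
galt_titration <- function(model, galt_multipliers, n_glycans = 10000L,
                           seed = 1L, ruleset = default_mammalian_rules()) {
  stopifnot(all(galt_multipliers >= 0))
  rows <- lapply(galt_multipliers, function(m) {
    sim <- simulate_profile(scale_enzymes(model, c(GalT = m)), n_glycans,
                            seed, ruleset)
    ab <- antennarity_abundance(sim)
    data.frame(multiplier = m, tri_pct = ab[["3"]], tetra_pct = ab[["4"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
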