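# Gillespie simulation of glycan processing through the Golgi stack.

#' Construct a glycan profile
#'
#' A profile is a table of relative abundances (%) keyed by composition,
#' with an optional per-entry SEM (%).
#'
#' @param composition character vector of composition keys.
#' @param abundance_pct numeric relative abundances (%).
#' @param sem_pct optional numeric SEM (%), NA when unknown.
#' @return A `data.frame` with class `"glycan_profile"`.
#' @export
glycan_profile <- function(composition, abundance_pct, sem_pct = NA_real_) {
  stopifnot(length(composition) == length(abundance_pct))
  if (any(abundance_pct < 0)) stop("abundances must be >= 0")
  if (anyDuplicated(composition)) stop("duplicate composition keys")
  if (any(!is.na(sem_pct) & sem_pct < 0)) stop("SEM must be >= 0")
  df <- data.frame(composition = as.character(composition),
                   abundance_pct = as.numeric(abundance_pct),
                   sem_pct = rep_len(as.numeric(sem_pct), length(composition)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$composition, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("glycan_profile", "data.frame")
  df
}

#' @export
print.glycan_profile <- function(x, ...) {
  cat("<glycan_profile> ", nrow(x), " compositions, total ",
      round(sum(x$abundance_pct), 3), "%\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# Convert per-state counts into a filtered percentage profile.
profile_from_counts <- function(keys, counts, abundance_filter = 0.1) {
  pct <- 100 * counts / sum(counts)
  agg <- rowsum(pct, keys)
  keep <- agg[, 1L] >= abundance_filter
  p <- glycan_profile(rownames(agg)[keep], agg[keep, 1L])
  attr(p, "pre_filter_total") <- sum(agg)
  attr(p, "dropped") <- glycan_profile(rownames(agg)[!keep], agg[!keep, 1L])
  p
}

#' Simulate a glycan profile
#'
#' Simulates `n_glycans` independent glycans (default 10,000), each drawn
#' from the model's ER-input distribution and processed one at a time by
#' the Gillespie SSA through every cisterna: reactions are enumerated, the
#' waiting time is exponential with mean 1/total-propensity, reaction i
#' fires with probability propensity_i / total, and the glycan moves to the
#' next cisterna when the waiting time would cross the residence deadline.
#' Enzyme competition is implicit; glycans do not compete for enzymes.
#' Final structures are collated by composition key and entries below the
#' abundance filter (default 0.1%, not renormalized) are dropped.
#'
#' Each glycan has its own RNG substream derived from `(seed, index)`, so a
#' given (seed, model, n) triple fully determines the output.
#'
#' @param model a [golgi_model()].
#' @param n_glycans number of glycans (default 10000).
#' @param seed integer seed.
#' @param ruleset rule set from [default_mammalian_rules()] (or compatible
#'   `list(rules, scales)`).
#' @param record_events keep the full reaction-event log (one row per
#'   reaction) in addition to the aggregated flux counts.
#' @param abundance_filter profile filter in % (0 disables).
#' @return An object of class `"golgi_sim"`: `profile` (a
#'   [glycan_profile()]), `flux` (a [flux_map()]), `structures` (per-state
#'   tallies with class and antenna counts), `events` (if recorded), plus
#'   the network, model and seed used.
#' @export
simulate_profile <- function(model, n_glycans = 10000L, seed = 1L,
                             ruleset = default_mammalian_rules(),
                             record_events = FALSE, abundance_filter = 0.1) {
  stopifnot(n_glycans >= 1L)
  net <- network_for_model(model, ruleset)
  missing <- setdiff(net$enzymes, rownames(model$rates))
  if (length(missing))
    stop("model rates missing enzyme(s): ", paste(missing, collapse = ", "))
  rates <- model$rates[net$enzymes, , drop = FALSE]
  frac <- model$input_distribution / sum(model$input_distribution)
  res <- .ssa_run(net$edge_ptr, net$edges$to - 1L,
                  match(net$edges$enzyme, net$enzymes) - 1L,
                  net$edges$scale, rates, model$residence_time,
                  cumsum(as.numeric(frac)),
                  as.integer(net$input_ids[names(frac)]) - 1L,
                  as.integer(n_glycans), as.numeric(seed),
                  isTRUE(record_events))
  counts <- tabulate(res$final_state, nbins = nrow(net$states))
  profile <- profile_from_counts(net$states$composition, counts,
                                 abundance_filter)
  structures <- cbind(net$states, count = counts,
                      abundance_pct = 100 * counts / n_glycans)
  edge_total <- rowSums(res$edge_counts)
  flux <- flux_map(substrate = net$states$composition[net$edges$from],
                   product = net$states$composition[net$edges$to],
                   enzyme = net$edges$enzyme, count = edge_total,
                   profile = profile)
  events <- NULL
  if (isTRUE(record_events)) {
    ev <- res$events
    e <- ev$edge
    events <- data.frame(glycan_index = ev$glycan, cisterna = ev$cisterna,
                         time = ev$time, enzyme = net$edges$enzyme[e],
                         substrate_key = net$states$composition[net$edges$from[e]],
                         product_key = net$states$composition[net$edges$to[e]],
                         substrate = net$states$structure[net$edges$from[e]],
                         product = net$states$structure[net$edges$to[e]],
                         stringsAsFactors = FALSE)
  }
  structure(list(profile = profile, flux = flux, structures = structures,
                 edge_counts = res$edge_counts, network = net, events = events,
                 model = model, n_glycans = n_glycans, seed = seed),
            class = "golgi_sim")
}

#' @export
print.golgi_sim <- function(x, ...) {
  cat("<golgi_sim> ", x$n_glycans, " glycans, seed ", x$seed, "\n", sep = "")
  cls <- rowsum(x$structures$abundance_pct, x$structures$class)
  for (k in rownames(cls)) cat(sprintf("  %-13s %6.2f%%\n", k, cls[k, 1]))
  invisible(x)
}

#' Class-level abundance summary of a simulation
#'
#' @param sim a `"golgi_sim"` object.
#' @return Named numeric vector of percentage abundance per glycan class.
#' @export
class_abundance <- function(sim) {
  cls <- rowsum(sim$structures$abundance_pct, sim$structures$class)
  out <- setNames(numeric(4), c("oligomannose", "hybrid", "complex", "other"))
  out[rownames(cls)] <- cls[, 1L]
  out
}

#' Antenna-number abundance summary of a simulation
#'
#' Percentage abundance of complex glycans by antenna count (used for the
#' GalT branching titration).
#'
#' @param sim a `"golgi_sim"` object.
#' @return Named numeric vector, names "1".."4".
#' @export
antennarity_abundance <- function(sim) {
  st <- sim$structures[sim$structures$class == "complex", ]
  out <- setNames(numeric(4), as.character(1:4))
  if (nrow(st)) {
    agg <- rowsum(st$abundance_pct, as.character(st$antennae))
    out[rownames(agg)] <- agg[, 1L]
  }
  out
}

#' Replicate simulation with SEM
#'
#' Simulates the profile `n_replicates` times (default 3, mirroring
#' triplicate experimental profiles) with distinct seeds and reports the
#' per-key mean abundance and SEM = sd/sqrt(n); keys absent from a
#' replicate contribute 0.
#'
#' @param model a [golgi_model()].
#' @param n_glycans glycans per replicate.
#' @param n_replicates at least 2; default 3.
#' @param seed base seed; replicate r uses `seed + r - 1` unless `seeds`
#'   gives explicit per-replicate seeds.
#' @param seeds optional vector of length `n_replicates`.
#' @param ruleset rule set as in [simulate_profile()].
#' @param abundance_filter filter (%) applied to the mean profile.
#' @return A [glycan_profile()] with `sem_pct` filled in.
#' @export
replicate_profile <- function(model, n_glycans = 10000L, n_replicates = 3L,
                              seed = 1L, seeds = NULL,
                              ruleset = default_mammalian_rules(),
                              abundance_filter = 0.1) {
  stopifnot(n_replicates >= 2L)
  if (is.null(seeds)) seeds <- seed + seq_len(n_replicates) - 1L
  stopifnot(length(seeds) == n_replicates)
  sims <- lapply(seeds, function(s)
    simulate_profile(model, n_glycans, s, ruleset, abundance_filter = 0)$profile)
  keys <- sort(unique(unlist(lapply(sims, `[[`, "composition"))))
  m <- vapply(sims, function(p)
    p$abundance_pct[match(keys, p$composition)], numeric(length(keys)))
  m[is.na(m)] <- 0
  mean_ab <- rowMeans(m)
  sem <- apply(m, 1L, sd) / sqrt(n_replicates)
  keep <- mean_ab >= abundance_filter
  out <- glycan_profile(keys[keep], mean_ab[keep], sem[keep])
  attr(out, "n_replicates") <- n_replicates
  out
}

# ---- tree-level reference simulator --------------------------------------

#' One SSA step: waiting time and reaction choice
#'
#' Draws the waiting time dt ~ Exponential(mean 1/R) where R is the total
#' propensity, and selects reaction i with probability propensity_i / R.
#' Returns a cisterna exit when R = 0 or the clock would cross the
#' residence deadline (the overshooting step does not fire).  Uses R's RNG.
#'
#' @param reactions list from [enumerate_reactions()].
#' @param clock current within-cisterna time (min).
#' @param residence_time cisterna residence time (min).
#' @return `list(exit = TRUE, dt = <draw or Inf>)` on exit, otherwise
#'   `list(exit = FALSE, index = i, dt = dt)`.
#' @export
draw_step <- function(reactions, clock, residence_time) {
  props <- vapply(reactions, `[[`, 0, "propensity")
  R <- sum(props)
  if (R <= 0) return(list(exit = TRUE, dt = Inf))
  dt <- rexp(1L, rate = R)
  if (clock + dt >= residence_time) return(list(exit = TRUE, dt = dt))
  i <- if (length(props) == 1L) 1L else
    sample.int(length(props), 1L, prob = props / R)
  list(exit = FALSE, index = i, dt = dt)
}

#' Simulate a single glycan through the Golgi (tree-level reference)
#'
#' Direct tree-rewriting implementation of the per-glycan SSA, operating on
#' [glycan()] objects without network compilation.  Used as the reference
#' path; [simulate_profile()] runs the same process on the compiled network.
#' The within-cisterna clock resets on entry to each cisterna.  Uses R's
#' RNG (seed with [set.seed()]).
#'
#' @param g0 input [glycan()].
#' @param model a [golgi_model()].
#' @param ruleset rule set (`list(rules, scales)`).
#' @return `list(final = <glycan>, events = <data.frame>)`; events carry
#'   glycan-local cisterna, time, enzyme and substrate/product keys.
#' @export
simulate_glycan <- function(g0, model, ruleset = default_mammalian_rules()) {
  g <- glycan_canonical(g0)
  ev <- list()
  for (ci in seq_len(n_cisternae(model))) {
    clock <- 0
    repeat {
      reactions <- enumerate_reactions(g, ruleset$rules, ruleset$scales,
                                       model$rates[, ci])
      st <- draw_step(reactions, clock, model$residence_time[[ci]])
      if (st$exit) break
      clock <- clock + st$dt
      rx <- reactions[[st$index]]
      g2 <- apply_rule(rx$rule, g, rx$site)
      ev[[length(ev) + 1L]] <- data.frame(
        cisterna = ci, time = clock, enzyme = rx$enzyme,
        substrate_key = composition_key(g), product_key = composition_key(g2),
        substrate = glycan_serialize(g), product = glycan_serialize(g2),
        stringsAsFactors = FALSE)
      g <- g2
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(cisterna = integer(), time = numeric(), enzyme = character(),
               substrate_key = character(), product_key = character(),
               substrate = character(), product = character(),
               stringsAsFactors = FALSE)
  list(final = g, events = events)
}
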