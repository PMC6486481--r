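# Approximate Bayesian computation: rejection sampling of effective-rate
# parameters under an adaptively shrinking score threshold.

#' Discrepancy score between observed and simulated profiles
#'
#' Per-glycan contribution is 0 when the absolute abundance difference is
#' strictly below that glycan's SEM, and (sem - |obs - sim|)^2 otherwise;
#' the score is the sum over the union of composition keys (a key missing
#' on either side counts as abundance 0).  Lower is better; a simulated
#' profile lying within the SEM band everywhere scores exactly 0.
#'
#' @param observed a [glycan_profile()] with SEMs.
#' @param simulated a [glycan_profile()].
#' @param sem_policy what to do for entries without an SEM (including keys
#'   present only in the simulation): `"default"` substitutes
#'   `max(0.1, 0.05 * observed abundance)` percent; `"error"` fails.
#' @return Non-negative score (squared percent units).
#' @export
profile_score <- function(observed, simulated,
                          sem_policy = c("default", "error")) {
  sem_policy <- match.arg(sem_policy)
  keys <- sort(unique(c(observed$composition, simulated$composition)))
  obs <- simx <- numeric(length(keys))
  i <- match(observed$composition, keys)
  obs[i] <- observed$abundance_pct
  sem <- rep(NA_real_, length(keys))
  sem[i] <- observed$sem_pct
  simx[match(simulated$composition, keys)] <- simulated$abundance_pct
  if (anyNA(sem)) {
    if (sem_policy == "error")
      stop("observed profile lacks SEM for: ",
           paste(keys[is.na(sem)], collapse = ", "))
    sem[is.na(sem)] <- pmax(0.1, 0.05 * obs[is.na(sem)])
  }
  d <- abs(obs - simx)
  sum(ifelse(d < sem, 0, (sem - d)^2))
}

#' Prior specification for effective-rate parameters
#'
#' One row per fitted parameter (named `<enzyme>.c<cisterna>`): a
#' log-normal prior (`p1` = meanlog, `p2` = sdlog) where the enzyme is
#' believed to reside, or an exponential-decay prior (`p1` = rate) where it
#' is not.
#'
#' @param param parameter names.
#' @param dist `"lnorm"` or `"exp"` per parameter.
#' @param p1,p2 distribution parameters (`p2` ignored for `"exp"`).
#' @return A `data.frame` of class `"prior_spec"`.
#' @export
prior_spec <- function(param, dist, p1, p2 = NA_real_) {
  dist <- match.arg(dist, c("lnorm", "exp"), several.ok = TRUE)
  if (anyDuplicated(param)) stop("duplicate parameter in prior spec")
  structure(data.frame(param = param, dist = rep_len(dist, length(param)),
                       p1 = p1, p2 = rep_len(p2, length(param)),
                       stringsAsFactors = FALSE),
            class = c("prior_spec", "data.frame"))
}

#' Localization-based default priors
#'
#' Builds the standard prior layout: for each enzyme a fraction
#' `home_frac` (default 80%) of its total effective rate is placed in its
#' home cisterna with a log-normal prior centred there, and the remainder
#' is spread over the other cisternae with exponential-decay priors whose
#' mean equals the per-cisterna remainder.
#'
#' @param model a [golgi_model()] template (defines enzymes and cisternae).
#' @param home named integer vector: home cisterna per enzyme.
#' @param total_rate named numeric vector: expected total effective rate
#'   per enzyme (min^-1).
#' @param home_frac fraction of the total rate in the home cisterna.
#' @param sdlog shape of the log-normal home priors.
#' @return A [prior_spec()] covering every (enzyme, cisterna) parameter.
#' @export
localization_priors <- function(model, home, total_rate, home_frac = 0.8,
                                sdlog = 0.8) {
  enz <- rownames(model$rates)
  C <- n_cisternae(model)
  stopifnot(all(enz %in% names(home)), all(enz %in% names(total_rate)))
  rows <- list()
  for (e in enz) for (ci in seq_len(C)) {
    if (ci == home[[e]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        param = paste0(e, ".c", ci), dist = "lnorm",
        p1 = log(total_rate[[e]] * home_frac), p2 = sdlog,
        stringsAsFactors = FALSE)
    } else {
      mean_rest <- total_rate[[e]] * (1 - home_frac) / max(1L, C - 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        param = paste0(e, ".c", ci), dist = "exp",
        p1 = 1 / mean_rest, p2 = NA_real_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("prior_spec", "data.frame")
  out
}

#' Draw parameter sets from the priors
#'
#' @param priors a [prior_spec()].
#' @param n number of draws.
#' @return Numeric matrix `n x nrow(priors)` with parameter column names.
#'   Uses R's RNG.
#' @export
sample_prior <- function(priors, n = 1L) {
  draws <- vapply(seq_len(nrow(priors)), function(i) {
    if (priors$dist[i] == "lnorm") stats::rlnorm(n, priors$p1[i], priors$p2[i])
    else stats::rexp(n, rate = priors$p1[i])
  }, numeric(n))
  if (n == 1L) draws <- matrix(draws, nrow = 1L)
  colnames(draws) <- priors$param
  draws
}

prior_density <- function(priors, i, x) {
  if (priors$dist[i] == "lnorm") stats::dlnorm(x, priors$p1[i], priors$p2[i])
  else stats::dexp(x, rate = priors$p1[i])
}

# Fast scorer: profiles compared as numeric vectors over the fixed union of
# network composition keys and observed keys, avoiding per-proposal
# data-frame construction.
.make_fast_scorer <- function(observed, model, ruleset, n_glycans) {
  net <- network_for_model(model, ruleset)
  keys <- sort(unique(c(net$states$composition, observed$composition)))
  state_key_idx <- match(net$states$composition, keys)
  obs <- sem <- numeric(length(keys))
  i <- match(observed$composition, keys)
  obs[i] <- observed$abundance_pct
  sem[] <- NA_real_
  sem[i] <- observed$sem_pct
  sem[is.na(sem)] <- pmax(0.1, 0.05 * obs[is.na(sem)])
  enzymes <- net$enzymes
  edge_to0 <- net$edges$to - 1L
  edge_enz0 <- match(net$edges$enzyme, enzymes) - 1L
  frac <- model$input_distribution / sum(model$input_distribution)
  input_cum <- cumsum(as.numeric(frac))
  input_ids0 <- as.integer(net$input_ids[names(frac)]) - 1L
  template <- model$rates[enzymes, , drop = FALSE]
  nstates <- nrow(net$states)
  function(params, sim_seed) {
    rates <- params_to_rates_partial(template, params)
    res <- .ssa_run(net$edge_ptr, edge_to0, edge_enz0, net$edges$scale,
                    rates, model$residence_time, input_cum, input_ids0,
                    as.integer(n_glycans), as.numeric(sim_seed), FALSE)
    cnt <- tabulate(state_key_idx[res$final_state], nbins = length(keys))
    simx <- 100 * cnt / n_glycans
    d <- abs(obs - simx)
    contrib <- (sem - d)^2
    sum(contrib[d >= sem])
  }
}

# Overlay a named parameter vector onto a rates matrix ("ENZ.c<j>" names);
# parameters without a matching entry are ignored, entries without a
# parameter keep their template value.
params_to_rates_partial <- function(template, params) {
  nm <- names(params)
  enz <- sub("\\.c[0-9]+$", "", nm)
  cis <- as.integer(sub("^.*\\.c", "", nm))
  ri <- match(enz, rownames(template))
  ok <- !is.na(ri) & cis >= 1L & cis <= ncol(template)
  template[cbind(ri[ok], cis[ok])] <- params[ok]
  template
}

#' Fit a Golgi model by rejection ABC with an adaptive threshold
#'
#' Repeatedly draws effective-rate parameter sets from the priors,
#' simulates a glycan profile, scores it against the observation with
#' [profile_score()], and accepts draws scoring at or below the current
#' threshold.  The initial threshold is a quantile of a pilot round; while
#' the acceptance rate over the monitoring window exceeds
#' `accept_rate_trigger` (default 7%) the threshold is shrunk by
#' `threshold_shrink` (default 10%).  Once the threshold reaches
#' `final_threshold` sampling continues at that fixed threshold until
#' `target_accepted` parameter sets have been accepted; only fixed-phase
#' acceptances form the posterior.  `n_chains` independent chains run over
#' disjoint seed ranges.
#'
#' @param observed a [glycan_profile()] with SEMs.
#' @param model a [golgi_model()] template: enzymes, cisternae, residence
#'   times and input distribution; rate entries not covered by `priors`
#'   stay fixed at their template values.
#' @param priors a [prior_spec()].
#' @param ruleset rule set (`list(rules, scales)`).
#' @param n_glycans glycans per simulated proposal (default 10000).
#' @param target_accepted total accepted draws across chains (default 10000).
#' @param final_threshold fixed-phase score threshold; default the
#'   `final_quantile` quantile of the pilot scores.
#' @param n_chains independent chains (default 4).
#' @param seed master seed; chain c derives its own R and simulation
#'   streams from it.
#' @param window proposals per acceptance-rate check (default 1000).
#' @param accept_rate_trigger acceptance rate above which the threshold
#'   shrinks (default 0.07).
#' @param threshold_shrink relative shrink per trigger (default 0.10).
#' @param pilot pilot proposals used to set the initial threshold.
#' @param pilot_quantile quantile of pilot scores for the initial
#'   threshold (default 0.5).
#' @param final_quantile quantile of pilot scores for the default
#'   `final_threshold` (default 0.1).
#' @param max_proposals per-chain proposal cap; reaching it yields a
#'   partial posterior with a warning.
#' @param simulator override for testing: `function(params, seed)`
#'   returning a [glycan_profile()] (scored with [profile_score()]).
#' @return An object of class `"golgi_abc"`; see [summary.golgi_abc()],
#'   [coef.golgi_abc()], [simulate.golgi_abc()], [plot.golgi_abc()].
#' @export
golgi_abc <- function(observed, model, priors,
                      ruleset = default_mammalian_rules(),
                      n_glycans = 10000L, target_accepted = 10000L,
                      final_threshold = NULL, n_chains = 4L, seed = 1L,
                      window = 1000L, accept_rate_trigger = 0.07,
                      threshold_shrink = 0.10, pilot = 200L,
                      pilot_quantile = 0.5, final_quantile = 0.1,
                      max_proposals = 2e5, simulator = NULL) {
  stopifnot(target_accepted >= 1L, n_chains >= 1L,
            accept_rate_trigger > 0, accept_rate_trigger < 1,
            threshold_shrink > 0, threshold_shrink < 1)
  scorer <- if (is.null(simulator)) {
    .make_fast_scorer(observed, model, ruleset, n_glycans)
  } else {
    function(params, sim_seed)
      profile_score(observed, simulator(params, sim_seed))
  }
  npar <- nrow(priors)

  # Shared pilot round: sets the initial and (by default) final thresholds.
  set.seed(seed)
  pilot_params <- sample_prior(priors, pilot)
  pilot_scores <- vapply(seq_len(pilot), function(i)
    scorer(pilot_params[i, ], seed * 131071 + i), 0)
  pilot_scores <- pilot_scores[is.finite(pilot_scores)]
  thr0 <- as.numeric(quantile(pilot_scores, pilot_quantile))
  if (is.null(final_threshold))
    final_threshold <- as.numeric(quantile(pilot_scores, final_quantile))
  if (thr0 <= final_threshold) thr0 <- final_threshold

  per_chain <- ceiling(target_accepted / n_chains)
  draws <- list(); chain_id <- integer(); scores <- numeric()
  acc_seeds <- numeric(); acc_thr <- numeric()
  trajectory <- list(); prop_count <- integer(n_chains)
  partial <- FALSE

  for (ch in seq_len(n_chains)) {
    chain_seed <- seed + (ch - 1L) * 100003L
    set.seed(chain_seed)
    thr <- thr0
    traj <- data.frame(proposal = 0L, threshold = thr)
    # sliding window of recent proposal scores for the acceptance-rate check
    win_scores <- rep(NA_real_, window)
    win_pos <- 0L
    n_acc <- 0L; prop <- 0L
    fixed_phase <- thr <= final_threshold
    while (n_acc < per_chain) {
      if (prop >= max_proposals) { partial <- TRUE; break }
      prop <- prop + 1L
      params <- sample_prior(priors, 1L)[1L, ]
      sim_seed <- chain_seed * 524287 + prop
      sc <- scorer(params, sim_seed)
      if (!is.finite(sc)) next
      if (sc <= thr && fixed_phase) {
        n_acc <- n_acc + 1L
        draws[[length(draws) + 1L]] <- params
        chain_id <- c(chain_id, ch)
        scores <- c(scores, sc)
        acc_seeds <- c(acc_seeds, sim_seed)
        acc_thr <- c(acc_thr, thr)
      }
      if (!fixed_phase) {
        win_pos <- win_pos %% window + 1L
        win_scores[win_pos] <- sc
        if (!anyNA(win_scores)) {
          # shrink while the windowed acceptance rate under the current
          # threshold stays above the trigger
          while (!fixed_phase &&
                 mean(win_scores <= thr) > accept_rate_trigger) {
            thr <- thr * (1 - threshold_shrink)
            if (thr <= final_threshold) {
              thr <- final_threshold
              fixed_phase <- TRUE
            }
            traj <- rbind(traj, data.frame(proposal = prop, threshold = thr))
          }
        }
      }
    }
    prop_count[ch] <- prop
    trajectory[[ch]] <- traj
  }
  if (partial)
    warning("proposal cap reached before target_accepted; partial posterior")

  draws <- do.call(rbind, draws)
  if (is.null(draws)) draws <- matrix(numeric(), 0L, npar,
                                      dimnames = list(NULL, priors$param))
  structure(list(draws = draws, scores = scores, chain = chain_id,
                 accept_seeds = acc_seeds, accept_thresholds = acc_thr,
                 threshold_trajectory = trajectory,
                 proposals = prop_count, priors = priors, model = model,
                 observed = observed, ruleset = ruleset,
                 n_glycans = n_glycans, final_threshold = final_threshold,
                 initial_threshold = thr0, pilot_scores = pilot_scores,
                 seed = seed, partial = partial, call = match.call()),
            class = "golgi_abc")
}

#' @export
print.golgi_abc <- function(x, ...) {
  cat("Golgi effective-rate fit (rejection ABC)\n")
  cat("  accepted draws: ", nrow(x$draws), " over ",
      length(x$threshold_trajectory), " chains (",
      sum(x$proposals), " proposals)\n", sep = "")
  cat("  threshold: ", signif(x$initial_threshold, 4), " -> ",
      signif(x$final_threshold, 4), "\n", sep = "")
  cat("  parameters: ", ncol(x$draws), "\n", sep = "")
  invisible(x)
}

#' Posterior means of the fitted parameters
#' @param object a `"golgi_abc"` fit.
#' @param ... unused.
#' @return Named numeric vector of posterior mean effective rates.
#' @export
coef.golgi_abc <- function(object, ...) colMeans(object$draws)

#' Golgi model at the posterior means
#' @param fit a `"golgi_abc"` fit.
#' @return A [golgi_model()] with fitted rates.
#' @export
fitted_model <- function(fit) {
  m <- fit$model
  m$rates <- params_to_rates_partial(m$rates, coef(fit))
  m
}

#' Simulate replicate profiles from a fit
#'
#' Runs [replicate_profile()] at the posterior-mean parameters (the
#' standard way to produce a fitted profile with error bars).
#'
#' @param object a `"golgi_abc"` fit.
#' @param nsim number of replicates (default 3).
#' @param seed seed for the replicates.
#' @param ... passed to [replicate_profile()].
#' @return A [glycan_profile()] with SEMs.
#' @export
simulate.golgi_abc <- function(object, nsim = 3L, seed = 1L, ...) {
  replicate_profile(fitted_model(object), n_glycans = object$n_glycans,
                    n_replicates = nsim, seed = seed,
                    ruleset = object$ruleset, ...)
}

#' @export
fitted.golgi_abc <- function(object, ...) simulate(object, nsim = 3L, seed = object$seed)

#' Abundance residuals at the posterior means
#' @param object a `"golgi_abc"` fit.
#' @param ... passed to [simulate.golgi_abc()].
#' @return Named vector observed minus fitted abundance (%) per key.
#' @export
residuals.golgi_abc <- function(object, ...) {
  sim <- fitted(object, ...)
  keys <- sort(unique(c(object$observed$composition, sim$composition)))
  obs <- simx <- numeric(length(keys))
  obs[match(object$observed$composition, keys)] <- object$observed$abundance_pct
  simx[match(sim$composition, keys)] <- sim$abundance_pct
  setNames(obs - simx, keys)
}

#' Summarize an ABC fit
#'
#' Per-parameter posterior mean, SD and central credible interval, the
#' Gelman-Rubin potential scale reduction across chains, and the
#' Mann-Whitney prior-shift test against a fresh prior sample.
#'
#' @param object a `"golgi_abc"` fit.
#' @param level credible-interval level (default 0.9).
#' @param n_prior prior draws for the shift test.
#' @param alpha significance level for the shift flag.
#' @param ... unused.
#' @return A `data.frame` of class `"summary.golgi_abc"`.
#' @export
summary.golgi_abc <- function(object, level = 0.9, n_prior = 2000L,
                              alpha = 0.05, ...) {
  d <- object$draws
  a <- (1 - level) / 2
  set.seed(object$seed + 777L)
  pr <- sample_prior(object$priors, n_prior)
  shift <- prior_shift_test(pr, d, alpha = alpha)
  rhat <- gelman_rubin(split_chains(d, object$chain))
  out <- data.frame(
    param = colnames(d),
    mean = colMeans(d), sd = apply(d, 2L, sd),
    lower = apply(d, 2L, quantile, probs = a),
    upper = apply(d, 2L, quantile, probs = 1 - a),
    rhat = rhat[colnames(d)],
    shift_p = shift$p_value[match(colnames(d), shift$param)],
    shifted = shift$shifted[match(colnames(d), shift$param)],
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "level") <- level
  attr(out, "n_accepted") <- nrow(d)
  class(out) <- c("summary.golgi_abc", "data.frame")
  out
}

#' @export
print.summary.golgi_abc <- function(x, ...) {
  cat("Posterior summary (", attr(x, "n_accepted"), " accepted draws, ",
      round(100 * attr(x, "level")), "% credible intervals)\n", sep = "")
  df <- as.data.frame(x)
  df[-1L] <- lapply(df[-1L], function(v) if (is.numeric(v)) signif(v, 3) else v)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Prior and posterior densities per parameter
#'
#' @param x a `"golgi_abc"` fit.
#' @param params parameters to draw (default: up to 12 first).
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.golgi_abc <- function(x, params = NULL, ...) {
  if (is.null(params)) params <- head(colnames(x$draws), 12L)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(params)),
                       mar = c(3, 3, 2, 0.5))
  on.exit(graphics::par(old))
  for (p in params) {
    i <- match(p, x$priors$param)
    post <- x$draws[, p]
    xs <- seq(0, max(post, stats::quantile(post, 0.99) * 1.5), length.out = 200L)
    dpr <- prior_density(x$priors, i, xs)
    dpo <- density(post, from = 0)
    graphics::plot(xs, dpr, type = "l", lty = 2, col = "grey40",
                   ylim = c(0, max(dpr, dpo$y)), xlab = "", ylab = "",
                   main = p, ...)
    graphics::lines(dpo, col = "firebrick")
  }
  invisible(x)
}

split_chains <- function(draws, chain) {
  lapply(split(seq_len(nrow(draws)), chain), function(i)
    draws[i, , drop = FALSE])
}

#' Gelman-Rubin potential scale reduction
#'
#' Compares within-chain and between-chain variance per parameter:
#' R = sqrt(((n-1)/n * W + B/n) / W) with W the mean within-chain variance
#' and B/n the variance of the chain means.  Values near 1 indicate the
#' chains explore the same distribution.
#'
#' @param chains list (>= 2) of equal-size draw matrices (iterations x
#'   parameters), or of numeric vectors for a single parameter.
#' @return Named numeric vector of R per parameter; NaN (with a warning)
#'   where every chain has zero within-chain variance.
#' @export
gelman_rubin <- function(chains) {
  if (length(chains) < 2L) stop("need at least 2 chains")
  chains <- lapply(chains, function(x) {
    if (is.null(dim(x))) matrix(x, ncol = 1L, dimnames = list(NULL, "param"))
    else as.matrix(x)
  })
  n <- unique(vapply(chains, nrow, 0L))
  if (length(n) != 1L) {
    n <- min(vapply(chains, nrow, 0L))
    chains <- lapply(chains, function(x) x[seq_len(n), , drop = FALSE])
  }
  if (n < 2L) stop("chains must have length >= 2")
  params <- colnames(chains[[1L]])
  out <- setNames(numeric(length(params)), params)
  for (j in seq_along(params)) {
    x <- vapply(chains, function(ch) ch[, j], numeric(n))
    W <- mean(apply(x, 2L, stats::var))
    B_over_n <- stats::var(colMeans(x))
    if (W == 0) {
      out[j] <- if (B_over_n == 0) 1 else NaN
      if (B_over_n != 0)
        warning("zero within-chain variance for ", params[j])
      next
    }
    out[j] <- sqrt(((n - 1) / n * W + B_over_n) / W)
  }
  out
}

#' Mann-Whitney prior-shift test
#'
#' Two-sided rank-sum test per parameter between prior and posterior
#' samples; a significant shift flags the parameter as a candidate for
#' prior re-centring before a re-run.
#'
#' @param prior_draws,posterior_draws matrices with matching parameter
#'   columns (vectors accepted for a single parameter).
#' @param alpha significance level for the shift flag (default 0.05).
#' @return data.frame(param, p_value, shifted).
#' @export
prior_shift_test <- function(prior_draws, posterior_draws, alpha = 0.05) {
  if (is.null(dim(prior_draws))) prior_draws <- cbind(param = prior_draws)
  if (is.null(dim(posterior_draws))) posterior_draws <- cbind(param = posterior_draws)
  params <- colnames(prior_draws)
  p <- vapply(params, function(nm)
    suppressWarnings(wilcox.test(prior_draws[, nm], posterior_draws[, nm],
                                 exact = FALSE)$p.value), 0)
  data.frame(param = params, p_value = p, shifted = p < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Re-centre flagged priors on the posterior
#'
#' For parameters flagged by [prior_shift_test()], a log-normal prior's
#' meanlog moves to the mean of the log posterior draws (sdlog unchanged)
#' and an exponential prior's rate moves to 1 / posterior mean.  This is an
#' explicit between-run step, never automatic.
#'
#' @param priors a [prior_spec()].
#' @param posterior_draws accepted draw matrix.
#' @param shifted logical vector or character vector of parameter names to
#'   re-centre (e.g. from [prior_shift_test()]).
#' @return The updated [prior_spec()].
#' @export
recenter_priors <- function(priors, posterior_draws, shifted) {
  if (is.logical(shifted)) shifted <- priors$param[shifted]
  for (p in shifted) {
    i <- match(p, priors$param)
    if (is.na(i)) stop("unknown parameter: ", p)
    x <- posterior_draws[, p]
    if (priors$dist[i] == "lnorm") priors$p1[i] <- mean(log(x))
    else priors$p1[i] <- 1 / mean(x)
  }
  priors
}

#' Pool several independent fitting runs
#'
#' Per-parameter mean over the accepted draws of all runs (the values used
#' to generate the average fitted profile), the SD of the per-run means
#' (the run-to-run error bar), and a triplicate profile simulated at the
#' pooled means.
#'
#' @param fits a `"golgi_abc"` fit or list of them (same parameters).
#' @param n_glycans,n_replicates,seed passed to [replicate_profile()].
#' @return `list(mean = <named vector>, run_sd = <named vector>,
#'   run_means = <matrix>, profile = <glycan_profile>, model =
#'   <golgi_model>)`.
#' @export
posterior_summary <- function(fits, n_glycans = NULL, n_replicates = 3L,
                              seed = 1L) {
  if (inherits(fits, "golgi_abc")) fits <- list(fits)
  stopifnot(length(fits) >= 1L)
  run_means <- t(vapply(fits, coef, coef(fits[[1L]])))
  all_draws <- do.call(rbind, lapply(fits, `[[`, "draws"))
  mean_params <- colMeans(all_draws)
  run_sd <- if (nrow(run_means) > 1L) apply(run_means, 2L, sd)
            else setNames(rep(NA_real_, ncol(run_means)), colnames(run_means))
  fit1 <- fits[[1L]]
  model <- fit1$model
  model$rates <- params_to_rates_partial(model$rates, mean_params)
  if (is.null(n_glycans)) n_glycans <- fit1$n_glycans
  profile <- replicate_profile(model, n_glycans = n_glycans,
                               n_replicates = n_replicates, seed = seed,
                               ruleset = fit1$ruleset)
  list(mean = mean_params, run_sd = run_sd, run_means = run_means,
       profile = profile, model = model)
}
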