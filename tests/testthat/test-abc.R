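# Score, priors, rejection loop with adaptive threshold, convergence
# diagnostics and prior-shift machinery.

test_that("score worked cases match the printed formula", {
  obs <- glycan_profile(c("Hex5HexNAc2", "Hex6HexNAc2"), c(60, 40), c(1, 1))
  # every |obs - sim| strictly below sem: exact zero
  sim <- glycan_profile(c("Hex5HexNAc2", "Hex6HexNAc2"), c(60.5, 39.6))
  expect_identical(profile_score(obs, sim), 0)
  # identical profiles with positive sem: zero
  expect_identical(profile_score(obs, obs), 0)
  # single-entry hand case: obs 10, sim 12, sem 1 -> (1 - 2)^2 = 1
  obs1 <- glycan_profile("Hex5HexNAc2", 10, 1)
  sim1 <- glycan_profile("Hex5HexNAc2", 12)
  expect_equal(profile_score(obs1, sim1), 1)
  # union-of-keys: a simulated-only key is compared against obs 0 with the
  # default SEM max(0.1, 5% of 0) = 0.1
  sim2 <- glycan_profile(c("Hex5HexNAc2", "Fuc1Hex5HexNAc2"), c(10, 3))
  expect_equal(profile_score(obs1, sim2), (0.1 - 3)^2)
  # missing SEM errors under the strict policy
  expect_error(profile_score(glycan_profile("Hex5HexNAc2", 10), sim1,
                             sem_policy = "error"), "lacks SEM")
})

test_that("prior sampling matches closed-form moments", {
  pr <- prior_spec(c("a.c1", "b.c1", "c.c1"),
                   c("exp", "lnorm", "lnorm"),
                   p1 = c(2, log(0.5), log(3)), p2 = c(NA, 0.7, 1e-8))
  set.seed(4)
  d <- sample_prior(pr, 20000L)
  expect_true(all(d > 0))
  # exponential mean 1/lambda
  expect_lt(abs(mean(d[, "a.c1"]) - 0.5), 3 * 0.5 / sqrt(20000))
  # log-normal median exp(mu)
  med <- median(d[, "b.c1"])
  expect_lt(abs(log(med) - log(0.5)), 3 * 0.7 / sqrt(20000) * sqrt(pi / 2))
  # degenerate sdlog: effectively constant
  expect_lt(diff(range(d[, "c.c1"])), 1e-6)
})

test_that("localization priors put log-normals at home, exponentials elsewhere", {
  sc <- make_scenario("recovery-3c5e")
  pr <- scenario_priors(sc)
  expect_equal(nrow(pr), 15L)
  expect_equal(sum(pr$dist == "lnorm"), 5L)
  home_param <- paste0(names(sc$home), ".c", sc$home)
  expect_setequal(pr$param[pr$dist == "lnorm"], home_param)
  validate_config(sc$ground_truth, scenario_ruleset(sc), pr)
})

stub_abc <- function(observed, scorer_profile, ...) {
  # simulator ignores parameters and returns a fixed profile
  golgi_abc(observed, toy_single_model(0.1), prior_spec("MGAT1.c1", "exp", 1),
            simulator = function(params, seed) scorer_profile, ...)
}

test_that("identity-simulator stub accepts everything; posterior == prior", {
  obs <- glycan_profile(c("Hex5HexNAc2", "Hex5HexNAc3"), c(70, 30), c(1, 1))
  fit <- stub_abc(obs, obs, target_accepted = 400L, n_chains = 2L,
                  seed = 3, pilot = 50L, window = 50L)
  expect_equal(nrow(fit$draws), 400L)
  expect_true(all(fit$scores == 0))
  # accepted draws are plain prior draws: rank-sum against a fresh prior
  # sample is non-significant
  set.seed(1234)
  prior <- stats::rexp(4000, 1)
  p <- suppressWarnings(wilcox.test(fit$draws[, 1], prior)$p.value)
  expect_gt(p, 0.01)
})

test_that("threshold schedule shrinks by exactly 10% on a >7% window rate", {
  obs <- glycan_profile("Hex5HexNAc2", 50, 1)
  # score is (1 - |delta|)^2 for |delta| >= 1 where delta ~ prior; with an
  # exp(1) prior roughly half the proposals beat the pilot median, so the
  # windowed acceptance rate stays far above 7% and every window triggers
  sim_fun <- function(params, seed)
    glycan_profile("Hex5HexNAc2", 50 + 1 + params[[1]])
  fit <- golgi_abc(obs, toy_single_model(0.1),
                   prior_spec("MGAT1.c1", "exp", 1),
                   simulator = sim_fun, target_accepted = 30L,
                   n_chains = 1L, seed = 8, pilot = 100L, window = 50L,
                   final_quantile = 0.05, max_proposals = 20000L)
  traj <- fit$threshold_trajectory[[1L]]$threshold
  expect_gt(length(traj), 2L)
  # non-increasing throughout
  expect_true(all(diff(traj) <= 0))
  # every shrink before the final clamp is exactly 10%
  ratios <- traj[-1L] / traj[-length(traj)]
  expect_true(all(abs(ratios[-length(ratios)] - 0.9) < 1e-12))
  # final threshold respected by every accepted draw
  expect_true(all(fit$scores <= fit$final_threshold + 1e-12))
  # acceptance-time thresholds recorded consistently
  expect_true(all(fit$scores <= fit$accept_thresholds + 1e-12))
})

test_that("rejection ABC on a tiny synthetic fit recovers structure", {
  sc <- make_scenario("recovery-3c5e", seed = 5, n_glycans = 1500L)
  obs <- synth_observed(sc)
  pr <- scenario_priors(sc)
  fit <- golgi_abc(obs, sc$ground_truth, pr,
                   ruleset = scenario_ruleset(sc), n_glycans = 1500L,
                   target_accepted = 120L, n_chains = 2L, seed = 21,
                   window = 200L, pilot = 60L, final_quantile = 0.25,
                   max_proposals = 6000L)
  expect_s3_class(fit, "golgi_abc")
  expect_gte(nrow(fit$draws), 120L)
  expect_equal(colnames(fit$draws), pr$param)
  # monotone thresholds in every chain
  for (tr in fit$threshold_trajectory)
    expect_true(all(diff(tr$threshold) <= 0))
  # acceptance consistency: re-scoring accepted (params, seed) pairs
  # reproduces a score at or below the acceptance threshold
  scorer <- golgisim:::.make_fast_scorer(obs, sc$ground_truth,
                                         scenario_ruleset(sc), 1500L)
  idx <- sample(nrow(fit$draws), 10L)
  for (i in idx) {
    sc_i <- scorer(fit$draws[i, ], fit$accept_seeds[i])
    expect_equal(sc_i, fit$scores[i])
    expect_lte(sc_i, fit$accept_thresholds[i] + 1e-12)
  }
  # posterior contraction: posterior SD below prior SD for most parameters
  set.seed(2)
  prior_draws <- sample_prior(pr, 4000L)
  contr <- apply(fit$draws, 2, sd) < apply(prior_draws, 2, sd)
  expect_gt(mean(contr), 0.6)
  # S3 surface
  expect_named(coef(fit), pr$param)
  s <- summary(fit)
  expect_s3_class(s, "summary.golgi_abc")
  expect_true(all(c("mean", "lower", "upper", "rhat", "shift_p") %in% names(s)))
  prof <- simulate(fit, nsim = 2L, seed = 4)
  expect_s3_class(prof, "glycan_profile")
  res <- residuals(fit)
  expect_true(is.numeric(res) && length(res) > 0)
  fm <- fitted_model(fit)
  expect_equal(fm$rates["MGAT1", "c2"], coef(fit)[["MGAT1.c2"]])
  # pooling two "runs" (same fit twice) keeps means, zero run SD
  pool <- posterior_summary(list(fit, fit), n_glycans = 800L,
                            n_replicates = 2L)
  expect_equal(pool$mean, coef(fit))
  expect_true(all(pool$run_sd == 0))
})

test_that("gelman_rubin matches its defining formula and edge cases", {
  set.seed(6)
  # same-distribution chains converge to R near 1
  chains <- lapply(1:4, function(i) matrix(rnorm(5000), ncol = 1,
                                           dimnames = list(NULL, "p")))
  expect_lt(gelman_rubin(chains)[["p"]], 1.1)
  # well-separated chains: R >> 1
  sep <- list(matrix(rnorm(100, 0, 0.01), ncol = 1, dimnames = list(NULL, "p")),
              matrix(rnorm(100, 10, 0.01), ncol = 1, dimnames = list(NULL, "p")))
  expect_gt(gelman_rubin(sep)[["p"]], 2)
  # duplicated chain: between-chain variance 0, R <= 1
  x <- matrix(rnorm(200), ncol = 1, dimnames = list(NULL, "p"))
  expect_lte(gelman_rubin(list(x, x))[["p"]], 1)
  # all-constant chains: undefined, NaN with warning
  const <- matrix(1, 50, 1, dimnames = list(NULL, "p"))
  const2 <- matrix(2, 50, 1, dimnames = list(NULL, "p"))
  expect_warning(r <- gelman_rubin(list(const, const2)), "zero within-chain")
  expect_true(is.nan(r[["p"]]))
})

test_that("gelman_rubin agrees with the coda reference implementation", {
  set.seed(9)
  chains <- lapply(1:3, function(i)
    matrix(rnorm(400, mean = i * 0.05), ncol = 1,
           dimnames = list(NULL, "p")))
  ours <- gelman_rubin(chains)[["p"]]
  cd <- coda::gelman.diag(coda::mcmc.list(lapply(chains, coda::mcmc)),
                          autoburnin = FALSE)$psrf[1L]
  # coda reports the df-adjusted PSRF; the raw statistic agrees closely
  expect_lt(abs(ours - cd), 0.02)
})

test_that("prior-shift test flags shifted parameters and re-centres priors", {
  set.seed(14)
  prior <- cbind(a = rlnorm(800, 0, 0.5), b = rlnorm(800, 0, 0.5))
  post_same <- cbind(a = rlnorm(800, 0, 0.5), b = rlnorm(800, 0, 0.5))
  res <- prior_shift_test(prior, post_same)
  expect_true(all(res$p_value > 1e-3))
  # shift b by ~5 prior SDs on the log scale
  post_shift <- cbind(a = rlnorm(800, 0, 0.5), b = rlnorm(800, 2.5, 0.5))
  res2 <- prior_shift_test(prior, post_shift)
  expect_lt(res2$p_value[res2$param == "b"], 1e-6)
  expect_true(res2$shifted[res2$param == "b"])
  # re-centring moves the log-normal meanlog to the log posterior mean
  pr <- prior_spec(c("a", "b"), "lnorm", p1 = c(0, 0), p2 = 0.5)
  pr2 <- recenter_priors(pr, post_shift, res2$shifted)
  expect_equal(pr2$p1[pr2$param == "b"], mean(log(post_shift[, "b"])))
  expect_equal(pr2$p1[pr2$param == "a"], 0)    # unflagged: untouched
  expect_equal(pr2$p2, pr$p2)                  # shapes unchanged
  # exponential rule: rate = 1 / posterior mean
  pre <- prior_spec("b", "exp", p1 = 1)
  pre2 <- recenter_priors(pre, post_shift, "b")
  expect_equal(pre2$p1, 1 / mean(post_shift[, "b"]))
})
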