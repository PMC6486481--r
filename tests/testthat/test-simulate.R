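# SSA correctness: waiting times, selection probabilities, deadline
# semantics, closed-form and matrix-exponential oracles, determinism.

test_that("all-zero rates leave the glycan untouched", {
  rates <- matrix(0, 2, 2, dimnames = list(c("MGAT1", "GalT"), NULL))
  model <- golgi_model(rates, input_distribution = c(Man5 = 1))
  set.seed(1)
  out <- simulate_glycan(pathway_glycan("Man5"), model,
                         restrict_rules(c("MGAT1", "GalT")))
  expect_identical(glycan_serialize(out$final), MAN5_STR)
  expect_equal(nrow(out$events), 0L)
  sim <- simulate_profile(model, n_glycans = 50, seed = 9,
                          ruleset = restrict_rules(c("MGAT1", "GalT")))
  expect_equal(sim$profile$composition, "Hex5HexNAc2")
  expect_equal(sim$profile$abundance_pct, 100)
})

test_that("draw_step: selection probabilities are propensity ratios", {
  fake <- function(p) lapply(p, function(x) list(propensity = x))
  # R = 0: immediate exit
  expect_true(draw_step(fake(numeric()), 0, 10)$exit)
  expect_true(draw_step(fake(c(0, 0)), 0, 10)$exit)
  set.seed(101)
  n <- 10000L
  picks <- integer(n); dts <- numeric(n)
  for (i in seq_len(n)) {
    st <- draw_step(fake(c(1, 3)), 0, Inf)
    picks[i] <- st$index; dts[i] <- st$dt
  }
  # frequencies (0.25, 0.75) within 3 binomial sigma
  sigma <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(mean(picks == 1L) - 0.25), 3 * sigma)
  # dt ~ Exp(mean 1/R), R = 4
  expect_lt(abs(mean(dts) - 0.25), 3 * 0.25 / sqrt(n))
  # equal propensities are symmetric
  eq <- vapply(seq_len(n), function(i) draw_step(fake(c(2, 2)), 0, Inf)$index,
               0L)
  expect_lt(abs(mean(eq == 1L) - 0.5), 3 * sqrt(0.25 / n))
  # mean dt at R = 2 is 0.5 within 3 sigma
  d2 <- vapply(seq_len(n), function(i) draw_step(fake(c(1, 1)), 0, Inf)$dt, 0)
  expect_lt(abs(mean(d2) - 0.5), 3 * 0.5 / sqrt(n))
})

test_that("single-reaction conversion matches 1 - exp(-kT)", {
  k <- 0.12; T <- 10; n <- 10000L
  sim <- simulate_profile(toy_single_model(k, 1L, T), n, seed = 23,
                          ruleset = toy_single_ruleset(),
                          abundance_filter = 0)
  p_theory <- 1 - exp(-k * T)
  converted <- sim$profile$abundance_pct[sim$profile$composition == "Hex5HexNAc3"] / 100
  expect_lt(abs(converted - p_theory),
            3 * sqrt(p_theory * (1 - p_theory) / n))
})

test_that("first-event times follow the deadline-truncated exponential", {
  k <- 0.2; T <- 5
  sim <- simulate_profile(toy_single_model(k, 1L, T), 10000L, seed = 31,
                          ruleset = toy_single_ruleset(),
                          record_events = TRUE)
  t1 <- sim$events$time
  expect_true(all(t1 >= 0 & t1 < T))
  # E[t | t < T] for t ~ Exp(k) truncated at T
  m_theory <- 1 / k - T * exp(-k * T) / (1 - exp(-k * T))
  expect_lt(abs(mean(t1) - m_theory), 3 * sd(t1) / sqrt(length(t1)))
})

test_that("competing-reaction occupancy matches the CTMC matrix exponential", {
  model <- toy_competing_model(0.08, 0.05, 0.06)
  ruleset <- toy_competing_ruleset()
  n <- 10000L
  sim <- simulate_profile(model, n, seed = 77, ruleset = ruleset,
                          abundance_filter = 0)
  net <- sim$network
  S <- nrow(net$states)
  rates <- model$rates[net$enzymes, , drop = FALSE]
  Q <- matrix(0, S, S)
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    r <- rates[e$enzyme, 1L] * e$scale
    Q[e$from, e$to] <- Q[e$from, e$to] + r
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  p0 <- numeric(S); p0[net$input_ids[["Man5"]]] <- 1
  pT <- as.numeric(p0 %*% as.matrix(Matrix::expm(Q * model$residence_time[1L])))
  occ <- sim$structures$count / n
  for (s in seq_len(S)) {
    tol <- 4 * sqrt(max(pT[s] * (1 - pT[s]), 1e-6) / n)
    expect_lt(abs(occ[s] - pT[s]), tol + 1e-9)
  }
})

test_that("profiles are seed-deterministic and seed-consistent", {
  sc <- make_scenario("recovery-3c5e")
  rules <- scenario_ruleset(sc)
  a <- simulate_profile(scenario_model(sc), 4000, seed = 5, ruleset = rules)
  b <- simulate_profile(scenario_model(sc), 4000, seed = 5, ruleset = rules)
  expect_identical(a$profile, b$profile)
  expect_identical(a$flux, b$flux)
  c2 <- simulate_profile(scenario_model(sc), 4000, seed = 6, ruleset = rules)
  expect_false(identical(a$profile, c2$profile))
  # different seeds agree within multinomial sampling error (chi-square)
  keys <- union(a$structures$structure, c2$structures$structure)
  tab <- rbind(a$structures$count[match(keys, a$structures$structure)],
               c2$structures$count[match(keys, c2$structures$structure)])
  tab[is.na(tab)] <- 0
  tab <- tab[, colSums(tab) > 5, drop = FALSE]
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(p, 1e-4)
})

test_that("pre-filter abundances sum to 100% and the 0.1% filter drops mass", {
  sc <- make_scenario("oligomannose-3c")
  sim <- simulate_profile(scenario_model(sc), 5000, seed = 2)
  expect_equal(attr(sim$profile, "pre_filter_total"), 100)
  expect_true(all(sim$profile$abundance_pct >= 0.1))
  dropped <- attr(sim$profile, "dropped")
  expect_equal(sum(sim$profile$abundance_pct) + sum(dropped$abundance_pct),
               100)
})

test_that("tree-level reference and compiled engine sample the same law", {
  sc <- make_scenario("recovery-3c5e")
  model <- scenario_model(sc)
  rules <- scenario_ruleset(sc)
  big <- simulate_profile(model, 20000, seed = 41, ruleset = rules,
                          abundance_filter = 0)
  state_id <- function(structure, quenched)
    paste0(ifelse(quenched, "Q|", ""), structure)
  probs <- setNames(big$structures$count / 20000,
                    state_id(big$structures$structure,
                             big$structures$quenched))
  set.seed(99)
  n_ref <- 300L
  finals <- character(n_ref)
  inputs <- sample(names(model$input_distribution), n_ref, replace = TRUE,
                   prob = model$input_distribution)
  for (i in seq_len(n_ref)) {
    fin <- simulate_glycan(pathway_glycan(inputs[i]), model, rules)$final
    finals[i] <- state_id(glycan_serialize(fin), golgisim:::is_quenched(fin))
  }
  # goodness of fit of reference-path outcomes against engine frequencies
  expect_true(all(finals %in% names(probs)))
  cnt <- table(factor(finals, levels = names(probs)))
  keep <- probs * n_ref >= 2
  p <- suppressWarnings(
    stats::chisq.test(c(cnt[keep], sum(cnt[!keep])),
                      p = c(probs[keep], sum(probs[!keep])),
                      rescale.p = TRUE)$p.value)
  expect_gt(p, 1e-3)
})

test_that("replicate profiles report SEM = sd/sqrt(n) with zero-fill", {
  sc <- make_scenario("recovery-3c5e")
  model <- scenario_model(sc); rules <- scenario_ruleset(sc)
  # identical replicate seeds give SEM exactly 0
  same <- replicate_profile(model, 1000, 3, seeds = c(4, 4, 4),
                            ruleset = rules)
  expect_true(all(same$sem_pct == 0))
  r3 <- replicate_profile(model, 1000, 3, seed = 10, ruleset = rules)
  expect_equal(attr(r3, "n_replicates"), 3L)
  expect_true(all(r3$sem_pct >= 0))
  # SEM shrinks roughly like 1/sqrt(n_replicates)
  r48 <- replicate_profile(model, 1000, 48, seed = 10, ruleset = rules)
  common <- intersect(r3$composition, r48$composition)
  ratio <- mean(r3$sem_pct[match(common, r3$composition)]) /
    mean(r48$sem_pct[match(common, r48$composition)])
  expect_gt(ratio, 2)    # theory: 4
  expect_lt(ratio, 8)
})

test_that("event logs respect cisterna clocks and composition bookkeeping", {
  sc <- make_scenario("recovery-3c5e")
  sim <- simulate_profile(scenario_model(sc), 500, seed = 17,
                          ruleset = scenario_ruleset(sc),
                          record_events = TRUE)
  ev <- sim$events
  expect_true(all(ev$time >= 0 &
                    ev$time < scenario_model(sc)$residence_time[ev$cisterna]))
  expect_true(all(ev$cisterna %in% 1:3))
  # within a glycan and cisterna, times increase
  ord <- order(ev$glycan_index, ev$cisterna, ev$time)
  expect_identical(ord, seq_len(nrow(ev)))
  # non-quench events change the structure
  changed <- ev$substrate != ev$product
  expect_true(all(changed | ev$enzyme == "OMquench"))
})
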