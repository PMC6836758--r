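# a small hand-made reference table for bookkeeping tests
fake_table <- function(stats, labels, params = NULL, scenarios = NULL) {
  mads <- apply(stats, 2, mad)
  mads[mads == 0] <- 1
  if (is.null(params))
    params <- matrix(runif(nrow(stats)), ncol = 1, dimnames = list(NULL, "N_X"))
  structure(list(scenario = factor(labels), params = params, stats = stats,
                 mads = mads, scenarios = scenarios, loci = NULL,
                 design = NULL, master_seed = 0L),
            class = "ref_table")
}

test_that("summary vectors share one fixed schema across observed and simulated data", {
  sc <- builtin_scenarios()$scenario1
  loci <- default_loci(); des <- default_design()
  d <- draw_parameters(sc, seed = 11)
  p <- simulate_dataset(sc, d, loci, des, seed = 11)
  sv <- summary_vector(p)
  # 7 pops x 5 one-sample + 21 pairs x 3 two-sample, for mt and nuclear
  expect_length(sv, 2 * (7 * 5 + 21 * 3))
  expect_true(all(c("mt.ERI.H", "mt.ERI_KHO.phiST", "nuc.KOD.D",
                    "nuc.COR_JUN.betweenK") %in% names(sv)))
  expect_false(any(is.na(sv)))
  # the string-alignment path agrees with the fast simulation path
  set.seed(11)
  sims <- lapply(loci, function(lc) coalABC:::sim_locus_matrix(sc, d, lc, des))
  sv2 <- coalABC:::summary_vector_sim(sims, loci)
  expect_equal(unname(sv[names(sv2)]), unname(sv2), tolerance = 1e-12)
})

test_that("reference tables are balanced, deterministic and MAD-normalized", {
  scs <- builtin_scenarios()[c("scenario1", "scenario4")]
  loci <- list(CYTB = default_loci()$CYTB)
  des <- default_design()
  tab <- build_reference_table(scs, loci, des, n_per_scenario = 15,
                               master_seed = 5)
  expect_equal(nrow(tab$stats), 30L)
  expect_equal(as.vector(table(tab$scenario)), c(15L, 15L))
  expect_true(all(tab$mads > 0))
  tab2 <- build_reference_table(scs, loci, des, n_per_scenario = 15,
                                master_seed = 5)
  expect_identical(tab$stats, tab2$stats)
  expect_identical(tab$params, tab2$params)
})

test_that("rejection keeps the closest rows with hand-checked distances", {
  stats <- matrix(c(1, 2,
                    0, 0,
                    3, 1), ncol = 2, byrow = TRUE,
                  dimnames = list(NULL, c("s1", "s2")))
  tab <- fake_table(stats, c("a", "b", "a"))
  obs <- c(s1 = 0, s2 = 0)
  rej <- abc_reject(tab, obs, 3)
  manual <- sqrt(rowSums(sweep(stats, 2, tab$mads, "/")^2))
  expect_equal(unname(rej$dist), sort(manual))
  expect_equal(rej$idx[1], 2L)           # exact match retained first
  expect_equal(rej$dist[1], 0)
  # retaining everything returns all rows whatever the observed vector
  expect_length(abc_reject(tab, c(s1 = 99, s2 = -99), 3)$idx, 3L)
  expect_error(abc_reject(tab, c(bad = 1, s2 = 0), 2), "schema")
  expect_error(abc_reject(tab, obs, 10), "exceeds")
})

test_that("rejection distances are a prefix of the full ordering", {
  set.seed(3)
  stats <- matrix(rnorm(600), ncol = 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  tab <- fake_table(stats, rep(c("s1", "s2"), each = 100))
  obs <- c(a = 0, b = 0, c = 0)
  r100 <- abc_reject(tab, obs, 100)
  r20 <- abc_reject(tab, obs, 20)
  expect_identical(r20$idx, r100$idx[1:20])
  expect_lte(max(r20$dist), max(r100$dist))
})

test_that("model choice handles degenerate and no-signal retained sets", {
  set.seed(9)
  stats <- matrix(rnorm(400), ncol = 2, dimnames = list(NULL, c("a", "b")))
  # all retained rows from one scenario -> probability 1
  tab1 <- fake_table(stats, rep("s1", 200))
  rej1 <- abc_reject(tab1, c(a = 0, b = 0), 50)
  mc1 <- model_choice(rej1, n_boot = 0)
  expect_equal(unname(mc1$posterior["s1"]), 1)
  # labels independent of stats -> probabilities near class frequencies
  labs <- rep(c("s1", "s2"), times = c(150, 50))
  tab2 <- fake_table(stats, labs)
  rej2 <- abc_reject(tab2, c(a = 0, b = 0), 200)
  mc2 <- model_choice(rej2, n_boot = 0)
  expect_equal(unname(mc2$posterior["s1"]), 0.75, tolerance = 0.12)
  expect_equal(sum(mc2$posterior), 1, tolerance = 1e-9)
})

test_that("bootstrap intervals bracket the point estimate", {
  set.seed(10)
  z <- matrix(rnorm(300), ncol = 2, dimnames = list(NULL, c("a", "b")))
  labs <- ifelse(z[, 1] + rnorm(150, sd = 2) > 0, "s1", "s2")
  tab <- fake_table(z, labs)
  rej <- abc_reject(tab, c(a = 0, b = 0), 150)
  mc <- model_choice(rej, n_boot = 50, seed = 2)
  expect_equal(sum(mc$posterior), 1, tolerance = 1e-9)
  for (s in names(mc$posterior)) {
    expect_lte(mc$ci[1, s], mc$posterior[s] + 1e-9)
    expect_gte(mc$ci[2, s], mc$posterior[s] - 1e-9)
  }
})

test_that("error rates follow the false-positive / false-negative definitions", {
  # oracle choices: perfect classification -> both rates zero
  perfect <- list(
    s1 = data.frame(true = "s1", selected = rep("s1", 10)),
    s2 = data.frame(true = "s2", selected = rep("s2", 10)))
  tab <- fake_table(matrix(rnorm(20), ncol = 2,
                           dimnames = list(NULL, c("a", "b"))),
                    rep(c("s1", "s2"), 5))
  er <- error_rates(tab, "s1", pods = perfect)
  expect_equal(er$false_positive_rate, 0)
  expect_equal(er$false_negative_rate, 0)
  # hand-built confusion: s1 pods picked wrong 3/10; s2 pods picked s1 4/10
  mixed <- list(
    s1 = data.frame(true = "s1", selected = c(rep("s1", 7), rep("s2", 3))),
    s2 = data.frame(true = "s2", selected = c(rep("s1", 4), rep("s2", 6))))
  er2 <- error_rates(tab, "s1", pods = mixed)
  expect_equal(er2$false_negative_rate, 0.3)
  expect_equal(er2$false_positive_rate, 0.4)
})

test_that("indistinguishable scenarios misclassify at the chance rate", {
  # two scenarios with identical parameterization and topology
  sc <- builtin_scenarios()$scenario1
  scs <- list(scenario1 = sc, scenario1b = sc)
  scs$scenario1b$id <- "scenario1b"
  loci <- list(CYTB = default_loci()$CYTB)
  tab <- build_reference_table(scs, loci, default_design(),
                               n_per_scenario = 150, master_seed = 3)
  pods <- run_pods(tab, scs$scenario1, n_pods = 20, n_retain = 100, seed = 17)
  er <- error_rates(tab, "scenario1", pods = list(scenario1 = pods,
                                                  scenario1b = pods))
  # chance rate (K-1)/K = 0.5 within binomial noise at 20 pods
  expect_gt(er$false_negative_rate, 0.15)
  expect_lt(er$false_negative_rate, 0.85)
})

test_that("parameter estimation adjusts, transforms and covers edge cases", {
  set.seed(14)
  n <- 400
  truth <- runif(n, 100, 1e4)
  stats <- cbind(s1 = truth / 1e3 + rnorm(n, sd = 0.1),
                 s2 = rnorm(n))
  sc <- one_pop_scenario(5000)
  sc$priors$N_X <- prior_spec(100, 1e4)
  tab <- fake_table(stats, rep("onepop", n),
                    params = matrix(truth, ncol = 1,
                                    dimnames = list(NULL, "N_X")),
                    scenarios = list(onepop = sc))
  obs <- c(s1 = 5, s2 = 0)   # implies N ~ 5000
  est <- estimate_parameters(tab, obs, "onepop", retain_fraction = 0.25)
  expect_true(est$adjusted)
  expect_equal(est$N_X$mode, 5000, tolerance = 0.2)
  expect_lt(est$N_X$ci[1], est$N_X$ci[2])
  # samples stay inside prior bounds after back-transform
  expect_true(all(est$N_X$sample >= 100 & est$N_X$sample <= 1e4))
  # midpoint parameter maps to logit zero
  mid <- (100 + 1e4) / 2
  phi <- log((mid - 100) / (1e4 - mid))
  expect_equal(phi, 0)
})

test_that("estimation is equivariant under affine rescaling of a statistic", {
  set.seed(15)
  n <- 300
  truth <- runif(n, 1, 100)
  stats <- cbind(s1 = truth + rnorm(n), s2 = rnorm(n))
  sc <- one_pop_scenario(50)
  sc$priors$N_X <- prior_spec(1, 100)
  mk <- function(scale_s1) {
    s <- stats; s[, "s1"] <- s[, "s1"] * scale_s1
    fake_table(s, rep("onepop", n),
               params = matrix(truth, ncol = 1, dimnames = list(NULL, "N_X")),
               scenarios = list(onepop = sc))
  }
  obs1 <- c(s1 = 50, s2 = 0)
  obs2 <- c(s1 = 50 * 1000, s2 = 0)
  e1 <- estimate_parameters(mk(1), obs1, "onepop", retain_fraction = 0.2)
  e2 <- estimate_parameters(mk(1000), obs2, "onepop", retain_fraction = 0.2)
  expect_equal(e1$N_X$mode, e2$N_X$mode, tolerance = 1e-9)
  expect_equal(e1$N_X$ci, e2$N_X$ci, tolerance = 1e-9)
})

test_that("unit scaling converts between mutation, generation and year scales", {
  cfg <- scaling_config()
  cytb <- default_loci()$CYTB
  # 1%/Myr divergence -> per-lineage per-site 5e-9 / year
  expect_equal(cfg$mu_site_year, 5e-9)
  expect_equal(scale_units(20000, "generations_to_years", cytb, cfg), 20000)
  # t_mut = 0.2 on CYTB: 0.2 / (433 * 5e-9) years
  expect_equal(scale_units(0.2, "t_mut_to_years", cytb, cfg),
               0.2 / (433 * 5e-9), tolerance = 1e-9)
  expect_equal(scale_units(0.2, "t_mut_to_years", cytb, cfg), 92378.75,
               tolerance = 1e-4)
  # theta_to_N honours the inheritance scalar
  theta <- 0.5
  expect_equal(scale_units(theta, "theta_to_N", cytb, cfg),
               theta / (4 * mu_locus(cytb) * 0.25))
  expect_error(scale_units(-1, "generations_to_years", cytb, cfg), "positive")
  expect_error(scaling_config(divergence_rate_per_Myr = 0), "positive")
})
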