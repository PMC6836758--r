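test_that("builtin scenarios encode the four competing histories", {
  scs <- builtin_scenarios()
  expect_named(scs, paste0("scenario", 1:4))
  # 6 merges for 7 populations, every scenario
  for (sc in scs) expect_equal(nrow(sc$events), 6L)
  # scenario 1: NEP clade {KOD, COR, JUN} funnels into the PET lineage
  ev1 <- scs$scenario1$events
  expect_equal(ev1$dst[ev1$src == "KOD"], "COR")
  expect_equal(ev1$dst[ev1$src == "COR"], "JUN")
  expect_equal(ev1$dst[ev1$src == "JUN"], "PET")
  # scenario 3 reverses the direction: PET derived from the NEP lineage
  ev3 <- scs$scenario3$events
  expect_equal(ev3$dst[ev3$src == "PET"], "JUN")
  # scenario 2: two independent arrivals into PET
  ev2 <- scs$scenario2$events
  expect_setequal(ev2$src[ev2$dst == "PET"], c("COR", "KOD"))
  # scenario 4: NEP clade joins only at the root
  ev4 <- scs$scenario4$events
  expect_true(all(c("t_g") %in% ev4$time_param))
})

test_that("scenario_spec validates tree structure", {
  expect_error(scenario_spec("bad", c("A", "B"),
                             data.frame(time_param = character(0),
                                        src = character(0), dst = character(0)),
                             list()),
               "merge events")
  expect_error(
    scenario_spec("bad", c("A", "B", "C"),
                  data.frame(time_param = c("t1", "t2"),
                             src = c("A", "A"), dst = c("B", "C")),
                  list()),
    "exactly once")
})

test_that("modal parameters satisfy scenario 1's constraints", {
  sc <- builtin_scenarios()$scenario1
  d <- fixed_parameters(sc, scenario1_modal_parameters())
  expect_s3_class(d, "parameter_draw")
  v <- d$values
  expect_lt(v[["t_a"]], v[["t_b"]])
  expect_lt(v[["t_c"]], v[["t_e"]])
})

test_that("draw_parameters respects bounds, constraints and seeds", {
  sc <- builtin_scenarios()$scenario1
  for (i in 1:50) {
    d <- draw_parameters(sc, seed = i)
    v <- d$values
    for (pn in names(sc$priors)) {
      expect_gte(v[[pn]], sc$priors[[pn]]$lower)
      expect_lte(v[[pn]], sc$priors[[pn]]$upper)
    }
    expect_lt(v[["t_a"]], v[["t_b"]])
    expect_lt(v[["t_b"]], v[["t_c"]])
    expect_lt(v[["t_c"]], v[["t_e"]])
    expect_lt(v[["t_d"]], v[["t_f"]])
  }
  expect_identical(draw_parameters(sc, seed = 3)$values,
                   draw_parameters(sc, seed = 3)$values)
  # unsatisfiable constraints
  bad <- sc
  bad$constraints <- list(c("t_a", "t_b"), c("t_b", "t_a"))
  expect_error(draw_parameters(bad, seed = 1, max_tries = 128),
               "prior-specification")
})

test_that("pairwise coalescence time and diversity match theory", {
  # E[T2] = inheritance * 2N generations for two gene copies
  N <- 5000
  loc_nuc <- locus_spec("NUC", 500, 1, 2e-6, 2)
  loc_mt <- locus_spec("MT", 500, 0.25, 2e-6, 1)
  set.seed(42)
  reps <- 3000
  k_nuc <- k_mt <- numeric(reps)
  for (i in 1:reps) {
    k_nuc[i] <- sum(sim_one_pop_matrix(N, 2, loc_nuc)$haps)
    k_mt[i] <- sum(sim_one_pop_matrix(N, 2, loc_mt)$haps)
  }
  # E[k] = 2 * (inh * 2N) * u
  u <- 500 * 2e-6
  exp_nuc <- 2 * (2 * N) * u
  exp_mt <- 2 * (0.25 * 2 * N) * u
  expect_lt(abs(mean(k_nuc) - exp_nuc), 3 * sd(k_nuc) / sqrt(reps))
  expect_lt(abs(mean(k_mt) - exp_mt), 3 * sd(k_mt) / sqrt(reps))
})

test_that("single-population neutral simulations calibrate to theory", {
  # n = 20, theta = 5: E[S] = theta * a1, E[k] = theta, E[D] ~ 0
  n <- 20L; theta <- 5
  N <- 10000
  loc <- locus_spec("L", 1000, 1, theta / (4 * N) / 1000, 1)
  set.seed(2024)
  reps <- 1000
  S <- k <- D <- numeric(reps)
  for (i in 1:reps) {
    X <- sim_one_pop_matrix(N, n, loc)$haps
    S[i] <- ncol(X)
    dm <- coalABC:::pair_diff_matrix(X)
    k[i] <- mean(dm[upper.tri(dm)])
    D[i] <- coalABC:::tajima_d_core(n, S[i], k[i])
  }
  a1 <- sum(1 / (1:(n - 1)))
  expect_lt(abs(mean(S) - theta * a1), 3 * sd(S) / sqrt(reps))
  expect_lt(abs(mean(k) - theta), 3 * sd(k) / sqrt(reps))
  expect_gt(mean(D, na.rm = TRUE), -0.15)
  expect_lt(mean(D, na.rm = TRUE), 0.15)
})

test_that("a zero split time leaves populations indistinguishable", {
  sc <- two_pop_scenario()
  des <- sampling_design(c(X = 10L, Y = 10L), c(X = "NWP", Y = "NEP"))
  loc <- locus_spec("L", 500, 1, 1e-6, 1)
  d0 <- fixed_parameters(sc, c(N_X = 5000, N_Y = 5000, t_s = 0.2))
  set.seed(31)
  del <- replicate(200, {
    s <- coalABC:::sim_locus_matrix(sc, d0, loc, des)
    dm <- coalABC:::pair_diff_matrix(s$haps)
    ia <- which(s$pop == "X"); ib <- which(s$pop == "Y")
    mean(dm[ia, ib]) - mean(dm[ia, ia][upper.tri(dm[ia, ia])])
  })
  expect_lt(abs(mean(del)), 3 * sd(del) / sqrt(200))
})

test_that("between-population divergence is monotone in split time", {
  sc <- two_pop_scenario()
  des <- sampling_design(c(X = 8L, Y = 8L), c(X = "NWP", Y = "NEP"))
  loc <- locus_spec("L", 500, 1, 1e-6, 1)
  between_k <- function(t_s) {
    d <- fixed_parameters(sc, c(N_X = 5000, N_Y = 5000, t_s = t_s))
    mean(replicate(150, {
      s <- coalABC:::sim_locus_matrix(sc, d, loc, des)
      dm <- coalABC:::pair_diff_matrix(s$haps)
      mean(dm[which(s$pop == "X"), which(s$pop == "Y")])
    }))
  }
  set.seed(13)
  ks <- vapply(c(10, 20000, 100000), between_k, 0)
  expect_true(all(diff(ks) > 0))
})

test_that("simulate_dataset matches the empirical design and is reproducible", {
  sc <- builtin_scenarios()$scenario1
  d <- draw_parameters(sc, seed = 4)
  loci <- default_loci(); des <- default_design()
  p <- simulate_dataset(sc, d, loci, des, seed = 4)
  # 80 individuals -> 80 mtDNA records, 160 records per nuclear locus
  expect_equal(nrow(p$records$CYTB), 80L)
  expect_equal(nrow(p$records$ATPSa), 160L)
  expect_equal(sort(unique(p$records$CYTB$population)),
               sort(c("ERI", "KHO", "STA", "PET", "KOD", "COR", "JUN")))
  expect_equal(unique(nchar(p$records$CYTB$seq)), 433L)
  # determinism
  p2 <- simulate_dataset(sc, d, loci, des, seed = 4)
  expect_identical(p$records, p2$records)
  # zero mutation rate: all sequences identical
  loci0 <- list(Z = locus_spec("Z", 100, 1, 1e-30, 1))
  pz <- simulate_dataset(sc, d, loci0, des, seed = 1)
  expect_equal(length(unique(pz$records$Z$seq)), 1L)
})

test_that("per-row seed derivation is stable and in integer range", {
  s <- derive_seed(123, 0:10000)
  expect_true(all(s >= 0 & s < 2^31 - 1))
  expect_false(any(duplicated(s)))
  expect_identical(derive_seed(123, 5), derive_seed(123, 5))
})
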