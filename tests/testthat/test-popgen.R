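test_that("diversity reproduces hand-computed values", {
  # haplotype counts {3, 2}: h = 5/4 * (1 - (0.6^2 + 0.4^2)) = 0.6
  d <- diversity(c("AAT", "AAT", "AAT", "ACT", "ACT"))
  expect_equal(d$h, 0.6)
  expect_equal(d$S, 1L)
  # all identical
  d0 <- diversity(rep("ACGT", 4))
  expect_equal(d0$h, 0)
  expect_equal(d0$S, 0L)
  expect_equal(d0$k, 0)
  # two copies differing at 2 of 10 usable sites
  d2 <- diversity(c("AAAAAAAAAA", "TTAAAAAAAA"))
  expect_equal(d2$k, 2)
  expect_equal(d2$pi, 0.2)
  expect_error(diversity("ACGT"), "sample-size")
})

test_that("gap and ambiguity sites are excluded listwise", {
  # site 2 has a gap in one sequence: dropped for everyone
  d <- diversity(c("A-T", "AGT", "AGA"))
  expect_equal(d$usable, 2L)
  expect_equal(d$S, 1L)
  d2 <- diversity(c("ANT", "AGT"))
  expect_equal(d2$usable, 2L)
})

test_that("Tajima's D matches the worked four-sequence example", {
  L <- 100
  seqs <- c(strrep("A", L), strrep("A", L),
            paste0("GG", strrep("A", L - 2)), paste0("AG", strrep("A", L - 2)))
  expect_equal(tajima_d(seqs), 0.5915801, tolerance = 1e-6)
  expect_true(is.na(tajima_d(rep("AAAA", 5))))       # S = 0
  expect_true(is.na(tajima_d(c("AA", "AT", "TA")))) # n < 4
})

test_that("Fu's Fs matches the Ewens closed forms", {
  # n = 3, all distinct, theta-hat = 1: S' = 1/6, Fs = ln(1/5)
  expect_equal(fu_fs(c("A", "G", "C")), log(0.2), tolerance = 1e-9)
  # n = 2 differing copies: S' = P(K >= 2) = theta / (theta + 1)
  seqs2 <- c("AAAA", "GGAA")   # k = 2
  sp <- 2 / 3
  expect_equal(fu_fs(seqs2), log(sp / (1 - sp)), tolerance = 1e-9)
  expect_true(is.na(fu_fs(rep("AC", 3))))            # k = 0
})

test_that("R2 matches hand computations", {
  expect_equal(r2_stat(c("A", "G")), 0.5)
  # all-doubleton case: U_i = 0 for every copy, R2 = (k/2)/S
  seqs <- c("AAAA", "AAAA", "GGAA", "GGAA")
  k <- oracle_k(seqs)$k
  expect_equal(r2_stat(seqs), (k / 2) / 2)
  expect_true(is.na(r2_stat(rep("AAA", 4))))
})

test_that("neutrality statistics agree with brute-force oracles on random panels", {
  set.seed(1234)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    seqs <- random_seqs(n, sample(10:30, 1))
    oD <- oracle_tajima_d(seqs)
    D <- tajima_d(seqs)
    if (is.na(oD)) expect_true(is.na(D)) else expect_equal(D, oD, tolerance = 1e-9)
    oF <- oracle_fu_fs(seqs)
    Fs <- fu_fs(seqs)
    if (is.na(oF)) expect_true(is.na(Fs)) else expect_equal(Fs, oF, tolerance = 1e-6)
    oR <- oracle_r2(seqs)
    R2 <- r2_stat(seqs)
    if (is.na(oR)) expect_true(is.na(R2)) else expect_equal(R2, oR, tolerance = 1e-9)
    dv <- diversity(seqs)
    ok <- oracle_k(seqs)
    expect_equal(dv$k, ok$k, tolerance = 1e-9)
    expect_equal(dv$var_k, ok$var_k, tolerance = 1e-9)
    expect_equal(dv$S, oracle_S(seqs))
  }
})

test_that("Fu's Fs tail probability agrees with a CRP simulation", {
  set.seed(99)
  seqs <- random_seqs(8, 20, n_base = 4, mut_per_copy = 2)
  k <- oracle_k(seqs)$k
  H <- length(unique(seqs))
  fs <- fu_fs(seqs)
  sp <- exp(fs) / (1 + exp(fs))
  sim <- oracle_crp_p_k_ge(8, k, H, reps = 40000)
  expect_lt(abs(sp - sim), 0.003)  # ~3.5 Monte-Carlo SEs at 40k reps
})

test_that("haplotype diversity is maximal when every copy is unique", {
  set.seed(7)
  seqs <- c("AAAA", "GAAA", "AGAA", "AAGA", "AAAG")
  expect_equal(diversity(seqs)$h, 1)
})

test_that("significance obeys the add-one convention and calibrates on null data", {
  seqs <- c(strrep("A", 30), strrep("A", 30),
            paste0("GG", strrep("A", 28)), paste0("AG", strrep("A", 28)))
  s <- significance(seqs, "D", n_sims = 50, seed = 1)
  expect_gte(s$p_value, 1 / 51)
  expect_lte(s$p_value, 1)
  expect_error(significance(seqs, "D", n_sims = 0), "n_sims")
  expect_error(significance(rep("AAA", 5), "D", n_sims = 10), "undefined")
  # null calibration: neutral data should not be rejected too often
  set.seed(5)
  rej <- 0
  n_rep <- 60
  for (i in 1:n_rep) {
    X <- coalABC:::sim_conditional_cpp(12L, 6L)
    seqs <- apply(X, 1, function(r) paste(c("A", "G")[r + 1], collapse = ""))
    p <- significance(seqs, "r2", n_sims = 99)$p_value
    if (p < 0.05) rej <- rej + 1
  }
  expect_lte(rej / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("pairwise Phi_ST matches fixed cases and the brute-force oracle", {
  # fixed difference between populations: all variance among groups
  res <- pairwise_phi_st(rep("AAAA", 4), rep("GGGG", 4), n_perms = 99, seed = 1)
  expect_equal(res$phi_st, 1)
  # identical sequences: defined as 0 with p = 1
  res0 <- pairwise_phi_st(rep("AAAA", 3), rep("AAAA", 3), n_perms = 99)
  expect_equal(res0$phi_st, 0)
  expect_equal(res0$p_value, 1)
  # small worked instance vs brute-force variance components
  set.seed(77)
  for (rep in 1:10) {
    a <- random_seqs(3, 12); b <- random_seqs(3, 12)
    if (all(c(a, b) == c(a, b)[1])) next
    res <- pairwise_phi_st(a, b, n_perms = 9, seed = 1)
    orc <- oracle_phi_st(a, b)
    expect_equal(res$phi_st, orc$phi, tolerance = 1e-12)
    expect_equal(res$sigma_among, orc$s2a, tolerance = 1e-12)
    expect_equal(res$sigma_within, orc$s2b, tolerance = 1e-12)
  }
})

test_that("Phi_ST is symmetric and invariant to duplicating site columns", {
  set.seed(8)
  a <- random_seqs(5, 10); b <- random_seqs(4, 10)
  r1 <- pairwise_phi_st(a, b, n_perms = 9, seed = 1)
  r2 <- pairwise_phi_st(b, a, n_perms = 9, seed = 1)
  expect_equal(r1$phi_st, r2$phi_st, tolerance = 1e-12)
  r3 <- pairwise_phi_st(paste0(a, a), paste0(b, b), n_perms = 9, seed = 1)
  expect_equal(r1$phi_st, r3$phi_st, tolerance = 1e-12)
})

test_that("panmictic populations give near-zero Phi_ST with uniform p-values", {
  set.seed(11)
  phis <- ps <- numeric(20)
  for (i in 1:20) {
    pool <- random_seqs(12, 15, n_base = 4, mut_per_copy = 2)
    res <- pairwise_phi_st(pool[1:6], pool[7:12], n_perms = 99)
    phis[i] <- res$phi_st; ps[i] <- res$p_value
  }
  expect_lt(abs(mean(phis)), 0.12)
  expect_gt(mean(ps > 0.2), 0.5)   # p-values not piled near 0 under the null
})

test_that("Tajima's D agrees with an independent implementation (dendropy)", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  set.seed(202)
  for (rep in 1:5) {
    seqs <- random_seqs(8, 40, n_base = 3, mut_per_copy = 2)
    if (oracle_S(seqs) == 0) next
    fa <- tempfile(fileext = ".fasta")
    writeLines(as.vector(rbind(paste0(">s", seq_along(seqs)), seqs)), fa)
    script <- tempfile(fileext = ".py")
    writeLines(c(
      "import sys, dendropy",
      "from dendropy.calculate import popgenstat",
      "m = dendropy.DnaCharacterMatrix.get(path=sys.argv[1], schema='fasta')",
      "print(popgenstat.tajimas_d(m))"), script)
    out <- suppressWarnings(system2(py, c(script, fa), stdout = TRUE, stderr = TRUE))
    val <- suppressWarnings(as.numeric(tail(out, 1)))
    skip_if(is.na(val), "dendropy unavailable")
    expect_equal(tajima_d(seqs), val, tolerance = 1e-6)
  }
})
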