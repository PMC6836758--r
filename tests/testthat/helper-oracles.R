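# Independent brute-force oracles, kept deliberately naive: explicit loops
# and textbook formulas, sharing no code path with the package internals.

ACGT <- c("A", "C", "G", "T")

# naive pairwise difference count on sites free of gaps/ambiguity
oracle_pairdiff <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  ok <- a %in% ACGT & b %in% ACGT
  sum(a[ok] != b[ok])
}

oracle_usable_columns <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  which(apply(m, 2, function(col) all(col %in% ACGT)))
}

oracle_k <- function(seqs) {
  # listwise usable sites, then mean over all pairs
  m <- do.call(rbind, strsplit(seqs, ""))
  keep <- oracle_usable_columns(seqs)
  m <- m[, keep, drop = FALSE]
  n <- length(seqs)
  d <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    d <- c(d, sum(m[i, ] != m[j, ]))
  list(k = mean(d), var_k = if (length(d) > 1) var(d) else 0, pairs = d)
}

oracle_S <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  keep <- oracle_usable_columns(seqs)
  m <- m[, keep, drop = FALSE]
  sum(apply(m, 2, function(col) length(unique(col)) > 1))
}

oracle_tajima_d <- function(seqs) {
  n <- length(seqs)
  S <- oracle_S(seqs)
  if (n < 4 || S == 0) return(NA_real_)
  k <- oracle_k(seqs)$k
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Ewens K-distribution by expanding the rising factorial polynomial
# x(x+1)...(x+n-1): coefficient of x^j is |s(n, j)|.  Exact in doubles for
# the small n used in tests.
oracle_stirling_coefs <- function(n) {
  coefs <- c(0, 1)                       # polynomial x
  if (n > 1) for (m in 1:(n - 1)) {
    shifted <- c(0, coefs)               # x * p(x)
    coefs <- m * c(coefs, 0) + shifted   # (x + m) p(x)
  }
  coefs[-1]                              # drop x^0 term (zero); index j = x^j
}

oracle_fu_fs <- function(seqs) {
  n <- length(seqs)
  k <- oracle_k(seqs)$k
  if (k <= 0) return(NA_real_)
  H <- length(unique(seqs))
  cf <- oracle_stirling_coefs(n)
  theta <- k
  probs <- cf * theta^(seq_len(n)) / prod(theta + 0:(n - 1))
  sp <- sum(probs[H:n])
  log(sp / (1 - sp))
}

oracle_r2 <- function(seqs) {
  n <- length(seqs)
  S <- oracle_S(seqs)
  if (S == 0) return(NA_real_)
  k <- oracle_k(seqs)$k
  m <- do.call(rbind, strsplit(seqs, ""))
  m <- m[, oracle_usable_columns(seqs), drop = FALSE]
  U <- numeric(n)
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    if (length(tab) != 2) next
    if (min(tab) != 1) next
    minors <- names(tab)[tab == 1]
    carrier <- if (length(minors) == 2) max(minors) else minors
    U[m[, j] == carrier] <- U[m[, j] == carrier] + 1
  }
  sqrt(sum((U - k / 2)^2) / n) / S
}

# two-level AMOVA variance components by explicit summation
oracle_phi_st <- function(seqs_a, seqs_b) {
  seqs <- c(seqs_a, seqs_b)
  n1 <- length(seqs_a); n2 <- length(seqs_b); nt <- n1 + n2
  d <- matrix(0, nt, nt)
  for (i in 1:(nt - 1)) for (j in (i + 1):nt)
    d[i, j] <- d[j, i] <- oracle_pairdiff(seqs[i], seqs[j])
  if (all(d == 0)) return(list(phi = 0, s2a = 0, s2b = 0))
  ssd_tot <- 0
  for (i in 1:(nt - 1)) for (j in (i + 1):nt) ssd_tot <- ssd_tot + d[i, j]^2
  ssd_tot <- ssd_tot / nt
  ssd_w <- 0
  for (i in 1:(n1 - 1)) for (j in (i + 1):n1) ssd_w <- ssd_w + d[i, j]^2 / n1
  for (i in (n1 + 1):(nt - 1)) for (j in (i + 1):nt) ssd_w <- ssd_w + d[i, j]^2 / n2
  ssd_a <- ssd_tot - ssd_w
  s2b <- ssd_w / (nt - 2)
  nbar <- (nt - (n1^2 + n2^2) / nt)
  s2a <- (ssd_a - s2b) / nbar
  list(phi = s2a / (s2a + s2b), s2a = s2a, s2b = s2b)
}

# Chinese-restaurant-process simulation of the Ewens K distribution
oracle_crp_p_k_ge <- function(n, theta, kmin, reps = 20000) {
  ks <- replicate(reps, {
    k <- 1
    for (i in 2:n) if (runif(1) < theta / (theta + i - 1)) k <- k + 1
    k
  })
  mean(ks >= kmin)
}
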