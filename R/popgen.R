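# Descriptive diversity statistics, neutrality tests and pairwise AMOVA.
#
# Public functions accept either a character vector of aligned sequences
# or a data frame of panel records (with a `seq` column). Sites containing
# gaps or ambiguity codes in any sequence are excluded listwise.

as_seqs <- function(records) {
  if (is.data.frame(records)) records <- records$seq
  if (!is.character(records)) stop("records must be sequences or panel records")
  records
}

# pairwise Hamming difference matrix from an integer allele matrix
pair_diff_matrix <- function(am) {
  n <- nrow(am)
  if (ncol(am) == 0L) return(matrix(0, n, n))
  states <- sort(unique(as.vector(am)))
  eq <- matrix(0, n, n)
  for (s in states) {
    ind <- (am == s) * 1
    eq <- eq + tcrossprod(ind)
  }
  ncol(am) - eq
}

# core one-sample statistics from an integer allele matrix over usable sites
one_sample_core <- function(am, usable) {
  n <- nrow(am)
  poly <- which(apply(am, 2L, function(col) length(unique(col)) > 1L))
  S <- length(poly)
  key <- if (ncol(am)) do.call(paste, c(as.data.frame(am), sep = "\r")) else rep("", n)
  cnt <- as.integer(table(key))
  H <- length(cnt)
  h <- if (n > 1L) n / (n - 1) * (1 - sum((cnt / n)^2)) else NA_real_
  dm <- pair_diff_matrix(am[, poly, drop = FALSE])
  pd <- dm[upper.tri(dm)]
  k <- if (length(pd)) mean(pd) else 0
  var_k <- if (length(pd) > 1L) var(pd) else 0
  list(n = n, H = H, h = h, S = S, k = k, var_k = var_k,
       pi = if (usable > 0L) k / usable else NA_real_,
       poly = poly, pairdiff = dm)
}

encode_records <- function(records) {
  enc <- encode_alignment(as_seqs(records))
  enc
}

#' Within-population sequence diversity
#'
#' Haplotype count and diversity, segregating sites, mean (and variance of)
#' pairwise differences, and per-site nucleotide diversity. Haplotype
#' diversity uses Nei's small-sample correction
#' `h = n/(n-1) (1 - sum p_i^2)`; `pi = k / usable_sites`.
#'
#' @param records aligned sequences (character vector) or panel records.
#' @return List with `n`, `H`, `h`, `S`, `k`, `var_k`, `pi`, `usable`.
#' @export
#' @examples
#' diversity(c("AAT", "AAT", "AAT", "ACT", "ACT"))$h # counts {3, 2}
diversity <- function(records) {
  seqs <- as_seqs(records)
  if (length(seqs) < 2L) stop("need at least 2 sequences [sample-size error]")
  enc <- encode_records(seqs)
  st <- one_sample_core(enc$alleles, enc$usable)
  c(st[c("n", "H", "h", "S", "k", "var_k", "pi")], list(usable = enc$usable))
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

tajima_d_core <- function(n, S, k) {
  if (n < 4L || S < 1L) return(NA_real_)
  cs <- tajima_constants(n)
  v <- cs$e1 * S + cs$e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (k - S / cs$a1) / sqrt(v)
}

#' Tajima's D
#'
#' Scaled difference between the pairwise-difference and segregating-sites
#' estimators of theta. Undefined (NA) when `S = 0` or `n < 4` (the
#' variance constants degenerate at `n <= 3`).
#'
#' @inheritParams diversity
#' @return Numeric, or `NA` when undefined.
#' @export
tajima_d <- function(records) {
  enc <- encode_records(records)
  st <- one_sample_core(enc$alleles, enc$usable)
  tajima_d_core(st$n, st$S, st$k)
}

# log unsigned Stirling numbers of the first kind, row n (k = 1..n)
log_stirling1_row <- function(n) {
  lse <- function(a, b) {
    m <- pmax(a, b)
    ifelse(is.infinite(m), -Inf, m + log(exp(a - m) + exp(b - m)))
  }
  row <- c(0)                       # n = 1: |s(1,1)| = 1
  if (n == 1L) return(row)
  for (m in 1:(n - 1L)) {
    # |s(m+1, k)| = m * |s(m, k)| + |s(m, k-1)|
    row <- lse(c(-Inf, row), log(m) + c(row, -Inf))
  }
  row
}

fu_fs_core <- function(n, H, k) {
  if (k <= 0) return(NA_real_)
  ls <- log_stirling1_row(n)
  theta <- k
  lrf <- sum(log(theta + 0:(n - 1L)))   # log rising factorial theta^(n)
  logp <- ls + seq_len(n) * log(theta) - lrf
  sp <- sum(exp(logp[H:n]))
  sp <- min(max(sp, .Machine$double.xmin), 1 - 1e-16)
  log(sp / (1 - sp))
}

#' Fu's Fs
#'
#' The log-odds of sampling at least the observed number of distinct
#' haplotypes under the Ewens sampling formula at `theta = k` (mean
#' pairwise differences), computed exactly through unsigned Stirling
#' numbers of the first kind in log space. Undefined (NA) when `k = 0`.
#' Large negative values indicate an excess of haplotypes, as after
#' population expansion.
#'
#' @inheritParams diversity
#' @return Numeric, or `NA` when undefined.
#' @export
#' @examples
#' fu_fs(c("A", "G", "C")) # three distinct haplotypes at theta-hat = 1
fu_fs <- function(records) {
  enc <- encode_records(records)
  st <- one_sample_core(enc$alleles, enc$usable)
  fu_fs_core(st$n, st$H, st$k)
}

# singleton load per copy: for each biallelic usable site whose minor
# allele has count 1, the carrier of that allele gets +1 (at n = 2 both
# alleles are minor; the alphabetically/numerically larger state carries)
singletons_per_copy <- function(am) {
  n <- nrow(am)
  U <- integer(n)
  for (j in seq_len(ncol(am))) {
    tab <- table(am[, j])
    if (length(tab) != 2L) next
    minors <- names(tab)[tab == 1L]
    if (!length(minors)) next
    carrier_state <- if (length(minors) == 2L) max(as.integer(minors)) else as.integer(minors)
    U[am[, j] == carrier_state] <- U[am[, j] == carrier_state] + 1L
  }
  U
}

r2_core <- function(am, n, S, k) {
  if (S < 1L) return(NA_real_)
  U <- singletons_per_copy(am)
  sqrt(mean((U - k / 2)^2)) / S
}

#' Ramos-Onsins and Rozas' R2
#'
#' Contrasts the singleton load per sequence with half the mean pairwise
#' differences: `R2 = sqrt(mean((U_i - k/2)^2)) / S`. Low values indicate
#' recent population growth. Undefined (NA) when `S = 0`.
#'
#' @inheritParams diversity
#' @return Numeric, or `NA` when undefined.
#' @export
r2_stat <- function(records) {
  enc <- encode_records(records)
  st <- one_sample_core(enc$alleles, enc$usable)
  r2_core(enc$alleles[, st$poly, drop = FALSE], st$n, st$S, st$k)
}

# statistic on a 0/1 matrix from the conditional null simulator
null_stat <- function(X, statistic) {
  st <- one_sample_core(X, ncol(X))
  switch(statistic,
         D = tajima_d_core(st$n, st$S, st$k),
         Fs = fu_fs_core(st$n, st$H, st$k),
         r2 = r2_core(X[, st$poly, drop = FALSE], st$n, st$S, st$k))
}

#' Significance of a neutrality statistic by coalescent simulation
#'
#' The null distribution comes from neutral constant-size coalescent
#' simulations conditioned on the sample size and the observed number of
#' segregating sites (mutations placed on branches proportionally to
#' branch length). `Fs` and `r2` are one-tailed (small values
#' significant); `D` is two-tailed on `|D|`. The add-one correction
#' `p = (b + 1) / (n_sims + 1)` is applied.
#'
#' @inheritParams diversity
#' @param statistic one of `"D"`, `"Fs"`, `"r2"`.
#' @param n_sims number of coalescent simulations (default 10000).
#' @param seed optional integer seed.
#' @return List with `statistic`, `value`, `p_value`, `n_sims`.
#' @export
significance <- function(records, statistic = c("D", "Fs", "r2"),
                         n_sims = 10000L, seed = NULL) {
  statistic <- match.arg(statistic)
  if (n_sims < 1L) stop("n_sims must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  enc <- encode_records(records)
  st <- one_sample_core(enc$alleles, enc$usable)
  obs <- switch(statistic,
                D = tajima_d_core(st$n, st$S, st$k),
                Fs = fu_fs_core(st$n, st$H, st$k),
                r2 = r2_core(enc$alleles[, st$poly, drop = FALSE], st$n, st$S, st$k))
  if (is.na(obs)) stop("statistic undefined on this input")
  nulls <- vapply(seq_len(n_sims), function(i)
    null_stat(sim_conditional_cpp(st$n, st$S), statistic), 0)
  nulls <- nulls[!is.na(nulls)]
  b <- if (statistic == "D") sum(abs(nulls) >= abs(obs)) else sum(nulls <= obs)
  list(statistic = statistic, value = obs,
       p_value = (b + 1) / (length(nulls) + 1), n_sims = n_sims)
}

# Phi_ST point estimate from a squared-distance matrix and two index sets
phi_from_d2 <- function(d2, ia, ib) {
  n1 <- length(ia); n2 <- length(ib); nt <- n1 + n2
  ssd_tot <- sum(d2[c(ia, ib), c(ia, ib)]) / 2 / nt
  ssd_w <- sum(d2[ia, ia]) / 2 / n1 + sum(d2[ib, ib]) / 2 / n2
  ssd_a <- ssd_tot - ssd_w
  s2_b <- ssd_w / (nt - 2)
  nbar <- (nt - (n1^2 + n2^2) / nt) / 1
  s2_a <- (ssd_a / 1 - s2_b) / nbar
  denom <- s2_a + s2_b
  list(phi = if (denom > 0) s2_a / denom else 0,
       s2_a = s2_a, s2_b = s2_b)
}

#' Pairwise AMOVA Phi_ST between two populations
#'
#' Two-level analysis of molecular variance on the matrix of pairwise
#' sequence differences (Hamming counts on usable sites, optionally
#' Jukes-Cantor corrected). Significance by permuting population labels:
#' `p` is the add-one-corrected proportion of permutations with
#' `Phi_ST >= observed`. When every sequence is identical `Phi_ST` is
#' defined as 0 with `p = 1`.
#'
#' @param pop_a,pop_b aligned sequences (or panel records) for the two
#'   populations; both need `n >= 2`.
#' @param n_perms label permutations (default 10000).
#' @param seed optional integer seed.
#' @param distance `"hamming"` (default) or `"jc"` (Jukes-Cantor).
#' @return An object of class `amova_result`: list with `phi_st`,
#'   `sigma_among`, `sigma_within`, `p_value`, `n`.
#' @export
pairwise_phi_st <- function(pop_a, pop_b, n_perms = 10000L, seed = NULL,
                            distance = c("hamming", "jc")) {
  distance <- match.arg(distance)
  a <- as_seqs(pop_a); b <- as_seqs(pop_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("both populations need n >= 2 [sample-size error]")
  if (!is.null(seed)) set.seed(seed)
  enc <- encode_records(c(a, b))
  dm <- pair_diff_matrix(enc$alleles)
  if (distance == "jc" && enc$usable > 0L) {
    p <- pmin(dm / enc$usable, 0.749)
    dm <- -0.75 * enc$usable * log(1 - 4 / 3 * p)
  }
  d2 <- dm^2
  ia <- seq_along(a); ib <- length(a) + seq_along(b)
  if (all(dm == 0))
    return(structure(list(phi_st = 0, sigma_among = 0, sigma_within = 0,
                          p_value = 1, n = c(length(a), length(b))),
                     class = "amova_result"))
  obs <- phi_from_d2(d2, ia, ib)
  nt <- length(a) + length(b)
  perm <- vapply(seq_len(n_perms), function(i) {
    sh <- sample.int(nt)
    phi_from_d2(d2, sh[ia], sh[ib])$phi
  }, 0)
  structure(list(phi_st = obs$phi, sigma_among = obs$s2_a,
                 sigma_within = obs$s2_b,
                 p_value = (sum(perm >= obs$phi) + 1) / (n_perms + 1),
                 n = c(length(a), length(b))),
            class = "amova_result")
}

#' @exportS3Method base::print
print.amova_result <- function(x, ...) {
  cat(sprintf("Phi_ST = %.4f (p = %.4g; n = %d + %d)\n", x$phi_st,
              x$p_value, x$n[1], x$n[2]))
  invisible(x)
}

#' Per-population diversity and neutrality table for a panel
#'
#' Convenience driver mirroring the usual supplementary-table layout:
#' one row per population per locus with `n`, `H`, `h`, `pi`, `S`, `k`,
#' Tajima's D, Fu's Fs and R2 (p-values optional).
#'
#' @param panel a [seq_panel()].
#' @param n_sims simulations for p-values; 0 skips significance testing.
#' @param seed optional integer seed.
#' @return Data frame.
#' @export
diversity_table <- function(panel, n_sims = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (nm in names(panel$records)) {
    r <- panel$records[[nm]]
    for (p in unique(r$population)) {
      seqs <- r$seq[r$population == p]
      if (length(seqs) < 2L) next
      dv <- diversity(seqs)
      D <- tajima_d(seqs); Fs <- fu_fs(seqs); R2 <- r2_stat(seqs)
      row <- data.frame(locus = nm, population = p, n = dv$n, H = dv$H,
                        h = dv$h, pi = dv$pi, S = dv$S, k = dv$k,
                        tajima_D = D, fu_Fs = Fs, r2 = R2,
                        p_D = NA_real_, p_Fs = NA_real_, p_r2 = NA_real_,
                        stringsAsFactors = FALSE)
      if (n_sims > 0L) {
        if (!is.na(D)) row$p_D <- significance(seqs, "D", n_sims)$p_value
        if (!is.na(Fs)) row$p_Fs <- significance(seqs, "Fs", n_sims)$p_value
        if (!is.na(R2)) row$p_r2 <- significance(seqs, "r2", n_sims)$p_value
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Pairwise Phi_ST matrix for one locus
#'
#' @param panel a [seq_panel()].
#' @param locus locus name.
#' @param n_perms permutations per pair.
#' @param seed optional integer seed.
#' @return List with matrices `phi_st` and `p_value`.
#' @export
phi_st_matrix <- function(panel, locus, n_perms = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- panel$records[[locus]]
  pops <- unique(r$population)
  k <- length(pops)
  phi <- p <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    a <- r$seq[r$population == pops[i]]
    b <- r$seq[r$population == pops[j]]
    if (length(a) < 2L || length(b) < 2L) next
    res <- pairwise_phi_st(a, b, n_perms = n_perms)
    phi[i, j] <- phi[j, i] <- res$phi_st
    p[i, j] <- p[j, i] <- res$p_value
  }
  list(phi_st = phi, p_value = p)
}
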