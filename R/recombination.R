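# Intra-locus recombination detection (pairwise homoplasy index) and
# four-gamete site filtering.

# biallelic usable sites with original 1-based positions and 0/1 coding
biallelic_sites <- function(records) {
  enc <- encode_records(records)
  am <- enc$alleles
  nstate <- apply(am, 2L, function(col) length(unique(col)))
  bi <- which(nstate == 2L)
  multi <- enc$positions[nstate > 2L]
  X <- am[, bi, drop = FALSE]
  for (j in seq_len(ncol(X))) X[, j] <- as.integer(X[, j] == max(X[, j]))
  list(X = X, positions = enc$positions[bi], multistate = multi)
}

four_gamete_violations <- function(X, positions) {
  B <- ncol(X)
  out <- list()
  if (B >= 2L) {
    M11 <- crossprod(X)
    M10 <- crossprod(X, 1L - X)
    M00 <- crossprod(1L - X)
    for (i in seq_len(B - 1L)) for (j in (i + 1L):B) {
      if (M11[i, j] > 0 && M10[i, j] > 0 && M10[j, i] > 0 && M00[i, j] > 0)
        out[[length(out) + 1L]] <- c(positions[i], positions[j])
    }
  }
  if (!length(out))
    return(data.frame(site1 = integer(0), site2 = integer(0)))
  m <- do.call(rbind, out)
  data.frame(site1 = m[, 1L], site2 = m[, 2L])
}

#' Four-gamete test over all biallelic site pairs
#'
#' Two biallelic sites showing all four allele combinations (gametes)
#' imply recombination or recurrent mutation. Sites with more than two
#' states are excluded from pairing and reported in the `multistate_sites`
#' attribute. Positions are 1-based alignment coordinates.
#'
#' @param records aligned sequences (>= 2) or panel records.
#' @return Data frame of violating pairs (`site1`, `site2`), with
#'   attribute `multistate_sites`.
#' @export
#' @examples
#' four_gamete_pairs(c("AA", "AG", "GA", "GG")) # one violating pair
four_gamete_pairs <- function(records) {
  seqs <- as_seqs(records)
  if (length(seqs) < 2L) stop("need an alignment of >= 2 sequences")
  bs <- biallelic_sites(seqs)
  v <- four_gamete_violations(bs$X, bs$positions)
  attr(v, "multistate_sites") <- bs$multistate
  v
}

#' Excise putative recombinant sites until the four-gamete test passes
#'
#' Greedy filter: repeatedly remove the site participating in the most
#' remaining violating pairs (leftmost on ties) and recompute, until no
#' pair of biallelic sites shows all four gametes. Conservative and
#' deterministic; alignments already free of violations pass through
#' unchanged.
#'
#' @inheritParams four_gamete_pairs
#' @return An object of class `filter_report`: list with
#'   `removed_site_positions` (1-based), `retained` (sequences with those
#'   columns excised), `violating_pairs_before`, `violating_pairs_after`.
#' @export
filter_recombinant_sites <- function(records) {
  seqs <- as_seqs(records)
  bs <- biallelic_sites(seqs)
  X <- bs$X; pos <- bs$positions
  before <- nrow(four_gamete_violations(X, pos))
  removed <- integer(0)
  repeat {
    v <- four_gamete_violations(X, pos)
    if (!nrow(v)) break
    tab <- table(factor(c(v$site1, v$site2), levels = pos))
    worst <- pos[which.max(tab)]   # which.max takes the leftmost on ties
    removed <- c(removed, worst)
    keep <- pos != worst
    X <- X[, keep, drop = FALSE]
    pos <- pos[keep]
  }
  L <- nchar(seqs[1L])
  keep_cols <- setdiff(seq_len(L), removed)
  retained <- vapply(strsplit(seqs, "", fixed = TRUE),
                     function(s) paste(s[keep_cols], collapse = ""), "")
  structure(list(removed_site_positions = removed, retained = retained,
                 violating_pairs_before = before, violating_pairs_after = 0L),
            class = "filter_report")
}

#' @exportS3Method base::print
print.filter_report <- function(x, ...) {
  cat("four-gamete filter:", x$violating_pairs_before, "violating pairs,",
      length(x$removed_site_positions), "sites removed\n")
  if (length(x$removed_site_positions))
    cat("  positions:", paste(x$removed_site_positions, collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise homoplasy index (PHI) test for recombination
#'
#' The incompatibility score of a pair of biallelic parsimony-informative
#' sites is 1 if all four gametes occur and 0 otherwise (a binary
#' simplification of the refined incompatibility score, adequate for
#' predominantly biallelic data). `phi_w` is the mean score over all
#' informative-site pairs lying within `window_w` alignment positions of
#' each other. Under recombination, incompatibility grows with distance,
#' so nearby pairs are more compatible than expected: significance is the
#' add-one-corrected proportion of site-order permutations with a
#' permuted `phi_w` at or below the observed one.
#'
#' @inheritParams four_gamete_pairs
#' @param window_w window width in alignment base pairs (default 100).
#' @param n_perms number of site-order permutations (default 1000).
#' @param seed optional integer seed.
#' @return An object of class `phi_test_result`: list with `phi_w`,
#'   `p_value`, `n_informative_sites`, `window_w`, `applicable`.
#' @export
phi_test <- function(records, window_w = 100L, n_perms = 1000L, seed = NULL) {
  seqs <- as_seqs(records)
  if (length(seqs) < 4L) stop("PHI test needs >= 4 sequences")
  if (!is.null(seed)) set.seed(seed)
  bs <- biallelic_sites(seqs)
  counts <- colSums(bs$X)
  n <- nrow(bs$X)
  inf <- which(counts >= 2L & counts <= n - 2L)  # parsimony-informative
  if (length(inf) < 2L)
    return(structure(list(phi_w = NA_real_, p_value = NA_real_,
                          n_informative_sites = length(inf),
                          window_w = window_w, applicable = FALSE),
                     class = "phi_test_result"))
  X <- bs$X[, inf, drop = FALSE]
  pos <- bs$positions[inf]
  B <- length(inf)
  incomp <- matrix(0L, B, B)
  M11 <- crossprod(X); M10 <- crossprod(X, 1L - X); M00 <- crossprod(1L - X)
  for (i in seq_len(B - 1L)) for (j in (i + 1L):B)
    if (M11[i, j] > 0 && M10[i, j] > 0 && M10[j, i] > 0 && M00[i, j] > 0)
      incomp[i, j] <- incomp[j, i] <- 1L
  phi_for_order <- function(ord) {
    # ord[b] = which site column sits at physical position pos[b]
    near <- abs(outer(pos, pos, "-")) <= window_w
    diag(near) <- FALSE
    sel <- incomp[ord, ord][near]
    if (!length(sel)) NA_real_ else mean(sel)
  }
  obs <- phi_for_order(seq_len(B))
  perm <- vapply(seq_len(n_perms), function(i) phi_for_order(sample.int(B)), 0)
  b <- sum(perm <= obs, na.rm = TRUE)
  structure(list(phi_w = obs, p_value = (b + 1) / (n_perms + 1),
                 n_informative_sites = B, window_w = window_w,
                 applicable = TRUE),
            class = "phi_test_result")
}

#' @exportS3Method base::print
print.phi_test_result <- function(x, ...) {
  if (!x$applicable)
    cat("PHI test not applicable (<2 informative sites)\n")
  else
    cat(sprintf("PHI test: phi_w = %.4f, p = %.4g (%d informative sites, w = %d)\n",
                x$phi_w, x$p_value, x$n_informative_sites, x$window_w))
  invisible(x)
}
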