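# The ABC engine: summary statistics, reference tables, rejection,
# polychotomous logistic-regression scenario choice, local-linear
# parameter estimation and demographic unit scaling.

# ---- summary statistics --------------------------------------------------

# per-locus statistic block from an integer allele matrix and a population
# factor: one-sample {H, S, k, var_k, D} per population and two-sample
# {pooled S, between-population mean pairwise differences, Phi_ST} per pair.
locus_stat_block <- function(am, pop) {
  pops <- levels(pop)
  P <- length(pops)
  poly_of <- function(idx) {
    sub <- am[idx, , drop = FALSE]
    if (!ncol(sub)) return(0L)
    sum(colSums(sub != rep(sub[1L, ], each = nrow(sub))) > 0L)
  }
  dm <- pair_diff_matrix(am)
  d2 <- dm^2
  one <- matrix(NA_real_, P, 5L, dimnames = list(pops, c("H", "S", "k", "var_k", "D")))
  idx_by_pop <- split(seq_len(nrow(am)), pop)
  key_all <- if (ncol(am))
    do.call(paste, c(as.data.frame(am), sep = "\r")) else rep("", nrow(am))
  for (p in pops) {
    idx <- idx_by_pop[[p]]
    H <- length(unique(key_all[idx]))
    S <- poly_of(idx)
    sdm <- dm[idx, idx, drop = FALSE]
    pd <- sdm[upper.tri(sdm)]
    k <- if (length(pd)) mean(pd) else 0
    vk <- if (length(pd) > 1L) var(pd) else 0
    one[p, ] <- c(H, S, k, vk, tajima_d_core(length(idx), S, k))
  }
  prs <- utils::combn(pops, 2L)
  two <- matrix(NA_real_, ncol(prs), 3L,
                dimnames = list(paste(prs[1L, ], prs[2L, ], sep = "_"),
                                c("pooledS", "betweenK", "phiST")))
  for (q in seq_len(ncol(prs))) {
    ia <- idx_by_pop[[prs[1L, q]]]; ib <- idx_by_pop[[prs[2L, q]]]
    S2 <- poly_of(c(ia, ib))
    bk <- mean(dm[ia, ib])
    phi <- if (all(dm[c(ia, ib), c(ia, ib)] == 0)) 0 else phi_from_d2(d2, ia, ib)$phi
    two[q, ] <- c(S2, bk, phi)
  }
  list(one = one, two = two)
}

flatten_blocks <- function(blocks, group) {
  one <- blocks$one; two <- blocks$two
  v1 <- as.vector(t(one))
  n1 <- as.vector(t(outer(rownames(one), colnames(one), paste, sep = ".")))
  v2 <- as.vector(t(two))
  n2 <- as.vector(t(outer(rownames(two), colnames(two), paste, sep = ".")))
  setNames(c(v1, v2), paste(group, c(n1, n2), sep = "."))
}

#' DIYABC-style summary-statistic vector for a panel
#'
#' Statistics are computed per locus group - the mtDNA locus on its own,
#' nuclear loci averaged - to respect inheritance differences. One-sample
#' statistics per population: haplotype count `H`, segregating sites `S`,
#' mean pairwise differences `k`, their variance `var_k`, and Tajima's
#' `D`. Two-sample statistics per population pair: pooled `S`,
#' between-population mean pairwise differences, and `Phi_ST` (labeled
#' `phiST`). Statistics that are undefined on a realization (e.g. `D`
#' with `S = 0`) are encoded as 0, identically for observed and simulated
#' data; the `undefined` attribute marks them.
#'
#' @param panel a [seq_panel()] whose loci include exactly one
#'   single-copy (mtDNA) locus group and at least one nuclear locus.
#' @return Named numeric vector with attribute `undefined` (logical).
#' @export
summary_vector <- function(panel) {
  groups <- list(mt = character(0), nuc = character(0))
  for (nm in names(panel$loci)) {
    g <- if (panel$loci[[nm]]$copies_per_individual == 1L) "mt" else "nuc"
    groups[[g]] <- c(groups[[g]], nm)
  }
  out <- NULL
  for (g in names(groups)) {
    if (!length(groups[[g]])) next
    per_locus <- lapply(groups[[g]], function(nm) {
      r <- panel$records[[nm]]
      enc <- encode_alignment(r$seq)
      pop <- factor(r$population, levels = unique(r$population))
      flatten_blocks(locus_stat_block(enc$alleles, pop), g)
    })
    avg <- Reduce(`+`, lapply(per_locus, function(v) ifelse(is.na(v), 0, v))) /
      length(per_locus)
    out <- c(out, avg)
  }
  und <- is.na(out)
  out[is.na(out)] <- 0
  attr(out, "undefined") <- und
  out
}

# fast path: summary vector straight from simulated site matrices
summary_vector_sim <- function(sims, loci) {
  out <- NULL
  groups <- list(mt = character(0), nuc = character(0))
  for (nm in names(loci)) {
    g <- if (loci[[nm]]$copies_per_individual == 1L) "mt" else "nuc"
    groups[[g]] <- c(groups[[g]], nm)
  }
  for (g in names(groups)) {
    if (!length(groups[[g]])) next
    per_locus <- lapply(groups[[g]], function(nm)
      flatten_blocks(locus_stat_block(sims[[nm]]$haps, sims[[nm]]$pop), g))
    avg <- Reduce(`+`, lapply(per_locus, function(v) ifelse(is.na(v), 0, v))) /
      length(per_locus)
    out <- c(out, avg)
  }
  out[is.na(out)] <- 0
  out
}

# ---- reference tables ----------------------------------------------------

#' Build an ABC reference table
#'
#' For each scenario, `n_per_scenario` rows of (parameter draw ->
#' simulated panel -> summary vector). Per-row seeds derive from
#' `master_seed` via [derive_seed()] (row index runs over scenarios then
#' replicates), so any row can be regenerated alone. Per-statistic MAD
#' normalizers are computed over the full table; a constant column's MAD
#' is replaced by 1 with a warning.
#'
#' @param scenarios named list of [scenario_spec()].
#' @param loci named list of [locus_spec()].
#' @param design a [sampling_design()].
#' @param n_per_scenario simulations per scenario (>= 100 for inference;
#'   smaller values are accepted for toy runs with a message).
#' @param master_seed integer master seed.
#' @param progress print a line every 1000 rows.
#' @return An object of class `ref_table`: list with `scenario` (factor),
#'   `params` (matrix, NA where a parameter is absent from a scenario),
#'   `stats` (matrix), `mads`, `scenarios`, `loci`, `design`,
#'   `master_seed`.
#' @export
build_reference_table <- function(scenarios, loci, design, n_per_scenario,
                                  master_seed, progress = FALSE) {
  stopifnot(length(scenarios) >= 1L, n_per_scenario >= 1L)
  par_names <- unique(unlist(lapply(scenarios, function(s) names(s$priors))))
  n_tot <- n_per_scenario * length(scenarios)
  params <- matrix(NA_real_, n_tot, length(par_names),
                   dimnames = list(NULL, par_names))
  stats <- NULL
  labels <- character(n_tot)
  row <- 0L
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    for (i in seq_len(n_per_scenario)) {
      row <- row + 1L
      set.seed(derive_seed(master_seed, row))
      for (try in 1:5) {
        ok <- TRUE
        draw <- draw_parameters(sc)
        sims <- tryCatch(
          lapply(loci, function(lc) sim_locus_matrix(sc, draw, lc, design)),
          error = function(e) { ok <<- FALSE; NULL })
        if (ok) break
      }
      if (!ok) stop("simulation failed repeatedly for scenario ", sc$id)
      sv <- summary_vector_sim(sims, loci)
      if (is.null(stats))
        stats <- matrix(NA_real_, n_tot, length(sv),
                        dimnames = list(NULL, names(sv)))
      stats[row, ] <- sv
      params[row, names(draw$values)] <- draw$values
      labels[row] <- sc$id
      if (progress && row %% 1000L == 0L)
        message("reference table: ", row, "/", n_tot)
    }
  }
  mads <- apply(stats, 2L, mad)
  if (any(mads == 0)) {
    warning(sum(mads == 0), " constant statistic column(s); MAD normalizer set to 1")
    mads[mads == 0] <- 1
  }
  scaled <- sweep(stats, 2L, mads, "/")
  structure(list(scenario = factor(labels, levels = names(scenarios)),
                 params = params, stats = stats, mads = mads,
                 scaled = scaled, rs2 = rowSums(scaled^2),
                 scenarios = scenarios, loci = loci, design = design,
                 master_seed = master_seed),
            class = "ref_table")
}

#' @exportS3Method base::print
print.ref_table <- function(x, ...) {
  cat("<ref_table>", nrow(x$stats), "rows,", ncol(x$stats), "statistics,",
      nlevels(x$scenario), "scenarios\n")
  invisible(x)
}

#' Rejection step: retain the closest simulations
#'
#' Euclidean distance on MAD-normalized summary statistics; the
#' `n_retain` smallest distances are kept, ties at the cutoff broken by
#' row index.
#'
#' @param table a [build_reference_table()] result.
#' @param observed a [summary_vector()] (same schema as the table).
#' @param n_retain rows to keep.
#' @return An object of class `abc_rejection`: list with `idx`, `dist`,
#'   `scenario`, `z` (normalized deviations stats - observed of retained
#'   rows), `params`, `observed`, `table_size`.
#' @export
abc_reject <- function(table, observed, n_retain) {
  if (!identical(colnames(table$stats), names(observed)))
    stop("summary-statistic schema mismatch [schema error]")
  if (n_retain > nrow(table$stats)) stop("n_retain exceeds table size")
  scaled <- table$scaled
  if (is.null(scaled)) scaled <- sweep(table$stats, 2L, table$mads, "/")
  rs2 <- table$rs2
  if (is.null(rs2)) rs2 <- rowSums(scaled^2)
  obs_s <- as.numeric(observed) / table$mads
  d2 <- rs2 - 2 * drop(scaled %*% obs_s) + sum(obs_s^2)
  ord <- order(d2, seq_along(d2))
  idx <- ord[seq_len(n_retain)]
  z <- sweep(scaled[idx, , drop = FALSE], 2L, obs_s)
  structure(list(idx = idx, dist = sqrt(rowSums(z^2)),
                 scenario = table$scenario[idx], z = z,
                 params = table$params[idx, , drop = FALSE],
                 observed = observed, table_size = nrow(table$stats)),
            class = "abc_rejection")
}

# ---- scenario choice -----------------------------------------------------

fit_multinom_probs <- function(z, y, w, penalty) {
  fit <- glmnet::glmnet(z, y, family = "multinomial", alpha = 0,
                        lambda = c(1, 0.1, penalty), weights = w,
                        standardize = FALSE)
  p <- drop(predict(fit, matrix(0, 1L, ncol(z)), s = penalty,
                    type = "response"))
  list(probs = p, fit = fit)
}

# Epanechnikov kernel weights on rejection distances (bandwidth = largest
# retained distance); all-equal distances degrade to uniform weights
epa_weights <- function(d) {
  h <- max(d)
  if (h <= 0) return(rep(1, length(d)))
  w <- 1 - (d / h)^2
  if (all(w <= 0)) return(rep(1, length(d)))
  w[w <= 0] <- min(w[w > 0]) / 2
  w
}

#' Scenario choice by polychotomous logistic regression
#'
#' Weighted multinomial logistic regression of the scenario label on the
#' MAD-normalized deviations of each retained row's statistics from the
#' observed vector, with Epanechnikov kernel weights on the rejection
#' distances (bandwidth = the largest retained distance); the fitted
#' class probabilities evaluated at the observed point (the zero vector)
#' are the posterior scenario probabilities. A small fixed ridge penalty
#' (`penalty`) keeps the fit defined on near-separable retained sets, which
#' are the rule when hundreds of rows meet hundreds of statistics; the
#' `regularized` field records it. Confidence intervals come from a
#' nonparametric bootstrap of the retained rows.
#'
#' @param rej an [abc_reject()] result.
#' @param n_boot bootstrap refits for 95% CIs (0 skips CIs).
#' @param seed optional integer seed.
#' @param penalty ridge penalty for the multinomial fit.
#' @return An object of class `model_choice_result`: list with
#'   `posterior` (named probabilities), `ci` (2 x K matrix or NULL),
#'   `selected`, `n_retained`, `regularized`.
#' @export
model_choice <- function(rej, n_boot = 200L, seed = NULL, penalty = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  y <- droplevels(rej$scenario)
  all_lv <- levels(rej$scenario)
  if (nlevels(y) < 2L) {
    if (length(all_lv) > 1L)
      warning("only one scenario among retained rows; its probability is 1")
    post <- setNames(as.numeric(all_lv == levels(y)), all_lv)
    return(structure(list(posterior = post, ci = NULL,
                          selected = levels(y), n_retained = length(y),
                          regularized = FALSE),
                     class = "model_choice_result"))
  }
  if (length(setdiff(all_lv, levels(y))))
    warning("scenario(s) absent from retained set get probability 0: ",
            paste(setdiff(all_lv, levels(y)), collapse = ", "))
  z <- rej$z
  keep <- apply(z, 2L, function(col) var(col) > 0)
  z <- z[, keep, drop = FALSE]
  w <- epa_weights(rej$dist)
  res <- fit_multinom_probs(z, y, w, penalty = penalty)
  probs <- setNames(rep(0, length(all_lv)), all_lv)
  probs[names(res$probs)] <- res$probs
  ci <- NULL
  if (n_boot > 0L) {
    bp <- matrix(NA_real_, n_boot, length(all_lv),
                 dimnames = list(NULL, all_lv))
    for (b in seq_len(n_boot)) {
      ii <- sample.int(length(y), replace = TRUE)
      yb <- droplevels(y[ii])
      if (nlevels(yb) < 2L) {
        bp[b, ] <- as.numeric(all_lv %in% levels(yb))
        next
      }
      rb <- tryCatch(
        fit_multinom_probs(z[ii, , drop = FALSE], yb, w[ii], penalty = penalty),
        error = function(e) NULL)
      if (is.null(rb)) next
      row <- setNames(rep(0, length(all_lv)), all_lv)
      row[names(rb$probs)] <- rb$probs
      bp[b, ] <- row
    }
    ci <- apply(bp, 2L, quantile, c(0.025, 0.975), na.rm = TRUE)
  }
  structure(list(posterior = probs / sum(probs), ci = ci,
                 selected = names(probs)[which.max(probs)],
                 n_retained = length(y), regularized = penalty > 0),
            class = "model_choice_result")
}

#' @exportS3Method base::print
print.model_choice_result <- function(x, ...) {
  cat("scenario posterior probabilities (", x$n_retained, "retained ):\n")
  for (nm in names(x$posterior)) {
    cat(sprintf("  %-12s %.3f", nm, x$posterior[nm]))
    if (!is.null(x$ci)) cat(sprintf("  [%.3f, %.3f]", x$ci[1, nm], x$ci[2, nm]))
    cat(if (nm == x$selected) "  <- selected\n" else "\n")
  }
  invisible(x)
}

# ---- pods and error rates ------------------------------------------------

#' Run pseudo-observed datasets through scenario choice
#'
#' Simulates `n_pods` datasets under `scenario` (parameters fixed, drawn
#' from the prior, or sampled from supplied rows), runs each through
#' rejection and [model_choice()] against `table`, and returns the
#' selected scenario per pod.
#'
#' @param table a [build_reference_table()] result.
#' @param scenario a [scenario_spec()] (must be one of the table's).
#' @param n_pods number of pseudo-observed datasets.
#' @param pod_params `NULL` for prior draws, a named numeric vector for
#'   fixed parameters, or a matrix of parameter rows to sample from.
#' @param n_retain rows retained per pod (default 500).
#' @param seed integer seed.
#' @return Data frame with one row per pod: `true`, `selected`, and the
#'   posterior probability of each scenario.
#' @export
run_pods <- function(table, scenario, n_pods, pod_params = NULL,
                     n_retain = 500L, seed = 1L) {
  lv <- levels(table$scenario)
  out <- data.frame(true = rep(scenario$id, n_pods),
                    selected = character(n_pods), stringsAsFactors = FALSE)
  pp <- matrix(NA_real_, n_pods, length(lv), dimnames = list(NULL, lv))
  for (i in seq_len(n_pods)) {
    set.seed(derive_seed(seed, i))
    draw <- if (is.null(pod_params)) draw_parameters(scenario)
    else if (is.matrix(pod_params))
      fixed_parameters(scenario, pod_params[sample.int(nrow(pod_params), 1L), ])
    else fixed_parameters(scenario, pod_params)
    sims <- lapply(table$loci, function(lc)
      sim_locus_matrix(scenario, draw, lc, table$design))
    sv <- setNames(summary_vector_sim(sims, table$loci), colnames(table$stats))
    mc <- model_choice(abc_reject(table, sv, n_retain), n_boot = 0L)
    out$selected[i] <- mc$selected
    pp[i, ] <- mc$posterior[lv]
  }
  cbind(out, as.data.frame(pp))
}

#' Type I / type II error rates for a focal scenario
#'
#' Definitions: the false-positive rate of a focal scenario is the
#' proportion of pods simulated under an alternative scenario for which
#' the focal scenario is nevertheless chosen; the false-negative rate is
#' the proportion of pods simulated under the focal scenario for which an
#' alternative is chosen.
#'
#' @param table a [build_reference_table()] result.
#' @param focal focal scenario id.
#' @param n_pods pods per scenario (default 500).
#' @param pod_params optional named list: per-scenario `pod_params`
#'   passed to [run_pods()] (defaults to prior draws).
#' @param n_retain rows retained per pod.
#' @param seed integer seed.
#' @param pods optional precomputed list of [run_pods()] results (one per
#'   scenario) to reuse across focal scenarios.
#' @return An object of class `error_rates`: list with
#'   `false_positive_rate`, `false_negative_rate`, `n_pods`, `pod_source`,
#'   `pods`.
#' @export
error_rates <- function(table, focal, n_pods = 500L, pod_params = list(),
                        n_retain = 500L, seed = 1L, pods = NULL) {
  lv <- levels(table$scenario)
  if (!focal %in% lv) stop("unknown focal scenario: ", focal)
  if (is.null(pods)) {
    pods <- lapply(seq_along(lv), function(si)
      run_pods(table, table$scenarios[[lv[si]]], n_pods,
               pod_params = pod_params[[lv[si]]], n_retain = n_retain,
               seed = derive_seed(seed, si)))
    names(pods) <- lv
  }
  sel_focal <- pods[[focal]]$selected
  fn <- mean(sel_focal != focal)
  alt <- unlist(lapply(setdiff(lv, focal), function(s) pods[[s]]$selected))
  fp <- mean(alt == focal)
  structure(list(false_positive_rate = fp, false_negative_rate = fn,
                 n_pods = n_pods,
                 pod_source = if (length(pod_params)) "supplied" else "prior",
                 pods = pods),
            class = "error_rates")
}

#' @exportS3Method base::print
print.error_rates <- function(x, ...) {
  cat(sprintf("false-positive rate: %.3f, false-negative rate: %.3f (%d pods/scenario)\n",
              x$false_positive_rate, x$false_negative_rate, x$n_pods))
  invisible(x)
}

# ---- parameter estimation ------------------------------------------------

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1L]], 0)
}

#' Local-linear ABC parameter estimation with logit transform
#'
#' Rows of the selected scenario are ranked by normalized distance to the
#' observed statistics; the closest `retain_fraction` are kept and
#' weighted with an Epanechnikov kernel (bandwidth = the largest retained
#' distance). Parameters are mapped to the real line by a logit transform
#' onto their prior bounds (clamped `1e-8` of the range off each bound),
#' adjusted by a weighted local-linear regression on the statistic
#' deviations (`phi* = phi - (s - s_obs)' beta`), and back-transformed.
#' The posterior mode is the peak of a Gaussian kernel density (Silverman
#' bandwidth); the 95% credible interval the 0.025/0.975 weighted
#' quantiles. A singular regression falls back to the unadjusted
#' rejection sample, flagged.
#'
#' @param table a [build_reference_table()] result.
#' @param observed a [summary_vector()].
#' @param scenario scenario id whose rows are used.
#' @param retain_fraction fraction of the scenario's rows kept (default
#'   0.01, floored at 20 rows).
#' @return An object of class `param_posterior`: per parameter a list
#'   with `sample`, `weights`, `mode`, `ci`; plus `adjusted` flag.
#' @export
estimate_parameters <- function(table, observed, scenario,
                                retain_fraction = 0.01) {
  rows <- which(table$scenario == scenario)
  if (!length(rows)) stop("no rows for scenario ", scenario)
  sc <- table$scenarios[[scenario]]
  z <- sweep(sweep(table$stats[rows, , drop = FALSE], 2L, as.numeric(observed)),
             2L, table$mads, "/")
  d <- sqrt(rowSums(z^2))
  n_keep <- max(20L, ceiling(retain_fraction * length(rows)))
  keep <- order(d, seq_along(d))[seq_len(min(n_keep, length(rows)))]
  zk <- z[keep, , drop = FALSE]
  dk <- d[keep]
  h <- max(dk)
  w <- if (h > 0) 0.75 * (1 - (dk / h)^2) else rep(1, length(dk))
  if (all(w == 0)) w <- rep(1, length(dk))
  par_names <- names(sc$priors)
  raw <- table$params[rows[keep], par_names, drop = FALSE]
  eps <- 1e-8
  lo <- vapply(sc$priors, `[[`, 0, "lower")
  hi <- vapply(sc$priors, `[[`, 0, "upper")
  cl <- sweep(sweep(raw, 2L, lo + eps * (hi - lo), pmax), 2L,
              hi - eps * (hi - lo), pmin)
  phi <- log(sweep(cl, 2L, lo) / sweep(-cl, 2L, hi, "+"))
  zv <- zk[, apply(zk, 2L, function(col) var(col) > 0), drop = FALSE]
  adjusted <- TRUE
  singular <- nrow(zv) <= ncol(zv) + 1L
  if (singular) adjusted <- FALSE
  phi_adj <- if (ncol(zv) == 0L || singular) phi else tryCatch({
    # Weighted local-linear adjustment, ridge-stabilized with the penalty
    # chosen by cross-validation (one-SE rule), so a barely informative
    # design shrinks the adjustment toward zero instead of inventing
    # precision. A singular design (fewer retained rows than statistics)
    # falls back to the unadjusted rejection sample, flagged via
    # `adjusted = FALSE`.
    sw <- sqrt(w / sum(w))
    mz <- colSums(zv * sw^2) / sum(sw^2)
    mp <- colSums(phi * sw^2) / sum(sw^2)
    Zc <- sweep(zv, 2L, mz) * sw
    Pc <- sweep(phi, 2L, mp) * sw
    n_r <- nrow(Zc)
    lams <- 10^seq(-2, 8, by = 0.5) * mean(colSums(Zc^2))
    folds <- rep_len(seq_len(5L), n_r)  # interleaved over distance ranks
    cvf <- matrix(0, length(lams), 5L)
    for (f in 1:5) {
      tr <- folds != f
      sv_f <- svd(Zc[tr, , drop = FALSE])
      uy <- crossprod(sv_f$u, Pc[tr, , drop = FALSE])
      for (j in seq_along(lams)) {
        beta <- sv_f$v %*% (uy * sv_f$d / (sv_f$d^2 + lams[j]))
        pred <- Zc[!tr, , drop = FALSE] %*% beta
        cvf[j, f] <- sum((Pc[!tr, , drop = FALSE] - pred)^2)
      }
    }
    cv <- rowSums(cvf)
    # one-SE rule: the largest (most conservative) penalty whose CV error
    # is within one fold-SE of the minimum
    se <- apply(cvf, 1L, sd) * sqrt(5)
    jmin <- which.min(cv)
    l <- lams[max(which(cv <= cv[jmin] + se[jmin]))]
    sv_a <- svd(Zc)
    beta <- sv_a$v %*% (crossprod(sv_a$u, Pc) * sv_a$d / (sv_a$d^2 + l))
    phi - sweep(zv, 2L, mz) %*% beta
  }, error = function(e) { adjusted <<- FALSE; phi })
  back <- sweep(sweep(1 / (1 + exp(-phi_adj)), 2L, hi - lo, "*"), 2L, lo, "+")
  post <- lapply(par_names, function(p) {
    x <- back[, p]
    dens <- suppressWarnings(
      density(x, weights = w / sum(w), bw = stats::bw.nrd0(x)))
    list(sample = x, weights = w, mode = dens$x[which.max(dens$y)],
         ci = weighted_quantile(x, w, c(0.025, 0.975)))
  })
  names(post) <- par_names
  structure(c(post, list(adjusted = adjusted, scenario = scenario)),
            class = "param_posterior")
}

#' @exportS3Method base::print
print.param_posterior <- function(x, ...) {
  pn <- setdiff(names(x), c("adjusted", "scenario"))
  cat("posterior for", x$scenario,
      if (!x$adjusted) "(unadjusted rejection sample)" else "", "\n")
  for (p in pn)
    cat(sprintf("  %-8s mode %12.4g  95%% CI [%12.4g, %12.4g]\n", p,
                x[[p]]$mode, x[[p]]$ci[1], x[[p]]$ci[2]))
  invisible(x)
}

# ---- unit scaling --------------------------------------------------------

#' Demographic unit-scaling configuration
#'
#' Converts mutation-scaled quantities into individuals and years using a
#' sequence divergence rate (default 1% per million years, i.e. a
#' per-lineage per-site rate of 5e-9/year) and a generation time.
#'
#' @param divergence_rate_per_Myr pairwise sequence divergence per
#'   million years (default 0.01).
#' @param generation_time_years generation time in years (default 1).
#' @return An object of class `scaling_config` with derived
#'   `mu_site_year` (= divergence rate / 2, per year).
#' @export
scaling_config <- function(divergence_rate_per_Myr = 0.01,
                           generation_time_years = 1) {
  if (divergence_rate_per_Myr <= 0 || generation_time_years <= 0)
    stop("rates and generation time must be positive")
  structure(list(divergence_rate_per_Myr = divergence_rate_per_Myr,
                 generation_time_years = generation_time_years,
                 mu_site_year = divergence_rate_per_Myr / 2 / 1e6),
            class = "scaling_config")
}

#' Convert mutation- or generation-scaled estimates to demographic units
#'
#' @param value positive numeric quantity.
#' @param kind `"theta_to_N"` (`N = theta / (4 u inheritance)` with `u`
#'   the per-generation locus rate), `"generations_to_years"`
#'   (multiply by generation time), or `"t_mut_to_years"` (divide a
#'   mutation-scaled time by the per-year locus rate).
#' @param locus a [locus_spec()].
#' @param cfg a [scaling_config()].
#' @return Numeric in demographic units.
#' @export
#' @examples
#' scale_units(20000, "generations_to_years", default_loci()$CYTB,
#'             scaling_config())
scale_units <- function(value, kind = c("theta_to_N", "generations_to_years",
                                        "t_mut_to_years"),
                        locus, cfg = scaling_config()) {
  kind <- match.arg(kind)
  if (any(value < 0)) stop("values must be positive")
  g <- cfg$generation_time_years
  switch(kind,
         theta_to_N = {
           u <- mu_locus(locus)
           if (u <= 0) stop("zero mutation rate")
           value / (4 * u * locus$inheritance_scalar)
         },
         generations_to_years = value * g,
         t_mut_to_years = {
           u_year <- cfg$mu_site_year * locus$length_bp
           if (u_year <= 0) stop("zero mutation rate")
           value / u_year
         })
}
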