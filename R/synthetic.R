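#' Uniform prior on a demographic parameter
#'
#' @param lower,upper bounds (individuals for sizes, generations for
#'   times); `0 <= lower < upper`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(lower, upper) {
  if (!is.numeric(lower) || !is.numeric(upper) || lower < 0 || lower >= upper)
    stop("need 0 <= lower < upper")
  structure(list(kind = "uniform", lower = lower, upper = upper),
            class = "prior_spec")
}

#' Define a population-divergence scenario
#'
#' A scenario is a rooted tree over sampled populations, expressed as a
#' list of merge events going backward in time: at time `time_param`, every
#' lineage of `src` joins the `dst` lineage group, which keeps its own
#' effective size. Each population lineage has one size parameter
#' (`N_<pop>`); the destination of a merge retains its size after the
#' merge, so a scenario over P populations has P size parameters and P-1
#' time parameters. `constraints` lists pairs `(a, b)` meaning parameter
#' `a` must be drawn smaller than `b` (child merges precede parent merges
#' backward in time).
#'
#' @param id scenario label.
#' @param populations ordered character vector of sampled populations.
#' @param events data frame with columns `time_param`, `src`, `dst`.
#' @param priors named list of [prior_spec()], one per parameter.
#' @param constraints list of length-2 character vectors `c(earlier, later)`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(id, populations, events, priors, constraints = list()) {
  stopifnot(is.data.frame(events),
            all(c("time_param", "src", "dst") %in% names(events)))
  if (nrow(events) != length(populations) - 1L)
    stop("a rooted tree over ", length(populations), " populations needs ",
         length(populations) - 1L, " merge events")
  if (anyDuplicated(events$src))
    stop("every lineage must merge exactly once (duplicated src)")
  bad <- setdiff(c(events$src, events$dst), populations)
  if (length(bad)) stop("events reference unknown populations: ",
                        paste(unique(bad), collapse = ", "))
  root <- setdiff(populations, events$src)
  if (length(root) != 1L) stop("exactly one lineage (the root) must never merge")
  pars <- c(paste0("N_", populations), events$time_param)
  missing <- setdiff(pars, names(priors))
  if (length(missing)) stop("missing priors for: ", paste(missing, collapse = ", "))
  structure(list(id = id, populations = populations, events = events,
                 priors = priors[pars], constraints = constraints, root = root),
            class = "scenario_spec")
}

#' @exportS3Method base::print
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", x$id, "-", length(x$populations), "populations\n")
  for (i in seq_len(nrow(x$events)))
    cat(sprintf("  %s -> %s @ %s\n", x$events$src[i], x$events$dst[i],
                x$events$time_param[i]))
  invisible(x)
}

#' The four built-in biogeographic scenarios
#'
#' Competing divergence histories for seven populations, four in the
#' northwestern Pacific (ERI, KHO, STA, PET) and three in the northeastern
#' Pacific (KOD, COR, JUN). Backward in time:
#' \describe{
#'   \item{scenario1}{single west-to-east colonization: KOD->COR (`t_a`),
#'     COR->JUN (`t_b`), the NEP clade into PET (`t_c`), STA->ERI (`t_d`),
#'     PET->ERI (`t_e`), KHO->ERI (`t_f`).}
#'   \item{scenario2}{two colonizations: KOD and the (COR,JUN) clade merge
#'     into PET independently at distinct times.}
#'   \item{scenario3}{east-to-west: PET is derived from the ancestral NEP
#'     lineage (PET merges into the NEP clade, which then joins the NWP).}
#'   \item{scenario4}{null: the NEP clade is sister to all NWP populations,
#'     merging only at the root.}
#' }
#' All sizes share one uniform prior and all times another; defaults
#' bracket every published multi-population estimate for this system.
#'
#' @param size_prior [prior_spec()] for effective sizes (individuals).
#' @param time_prior [prior_spec()] for merge times (generations).
#' @return Named list of four [scenario_spec()] objects.
#' @export
#' @examples
#' sc <- builtin_scenarios()
#' nrow(sc$scenario1$events) # 6 merges for 7 populations
builtin_scenarios <- function(size_prior = prior_spec(100, 1e6),
                              time_prior = prior_spec(10, 6e5)) {
  pops <- c("ERI", "KHO", "STA", "PET", "KOD", "COR", "JUN")
  pr <- function(times) {
    p <- c(setNames(rep(list(size_prior), 7L), paste0("N_", pops)),
           setNames(rep(list(time_prior), length(times)), times))
    p
  }
  ev <- function(...) {
    m <- matrix(c(...), ncol = 3L, byrow = TRUE)
    data.frame(time_param = m[, 1L], src = m[, 2L], dst = m[, 3L],
               stringsAsFactors = FALSE)
  }
  list(
    scenario1 = scenario_spec("scenario1", pops,
      ev("t_a", "KOD", "COR",  "t_b", "COR", "JUN",  "t_c", "JUN", "PET",
         "t_d", "STA", "ERI",  "t_e", "PET", "ERI",  "t_f", "KHO", "ERI"),
      pr(c("t_a", "t_b", "t_c", "t_d", "t_e", "t_f")),
      list(c("t_a", "t_b"), c("t_b", "t_c"), c("t_c", "t_e"), c("t_d", "t_f"))),
    scenario2 = scenario_spec("scenario2", pops,
      ev("t_a", "JUN", "COR",  "t_b", "COR", "PET",  "t_c", "KOD", "PET",
         "t_d", "STA", "ERI",  "t_e", "PET", "ERI",  "t_f", "KHO", "ERI"),
      pr(c("t_a", "t_b", "t_c", "t_d", "t_e", "t_f")),
      list(c("t_a", "t_b"), c("t_b", "t_e"), c("t_c", "t_e"), c("t_d", "t_f"))),
    scenario3 = scenario_spec("scenario3", pops,
      ev("t_a", "KOD", "COR",  "t_b", "COR", "JUN",  "t_c", "PET", "JUN",
         "t_d", "STA", "ERI",  "t_e", "JUN", "ERI",  "t_f", "KHO", "ERI"),
      pr(c("t_a", "t_b", "t_c", "t_d", "t_e", "t_f")),
      list(c("t_a", "t_b"), c("t_b", "t_c"), c("t_c", "t_e"), c("t_d", "t_f"))),
    scenario4 = scenario_spec("scenario4", pops,
      ev("t_a", "KOD", "COR",  "t_b", "COR", "JUN",  "t_d", "STA", "ERI",
         "t_e", "PET", "ERI",  "t_f", "KHO", "ERI",  "t_g", "JUN", "ERI"),
      pr(c("t_a", "t_b", "t_d", "t_e", "t_f", "t_g")),
      list(c("t_a", "t_b"), c("t_b", "t_g"), c("t_d", "t_f"),
           c("t_e", "t_g"), c("t_f", "t_g")))
  )
}

#' Posterior modal parameters for scenario 1
#'
#' The published posterior modes for the single-colonization history:
#' effective sizes in individuals and merge times in generations. Used to
#' parameterize pseudo-observed data sets in the validation experiments.
#'
#' @return Named numeric vector of 13 parameters.
#' @export
scenario1_modal_parameters <- function() {
  c(N_ERI = 321000, N_KHO = 88800, N_STA = 315000, N_PET = 99800,
    N_KOD = 19900, N_COR = 144000, N_JUN = 21200,
    t_a = 2810, t_b = 22400, t_c = 54400,
    t_d = 205000, t_e = 244000, t_f = 483000)
}

#' Sampling design: individuals per population
#'
#' @param individuals named integer vector, individuals sampled per
#'   population. A locus with `copies_per_individual = 2` contributes twice
#'   as many gene copies.
#' @param regions named character vector mapping population to region.
#' @return An object of class `sampling_design`.
#' @export
sampling_design <- function(individuals, regions) {
  stopifnot(!is.null(names(individuals)), all(individuals >= 1),
            all(names(individuals) %in% names(regions)))
  structure(list(individuals = individuals,
                 regions = regions[names(individuals)]),
            class = "sampling_design")
}

#' The empirical seven-population sampling design
#'
#' Individuals per multi-locus population, matching the field collections:
#' ERI 11, KHO 16, STA 8, PET 16 (NWP) and KOD 9, COR 12, JUN 8 (NEP).
#'
#' @return A [sampling_design()].
#' @export
default_design <- function() {
  sampling_design(
    c(ERI = 11L, KHO = 16L, STA = 8L, PET = 16L,
      KOD = 9L, COR = 12L, JUN = 8L),
    c(ERI = "NWP", KHO = "NWP", STA = "NWP", PET = "NWP",
      KOD = "NEP", COR = "NEP", JUN = "NEP"))
}

#' Draw one parameter vector from a scenario's priors
#'
#' Independent uniform draws; vectors violating the scenario's ordering
#' constraints are rejected and redrawn (bounded at `max_tries`).
#'
#' @param scenario a [scenario_spec()].
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @param max_tries rejection bound before a prior-specification error.
#' @return An object of class `parameter_draw`: list with `scenario`,
#'   `values` (named numeric), `seed`.
#' @export
draw_parameters <- function(scenario, seed = NULL, max_tries = 10000L) {
  if (!is.null(seed)) set.seed(seed)
  pr <- scenario$priors
  lo <- vapply(pr, `[[`, 0, "lower")
  hi <- vapply(pr, `[[`, 0, "upper")
  npar <- length(pr)
  block <- 64L
  tried <- 0L
  while (tried < max_tries) {
    cand <- matrix(runif(npar * block, lo, hi), nrow = npar,
                   dimnames = list(names(pr), NULL))
    ok <- rep(TRUE, block)
    for (cc in scenario$constraints)
      ok <- ok & cand[cc[1L], ] < cand[cc[2L], ]
    hit <- which(ok)
    if (length(hit))
      return(structure(list(scenario = scenario$id,
                            values = cand[, hit[1L]], seed = seed),
                       class = "parameter_draw"))
    tried <- tried + block
  }
  stop("ordering constraints unsatisfiable after ", max_tries,
       " rejections [prior-specification error]")
}

#' Fix a parameter vector without drawing
#'
#' Wraps externally supplied values (e.g. posterior modes) as a
#' [draw_parameters()] result after validating against priors and
#' constraints.
#'
#' @param scenario a [scenario_spec()].
#' @param values named numeric vector covering every scenario parameter.
#' @return A `parameter_draw`.
#' @export
fixed_parameters <- function(scenario, values) {
  need <- names(scenario$priors)
  missing <- setdiff(need, names(values))
  if (length(missing)) stop("missing parameters: ", paste(missing, collapse = ", "))
  v <- values[need]
  ok <- all(vapply(scenario$constraints,
                   function(cc) v[[cc[1L]]] < v[[cc[2L]]], TRUE))
  if (!ok) stop("values violate ordering constraints")
  structure(list(scenario = scenario$id, values = v, seed = NA_integer_),
            class = "parameter_draw")
}

# internal: simulate one locus, returning the raw 0/1 site matrix
# (rows = gene copies grouped by population in design order) plus metadata.
sim_locus_matrix <- function(scenario, draw, locus, design) {
  pops <- scenario$populations
  if (!all(names(design$individuals) %in% pops))
    stop("design populations not covered by scenario [design error]")
  if (!all(pops %in% names(design$individuals)))
    stop("scenario populations missing from design [design error]")
  n_cop <- design$individuals[pops] * locus$copies_per_individual
  v <- draw$values
  sizes <- v[paste0("N_", pops)]
  tt <- v[scenario$events$time_param]
  ord <- order(tt)
  res <- sim_locus_cpp(as.integer(n_cop), as.numeric(sizes),
                       as.numeric(tt[ord]),
                       match(scenario$events$src[ord], pops) - 1L,
                       match(scenario$events$dst[ord], pops) - 1L,
                       locus$inheritance_scalar, mu_locus(locus))
  X <- res$haps
  L <- locus$length_bp
  M <- ncol(X)
  finite_sites <- FALSE
  if (M <= L) {
    pos <- sort(sample.int(L, M))
  } else {
    # infinite-sites overflow: fall back to finite sites, recurrent
    # mutations at one position toggle the state (mod 2)
    finite_sites <- TRUE
    raw <- sample.int(L, M, replace = TRUE)
    pos <- sort(unique(raw))
    X2 <- matrix(0L, nrow(X), length(pos))
    for (j in seq_along(pos))
      X2[, j] <- rowSums(X[, raw == pos[j], drop = FALSE]) %% 2L
    X <- X2[, colSums(X2) > 0L & colSums(X2) < nrow(X2), drop = FALSE]
    pos <- pos[colSums(X2) > 0L & colSums(X2) < nrow(X2)]
  }
  list(haps = X, positions = pos,
       pop = factor(rep(pops, n_cop), levels = pops),
       n_cop = n_cop, finite_sites = finite_sites, tmrca = res$tmrca)
}

# internal: binary site matrix -> aligned sequence strings over {A, G}
matrix_to_seqs <- function(X, positions, length_bp) {
  n <- nrow(X)
  base <- rep("A", length_bp)
  vapply(seq_len(n), function(i) {
    s <- base
    s[positions[X[i, ] == 1L]] <- "G"
    paste(s, collapse = "")
  }, "")
}

#' Simulate one locus under a divergence scenario
#'
#' Standard n-coalescent within the scenario's population tree (no
#' migration, no recombination, no growth), with mutations Poisson on
#' branches at `mu_site_gen * length_bp` per generation and placed under
#' the infinite-sites model. Output sequences are encoded over \{A, G\}
#' (ancestral/derived) so every downstream statistic sees an ordinary
#' alignment. If more mutations arise than there are sites, the locus
#' falls back to finite sites (recurrent mutation toggles a position) and
#' the result is flagged with attribute `finite_sites`.
#'
#' @param scenario a [scenario_spec()].
#' @param draw a `parameter_draw` from [draw_parameters()] or
#'   [fixed_parameters()].
#' @param locus a [locus_spec()].
#' @param design a [sampling_design()] covering the scenario populations.
#' @param seed optional integer seed.
#' @return Data frame of locus records (`individual`, `population`,
#'   `region`, `allele`, `seq`), with attribute `finite_sites`.
#' @export
simulate_locus <- function(scenario, draw, locus, design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim <- sim_locus_matrix(scenario, draw, locus, design)
  seqs <- matrix_to_seqs(sim$haps, sim$positions, locus$length_bp)
  cpi <- locus$copies_per_individual
  pops <- as.character(sim$pop)
  ind <- unlist(lapply(names(sim$n_cop), function(p) {
    ni <- sim$n_cop[[p]] / cpi
    rep(sprintf("%s_%02d", p, seq_len(ni)), each = cpi)
  }))
  rec <- data.frame(individual = ind, population = pops,
                    region = unname(design$regions[pops]),
                    allele = rep_len(seq_len(cpi), length(pops)),
                    seq = seqs, stringsAsFactors = FALSE)
  attr(rec, "finite_sites") <- sim$finite_sites
  rec
}

#' Simulate a full multi-locus panel under a scenario
#'
#' Independent coalescent realizations per locus; nuclear loci contribute
#' two phased copies per individual. Deterministic given `seed`.
#'
#' @inheritParams simulate_locus
#' @param loci named list of [locus_spec()].
#' @return A [seq_panel()].
#' @export
#' @examples
#' sc <- builtin_scenarios()$scenario1
#' d <- draw_parameters(sc, seed = 1)
#' p <- simulate_dataset(sc, d, default_loci(), default_design(), seed = 1)
simulate_dataset <- function(scenario, draw, loci, design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  records <- lapply(loci, function(lc) simulate_locus(scenario, draw, lc, design))
  names(records) <- names(loci)
  seq_panel(loci, records)
}
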