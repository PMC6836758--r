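# Programmatic fixtures shared across test files.

# random alignment: a few base haplotypes plus per-copy mutations, so that
# panels have realistic haplotype structure (shared and singleton variants)
random_seqs <- function(n, L, n_base = 3, mut_per_copy = 1.5) {
  base <- replicate(n_base, paste(sample(ACGT, L, replace = TRUE), collapse = ""))
  vapply(seq_len(n), function(i) {
    s <- strsplit(sample(base, 1), "")[[1]]
    nm <- rpois(1, mut_per_copy)
    if (nm > 0) {
      pos <- sample.int(L, min(nm, L))
      s[pos] <- vapply(s[pos], function(b) sample(setdiff(ACGT, b), 1), "")
    }
    paste(s, collapse = "")
  }, "")
}

# single-population scenario, handy for calibration checks
one_pop_scenario <- function(N, pop = "X") {
  scenario_spec("onepop", pop,
                data.frame(time_param = character(0), src = character(0),
                           dst = character(0), stringsAsFactors = FALSE),
                setNames(list(prior_spec(N - 0.5, N + 0.5)), paste0("N_", pop)))
}

one_pop_draw <- function(sc, N, pop = "X") {
  fixed_parameters(sc, setNames(N, paste0("N_", pop)))
}

# two-population scenario with a single split at time t
two_pop_scenario <- function() {
  scenario_spec("twopop", c("X", "Y"),
                data.frame(time_param = "t_s", src = "Y", dst = "X",
                           stringsAsFactors = FALSE),
                list(N_X = prior_spec(100, 1e6), N_Y = prior_spec(100, 1e6),
                     t_s = prior_spec(0.1, 1e6)))
}

# simulate a single-population locus and return its 0/1 site matrix
sim_one_pop_matrix <- function(N, n_copies, locus) {
  sc <- one_pop_scenario(N)
  des <- sampling_design(setNames(as.integer(n_copies / locus$copies_per_individual), "X"),
                         c(X = "NWP"))
  coalABC:::sim_locus_matrix(sc, one_pop_draw(sc, N), locus, des)
}

tiny_loci <- function(L = 50) list(LOC = locus_spec("LOC", L, 1, 1e-9, 1))

# small two-population panel from explicit sequences
panel_from_seqs <- function(seqs_by_pop, L = nchar(seqs_by_pop[[1]][1]),
                            copies = 1L) {
  rec <- do.call(rbind, lapply(names(seqs_by_pop), function(p) {
    s <- seqs_by_pop[[p]]
    data.frame(individual = sprintf("%s_%02d", p, ceiling(seq_along(s) / copies)),
               population = p, region = if (p %in% c("KOD", "COR", "JUN")) "NEP" else "NWP",
               allele = rep_len(seq_len(copies), length(s)), seq = s,
               stringsAsFactors = FALSE)
  }))
  loci <- list(LOC = locus_spec("LOC", L, 1, 1e-9, copies))
  seq_panel(loci, list(LOC = rec))
}
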