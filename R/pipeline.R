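# End-to-end orchestration: load or simulate a panel, recombination
# screening and filtering, haplotype networks, diversity/differentiation
# tables, and the ABC stage, with one master seed and checksummed outputs.

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate the panel; PHI recombination test
#' per nuclear locus; four-gamete filtering of loci flagged (or listed in
#' the config); a minimum-spanning haplotype network per locus;
#' per-population diversity and neutrality tables; pairwise Phi_ST
#' matrices; and, when an `abc` block is present, reference-table
#' construction, scenario choice, optional error rates, parameter
#' estimation and unit scaling. Every output file is checksummed into
#' `manifest.tsv`. A stage failure halts with a stage-tagged error;
#' partial outputs are retained.
#'
#' @param cfg configuration list, or path to a YAML file. Recognized
#'   blocks: `panel` (`fasta` named paths + `metadata`) or `synthetic`
#'   (`scenario`, optional `params`), `stats` (`n_perms`, `n_sims`),
#'   `recombination` (`loci`, `window_w`, `n_perms`), `abc`
#'   (`n_per_scenario`, `n_retain`, `retain_fraction`, `n_boot`,
#'   `error_pods`), `scaling` (`divergence_rate_per_Myr`,
#'   `generation_time_years`).
#' @param out_dir output directory.
#' @param seed master seed governing every stochastic stage.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(cfg, out_dir, seed = 1L) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("[stage ", name, "] ", conditionMessage(e),
                                      call. = FALSE))
  }
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  loci <- do.call(default_loci, cfg$loci %||% list())
  design <- default_design()

  panel <- stage("panel", {
    if (!is.null(cfg$panel)) {
      read_panel(unlist(cfg$panel$fasta), cfg$panel$metadata, loci)
    } else if (!is.null(cfg$synthetic)) {
      sc <- builtin_scenarios()[[cfg$synthetic$scenario]]
      if (is.null(sc)) stop("unknown scenario: ", cfg$synthetic$scenario)
      draw <- if (!is.null(cfg$synthetic$params))
        fixed_parameters(sc, unlist(cfg$synthetic$params))
      else draw_parameters(sc, seed = derive_seed(seed, 1L))
      note("synthetic panel under ", sc$id)
      simulate_dataset(sc, draw, loci, design, seed = derive_seed(seed, 2L))
    } else stop("config needs a 'panel' or 'synthetic' block")
  })
  write_panel(panel, file.path(out_dir, "panel"))

  rc <- cfg$recombination %||% list()
  phi_results <- stage("phi_test", {
    nuclear <- names(panel$loci)[vapply(panel$loci, function(l)
      l$copies_per_individual > 1L, TRUE)]
    res <- list()
    for (nm in nuclear) {
      r <- phi_test(panel$records[[nm]],
                    window_w = rc$window_w %||% 100L,
                    n_perms = rc$n_perms %||% 1000L,
                    seed = derive_seed(seed, 10L + match(nm, names(panel$loci))))
      res[[nm]] <- r
      note("PHI test ", nm, ": phi_w = ", signif(r$phi_w, 3),
           ", p = ", signif(r$p_value, 3))
    }
    res
  })
  stage("four_gamete_filter", {
    to_filter <- rc$loci %||%
      names(phi_results)[vapply(phi_results, function(r)
        isTRUE(r$applicable) && r$p_value < 0.05, TRUE)]
    for (nm in to_filter) {
      rep <- filter_recombinant_sites(panel$records[[nm]])
      note("filtered ", nm, ": removed ",
           length(rep$removed_site_positions), " site(s)")
      write_stats_table(
        data.frame(locus = nm,
                   position = if (length(rep$removed_site_positions))
                     rep$removed_site_positions else NA_integer_),
        file.path(out_dir, paste0("filter_", nm, ".tsv")))
      if (length(rep$removed_site_positions)) {
        panel$records[[nm]]$seq <- rep$retained
        panel$loci[[nm]]$length_bp <- nchar(rep$retained[1L])
      }
    }
  })
  stage("haplonet", {
    for (nm in names(panel$records)) {
      net <- build_msn(collapse_haplotypes(panel, nm))
      export_network(net, file.path(out_dir, paste0("network_", nm, ".graphml")),
                     file.path(out_dir, paste0("network_", nm, "_edges.tsv")))
    }
  })
  st <- cfg$stats %||% list()
  stage("diversity", {
    tab <- diversity_table(panel, n_sims = st$n_sims %||% 0L,
                           seed = derive_seed(seed, 20L))
    write_stats_table(tab, file.path(out_dir, "diversity.tsv"))
  })
  stage("phi_st", {
    for (nm in names(panel$records)) {
      m <- phi_st_matrix(panel, nm, n_perms = st$n_perms %||% 1000L,
                         seed = derive_seed(seed, 30L + match(nm, names(panel$records))))
      write.table(m$phi_st, file.path(out_dir, paste0("phist_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, na = "NA", col.names = NA)
      write.table(m$p_value, file.path(out_dir, paste0("phist_", nm, "_p.tsv")),
                  sep = "\t", quote = FALSE, na = "NA", col.names = NA)
    }
  })
  abc_out <- NULL
  if (!is.null(cfg$abc)) {
    abc_out <- stage("abc", {
      a <- cfg$abc
      scs <- builtin_scenarios()
      tab <- build_reference_table(scs, panel$loci, design,
                                   n_per_scenario = a$n_per_scenario %||% 1000L,
                                   master_seed = derive_seed(seed, 40L))
      obs <- summary_vector(panel)
      rej <- abc_reject(tab, obs, n_retain = a$n_retain %||% 500L)
      mc <- model_choice(rej, n_boot = a$n_boot %||% 200L,
                         seed = derive_seed(seed, 41L))
      note("selected scenario: ", mc$selected)
      er <- NULL
      if (!is.null(a$error_pods) && a$error_pods > 0L)
        er <- error_rates(tab, mc$selected, n_pods = a$error_pods,
                          n_retain = a$n_retain %||% 500L,
                          seed = derive_seed(seed, 42L))
      est <- estimate_parameters(tab, obs, mc$selected,
                                 retain_fraction = a$retain_fraction %||% 0.01)
      sc_cfg <- do.call(scaling_config, cfg$scaling %||% list())
      pn <- setdiff(names(est), c("adjusted", "scenario"))
      rows <- lapply(pn, function(p) {
        years <- if (startsWith(p, "t_"))
          scale_units(c(est[[p]]$mode, est[[p]]$ci), "generations_to_years",
                      panel$loci[[1L]], sc_cfg)
        else c(est[[p]]$mode, est[[p]]$ci)
        data.frame(parameter = p, mode = est[[p]]$mode,
                   ci_low = est[[p]]$ci[1], ci_high = est[[p]]$ci[2],
                   mode_demographic = years[1L],
                   stringsAsFactors = FALSE)
      })
      write_stats_table(do.call(rbind, rows), file.path(out_dir, "parameters.tsv"))
      jsonlite::write_json(
        list(posterior = as.list(mc$posterior), selected = mc$selected,
             error_rates = if (!is.null(er))
               list(false_positive = er$false_positive_rate,
                    false_negative = er$false_negative_rate)),
        file.path(out_dir, "abc_summary.json"), auto_unbox = TRUE, digits = NA)
      list(table = tab, model_choice = mc, error_rates = er, estimates = est)
    })
  }
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  files <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                   file.path(out_dir, "manifest.tsv"))
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_stats_table(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(panel = panel, phi = phi_results, abc = abc_out,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write small deterministic test fixtures
#'
#' \describe{
#'   \item{tiny_panel}{a 4-sequence, 2-site alignment (the worked
#'     Tajima's D example: haplotypes AA, AA, GG, AG) with metadata.}
#'   \item{recombinant_locus}{an alignment built by manual crossover of
#'     two divergent haplotypes, guaranteed to fail the four-gamete test.}
#'   \item{scenario1_pods}{ten pseudo-observed panels simulated under the
#'     single-colonization scenario at the posterior modal parameters.}
#' }
#'
#' @param name fixture name.
#' @param dir output directory.
#' @param seed integer seed.
#' @return Invisibly, the files written.
#' @export
make_fixture <- function(name = c("tiny_panel", "recombinant_locus",
                                  "scenario1_pods"),
                         dir, seed = 1L) {
  name <- match.arg(name)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (name == "tiny_panel") {
    loci <- list(TINY = locus_spec("TINY", 2L, 1, 1e-9, 1))
    rec <- data.frame(individual = paste0("ind", 1:4),
                      population = "POP1", region = "NWP", allele = 1L,
                      seq = c("AA", "AA", "GG", "AG"),
                      stringsAsFactors = FALSE)
    return(invisible(write_panel(seq_panel(loci, list(TINY = rec)), dir)))
  }
  if (name == "recombinant_locus") {
    # both reciprocal crossovers of two divergent haplotypes, so site
    # pairs spanning the breakpoint show all four gametes
    a <- "AAAAAAAAAA"; b <- "GGGGGGGGGG"
    ab <- paste0(substr(a, 1, 5), substr(b, 6, 10))
    ba <- paste0(substr(b, 1, 5), substr(a, 6, 10))
    seqs <- c(a, a, b, b, ab, ba)
    loci <- list(REC = locus_spec("REC", 10L, 1, 1e-9, 1))
    rec <- data.frame(individual = paste0("ind", seq_along(seqs)),
                      population = "POP1", region = "NWP", allele = 1L,
                      seq = seqs, stringsAsFactors = FALSE)
    return(invisible(write_panel(seq_panel(loci, list(REC = rec)), dir)))
  }
  sc <- builtin_scenarios()$scenario1
  draw <- fixed_parameters(sc, scenario1_modal_parameters())
  paths <- character(0)
  for (i in 1:10) {
    p <- simulate_dataset(sc, draw, default_loci(), default_design(),
                          seed = derive_seed(seed, i))
    paths <- c(paths, write_panel(p, file.path(dir, sprintf("pod%02d", i))))
  }
  invisible(paths)
}
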