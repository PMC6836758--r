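#' Describe a sequenced locus
#'
#' A locus specification carries everything the simulator and the
#' statistics need to know about a marker: its aligned length, its mode of
#' inheritance (expressed as the effective-copy-number scalar relative to a
#' diploid autosome: 1 for nuclear loci, 0.25 for maternally inherited
#' haploid mtDNA), the per-site per-generation mutation rate, and how many
#' sequence records one individual contributes (1 for mtDNA, 2 phased
#' alleles for a nuclear locus).
#'
#' @param name character label.
#' @param length_bp aligned length in base pairs (> 0).
#' @param inheritance_scalar relative effective gene-copy number
#'   (0.25 mtDNA, 1 autosomal by convention; any positive value accepted).
#' @param mu_site_gen mutation rate per site per generation (> 0).
#' @param copies_per_individual records contributed per typed individual.
#' @return An object of class `locus_spec`.
#' @export
#' @examples
#' locus_spec("CYTB", 433, 0.25, 5e-9, 1)
locus_spec <- function(name, length_bp, inheritance_scalar, mu_site_gen,
                       copies_per_individual) {
  stopifnot(is.character(name), length(name) == 1L)
  length_bp <- as.integer(length_bp)
  if (is.na(length_bp) || length_bp <= 0L) stop("length_bp must be a positive integer")
  if (!is.numeric(inheritance_scalar) || inheritance_scalar <= 0)
    stop("inheritance_scalar must be positive")
  if (!is.numeric(mu_site_gen) || mu_site_gen < 0)
    stop("mu_site_gen must be non-negative")
  copies_per_individual <- as.integer(copies_per_individual)
  if (is.na(copies_per_individual) || copies_per_individual < 1L)
    stop("copies_per_individual must be a positive integer")
  structure(list(name = name, length_bp = length_bp,
                 inheritance_scalar = inheritance_scalar,
                 mu_site_gen = mu_site_gen,
                 copies_per_individual = copies_per_individual),
            class = "locus_spec")
}

#' Per-locus mutation rate
#'
#' @param locus a [locus_spec()].
#' @return Mutation rate per gene copy per generation,
#'   `mu_site_gen * length_bp`.
#' @export
mu_locus <- function(locus) locus$mu_site_gen * locus$length_bp

#' The four-marker study design
#'
#' One mitochondrial cytochrome-b fragment and three nuclear introns, at
#' the aligned lengths of the empirical data set. The mtDNA per-site rate
#' follows from a sequence divergence rate of 1% per million years
#' (0.5%/lineage/Myr, i.e. 5e-9/site/year) times the generation time;
#' nuclear introns default to 1e-9 per site per generation-year, a typical
#' invertebrate intron rate an order of magnitude below mtDNA.
#'
#' @param generation_time_years generation time in years (default 1).
#' @param mu_nuclear nuclear per-site per-year mutation rate.
#' @return Named list of four [locus_spec()] objects.
#' @export
#' @examples
#' names(default_loci())
default_loci <- function(generation_time_years = 1, mu_nuclear = 1e-9) {
  g <- generation_time_years
  list(
    CYTB   = locus_spec("CYTB",   433, 0.25, 5e-9 * g, 1),
    ATPSa  = locus_spec("ATPSa",  881, 1.0,  mu_nuclear * g, 2),
    ATPSb  = locus_spec("ATPSb",  612, 1.0,  mu_nuclear * g, 2),
    APN54  = locus_spec("APN54",  597, 1.0,  mu_nuclear * g, 2)
  )
}

#' Construct a multi-locus sequence panel
#'
#' The universal data carrier: per-locus tables of aligned haplotype copies
#' tagged with the individual, population and region they came from.
#' Nuclear allele records are phase-known haplotypes (two records per
#' individual); mtDNA contributes one record per individual.
#'
#' @param loci named list of [locus_spec()]; names must match `records`.
#' @param records named list (one per locus) of data frames with columns
#'   `individual`, `population`, `region`, `allele` (integer copy index)
#'   and `seq` (aligned sequence string).
#' @return An object of class `seq_panel`.
#' @export
seq_panel <- function(loci, records) {
  stopifnot(is.list(loci), is.list(records))
  if (is.null(names(loci))) names(loci) <- vapply(loci, `[[`, "", "name")
  missing <- setdiff(names(records), names(loci))
  if (length(missing)) stop("records for unknown loci: ", paste(missing, collapse = ", "))
  for (nm in names(records)) {
    r <- records[[nm]]
    need <- c("individual", "population", "region", "allele", "seq")
    if (!all(need %in% names(r))) stop("locus ", nm, ": records need columns ",
                                       paste(need, collapse = ", "))
    L <- loci[[nm]]$length_bp
    if (nrow(r) && any(nchar(r$seq) != L))
      stop("locus ", nm, ": sequence length differs from configured ", L,
           " bp [format error]")
    key <- paste(r$individual, r$allele)
    if (anyDuplicated(key))
      stop("locus ", nm, ": duplicate (individual, allele) record [duplication error]")
    cpi <- loci[[nm]]$copies_per_individual
    tab <- table(r$individual)
    if (nrow(r) && any(tab != cpi))
      stop("locus ", nm, ": every typed individual must contribute exactly ",
           cpi, " records")
  }
  structure(list(loci = loci, records = records), class = "seq_panel")
}

#' @exportS3Method base::print
print.seq_panel <- function(x, ...) {
  cat("<seq_panel>", length(x$loci), "loci\n")
  for (nm in names(x$records)) {
    r <- x$records[[nm]]
    cat(sprintf("  %-8s %4d bp  %3d records  %d populations\n", nm,
                x$loci[[nm]]$length_bp, nrow(r),
                length(unique(r$population))))
  }
  invisible(x)
}

#' Read a multi-locus panel from FASTA alignments and a metadata table
#'
#' One FASTA per locus, headers formatted `>individualID|alleleIndex`
#' (`|alleleIndex` optional for single-copy loci, defaulting to 1), plus a
#' tab-delimited metadata table with columns `individual`, `population`,
#' `region`. Alignment lengths must match the locus configuration; gap or
#' ambiguity characters are allowed and such sites are excluded listwise by
#' every downstream statistic.
#'
#' @param fasta_paths named character vector of FASTA paths, names = locus
#'   names present in `loci`.
#' @param metadata_path path to the tab-delimited metadata table.
#' @param loci named list of [locus_spec()].
#' @return A [seq_panel()].
#' @export
read_panel <- function(fasta_paths, metadata_path, loci) {
  if (is.null(names(fasta_paths)) || any(names(fasta_paths) == ""))
    stop("fasta_paths must be named by locus")
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  need <- c("individual", "population", "region")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns ", paste(need, collapse = ", "),
         " [metadata error]")
  records <- list()
  for (nm in names(fasta_paths)) {
    if (!nm %in% names(loci)) stop("no locus_spec for ", nm)
    ss <- Biostrings::readBStringSet(fasta_paths[[nm]])
    sq <- toupper(as.character(ss))
    hdr <- names(ss)
    parts <- strsplit(hdr, "|", fixed = TRUE)
    ind <- vapply(parts, `[[`, "", 1L)
    allele <- vapply(parts, function(p) if (length(p) > 1L) as.integer(p[[2L]]) else 1L,
                     integer(1))
    unknown <- setdiff(ind, meta$individual)
    if (length(unknown))
      stop("locus ", nm, ": individuals absent from metadata: ",
           paste(unique(unknown), collapse = ", "), " [metadata error]")
    L <- loci[[nm]]$length_bp
    if (any(nchar(sq) != L))
      stop("locus ", nm, ": alignment length ", paste(unique(nchar(sq)), collapse = "/"),
           " != configured ", L, " bp [format error]")
    i <- match(ind, meta$individual)
    records[[nm]] <- data.frame(individual = ind,
                                population = meta$population[i],
                                region = meta$region[i],
                                allele = allele, seq = unname(sq),
                                stringsAsFactors = FALSE)
  }
  seq_panel(loci[names(records)], records)
}

#' Write a panel back to FASTA + metadata
#'
#' Inverse of [read_panel()]: one FASTA per locus with
#' `>individualID|alleleIndex` headers and a `metadata.tsv`.
#'
#' @param panel a [seq_panel()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  meta <- unique(do.call(rbind, lapply(panel$records, function(r)
    r[c("individual", "population", "region")])))
  meta <- meta[order(meta$individual), , drop = FALSE]
  mpath <- file.path(dir, "metadata.tsv")
  write.table(meta, mpath, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  for (nm in names(panel$records)) {
    r <- panel$records[[nm]]
    ss <- Biostrings::BStringSet(setNames(r$seq, paste0(r$individual, "|", r$allele)))
    fpath <- file.path(dir, paste0(nm, ".fasta"))
    Biostrings::writeXStringSet(ss, fpath)
    paths <- c(paths, fpath)
  }
  invisible(c(paths, mpath))
}

#' Collapse a locus to its distinct haplotypes
#'
#' Identical sequences are pooled into haplotypes, with counts overall, per
#' population and per region. Haplotypes are ordered deterministically by
#' descending count, ties broken lexicographically by sequence.
#'
#' @param panel a [seq_panel()].
#' @param locus locus name.
#' @return An object of class `haplotype_table`: a list with elements
#'   `locus`, `haplotypes` (data frame `id`, `seq`, `count`), `pop_counts`
#'   and `region_counts` (haplotype-by-group count matrices).
#' @export
collapse_haplotypes <- function(panel, locus) {
  if (!locus %in% names(panel$records)) stop("locus not in panel: ", locus)
  r <- panel$records[[locus]]
  if (nrow(r) == 0L) stop("locus ", locus, " has no records [empty input]")
  counts <- table(r$seq)
  ord <- order(-as.integer(counts), names(counts))
  seqs <- names(counts)[ord]
  hid <- paste0("H", seq_along(seqs))
  idx <- match(r$seq, seqs)
  pop_counts <- as.matrix(table(factor(idx, levels = seq_along(seqs)), r$population))
  region_counts <- as.matrix(table(factor(idx, levels = seq_along(seqs)), r$region))
  rownames(pop_counts) <- rownames(region_counts) <- hid
  structure(list(locus = locus,
                 haplotypes = data.frame(id = hid, seq = seqs,
                                         count = as.integer(counts)[ord],
                                         stringsAsFactors = FALSE),
                 pop_counts = pop_counts, region_counts = region_counts),
            class = "haplotype_table")
}

#' Write a homogeneous table of statistics as TSV
#'
#' Columns are written in the order of the first row; `NA`/`NaN` values are
#' encoded as the literal `NA`; output is UTF-8 with a header row.
#'
#' @param rows data frame, or list of identically named lists/vectors.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_stats_table <- function(rows, path) {
  if (!is.data.frame(rows)) {
    if (!length(rows)) stop("no rows")
    cols <- names(rows[[1L]])
    ok <- vapply(rows, function(r) identical(sort(names(r)), sort(cols)), TRUE)
    if (is.null(cols) || !all(ok))
      stop("heterogeneous rows: all rows must share one column set [schema error]")
    rows <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(as.list(r)[cols], stringsAsFactors = FALSE)))
  }
  df <- rows
  for (j in seq_along(df)) df[[j]][is.na(df[[j]])] <- NA  # NaN -> NA
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

# ---- internal sequence-matrix helpers shared by the statistics ----------

# character matrix (rows = copies) from aligned sequence strings
seqs_to_matrix <- function(seqs) {
  if (!length(seqs)) return(matrix(character(0), 0, 0))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences not aligned to one length")
  matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

# columns free of gaps/ambiguity in every sequence (listwise exclusion)
usable_site_idx <- function(m) {
  if (ncol(m) == 0L) return(integer(0))
  which(apply(m, 2L, function(col) all(col %in% c("A", "C", "G", "T", "0", "1"))))
}

# integer-coded allele matrix restricted to usable sites, plus usable length
encode_alignment <- function(seqs) {
  m <- seqs_to_matrix(seqs)
  keep <- usable_site_idx(m)
  mm <- m[, keep, drop = FALSE]
  am <- matrix(0L, nrow(mm), ncol(mm))
  for (j in seq_len(ncol(mm)))
    am[, j] <- as.integer(factor(mm[, j])) - 1L
  list(alleles = am, usable = length(keep), positions = keep)
}
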