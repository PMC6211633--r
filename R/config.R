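#' Read a flat key=value configuration file
#'
#' Blank lines and `#` comments are ignored; values that parse as numbers are
#' converted.  Every CLI flag has a config-file equivalent of the same name.
#'
#' @param path text file of `key = value` lines.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("read_config: malformed line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator: the tandem-paralog
#' geometry, allelic diversity, named chimeric alleles with their crossover
#' positions, regional diploid populations with genotype-class frequencies,
#' and the planted selective-sweep footprint.
#'
#' Defaults describe the stated world the generator emulates: a ~2 kb
#' paralog with an intron in its 3' half (the B1-like parent contributes the
#' intron and several hundred bp of coding sequence to each chimera), 5%
#' fixed divergence between the two parental ancestors, 1% per-site allelic
#' polymorphism, eight named chimeric alleles with distinct breakpoints all
#' 5' of the intron, a global population with an 88/9/3 percent
#' homozygous-chimeric / heterozygous / parental-only genotype split, and a
#' 150 kb variant segment scanned with 12 diploids carrying a planted sweep
#' (strength 0.9, footprint scale 2.5 kb).
#'
#' @param seed integer master seed; all generator stages derive their RNG
#'   streams from it and are byte-reproducible.
#' @param paralog_length paralog length in bp (both parents aligned 1:1).
#' @param intron_span integer pair, 0-based half-open intron coordinates in
#'   the B1-like parent.
#' @param theta_site per-site substitution probability within a parental
#'   allele pool, in `[0, 0.5)`.
#' @param n_alleles_per_parent alleles simulated per parental pool.
#' @param parent_divergence fraction of sites at which the two parental
#'   ancestors differ (informative sites for breakpoint mapping).
#' @param breakpoints named integer vector: crossover position (0-based; the
#'   first B1-derived column) per chimeric allele name.  Must lie 5' of the
#'   intron start.
#' @param regions list of region specs, each a list with `name`, `n`
#'   (individuals), `genotype_freqs` (named numeric over `B3/B3`, `B3/par`,
#'   `par/par`, summing to 1) and `allele_mixture` (named weights over
#'   chimeric allele names).
#' @param sweep list with `segment_length`, `site_density` (sites per bp),
#'   `sample_n` (diploids), `sweep_center`, `decay_length` (`L`, bp) and
#'   `strength` (`s` in `[0, 1]`).
#' @param primer_length diagnostic primer length in bp.
#' @param spacer_length intergenic spacer between the tandem B1 and B2 genes
#'   on a parental haplotype template; the default (5 kb) makes the
#'   reciprocal-orientation product exceed the PCR length cutoff, emulating
#'   the assay's negative reciprocal screen.
#' @param intron_indel_lengths optional integer vector; when given, B1 allele
#'   `i` receives an insertion of the `i`-th length (recycled) at the intron
#'   midpoint, emulating intron size variation among alleles.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              paralog_length = 2000L,
                              intron_span = c(1200L, 1700L),
                              theta_site = 0.01,
                              n_alleles_per_parent = 8L,
                              parent_divergence = 0.05,
                              breakpoints = c(v1 = 150L, v2 = 180L, v3 = 210L,
                                              v4 = 250L, v5 = 290L, v6 = 330L,
                                              v7 = 370L, v8 = 410L),
                              regions = list(),
                              sweep = list(segment_length = 150000L,
                                           site_density = 0.2,
                                           sample_n = 12L,
                                           sweep_center = 75000L,
                                           decay_length = 2500L,
                                           strength = 0.9),
                              primer_length = 20L,
                              spacer_length = 5000L,
                              intron_indel_lengths = NULL) {
  if (theta_site < 0 || theta_site >= 0.5)
    stop("simulation_config: theta_site must lie in [0, 0.5)")
  if (parent_divergence <= 0 || parent_divergence >= 0.5)
    stop("simulation_config: parent_divergence must lie in (0, 0.5)")
  stopifnot(paralog_length >= 600L,
            length(intron_span) == 2L,
            intron_span[1] < intron_span[2],
            intron_span[2] <= paralog_length)
  if (length(breakpoints)) {
    if (is.null(names(breakpoints)) || any(!nzchar(names(breakpoints))))
      stop("simulation_config: breakpoints must be named")
    if (any(breakpoints <= 0) || any(breakpoints >= intron_span[1]))
      stop("simulation_config: breakpoints must lie in (0, intron start)")
  }
  for (rg in regions) {
    stopifnot(all(c("name", "n", "genotype_freqs", "allele_mixture") %in% names(rg)))
    gf <- rg$genotype_freqs
    if (!isTRUE(all.equal(sum(gf), 1, tolerance = 1e-8)))
      stop("simulation_config: genotype_freqs must sum to 1 in region ", rg$name)
    if (!all(c("B3/B3", "B3/par", "par/par") %in% names(gf)))
      stop("simulation_config: genotype_freqs must be named over B3/B3, B3/par, par/par")
    unk <- setdiff(names(rg$allele_mixture), names(breakpoints))
    if (length(unk))
      stop("simulation_config: region ", rg$name,
           " allele_mixture references unknown allele(s): ",
           paste(unk, collapse = ", "))
  }
  sw <- sweep
  stopifnot(all(c("segment_length", "site_density", "sample_n", "sweep_center",
                  "decay_length", "strength") %in% names(sw)))
  if (sw$strength < 0 || sw$strength > 1)
    stop("simulation_config: sweep strength must lie in [0, 1]")
  if (sw$segment_length < 10 * sw$decay_length)
    warning("simulation_config: segment_length < 10 * decay_length; ",
            "the sweep footprint fills the whole segment")
  structure(list(seed = as.integer(seed), paralog_length = as.integer(paralog_length),
                 intron_span = as.integer(intron_span), theta_site = theta_site,
                 n_alleles_per_parent = as.integer(n_alleles_per_parent),
                 parent_divergence = parent_divergence,
                 breakpoints = breakpoints, regions = regions, sweep = sw,
                 primer_length = as.integer(primer_length),
                 spacer_length = as.integer(spacer_length),
                 intron_indel_lengths = intron_indel_lengths),
            class = "simulation_config")
}

#' Global-survey preset configuration
#'
#' A single "Global" region with the worldwide genotype split of the field
#' survey the package emulates (88% homozygous-chimeric, 9% heterozygous,
#' 3% parental-only) and an eight-allele chimera pool whose mixture weights
#' follow the published regional allele counts (v1 and v2 common, v7/v8
#' rare).
#'
#' @param seed master seed.
#' @param n individuals in the global region.
#' @return [simulation_config()].
#' @export
preset_paper_global <- function(seed = 1L, n = 999L) {
  mixture <- c(v1 = 91, v2 = 257, v3 = 5, v4 = 5, v5 = 96, v6 = 8, v7 = 1, v8 = 1)
  simulation_config(
    seed = seed,
    regions = list(list(
      name = "Global", n = as.integer(n),
      genotype_freqs = c("B3/B3" = 0.88, "B3/par" = 0.09, "par/par" = 0.03),
      allele_mixture = mixture / sum(mixture))))
}
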