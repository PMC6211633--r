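# Synthetic-data generator: parental allele pools, single-crossover chimeras,
# regional diploid populations and planted sweep footprints.  Every stage is
# seeded from config$seed (stage offsets keep streams independent) and records
# its planted truth for downstream oracle tests.

# Diagnostic primer footprints (0-based half-open template coordinates).
# Geometry: B2F at 100 and B1R ending at 454 give the 355 bp screening
# product spanning every default crossover position (150..410).
primer_footprints <- function(config) {
  pl <- config$primer_length
  L <- config$paralog_length
  list(b1f = c(10L, 10L + pl),
       b1r = c(455L - pl, 455L),
       b2f = c(100L, 100L + pl),
       b2r = c(L - 100L, L - 100L + pl))
}

# template positions that must differ between the two parental ancestors so
# each primer is parent-specific: the 3 bases pairing the primer 3' terminus
# (forward primers: footprint end; reverse primers: footprint start) plus one
# mid-footprint base.
.footprint_force_idx <- function(fp) {
  fwd <- function(f) c((f[2] - 2L):f[2], f[1] + 6L)
  rev <- function(f) c((f[1] + 1L):(f[1] + 3L), f[2] - 6L)
  sort(unique(c(fwd(fp$b1f), fwd(fp$b2f), rev(fp$b1r), rev(fp$b2r))))
}

#' Simulate parental allele pools
#'
#' Builds one random ancestral sequence per parent (the two ancestors differ
#' at a fixed fraction of sites, providing the informative sites breakpoint
#' mapping relies on), then derives each allele by independent per-site
#' substitution with probability `theta_site`.  Diagnostic primer footprints
#' are forced to be parent-diagnostic and are protected from allelic
#' substitution, emulating primers designed against conserved,
#' paralog-specific sites.  B1 alleles carry the intron annotation.
#'
#' @param config [simulation_config()].
#' @return list with `b1`, `b2` (lists of [allele_sequence()]), `ancestors`
#'   (named character), `footprints`, and `protected` (positions, 1-based,
#'   excluded from allelic substitution per parent).
#' @export
sample_parental_alleles <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  L <- config$paralog_length
  fp <- primer_footprints(config)
  if (any(vapply(fp, function(f) f[1] < 0L || f[2] > L, logical(1))))
    stop("sample_parental_alleles: paralog too short for primer footprints")
  with_seed(config$seed, {
    anc1 <- seq_chars(random_dna(L))
    n_div <- max(1L, round(config$parent_divergence * L))
    anc2 <- mutate_bases(anc1, sample.int(L, n_div))
    for (i in .footprint_force_idx(fp))
      if (anc2[i] == anc1[i]) anc2[i] <- sample(setdiff(DNA_BASES, anc1[i]), 1L)
    prot1 <- sort(unique(c(seq(fp$b1f[1] + 1L, fp$b1f[2]),
                           seq(fp$b1r[1] + 1L, fp$b1r[2]))))
    prot2 <- sort(unique(c(seq(fp$b2f[1] + 1L, fp$b2f[2]),
                           seq(fp$b2r[1] + 1L, fp$b2r[2]))))
    intron_ft <- data.frame(kind = "intron",
                            start = config$intron_span[1],
                            end = config$intron_span[2])
    draw_pool <- function(anc, protected, gene, prefix, intron) {
      lapply(seq_len(config$n_alleles_per_parent), function(k) {
        idx <- setdiff(which(runif(L) < config$theta_site), protected)
        ch <- mutate_bases(anc, idx)
        ft <- if (intron) intron_ft else NULL
        if (intron && !is.null(config$intron_indel_lengths)) {
          ins_len <- config$intron_indel_lengths[
            (k - 1L) %% length(config$intron_indel_lengths) + 1L]
          if (ins_len > 0L) {
            mid <- floor(mean(config$intron_span))
            ch <- c(ch[seq_len(mid)], seq_chars(random_dna(ins_len)),
                    ch[(mid + 1L):L])
            ft$end <- ft$end + ins_len
          }
        }
        allele_sequence(sprintf("%s_%02d", prefix, k), chars_seq(ch),
                        gene_label = gene, features = ft)
      })
    }
    b1 <- draw_pool(anc1, prot1, "B1", "B1", TRUE)
    b2 <- draw_pool(anc2, prot2, "B2", "B2", FALSE)
    cp_log("info", "sample_parental_alleles: seed=%d, %d+%d alleles of %d bp",
           config$seed, length(b1), length(b2), L)
    list(b1 = b1, b2 = b2,
         ancestors = c(b1 = chars_seq(anc1), b2 = chars_seq(anc2)),
         footprints = fp, protected = list(b1 = prot1, b2 = prot2))
  })
}

#' Derive the diagnostic primer set from simulated parents
#'
#' Four primer pairs mirror the field assay: `screening` (B2-forward +
#' B1-reverse, amplifying only across a 5'-B2 / 3'-B1 chimeric junction),
#' the two parental pairs, and the `reciprocal` pair (B1-forward +
#' B2-reverse) that would detect the reciprocal 5'-B1 / 3'-B2 fusion.
#'
#' @param pools result of [sample_parental_alleles()].
#' @return named list of [primer_pair()] with names
#'   `screening`, `parental_b1`, `parental_b2`, `reciprocal`.
#' @export
design_diagnostic_primers <- function(pools) {
  fp <- pools$footprints
  sub0 <- function(seq, f) substr(seq, f[1] + 1L, f[2])
  b1f <- sub0(pools$ancestors[["b1"]], fp$b1f)
  b1r <- revcomp(sub0(pools$ancestors[["b1"]], fp$b1r))
  b2f <- sub0(pools$ancestors[["b2"]], fp$b2f)
  b2r <- revcomp(sub0(pools$ancestors[["b2"]], fp$b2r))
  list(screening   = primer_pair("screening", b2f, b1r),
       parental_b1 = primer_pair("parental_b1", b1f, b1r),
       parental_b2 = primer_pair("parental_b2", b2f, b2r),
       reciprocal  = primer_pair("reciprocal", b1f, b2r))
}

#' Form a chimeric allele by a single crossover
#'
#' The chimera takes positions `[0, crossover_position)` from the B2-like
#' parent and `[crossover_position, end)` — including the intron — from the
#' B1-like parent, the geometry of a 5'-B2 / 3'-B1 unequal crossing-over
#' product.  The true breakpoint and parent ids are recorded as attributes
#' for planted-truth oracles.
#'
#' @param b2_allele,b1_allele [allele_sequence()] parents on the same
#'   coordinate frame.
#' @param crossover_position 0-based position of the first B1-derived column,
#'   in `[0, length]`.
#' @param name id of the chimeric allele.
#' @return [allele_sequence()] with `gene_label = "B3"` and attributes
#'   `breakpoint`, `b1_parent`, `b2_parent`.
#' @export
make_chimera <- function(b2_allele, b1_allele, crossover_position, name) {
  stopifnot(inherits(b2_allele, "allele_sequence"),
            inherits(b1_allele, "allele_sequence"))
  p <- as.integer(crossover_position)
  lmin <- min(nchar(b2_allele$sequence), nchar(b1_allele$sequence))
  if (p < 0L || p > lmin)
    stop("make_chimera: crossover_position outside [0, ", lmin, "]")
  seq <- paste0(substr(b2_allele$sequence, 1L, p),
                substr(b1_allele$sequence, p + 1L, nchar(b1_allele$sequence)))
  ft <- b1_allele$features
  ft <- ft[ft$start >= p, , drop = FALSE]  # features 5' of the junction are B2-derived
  ch <- allele_sequence(name, seq, gene_label = "B3", features = ft)
  attr(ch, "breakpoint") <- p
  attr(ch, "b1_parent") <- b1_allele$id
  attr(ch, "b2_parent") <- b2_allele$id
  ch
}

#' Build the named chimeric-allele pool
#'
#' One chimera per entry of `config$breakpoints`, each formed from a distinct
#' pair of parental alleles (cycling through the pools) at its configured
#' crossover position.
#'
#' @param config [simulation_config()].
#' @param pools result of [sample_parental_alleles()].
#' @return named list of chimeric [allele_sequence()].
#' @export
build_chimera_pool <- function(config, pools) {
  nm <- names(config$breakpoints)
  out <- setNames(vector("list", length(nm)), nm)
  for (i in seq_along(nm)) {
    pick <- function(pool) pool[[(i - 1L) %% length(pool) + 1L]]
    out[[i]] <- make_chimera(pick(pools$b2), pick(pools$b1),
                             config$breakpoints[[i]], nm[i])
  }
  seqs <- vapply(out, `[[`, character(1), "sequence")
  if (anyDuplicated(seqs))
    stop("build_chimera_pool: two named alleles have identical sequences; ",
         "increase theta_site or spread breakpoints")
  out
}

#' Simulate regional diploid populations at the tandem locus
#'
#' For each configured region, individuals draw a genotype class from the
#' region's class frequencies.  A chimeric chromosome carries one named B3
#' allele drawn from the region's allele mixture; a parental chromosome
#' carries one B1 and one B2 allele in tandem (B1, intergenic spacer, B2),
#' so the screening primers face away from each other and the reciprocal
#' pair spans more than the PCR length cutoff.  Per-individual haplotype
#' template sequences are emitted for in-silico PCR.
#'
#' @param config [simulation_config()] with at least one region.
#' @param pools result of [sample_parental_alleles()].
#' @param chimera_pool result of [build_chimera_pool()].
#' @return list with `metadata` (data.frame: `sample_id`, `species_label`,
#'   `region`, `source`), `genotypes` (data.frame truth table: `sample_id`,
#'   `region`, `genotype_class`, `allele_1`, `allele_2`) and `templates`
#'   (named list of two-haplotype character vectors).
#' @export
simulate_population <- function(config, pools, chimera_pool) {
  stopifnot(inherits(config, "simulation_config"), length(config$regions) > 0,
            length(pools$b1) > 0, length(chimera_pool) > 0)
  classes <- c("B3/B3", "B3/par", "par/par")
  with_seed(config$seed + 1L, {
    spacer <- random_dna(config$spacer_length)
    meta <- list(); truth <- list(); templates <- list()
    for (rg in config$regions) {
      mix <- rg$allele_mixture
      if (!all(names(mix) %in% names(chimera_pool)))
        stop("simulate_population: allele_mixture references unknown allele names")
      for (i in seq_len(rg$n)) {
        sid <- sprintf("%s_%04d", rg$name, i)
        cls <- sample(classes, 1L, prob = rg$genotype_freqs[classes])
        n_chim <- c("B3/B3" = 2L, "B3/par" = 1L, "par/par" = 0L)[[cls]]
        alleles <- if (n_chim > 0L)
          sample(names(mix), n_chim, replace = TRUE, prob = mix) else character(0)
        chim_tpl <- vapply(alleles, function(a) chimera_pool[[a]]$sequence,
                           character(1))
        par_tpl <- vapply(seq_len(2L - n_chim), function(k) {
          b1 <- pools$b1[[sample.int(length(pools$b1), 1L)]]
          b2 <- pools$b2[[sample.int(length(pools$b2), 1L)]]
          paste0(b1$sequence, spacer, b2$sequence)
        }, character(1))
        meta[[sid]] <- data.frame(sample_id = sid,
                                  species_label = "H. armigera",
                                  region = rg$name, source = "field")
        truth[[sid]] <- data.frame(sample_id = sid, region = rg$name,
                                   genotype_class = cls,
                                   allele_1 = if (n_chim >= 1L) alleles[1] else NA,
                                   allele_2 = if (n_chim >= 2L) alleles[2] else NA)
        templates[[sid]] <- unname(c(chim_tpl, par_tpl))
      }
    }
    cp_log("info", "simulate_population: seed=%d, %d individuals in %d region(s)",
           config$seed + 1L, length(templates), length(config$regions))
    list(metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
         genotypes = do.call(rbind, c(truth, list(make.row.names = FALSE))),
         templates = templates)
  })
}

#' Simulate a variant matrix with a planted sweep footprint
#'
#' A phenomenological (non-coalescent) sweep model: candidate biallelic-site
#' positions are drawn uniformly at density `site_density`; each site is
#' retained with probability `1 - s * exp(-|x - center| / L)` (local
#' diversity thinning); retained sites draw a derived-allele count `k` from
#' the neutral-like `1/k` spectrum over `1..2N-1`, except that sites within
#' `L` of the center draw from a singleton-inflated spectrum (`k = 1` mass
#' boosted by `1 + 4s`, renormalised).  Derived alleles are scattered over
#' haplotypes uniformly and haplotypes are paired into diploids.
#'
#' @param config [simulation_config()]; uses `config$sweep`.
#' @return [variant_matrix()] with attribute `sweep_center` (planted truth).
#' @export
simulate_variant_matrix <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  sw <- config$sweep
  N <- as.integer(sw$sample_n)
  if (N < 2L) stop("simulate_variant_matrix: need at least 2 diploids")
  n <- 2L * N
  with_seed(config$seed + 2L, {
    L <- as.integer(sw$segment_length)
    ncand <- rpois(1L, sw$site_density * L)
    pos <- sort(sample.int(L, min(ncand, L)))
    keep <- runif(length(pos)) <
      1 - sw$strength * exp(-abs(pos - sw$sweep_center) / sw$decay_length)
    pos <- pos[keep]
    np <- length(pos)
    near <- abs(pos - sw$sweep_center) <= sw$decay_length
    w_base <- 1 / seq_len(n - 1L)
    w_near <- w_base
    w_near[1L] <- w_base[1L] * (1 + 4 * sw$strength)
    k <- integer(np)
    if (any(!near)) k[!near] <- sample.int(n - 1L, sum(!near), TRUE, prob = w_base)
    if (any(near)) k[near] <- sample.int(n - 1L, sum(near), TRUE, prob = w_near)
    geno <- matrix(0L, nrow = N, ncol = np)
    for (j in seq_len(np)) {
      hap <- sample.int(n, k[j])
      geno[, j] <- tabulate((hap + 1L) %/% 2L, nbins = N)
    }
    vm <- variant_matrix(sprintf("S%02d", seq_len(N)), pos, geno, L)
    attr(vm, "sweep_center") <- sw$sweep_center
    cp_log("info",
           "simulate_variant_matrix: seed=%d, %d/%d sites retained, center=%d",
           config$seed + 2L, np, ncand, sw$sweep_center)
    vm
  })
}

#' Simulate an intron alignment with planted single- or multi-donor origin
#'
#' Emulates the data behind a monophyly test of chimeric-allele introns.
#' `n_b1` parental intron haplotypes diverge independently from a common
#' ancestor (`b1_theta` per-site substitution each, so ~`2*b1_theta`
#' pairwise).  Each chimera-formation event copies one donor haplotype and
#' accumulates `stem_divergence` substitutions (the shared history of that
#' origin); individual chimeric introns then add `tip_divergence` each.
#' With `n_donors = 1` the chimeric introns are clade-forming (single
#' origin); with `n_donors > 1` they are planted-paraphyletic, split evenly
#' across donors drawn from distant parts of the parental pool.
#'
#' @param n_b1,n_b3 numbers of parental and chimeric intron sequences.
#' @param n_donors number of independent origins (1 = monophyletic truth).
#' @param columns alignment length.
#' @param b1_theta,stem_divergence,tip_divergence per-site substitution
#'   probabilities of the three branches described above.
#' @param seed RNG seed.
#' @return list with `alignment` (named character vector, `B1_*` then
#'   `B3_*`), `b3_labels`, and `donors` (planted truth: donor of each B3).
#' @export
simulate_origin_alignment <- function(n_b1 = 6L, n_b3 = 6L, n_donors = 1L,
                                      columns = 200L, b1_theta = 0.05,
                                      stem_divergence = 0.03,
                                      tip_divergence = 0.01, seed = 1L) {
  stopifnot(n_donors >= 1L, n_donors <= n_b1, n_b1 >= 2L, n_b3 >= 2L)
  with_seed(seed, {
    anc <- seq_chars(random_dna(columns))
    mut <- function(ch, p) mutate_bases(ch, which(runif(length(ch)) < p))
    b1 <- lapply(seq_len(n_b1), function(i) mut(anc, b1_theta))
    donor_idx <- unique(round(seq(1L, n_b1, length.out = n_donors)))
    stems <- lapply(donor_idx, function(d) mut(b1[[d]], stem_divergence))
    assign_donor <- rep(seq_along(donor_idx), length.out = n_b3)
    b3 <- lapply(seq_len(n_b3), function(j) mut(stems[[assign_donor[j]]],
                                                tip_divergence))
    aln <- c(setNames(vapply(b1, chars_seq, character(1)),
                      sprintf("B1_%02d", seq_len(n_b1))),
             setNames(vapply(b3, chars_seq, character(1)),
                      sprintf("B3_%02d", seq_len(n_b3))))
    list(alignment = aln,
         b3_labels = grep("^B3_", names(aln), value = TRUE),
         donors = sprintf("B1_%02d", donor_idx[assign_donor]))
  })
}

#' Run the whole locus simulation
#'
#' Convenience wrapper: parental pools, diagnostic primers, chimera pool and
#' regional populations from one configuration.
#'
#' @param config [simulation_config()].
#' @return list with `pools`, `primers`, `chimera_pool`, `population`.
#' @export
simulate_locus <- function(config) {
  pools <- sample_parental_alleles(config)
  primers <- design_diagnostic_primers(pools)
  chim <- build_chimera_pool(config, pools)
  pop <- if (length(config$regions)) simulate_population(config, pools, chim)
         else NULL
  list(pools = pools, primers = primers, chimera_pool = chim, population = pop)
}
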