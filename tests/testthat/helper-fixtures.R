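# Shared fixtures, built in code.

two_region_config <- function(seed = 11, n_each = 30) {
  simulation_config(
    seed = seed,
    regions = list(
      list(name = "Australasia", n = n_each,
           genotype_freqs = c("B3/B3" = 0.8, "B3/par" = 0.15, "par/par" = 0.05),
           allele_mixture = c(v1 = 0.8, v2 = 0.2)),
      list(name = "Africa", n = n_each,
           genotype_freqs = c("B3/B3" = 0.6, "B3/par" = 0.3, "par/par" = 0.1),
           allele_mixture = c(v5 = 0.8, v6 = 0.2))))
}

# small sweep config for fast replicated tests
small_sweep_config <- function(seed, segment_length = 50000, s = 0.9,
                               density = 0.2, L = 2500, N = 12) {
  simulation_config(seed = seed,
                    sweep = list(segment_length = segment_length,
                                 site_density = density, sample_n = N,
                                 sweep_center = segment_length / 2,
                                 decay_length = L, strength = s))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

minimal_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=seg1,length=500>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "sA", "sB", "sC"), collapse = "\t"),
    paste(c("seg1", "10", ".", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0|1", "1/1"), collapse = "\t"),
    paste(c("seg1", "20", ".", "C", "T,G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "0/2"), collapse = "\t"),
    paste(c("seg1", "30", ".", "G", "A", ".", "LowQual", ".", "GT",
            "0/0", "0/0", "0/1"), collapse = "\t"),
    paste(c("seg1", "40", ".", "T", "C", ".", ".", ".", "GT",
            "./.", "0/1", "1/1"), collapse = "\t"))
}
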