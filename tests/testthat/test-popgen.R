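test_that("species_filter keeps the target species and tabulates the rest", {
  meta <- data.frame(
    sample_id = sprintf("s%04d", 1:1063),
    species_label = rep(c("H. armigera", "H. zea", "C. virescens"),
                        c(999, 59, 5)))
  res <- species_filter(meta, "H. armigera")
  expect_equal(nrow(res$kept), 999L)
  expect_equal(unname(res$counts[c("H. armigera", "H. zea", "C. virescens")]),
               c(999L, 59L, 5L))
  # empty and identity cases
  empty <- species_filter(meta[0, ], "H. armigera")
  expect_equal(nrow(empty$kept), 0L)
  allt <- meta[meta$species_label == "H. armigera", ]
  expect_equal(species_filter(allt, "H. armigera")$kept, allt)
})

test_that("genotype frequencies reproduce the worked global example", {
  rec <- data.frame(genotype_class = rep(c("B3/B3", "B3/par", "par/par"),
                                         c(878, 91, 30)))
  tab <- genotype_frequency_table(rec, "global")
  expect_equal(tab$n, 999L)
  expect_equal(round(tab$carriage_pct, 1), 97.0)
  expect_equal(round(tab$pct_B3B3), 88)
  expect_equal(round(tab$pct_B3par), 9)
  expect_equal(round(tab$pct_parpar), 3)
  # single individual
  one <- genotype_frequency_table(data.frame(genotype_class = "B3/B3"), "global")
  expect_equal(c(one$pct_B3B3, one$pct_B3par, one$pct_parpar), c(100, 0, 0))
})

test_that("genotype frequencies match a brute-force recount on random tables", {
  set.seed(19)
  for (k in 1:10) {
    rec <- data.frame(
      region = sample(c("A", "B"), 200, TRUE),
      genotype_class = sample(c("B3/B3", "B3/par", "par/par", "unknown"),
                              200, TRUE))
    tab <- genotype_frequency_table(rec, "region")
    for (g in tab$group) {
      sub <- rec[rec$region == g, ]
      expect_equal(tab$n_B3B3[tab$group == g], sum(sub$genotype_class == "B3/B3"))
      expect_equal(tab$n_unknown[tab$group == g],
                   sum(sub$genotype_class == "unknown"))
      n <- sum(sub$genotype_class != "unknown")
      expect_equal(tab$carriage_pct[tab$group == g],
                   100 * sum(sub$genotype_class %in% c("B3/B3", "B3/par")) / n)
    }
  }
})

test_that("allele frequencies sum homozygote and heterozygote alleles", {
  # Europe-style example: v2 n=20, v5 n=17 -> 54% / 46%
  # 10 v2/v2 homozygotes, 8 v5/v5 homozygotes, one B3/par heterozygote
  # contributing a single v5 allele: v2 n = 20, v5 n = 17
  rec <- data.frame(region = "Europe",
                    allele_1 = rep(c("v2", "v5"), c(10, 9)),
                    allele_2 = c(rep(c("v2", "v5"), c(10, 8)), NA))
  tab <- allele_frequency_table(rec, "region")
  expect_equal(tab$count[tab$allele == "v2"], 20L)
  expect_equal(tab$count[tab$allele == "v5"], 17L)
  expect_equal(round(tab$pct[tab$allele == "v2"]), 54)
  expect_equal(round(tab$pct[tab$allele == "v5"]), 46)
  # one v1 homozygote contributes two alleles
  hom <- allele_frequency_table(
    data.frame(region = "X", allele_1 = "v1", allele_2 = "v1"), "region")
  expect_equal(hom$count, 2L)
  # synthetic mixture vs generator truth
  cfg <- two_region_config(seed = 43, n_each = 40)
  sim <- simulate_locus(cfg)
  refs <- screening_products(sim$chimera_pool, sim$primers)
  called <- screen_population(sim$population$templates, sim$primers,
                              metadata = sim$population$metadata,
                              allele_refs = refs)
  t_called <- allele_frequency_table(called, "region")
  t_truth <- allele_frequency_table(sim$population$genotypes, "region")
  expect_equal(t_called[order(t_called$group, t_called$allele), ],
               t_truth[order(t_truth$group, t_truth$allele), ],
               ignore_attr = TRUE)
})

test_that("site_diversity is the unbiased mean pairwise difference", {
  expect_equal(site_diversity(0, 10), 0)
  expect_equal(site_diversity(1, 2), 1)
  # j = 3, n = 10: direct enumeration over the 45 haplotype pairs
  hap <- c(rep(1, 3), rep(0, 7))
  diffs <- 0
  for (a in 1:9) for (b in (a + 1):10) diffs <- diffs + (hap[a] != hap[b])
  expect_equal(site_diversity(3, 10), diffs / 45)
  expect_equal(site_diversity(3, 10), 42 / 90)
})

test_that("sweep_scan matches the brute-force oracle and handles S = 0", {
  # spec toy: n = 10 haplotypes, one window with derived counts {1,1,2,5}
  vm <- variant_matrix(sprintf("s%d", 1:5), c(100, 200, 300, 400),
                       rbind(c(1, 0, 0, 2), c(0, 1, 0, 2), c(0, 0, 1, 1),
                             c(0, 0, 1, 0), c(0, 0, 0, 0)), 2500)
  ws <- sweep_scan(vm, window_bp = 2500, step_bp = 2500)
  orc <- oracle_window_stats(vm, 2500, 2500)
  expect_equal(ws$pi, orc$pi, tolerance = 1e-12)
  expect_equal(ws$tajima_d, orc$tajima_d, tolerance = 1e-12)
  expect_equal(ws$S, orc$S)
  # invariant window: pi = 0 and D undefined (NA, never 0)
  vm0 <- variant_matrix(c("a", "b"), c(10, 20),
                        rbind(c(2, 0), c(2, 0)), 5000)
  ws0 <- sweep_scan(vm0)
  expect_true(all(ws0$pi == 0))
  expect_true(all(is.na(ws0$tajima_d)))
  expect_error(sweep_scan(variant_matrix(c("a", "b"), 5, matrix(0:1, 2), 10),
                          window_bp = 10), NA)
})

test_that("sweep_scan equals the naive oracle on random matrices", {
  for (seed in 1:20) {
    vm <- random_variant_matrix(seed)
    ws <- sweep_scan(vm)
    orc <- oracle_window_stats(vm)
    expect_equal(ws$pi, orc$pi, tolerance = 1e-10)
    expect_equal(ws$tajima_d, orc$tajima_d, tolerance = 1e-10)
  }
})

test_that("pi and D are invariant to ref/alt relabeling", {
  vm <- random_variant_matrix(99)
  flip <- variant_matrix(vm$sample_ids, vm$positions, 2L - vm$geno,
                         vm$segment_length)
  expect_equal(sweep_scan(vm)$pi, sweep_scan(flip)$pi)
  expect_equal(sweep_scan(vm)$tajima_d, sweep_scan(flip)$tajima_d)
})

test_that("window tiling covers the segment with the stated overlap", {
  vm <- random_variant_matrix(7, segment_length = 9000)
  ws <- sweep_scan(vm, 2500, 1250)
  expect_equal(ws$start, seq(1, 9000, by = 1250))
  expect_true(all(ws$end - ws$start + 1 <= 2500))
  covered <- rep(FALSE, 9000)
  for (i in seq_len(nrow(ws))) covered[ws$start[i]:ws$end[i]] <- TRUE
  expect_true(all(covered))
  # consecutive full windows overlap by window - step
  full <- ws[!ws$partial, ]
  expect_true(all(pmin(full$end[-nrow(full)], full$end[-1]) -
                  full$start[-1] + 1 == 1250))
  expect_true(ws$partial[nrow(ws)])
})

test_that("sites with missing genotypes are excluded and logged", {
  g <- rbind(c(1, NA, 0), c(0, 1, 2), c(1, 0, 1))
  vm <- variant_matrix(c("a", "b", "c"), c(10, 20, 30), g, 100)
  ws <- sweep_scan(vm, 100, 100)
  expect_equal(attr(ws, "n_dropped_missing"), 1L)
  expect_equal(ws$S[1], 2L)
})

test_that("Tajima's D is centred near zero under neutral simulation", {
  ds <- vapply(1:100, function(seed) {
    cfg <- small_sweep_config(seed = 500 + seed, segment_length = 25000,
                              s = 0, density = 0.05)
    ws <- sweep_scan(simulate_variant_matrix(cfg))
    mean(ws$tajima_d, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(ds)), 0.3)
})

test_that("sweep_report summarises extrema with leftmost tie-breaking", {
  vm <- random_variant_matrix(3)
  ws <- sweep_scan(vm)
  rp <- sweep_report(ws)
  expect_equal(rp$min_pi_window$pi, min(ws$pi))
  expect_equal(rp$min_pi_window$start, ws$start[which.min(ws$pi)])
  expect_equal(rp$mean_pi, mean(ws$pi))
  # uniform windows: min equals mean
  u <- ws[1, ]
  expect_equal(sweep_report(u)$min_pi_window$pi, sweep_report(u)$mean_pi)
  # all-undefined D reported as NA, not 0
  vm0 <- variant_matrix(c("a", "b"), c(10, 20), rbind(c(0, 2), c(0, 2)), 3000)
  rp0 <- sweep_report(sweep_scan(vm0))
  expect_true(is.na(rp0$mean_d))
  expect_null(rp0$min_d_window)
  # planted sweep: argmin-pi window overlaps the planted center
  cfg <- small_sweep_config(seed = 61, s = 0.9)
  vm_s <- simulate_variant_matrix(cfg)
  rp_s <- sweep_report(sweep_scan(vm_s))
  expect_lte(rp_s$min_pi_window$start, attr(vm_s, "sweep_center"))
  expect_gte(rp_s$min_pi_window$end, attr(vm_s, "sweep_center"))
})
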