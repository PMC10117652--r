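# Filtering cascade and scan orchestration.

test_that("pre-filter applies the informativeness thresholds as printed", {
  cfg <- scan_config()
  expect_true(prefilter(fake_pair_tallies(1000, 20, 0), cfg)$pass)
  p2 <- prefilter(fake_pair_tallies(999, 100, 100), cfg)
  expect_false(p2$pass)
  expect_match(p2$reasons, "informative offspring")
  p3 <- prefilter(fake_pair_tallies(5000, 19, 49), cfg)
  expect_false(p3$pass)
  expect_match(p3$reasons, "het sires")
  expect_true(prefilter(fake_pair_tallies(1000, 0, 50), cfg)$pass)
})

test_that("deviation screen computes cell deviations against Mendelian expectations", {
  # one het-by-het mating engineered so the AABB cell is observed 20,117
  # against an expectation of 12,063; the shortfall is spread over the
  # remaining cells in proportion to their Mendelian weights
  total <- 16 * 12063
  expected_rest <- total * c(2, 1, 2, 4, 2, 1, 2, 1) / 16
  rest <- floor(expected_rest * (total - 20117) / sum(expected_rest))
  rest[1] <- rest[1] + (total - 20117 - sum(rest))
  pair <- counted_pair("AaBb", "AaBb", c(20117, rest))
  dev <- deviation_screen(pair, scan_config())
  expect_equal(dev$max_abs_deviation, 20117 - 12063)
  top <- dev$cells[which.max(abs(dev$cells$deviation)), ]
  expect_equal(top$observed, 20117)
  expect_equal(top$expected, 12063)
  expect_equal(top$rel_vs_observed, 8054 / 20117, tolerance = 1e-12)
  expect_true(dev$pass)
  # observed equal to expected everywhere -> no deviation, fail
  flat <- counted_pair("AaBb", "AaBb", c(1, 2, 1, 2, 4, 2, 1, 2, 1) * 100)
  dev0 <- deviation_screen(flat, scan_config())
  expect_equal(dev0$max_abs_deviation, 0)
  expect_false(dev0$pass)
  # absolute threshold binds even when the relative deviation is large
  pair900 <- counted_pair("AaBb", "AaBb", c(1900, 2000, 1000, 2000, 4100, 2000, 1000, 1000, 1000))
  cells <- deviation_screen(pair900, scan_config())$cells
  aabb_cell <- cells[cells$off_class == 1, ]
  expect_false(aabb_cell$pass)
})

test_that("epistatic filter combines BF threshold, BF ratio and CV rules", {
  cfg <- scan_config()
  bf <- function(direct, epi) setNames(c(direct, epi), genotypic_param_names())
  # epistatic max 6, direct max 2: ratio 10^4 > 10^3 -> pass
  f1 <- fake_fit("genotypic", bf(c(2, 1, 0, 0), c(6, 1, 0, 0)))
  expect_true(epistatic_filter(f1, cfg)$pass)
  # epistatic max 4, direct max 2: ratio 10^2 -> fail
  f2 <- fake_fit("genotypic", bf(c(2, 1, 0, 0), c(4, 1, 0, 0)))
  r2 <- epistatic_filter(f2, cfg)
  expect_false(r2$pass)
  expect_match(paste(r2$reasons, collapse = " "), "ratio")
  # significant effect with CV 0.30 -> fail
  f3 <- fake_fit("genotypic", bf(c(1, 0, 0, 0), c(6, 0, 0, 0)),
    cv = setNames(c(rep(0.01, 4), 0.30, 0.01, 0.01, 0.01), genotypic_param_names())
  )
  r3 <- epistatic_filter(f3, cfg)
  expect_false(r3$pass)
  expect_match(paste(r3$reasons, collapse = " "), "CV")
  # absent direct effects pass the ratio by convention
  f4 <- fake_fit("genotypic", bf(rep(-Inf, 4), c(6, 0, 0, 0)))
  expect_true(epistatic_filter(f4, cfg)$pass)
})

test_that("effect categories follow the winning epistatic Bayes factor", {
  bf <- function(epi) setNames(c(0, 0, 0, 0, epi), genotypic_param_names())
  expect_equal(effect_category(fake_fit("genotypic", bf(c(5, 1, 1, 1)))), "additive_by_additive")
  expect_equal(effect_category(fake_fit("genotypic", bf(c(1, 5, 1, 1)))), "additive_by_dominance_or_reverse")
  expect_equal(effect_category(fake_fit("genotypic", bf(c(1, 1, 5, 1)))), "additive_by_dominance_or_reverse")
  expect_equal(effect_category(fake_fit("genotypic", bf(c(1, 1, 1, 5)))), "dominance_by_dominance")
})

test_that("top-fraction selection keeps ceiling(0.001 n) per category with deterministic ties", {
  rows <- tibble::tibble(
    snpA = sprintf("a%05d", 1:59831), snpB = sprintf("b%05d", 1:59831),
    category = "additive_by_additive",
    max_epi_bf = rev(seq_len(59831)) / 1000
  )
  sel <- select_top(rows, scan_config())
  expect_equal(sum(sel$selected), 60L)
  expect_true(all(rank(-sel$max_epi_bf)[sel$selected] <= 60))
  rows2 <- tibble::tibble(
    snpA = c("a2", "a1", "a3"), snpB = c("b", "b", "b"),
    category = "x", max_epi_bf = c(5, 5, 1)
  )
  sel2 <- select_top(rows2, scan_config())
  expect_equal(sum(sel2$selected), 1L)
  expect_equal(sel2$snpA[sel2$selected], "a1") # lexicographically smaller tie
  # 500 rows -> ceiling(0.5) = 1 kept
  rows3 <- tibble::tibble(
    snpA = sprintf("a%03d", 1:500), snpB = "b", category = "x",
    max_epi_bf = runif(500)
  )
  expect_equal(sum(select_top(rows3, scan_config())$selected), 1L)
})

test_that("linked-SNP collapsing keeps one row per linked partner cluster", {
  set.seed(1)
  # one anchor SNP paired with 26 partners spanning ~8.25 Mb on one chromosome
  partners <- sprintf("p%02d", 1:26)
  pos <- sort(as.integer(seq(4197354, 12447484, length.out = 26)))
  map <- tibble::tibble(
    snp_id = c("anchor", partners, "q1", "q2"),
    chrom = c("17", rep("23", 26), "5", "6"),
    pos = c(39696262L, pos, 100L, 100L)
  )
  rows <- tibble::tibble(
    snpA = "anchor", snpB = partners, category = "additive_by_additive",
    max_epi_bf = runif(26, 10, 100)
  )
  out <- collapse_linked(rows, map, scan_config())
  expect_equal(nrow(out), 1L)
  expect_equal(out$max_epi_bf, max(rows$max_epi_bf))
  # partners on different chromosomes are never collapsed
  rows2 <- tibble::tibble(
    snpA = "anchor", snpB = c("q1", "q2"), category = "x",
    max_epi_bf = c(5, 7)
  )
  expect_equal(nrow(collapse_linked(rows2, map, scan_config())), 2L)
  # single row unchanged
  expect_equal(nrow(collapse_linked(rows2[1, ], map, scan_config())), 1L)
  # partners further apart than the window form separate clusters
  map3 <- tibble::tibble(
    snp_id = c("anchor", "r1", "r2"), chrom = c("1", "2", "2"),
    pos = c(1L, 1L, 20000001L)
  )
  rows3 <- tibble::tibble(
    snpA = "anchor", snpB = c("r1", "r2"), category = "x", max_epi_bf = c(1, 2)
  )
  expect_equal(nrow(collapse_linked(rows3, map3, scan_config())), 2L)
})

test_that("the filter cascade is monotone in its thresholds", {
  set.seed(42)
  tallies <- tibble::tibble(
    informative = sample(500:2000, 50, TRUE),
    sires = sample(0:40, 50, TRUE),
    dams = sample(0:100, 50, TRUE)
  )
  loose <- scan_config(
    min_informative_offspring = 800, min_het_sires = 10, min_het_dams = 30
  )
  tight <- scan_config(
    min_informative_offspring = 1200, min_het_sires = 20, min_het_dams = 60
  )
  pass_loose <- purrr::pmap_lgl(tallies, function(informative, sires, dams) {
    prefilter(fake_pair_tallies(informative, sires, dams), loose)$pass
  })
  pass_tight <- purrr::pmap_lgl(tallies, function(informative, sires, dams) {
    prefilter(fake_pair_tallies(informative, sires, dams), tight)$pass
  })
  expect_true(all(pass_loose | !pass_tight)) # tight passes imply loose passes
  # same property for the BF filter
  bfs <- replicate(50, setNames(runif(8, -1, 7), genotypic_param_names()),
    simplify = FALSE
  )
  loose_bf <- scan_config(bf_threshold = 100, epi_direct_bf_ratio = 100)
  tight_bf <- scan_config(bf_threshold = 1000, epi_direct_bf_ratio = 1000)
  for (b in bfs) {
    f <- fake_fit("genotypic", b)
    expect_true(
      epistatic_filter(f, loose_bf)$pass || !epistatic_filter(f, tight_bf)$pass
    )
  }
})

test_that("run_pair fills scan rows and honors stage chain configurations", {
  pair <- hh_pair(1500, "genotypic", genotypic_params(aa_e = 0.8), seed = 5)
  row <- run_pair(pair,
    model = "both", stage = "preliminary",
    config = scan_config(), seed = 9
  )
  expect_equal(row$stage, "preliminary")
  # the preliminary preset keeps 10,000 post-burn-in sweeps (11,000 / 1,000)
  expect_equal(row$fit[[1]]$n_kept, 10000L)
  expect_equal(row$category, "additive_by_additive")
  expect_true(is.finite(row$dic_genotypic) && is.finite(row$dic_allelic))
  expect_true(row$max_epi_bf > row$max_direct_bf)
  expect_equal(row$est_aa_e, 0.8, tolerance = 0.1)
})

test_that("a planted epistatic pair is detected among nulls end to end", {
  pairs <- c(
    lapply(1:8, function(i) pop_pair(3000 + i, "none", n_dams = 6000)),
    list(pop_pair(3100, "genotypic", list(aa_e = 0.8), n_dams = 6000))
  )
  cfg <- scan_config(min_abs_deviation = 15) # desk-scale deviation threshold
  res <- trd_scan_pairs(pairs, "genotypic",
    config = cfg,
    chain_accurate = chain_accurate(n_iter = 20000, burn_in = 2000),
    seed = 55, quiet = TRUE
  )
  expect_equal(nrow(res), 9L)
  planted <- res[9, ]
  expect_true(planted$deviation_pass)
  expect_true(planted$filter_pass)
  expect_true(planted$selected && planted$kept)
  expect_equal(planted$stage, "accurate")
  expect_equal(planted$category, "additive_by_additive")
  # nulls never survive the Bayes-factor cascade
  expect_false(any(res$filter_pass[1:8]))
})

test_that("trd_scan runs from genotype tables and respects candidate pairs", {
  sim <- simulate_trios(
    sim_config(
      n_sires = 30, n_dams = 4000, freqA = 0.5, freqB = 0.5,
      mechanism = "genotypic", mechanism_params = list(aa_e = 0.9), seed = 71
    )
  )
  cfg <- scan_config(
    min_informative_offspring = 1000, min_het_sires = 5,
    min_het_dams = 50, min_abs_deviation = 10
  )
  res <- trd_scan(sim$genotypes, sim$trios,
    model = "genotypic", config = cfg,
    chain_preliminary = chain_preliminary(),
    run_accurate = FALSE, seed = 3, quiet = TRUE
  )
  expect_equal(nrow(res), 1L)
  expect_true(res$filter_pass)
  pairs_tab <- candidate_pairs(sim$genotypes$map)
  expect_equal(nrow(pairs_tab), 1L)
  expect_equal(
    nrow(candidate_pairs(sim$genotypes$map, include_snps = "absent")), 0L
  )
})
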