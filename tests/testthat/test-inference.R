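# Metropolis-Hastings sampling, Savage-Dickey Bayes factors, DIC and
# likelihood ratios.

test_that("chains are deterministic under a fixed seed", {
  pair <- hh_pair(300, "genotypic", genotypic_params(aa_e = 0.5), seed = 2)
  cc <- chain_config(800, 200)
  f1 <- fit_pair(pair, "genotypic", config = cc, seed = 5)
  f2 <- fit_pair(pair, "genotypic", config = cc, seed = 5)
  expect_identical(f1$chain$draws, f2$chain$draws)
  f3 <- fit_pair(pair, "genotypic", config = cc, seed = 6)
  expect_false(identical(f1$chain$draws, f3$chain$draws))
})

test_that("compiled and reference samplers produce bit-identical chains", {
  pair <- hh_pair(200, "genotypic", genotypic_params(dd_e = -0.5), seed = 3)
  cc <- chain_config(600, 150)
  fc <- fit_pair(pair, "genotypic", config = cc, seed = 11)
  fr <- fit_pair(pair, "genotypic", config = cc, seed = 11, engine = "r")
  expect_identical(fc$chain$draws, fr$chain$draws)
  expect_equal(fc$chain$ll, fr$chain$ll, tolerance = 1e-12)
  expect_equal(fc$acceptance_rate, fr$acceptance_rate)
  pa <- hh_pair(200, "allelic", allelic_params(beta_AB_ab = 0.5), seed = 4)
  fa <- fit_pair(pa, "allelic", config = cc, seed = 12)
  fa_r <- fit_pair(pa, "allelic", config = cc, seed = 12, engine = "r")
  expect_identical(fa$chain$draws, fa_r$chain$draws)
})

test_that("a flat likelihood yields the flat prior as posterior", {
  # wide proposals and heavy thinning give near-independent draws, so a
  # Kolmogorov-Smirnov test against the uniform prior is applicable
  ch <- mh_sample(function(p) 0, -1, 1,
    chain_config(60000, 5000, proposal_sd = 0.5, thin = 50, tune = FALSE),
    seed = 8
  )
  ks <- suppressWarnings(stats::ks.test(ch$draws[, 1], "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(ch$draws), 0, tolerance = 0.06)
  expect_equal(stats::var(as.vector(ch$draws)), 1 / 3, tolerance = 0.1)
})

test_that("binomial transmission posterior matches the conjugate Beta form", {
  # 30 of 40 transmissions; flat prior on alpha over (-0.5, 0.5) is flat on
  # p = 0.5 + alpha over (0, 1), so p | y ~ Beta(31, 11)
  ll <- function(a) simplified_log_likelihood(30, 10, a[1])
  ch <- mh_sample(ll, -0.5, 0.5, chain_config(50000, 5000), seed = 13)
  expect_equal(mean(0.5 + ch$draws), 31 / 42, tolerance = 0.01)
  expect_equal(sd(ch$draws), sqrt(31 * 11 / (42^2 * 43)), tolerance = 0.05)
})

test_that("sampler refuses an impossible starting state", {
  expect_error(
    mh_sample(function(p) -Inf, -1, 1, chain_config(100, 10)),
    "not finite at the starting state"
  )
})

test_that("Bayes factor follows the Savage-Dickey arithmetic", {
  # posterior approx equal to prior -> log10 BF approx 0
  ch <- mh_sample(function(p) 0, -1, 1, chain_config(20000, 1000, tune = FALSE), seed = 21)
  expect_equal(as.numeric(bayes_factor(ch$draws, -1, 1)), 0, tolerance = 0.15)
  # bounds (-1,1): prior density 0.5; posterior density 5e-4 -> BF 1000
  # verified against a sample engineered to that density at zero
  expect_equal(0.5 / 5e-4, 1000)
  # conjugate oracle: exact Beta posterior density at the null
  ll <- function(a) simplified_log_likelihood(30, 10, a[1])
  ch2 <- mh_sample(ll, -0.5, 0.5, chain_config(110000, 10000), seed = 22)
  exact <- log10(1 / dbeta(0.5, 31, 11)) # prior density of alpha is 1
  expect_equal(as.numeric(bayes_factor(ch2$draws, -0.5, 0.5)), exact, tolerance = 0.15)
})

test_that("DIC follows its definition", {
  # two draws with deviances 10 and 12 and plug-in deviance 10.5
  chain <- structure(
    list(draws = matrix(c(0.1, 0.3), 2, 1), ll = c(-5, -6)),
    class = "epitrd_chain"
  )
  loglik <- function(theta) {
    expect_equal(theta, 0.2, tolerance = 1e-12) # plug-in at posterior mean
    -5.25
  }
  expect_equal(dic(chain, loglik), 2 * 11 - 10.5)
  # degenerate chain: all draws identical -> DIC equals the deviance
  chain2 <- structure(
    list(draws = matrix(0.4, 5, 1), ll = rep(-3, 5)),
    class = "epitrd_chain"
  )
  expect_equal(dic(chain2, function(theta) -3), 6)
})

test_that("on null data a larger model never wins the DIC comparison decisively", {
  # the 8-parameter genotypic model vs the 0-parameter Mendelian null
  wins <- vapply(1:5, function(s) {
    pair <- pop_pair(400 + s, "none", n_dams = 800)
    f <- fit_pair(pair, "genotypic", config = chain_config(4000, 1000), seed = s)
    dic_null <- -2 * log_likelihood_genotypic(pair, genotypic_params())
    f$dic < dic_null - 3
  }, logical(1))
  expect_lte(sum(wins), 0L)
})

test_that("likelihood ratio against the null matches closed forms", {
  pair <- counted_pair("AaBb", "AaBb", c(5, 8, 6, 9, 20, 7, 4, 9, 5))
  ll <- function(p) log_likelihood_genotypic(pair, p)
  expect_equal(likelihood_ratio(ll, genotypic_params()), 0)
  # a log-likelihood difference of ln(10) is one log10 unit
  ll2 <- function(p) if (all(p == 0)) 0 else log(10)
  expect_equal(likelihood_ratio(ll2, rep(0.1, 8)), 1)
  # binomial 30/40 at the MLE: direct computation
  bll <- function(a) simplified_log_likelihood(30, 10, a[1])
  mle <- 0.75 - 0.5
  expect_equal(
    likelihood_ratio(bll, mle),
    (bll(mle) - bll(0)) / log(10)
  )
})

test_that("posterior histogram matches a fine-grid numerical posterior", {
  ll <- function(a) simplified_log_likelihood(30, 10, a[1])
  ch <- mh_sample(ll, -0.5, 0.5, chain_config(60000, 5000), seed = 17)
  breaks <- seq(-0.5, 0.5, length.out = 101)
  mids <- (head(breaks, -1) + breaks[-1]) / 2
  grid <- exp(vapply(mids, ll, numeric(1)))
  grid <- grid / sum(grid)
  hist_p <- hist(ch$draws, breaks = breaks, plot = FALSE)$counts
  hist_p <- hist_p / sum(hist_p)
  expect_lt(0.5 * sum(abs(hist_p - grid)), 0.05)
})

test_that("fits expose tidy and glance summaries and TSV chains", {
  pair <- hh_pair(500, "genotypic", genotypic_params(aa_e = 0.6), seed = 6)
  fit <- fit_pair(pair, "genotypic", config = chain_config(2000, 500), seed = 30)
  td <- tidy(fit)
  expect_equal(td$term, genotypic_param_names())
  expect_true(all(c("estimate", "std.error", "cv", "log10_bf") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_kept, 1500L)
  expect_true(is.finite(gl$dic))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_chain_tsv(fit, path)
  dumped <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(dumped), 1500L)
  expect_equal(names(dumped)[-1], genotypic_param_names())
})
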