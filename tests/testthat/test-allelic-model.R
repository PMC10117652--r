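# Allelic (gamete-transmission) TRD model.

# independent oracle for the double-heterozygous x double-heterozygous
# mating: the ten offspring weight products re-derived term by term, with
# the two parental-origin double-heterozygous classes kept separate
oracle_hh_allelic <- function(p) {
  bA <- p[["beta_A"]]
  bB <- p[["beta_B"]]
  ABab <- p[["beta_AB_ab"]]
  AbaB <- p[["beta_Ab_aB"]]
  w <- c(
    AABB = (0.5 + bA) * (0.5 + bB) * (0.5 + bA) * (0.5 + bB) * (1 + ABab) * (1 + ABab),
    AAbb = (0.5 + bA) * (0.5 - bB) * (0.5 + bA) * (0.5 - bB) * (1 + AbaB) * (1 + AbaB),
    aaBB = (0.5 - bA) * (0.5 + bB) * (0.5 - bA) * (0.5 + bB) * (1 - AbaB) * (1 - AbaB),
    aabb = (0.5 - bA) * (0.5 - bB) * (0.5 - bA) * (0.5 - bB) * (1 - ABab) * (1 - ABab),
    AABb = 2 * (0.5 + bA) * (0.5 + bB) * (0.5 + bA) * (0.5 - bB) * (1 + ABab) * (1 + AbaB),
    aaBb = 2 * (0.5 - bA) * (0.5 + bB) * (0.5 - bA) * (0.5 - bB) * (1 - ABab) * (1 - AbaB),
    AaBB = 2 * (0.5 + bA) * (0.5 + bB) * (0.5 - bA) * (0.5 + bB) * (1 + ABab) * (1 - AbaB),
    Aabb = 2 * (0.5 + bA) * (0.5 - bB) * (0.5 - bA) * (0.5 - bB) * (1 - ABab) * (1 + AbaB),
    AaBb_cis = 2 * (0.5 + bA) * (0.5 + bB) * (0.5 - bA) * (0.5 - bB) * (1 + ABab) * (1 - ABab),
    AaBb_trans = 2 * (0.5 + bA) * (0.5 + bB) * (0.5 - bA) * (0.5 - bB) * (1 + AbaB) * (1 - AbaB)
  )
  # collapse parental origin, order as two_locus_classes(), normalize
  out <- c(
    w[["AABB"]], w[["AaBB"]], w[["aaBB"]], w[["AABb"]],
    w[["AaBb_cis"]] + w[["AaBb_trans"]],
    w[["aaBb"]], w[["AAbb"]], w[["Aabb"]], w[["aabb"]]
  )
  out / sum(out)
}

test_that("model reproduces the ten transcribed het-by-het weight products", {
  # under the factorized parameterization each parent's gamete distribution
  # is normalized separately; the oracle normalizes jointly -- equality of
  # the two normalized vectors verifies that the joint weight factorizes
  draws <- random_allelic(300, seed = 21)
  for (i in seq_len(nrow(draws))) {
    p <- draws[i, ]
    expect_equal(
      unname(offspring_probabilities_allelic("AaBb", "AaBb", p)),
      unname(oracle_hh_allelic(p)),
      tolerance = 1e-10
    )
  }
})

test_that("gamete probabilities match hand-derived cases", {
  expect_equal(
    gamete_probabilities("AaBb", allelic_params()),
    c(AB = 0.25, Ab = 0.25, aB = 0.25, ab = 0.25)
  )
  expect_equal(
    gamete_probabilities("AaBb", allelic_params(beta_AB_ab = 1)),
    c(AB = 0.5, Ab = 0.25, aB = 0.25, ab = 0)
  )
  expect_equal(
    gamete_probabilities("AABb", allelic_params(beta_B = 0.25)),
    c(AB = 0.75, Ab = 0.25)
  )
  expect_equal(gamete_probabilities("AABB", allelic_params()), c(AB = 1))
  # single-heterozygous parent uses the pairwise term of its own gametes
  g <- gamete_probabilities("AABb", allelic_params(beta_AB_Ab = 0.5))
  expect_equal(unname(g), c(1.5, 0.5) / 2)
})

test_that("null parameters reproduce the Mendelian vector for all matings", {
  p0 <- allelic_params()
  for (s in 1:9) {
    for (d in 1:9) {
      expect_equal(
        offspring_probabilities_allelic(s, d, p0),
        mendelian_offspring_distribution(s, d),
        tolerance = 1e-12
      )
    }
  }
})

test_that("offspring probabilities are valid and match the scalar path", {
  draws <- random_allelic(400, seed = 8)
  for (s in c(1L, 2L, 5L, 6L, 9L)) {
    for (d in c(2L, 4L, 5L, 8L)) {
      pr <- offspring_probability_matrix_allelic(s, d, draws)
      expect_true(all(pr >= 0))
      expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-12)
      i <- c(1L, 57L)
      for (k in i) {
        expect_equal(
          pr[k, ], offspring_probabilities_allelic(s, d, draws[k, ]),
          tolerance = 1e-12
        )
      }
    }
  }
})

test_that("derived het-by-het values under beta_AB_ab = 1 hold", {
  p <- allelic_params(beta_AB_ab = 1)
  probs <- offspring_probabilities_allelic("AaBb", "AaBb", p)
  expect_equal(unname(probs[["aabb"]]), 0) # needs an ab gamete from each parent
  expect_equal(unname(probs[["AaBb"]]), 0.125) # Ab+aB and aB+Ab only
  expect_equal(unname(probs[["AABB"]]), 0.25)
})

test_that("with no epistatic terms the model factorizes into two single-locus models", {
  # oracle: independent per-locus transmission with probability 0.5 +/- beta
  single_locus <- function(dose, beta) {
    beta <- unname(beta)
    if (dose == 1) c(`0` = 0.5 - beta, `1` = 0.5 + beta) else setNames(1, dose / 2)
  }
  draws <- random_allelic(100, seed = 31)
  draws[, 3:8] <- 0
  for (i in seq_len(nrow(draws))) {
    p <- draws[i, ]
    for (s in c(2L, 5L, 4L)) {
      for (d in c(5L, 6L, 8L)) {
        expected <- numeric(9)
        ds <- class_dosage(s)
        dd <- class_dosage(d)
        for (sa in names(single_locus(ds[, "A"], p[1]))) {
          for (sb in names(single_locus(ds[, "B"], p[2]))) {
            for (da in names(single_locus(dd[, "A"], p[1]))) {
              for (db in names(single_locus(dd[, "B"], p[2]))) {
                k <- class_index(
                  as.integer(sa) + as.integer(da),
                  as.integer(sb) + as.integer(db)
                )
                expected[k] <- expected[k] +
                  single_locus(ds[, "A"], p[1])[[sa]] *
                    single_locus(ds[, "B"], p[2])[[sb]] *
                    single_locus(dd[, "A"], p[1])[[da]] *
                    single_locus(dd[, "B"], p[2])[[db]]
              }
            }
          }
        }
        expect_equal(
          unname(offspring_probabilities_allelic(s, d, p)),
          expected,
          tolerance = 1e-12
        )
      }
    }
  }
})

test_that("allelic log-likelihood matches hand computations and the C++ path", {
  p0 <- allelic_params()
  one <- counted_pair("AaBb", "AaBb", c(0, 0, 0, 0, 1, 0, 0, 0, 0))
  expect_equal(log_likelihood_allelic(one, p0), log(4 / 16))
  # zero-probability observed class
  obs_aabb <- counted_pair("AaBb", "AaBb", c(0, 0, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(log_likelihood_allelic(obs_aabb, allelic_params(beta_AB_ab = 1)), -Inf)
  # likelihood factorizes over matings
  pair <- pop_pair(4, "allelic", list(beta_AB_ab = 0.4), n_dams = 300, keep_trios = TRUE)
  p <- random_allelic(1, seed = 2)[1, ]
  cnt <- pair_count_matrix(pair)
  by_hand <- 0
  for (i in seq_len(nrow(cnt$counts))) {
    pr <- offspring_probabilities_allelic(cnt$sire_class[i], cnt$dam_class[i], p)
    keep <- cnt$counts[i, ] > 0
    by_hand <- by_hand + sum(cnt$counts[i, keep] * log(pr[keep]))
  }
  expect_equal(log_likelihood_allelic(pair, p), by_hand, tolerance = 1e-10)
  expect_equal(
    epitrd:::.allelic_loglik_cpp(
      cnt$counts,
      epitrd:::.dose_a(cnt$sire_class), epitrd:::.dose_b(cnt$sire_class),
      epitrd:::.dose_a(cnt$dam_class), epitrd:::.dose_b(cnt$dam_class), p
    ),
    by_hand,
    tolerance = 1e-9
  )
})

test_that("allelic parameter bounds are enforced", {
  expect_error(allelic_params(beta_A = 0.6), "bounds")
  expect_silent(allelic_params(beta_AB_ab = -1))
})
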