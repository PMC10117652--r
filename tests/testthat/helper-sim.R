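# Shared fixture builders (everything is generated in code).

# a pair where every trio is a double-heterozygous x double-heterozygous
# mating, offspring drawn from the given model's class distribution
hh_pair <- function(n, model = c("genotypic", "allelic", "mendelian"),
                    params = NULL, seed = 1) {
  model <- match.arg(model)
  set.seed(seed)
  p <- switch(model,
    mendelian = mendelian_offspring_distribution("AaBb", "AaBb"),
    genotypic = offspring_probabilities("AaBb", "AaBb", params),
    allelic = offspring_probabilities_allelic("AaBb", "AaBb", params)
  )
  cls <- sample.int(9L, n, replace = TRUE, prob = p)
  tr <- tibble::tibble(
    offspring_id = sprintf("O%06d", seq_len(n)),
    sire_id = sprintf("S%03d", rep(seq_len(50), length.out = n)),
    dam_id = sprintf("D%06d", seq_len(n)),
    sire_class = 5L, dam_class = 5L, off_class = cls
  )
  pair_trio_data(tr)
}

# a full half-sib population pair under a simulation mechanism
pop_pair <- function(seed, mechanism = "none", params = NULL,
                     n_sires = 50, n_dams = 2000, freq = 0.5,
                     keep_trios = FALSE, snpA = "snpA", snpB = "snpB") {
  cfg <- sim_config(
    n_sires = n_sires, n_dams = n_dams, freqA = freq, freqB = freq,
    mechanism = mechanism, mechanism_params = params, seed = seed
  )
  simulate_offspring(simulate_parents(cfg), cfg,
    snpA = snpA, snpB = snpB, keep_trios = keep_trios
  )
}

# a pair object with prescribed filter tallies (pre-filter unit tests)
fake_pair_tallies <- function(n_informative, n_het_sires, n_het_dams) {
  structure(
    list(
      snpA = "a", snpB = "b",
      n_informative_offspring = n_informative,
      n_het_sires = n_het_sires, n_het_dams = n_het_dams
    ),
    class = "epitrd_pair"
  )
}

# a single-mating pair with explicitly prescribed offspring counts
counted_pair <- function(sire, dam, counts, snpA = "snpA", snpB = "snpB") {
  if (is.character(sire)) sire <- match(sire, two_locus_classes())
  if (is.character(dam)) dam <- match(dam, two_locus_classes())
  cls <- rep(seq_len(9L), counts)
  n <- length(cls)
  tr <- tibble::tibble(
    offspring_id = sprintf("O%06d", seq_len(n)),
    sire_id = "S001", dam_id = sprintf("D%06d", seq_len(n)),
    sire_class = as.integer(sire), dam_class = as.integer(dam),
    off_class = cls
  )
  pair_trio_data(tr, snpA = snpA, snpB = snpB)
}

# a minimal fit-like object for filter arithmetic tests
fake_fit <- function(model, log10_bf, cv = rep(0.05, length(log10_bf)),
                     estimate = rep(0.5, length(log10_bf))) {
  params <- if (model == "genotypic") genotypic_param_names() else allelic_param_names()
  stopifnot(length(log10_bf) == length(params))
  structure(
    list(
      model = model, params = params,
      log10_bf = setNames(log10_bf, params),
      cv = setNames(cv, params), estimate = setNames(estimate, params)
    ),
    class = "epitrd_fit"
  )
}

# random valid parameter matrices
random_genotypic <- function(n, seed = 1) {
  set.seed(seed)
  matrix(runif(n * 8, -1, 1), ncol = 8, dimnames = list(NULL, genotypic_param_names()))
}
random_allelic <- function(n, seed = 1) {
  set.seed(seed)
  cbind(
    matrix(runif(n * 2, -0.5, 0.5), ncol = 2),
    matrix(runif(n * 6, -1, 1), ncol = 6)
  ) |> `colnames<-`(allelic_param_names())
}

# brute-force oracle: per-trio probability of the target double homozygote
# by enumerating all 16 ordered gamete combinations
oracle_expected <- function(pair, h) {
  ha <- if (substr(h, 1, 1) == "A") 1L else 0L
  hb <- if (substr(h, 2, 2) == "B") 1L else 0L
  target <- class_index(2L * ha, 2L * hb)
  gametes <- function(cls) {
    d <- class_dosage(cls)
    a <- if (d[, "A"] == 1) c(0L, 1L) else rep(d[, "A"] / 2L, 2)
    b <- if (d[, "B"] == 1) c(0L, 1L) else rep(d[, "B"] / 2L, 2)
    expand.grid(a = a, b = b) # 4 equally likely phase-expanded gametes
  }
  total <- 0
  cnt <- pair$counts
  for (i in seq_len(nrow(cnt))) {
    gs <- gametes(cnt$sire_class[i])
    gd <- gametes(cnt$dam_class[i])
    p <- 0
    for (u in seq_len(4)) {
      for (v in seq_len(4)) {
        k <- class_index(gs$a[u] + gd$a[v], gs$b[u] + gd$b[v])
        if (k == target) p <- p + 1 / 16
      }
    }
    total <- total + cnt$n[i] * p
  }
  total
}

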