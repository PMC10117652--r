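# Seeded synthetic trio generator.
#
# Emulates the livestock half-sib design: few sires mated to many dams with
# unbalanced family sizes, parent genotypes drawn from Hardy-Weinberg
# proportions at two unlinked loci, and offspring drawn under a configurable
# distortion mechanism.

#' Simulation configuration
#'
#' @param n_sires,n_dams,offspring_per_dam Population design. The default
#'   desk-scale preset (50 sires x 2,000 dams x 1 offspring) yields pair
#'   data of the same informative-offspring order of magnitude as the scan
#'   pre-filter while simulating in well under a second.
#' @param family_imbalance Gamma/Dirichlet concentration of sire usage:
#'   small values give a few heavily used sires (as in dairy cattle),
#'   large values approach balanced usage. Default 1.
#' @param freqA,freqB Capital-allele frequencies in (0, 1); default 0.30
#'   (a typical intermediate-frequency array SNP).
#' @param mechanism Distortion mechanism: `"none"`, `"genotypic"`,
#'   `"allelic"`, `"viability"` or `"recessive_lethal"`.
#' @param mechanism_params Mechanism parameters: a [genotypic_params()]
#'   vector, an [allelic_params()] vector, a length-9 per-class survival
#'   vector (`viability`), or `list(haplotype =, penetrance =)`
#'   (`recessive_lethal`). Ignored for `"none"`.
#' @param survival_mode For viability-type mechanisms: `"drop"` (default;
#'   non-surviving trios are removed, the biologically faithful behaviour
#'   since the distortion likelihood conditions on observed offspring) or
#'   `"redraw"` (offspring re-drawn until survival, keeping the trio count
#'   fixed; distributionally equal to sampling the survival-weighted
#'   Mendelian vector).
#' @param seed Optional integer seed.
#' @return List of class `epitrd_sim_config`.
#' @export
sim_config <- function(n_sires = 50, n_dams = 2000, offspring_per_dam = 1,
                       family_imbalance = 1, freqA = 0.30, freqB = 0.30,
                       mechanism = c(
                         "none", "genotypic", "allelic",
                         "viability", "recessive_lethal"
                       ),
                       mechanism_params = NULL,
                       survival_mode = c("drop", "redraw"),
                       seed = NULL) {
  mechanism <- match.arg(mechanism)
  survival_mode <- match.arg(survival_mode)
  stopifnot(
    n_sires >= 1, n_dams >= 1, offspring_per_dam >= 1,
    family_imbalance > 0,
    freqA > 0, freqA < 1, freqB > 0, freqB < 1
  )
  if (mechanism == "genotypic") {
    mechanism_params <- do.call(genotypic_params, as.list(mechanism_params))
  }
  if (mechanism == "allelic") {
    mechanism_params <- do.call(allelic_params, as.list(mechanism_params))
  }
  if (mechanism == "viability") {
    stopifnot(
      length(mechanism_params) == 9,
      all(mechanism_params >= 0), all(mechanism_params <= 1)
    )
  }
  if (mechanism == "recessive_lethal") {
    stopifnot(
      is.list(mechanism_params),
      mechanism_params$haplotype %in% gamete_labels(),
      mechanism_params$penetrance >= 0, mechanism_params$penetrance <= 1
    )
  }
  structure(
    list(
      n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
      offspring_per_dam = as.integer(offspring_per_dam),
      family_imbalance = family_imbalance,
      freqA = freqA, freqB = freqB,
      mechanism = mechanism, mechanism_params = mechanism_params,
      survival_mode = survival_mode, seed = seed
    ),
    class = "epitrd_sim_config"
  )
}

#' Simulate the parental generation
#'
#' Parent genotypes are drawn per locus from Hardy-Weinberg proportions at
#' `freqA`/`freqB` independently (the loci sit on different chromosomes);
#' dams are assigned to sires with Dirichlet-weighted usage controlled by
#' `family_imbalance`.
#'
#' @param config A [sim_config()].
#' @return List with `sires`, `dams` (tibbles: `id`, `dose_a`, `dose_b`)
#'   and `pedigree` (tibble: `offspring_id`, `sire_id`, `dam_id`).
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "epitrd_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sires <- tibble::tibble(
    id = sprintf("S%04d", seq_len(config$n_sires)),
    dose_a = rbinom(config$n_sires, 2, config$freqA),
    dose_b = rbinom(config$n_sires, 2, config$freqB)
  )
  dams <- tibble::tibble(
    id = sprintf("D%05d", seq_len(config$n_dams)),
    dose_a = rbinom(config$n_dams, 2, config$freqA),
    dose_b = rbinom(config$n_dams, 2, config$freqB)
  )
  w <- rgamma(config$n_sires, shape = config$family_imbalance)
  dam_sire <- sample(sires$id, config$n_dams, replace = TRUE, prob = w / sum(w))
  ped <- tibble::tibble(
    dam_id = rep(dams$id, each = config$offspring_per_dam),
    sire_id = rep(dam_sire, each = config$offspring_per_dam)
  ) |>
    dplyr::mutate(offspring_id = sprintf("O%06d", dplyr::row_number())) |>
    dplyr::select("offspring_id", "sire_id", "dam_id")
  list(sires = sires, dams = dams, pedigree = ped)
}

# per-mating offspring-class distribution under a mechanism
.mechanism_distribution <- function(sire_class, dam_class, config) {
  mend <- .mendelian_all_matings()[mating_index(sire_class, dam_class), ]
  switch(config$mechanism,
    none = mend,
    genotypic = offspring_probabilities(sire_class, dam_class, config$mechanism_params),
    allelic = offspring_probabilities_allelic(sire_class, dam_class, config$mechanism_params),
    viability = ,
    recessive_lethal = mend # survival applied separately
  )
}

.survival_vector <- function(config) {
  if (config$mechanism == "viability") {
    return(as.numeric(config$mechanism_params))
  }
  h <- config$mechanism_params$haplotype
  target <- class_index(
    2L * .gamete_alleles[h, 1],
    2L * .gamete_alleles[h, 2]
  )
  s <- rep(1, 9)
  s[target] <- 1 - config$mechanism_params$penetrance
  s
}

#' Simulate offspring for a SNP pair
#'
#' Draws each trio's offspring class from the mechanism-specific
#' distribution: Mendelian for `"none"`, the genotypic or allelic TRD model
#' vector for those mechanisms, and Mendelian followed by per-class
#' survival for the viability mechanisms (dropping or re-drawing
#' non-survivors according to `survival_mode`).
#'
#' @param parents Output of [simulate_parents()].
#' @param config The same [sim_config()].
#' @param snpA,snpB SNP identifiers for the resulting pair data.
#' @param keep_trios Retain per-trio records in the result.
#' @return An `epitrd_pair`; the number of dropped trios (viability, drop
#'   mode) is recorded in its exclusion table as `"did_not_survive"`.
#' @export
simulate_offspring <- function(parents, config, snpA = "snpA", snpB = "snpB",
                               keep_trios = TRUE) {
  stopifnot(inherits(config, "epitrd_sim_config"))
  ped <- parents$pedigree
  sire_class <- class_index(
    parents$sires$dose_a[match(ped$sire_id, parents$sires$id)],
    parents$sires$dose_b[match(ped$sire_id, parents$sires$id)]
  )
  dam_class <- class_index(
    parents$dams$dose_a[match(ped$dam_id, parents$dams$id)],
    parents$dams$dose_b[match(ped$dam_id, parents$dams$id)]
  )
  mat <- mating_index(sire_class, dam_class)
  off_class <- integer(nrow(ped))
  viability <- config$mechanism %in% c("viability", "recessive_lethal")
  surv <- if (viability) .survival_vector(config) else NULL
  for (m in sort(unique(mat))) {
    idx <- which(mat == m)
    s <- ((m - 1L) %/% 9L) + 1L
    d <- ((m - 1L) %% 9L) + 1L
    p <- .mechanism_distribution(s, d, config)
    if (viability && config$survival_mode == "redraw") {
      p <- p * surv
      if (sum(p) <= 0) {
        stop(sprintf(
          "degenerate offspring distribution for mating %s x %s",
          two_locus_classes()[s], two_locus_classes()[d]
        ), call. = FALSE)
      }
      p <- p / sum(p)
    }
    if (sum(p) <= 0) {
      stop(sprintf(
        "degenerate offspring distribution for mating %s x %s",
        two_locus_classes()[s], two_locus_classes()[d]
      ), call. = FALSE)
    }
    off_class[idx] <- sample.int(9L, length(idx), replace = TRUE, prob = p)
  }
  keep <- rep(TRUE, nrow(ped))
  if (viability && config$survival_mode == "drop") {
    keep <- runif(nrow(ped)) < surv[off_class]
  }
  excluded <- tibble::tibble(
    reason = "did_not_survive", n = sum(!keep)
  )[sum(!keep) > 0, ]
  trios <- tibble::tibble(
    offspring_id = ped$offspring_id, sire_id = ped$sire_id, dam_id = ped$dam_id,
    sire_class = sire_class, dam_class = dam_class, off_class = off_class
  )[keep, ]
  pair_trio_data(trios,
    snpA = snpA, snpB = snpB, excluded = excluded,
    keep_trios = keep_trios
  )
}

#' Simulate a complete two-SNP trio dataset
#'
#' Convenience wrapper: simulates parents and offspring and expands the
#' result into genotype and trio tables (plus the truth record), ready for
#' the file-based pipeline.
#'
#' @param config A [sim_config()].
#' @param snpA,snpB,chromA,chromB,posA,posB Identity and map coordinates of
#'   the two simulated SNPs.
#' @return List with `genotypes` (`epitrd_genotypes`), `trios` (tibble),
#'   `pair` (`epitrd_pair`) and `truth` (see [truth_record()]).
#' @export
simulate_trios <- function(config, snpA = "snpA", snpB = "snpB",
                           chromA = "1", chromB = "2",
                           posA = 1000L, posB = 2000L) {
  parents <- simulate_parents(config)
  pair <- simulate_offspring(parents, config, snpA = snpA, snpB = snpB)
  tabs <- pair_to_tables(pair,
    chromA = chromA, chromB = chromB,
    posA = posA, posB = posB
  )
  list(
    genotypes = tabs$genotypes, trios = tabs$trios, pair = pair,
    truth = truth_record(config)
  )
}

#' Truth record of a simulation
#'
#' Serializes the generating mechanism and parameters (for recovery
#' scoring), optionally to YAML on disk.
#'
#' @param config A [sim_config()].
#' @param path Optional YAML output path.
#' @return The truth list, invisibly when written to `path`.
#' @export
truth_record <- function(config, path = NULL) {
  stopifnot(inherits(config, "epitrd_sim_config"))
  params <- config$mechanism_params
  truth <- list(
    mechanism = config$mechanism,
    params = if (is.null(params)) {
      list()
    } else if (is.list(params)) {
      params
    } else {
      as.list(params)
    },
    n_sires = config$n_sires, n_dams = config$n_dams,
    offspring_per_dam = config$offspring_per_dam,
    freqA = config$freqA, freqB = config$freqB,
    seed = config$seed
  )
  if (!is.null(path)) {
    yaml::write_yaml(truth, path)
    return(invisible(truth))
  }
  truth
}

#' Read a truth record back
#'
#' @param path YAML path written by [truth_record()].
#' @return The truth list.
#' @export
read_truth <- function(path) yaml::read_yaml(path)
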