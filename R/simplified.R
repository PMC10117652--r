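# Simplified biallelic artificial-haplotype screen.
#
# Treats one two-SNP gamete ("artificial haplotype" j) against all
# alternatives with a single overall transmission parameter alpha_j:
# P(transmit j) = 0.5 + alpha_j for an informative parent. Only parents
# heterozygous at exactly one of the two loci that carry j are informative:
# such a parent has exactly two possible gametes (j and one alternative), so
# the Mendelian null of 1/2 is correct. Unphased double-heterozygous
# parents (null transmission 1/4 per specific gamete) are left to the full
# allelic model.

#' Transmission counts of an artificial haplotype
#'
#' Counts transmissions of gamete `j` from informative parents. A parent is
#' informative when heterozygous at exactly one of the two loci and carrying
#' `j`. The transmitted gamete is deduced from the offspring genotype given
#' the other parent; when the deduction is ambiguous (other parent also
#' heterozygous at the same locus and offspring heterozygous) the
#' parent-offspring event is skipped and tallied.
#'
#' @param pair An `epitrd_pair` retaining its per-trio table.
#' @param j Artificial haplotype: one of `"AB"`, `"Ab"`, `"aB"`, `"ab"`.
#' @return List with `n_transmitted`, `n_alternative`,
#'   `n_informative_parents` (distinct parents contributing a deduced
#'   transmission) and `n_ambiguous` (skipped events).
#' @export
simplified_transmission_counts <- function(pair, j) {
  stopifnot(inherits(pair, "epitrd_pair"))
  if (is.null(pair$trios)) {
    stop("pair does not retain per-trio records (rebuild with keep_trios = TRUE)",
      call. = FALSE
    )
  }
  j <- match.arg(j, gamete_labels())
  ja <- .gamete_alleles[j, 1]
  jb <- .gamete_alleles[j, 2]
  tr <- pair$trios
  tally <- function(par_class, other_class, par_id) {
    pd <- .class_dosage[par_class, , drop = FALSE]
    od <- .class_dosage[other_class, , drop = FALSE]
    offd <- .class_dosage[tr$off_class, , drop = FALSE]
    hetA <- pd[, "A"] == 1L
    hetB <- pd[, "B"] == 1L
    one_het <- xor(hetA, hetB)
    carries <- (hetA | pd[, "A"] == 2L * ja) & (hetB | pd[, "B"] == 2L * jb)
    info <- one_het & carries
    # deduce the transmitted allele at the parent's heterozygous locus
    het_is_A <- hetA
    off_dose <- ifelse(het_is_A, offd[, "A"], offd[, "B"])
    oth_dose <- ifelse(het_is_A, od[, "A"], od[, "B"])
    oth_het <- oth_dose == 1L
    x <- rep(NA_integer_, nrow(tr))
    x[off_dose == 0L] <- 0L
    x[off_dose == 2L] <- 1L
    amb <- off_dose == 1L & oth_het
    x[off_dose == 1L & !oth_het] <- 1L - as.integer(oth_dose[off_dose == 1L & !oth_het] / 2L)
    j_allele_at_het <- ifelse(het_is_A, ja, jb)
    transmitted_j <- x == j_allele_at_het
    list(
      n_t = sum(info & !amb & transmitted_j, na.rm = TRUE),
      n_a = sum(info & !amb & !transmitted_j, na.rm = TRUE),
      n_amb = sum(info & amb),
      parents = unique(par_id[info & !amb])
    )
  }
  s <- tally(tr$sire_class, tr$dam_class, tr$sire_id)
  d <- tally(tr$dam_class, tr$sire_class, tr$dam_id)
  list(
    n_transmitted = s$n_t + d$n_t,
    n_alternative = s$n_a + d$n_a,
    n_informative_parents = length(s$parents) + length(d$parents),
    n_ambiguous = s$n_amb + d$n_amb
  )
}

#' Log-likelihood of the simplified transmission model
#'
#' Binomial transmission with probability `0.5 + alpha_j` for the designated
#' haplotype and `0.5 - alpha_j` for the alternative.
#'
#' @param n_j,n_alt Transmission counts of the haplotype and its
#'   alternative.
#' @param alpha_j Overall distortion in `(-0.5, 0.5)` (boundaries allowed
#'   only when the opposing count is zero).
#' @return Scalar log-likelihood (`-Inf` at a contradicted boundary).
#' @export
simplified_log_likelihood <- function(n_j, n_alt, alpha_j) {
  stopifnot(n_j >= 0, n_alt >= 0, abs(alpha_j) <= 0.5)
  term <- function(n, p) if (n == 0) 0 else if (p <= 0) -Inf else n * log(p)
  term(n_j, 0.5 + alpha_j) + term(n_alt, 0.5 - alpha_j)
}

#' Fit the simplified artificial-haplotype model
#'
#' Samples the single overall distortion parameter of haplotype `j` with
#' the reference Metropolis-Hastings sampler and summarizes the posterior.
#'
#' @inheritParams simplified_transmission_counts
#' @param config A [chain_config()]; defaults to the simplified preset
#'   (110,000 sweeps, 10,000 burn-in).
#' @param seed Optional integer seed.
#' @return An `epitrd_fit` with a single term `alpha_j`.
#' @export
fit_simplified <- function(pair, j, config = chain_simplified(), seed = NULL) {
  cnts <- simplified_transmission_counts(pair, j)
  fit_simplified_counts(cnts$n_transmitted, cnts$n_alternative,
    config = config, seed = seed,
    snpA = pair$snpA, snpB = pair$snpB, haplotype = j,
    n_informative = cnts$n_informative_parents
  )
}

#' Fit the simplified model from raw transmission counts
#'
#' @inheritParams simplified_log_likelihood
#' @inheritParams fit_simplified
#' @param snpA,snpB,haplotype Identifiers carried into the result.
#' @param n_informative Informative-parent count carried into the result.
#' @return An `epitrd_fit` with a single term `alpha_j`.
#' @export
fit_simplified_counts <- function(n_j, n_alt, config = chain_simplified(),
                                  seed = NULL, snpA = "snpA", snpB = "snpB",
                                  haplotype = NA_character_,
                                  n_informative = n_j + n_alt) {
  loglik <- function(p) simplified_log_likelihood(n_j, n_alt, p[1])
  chain <- mh_sample(loglik, -0.5, 0.5, config, seed = seed)
  colnames(chain$draws) <- "alpha_j"
  bounds <- list(params = "alpha_j", lower = -0.5, upper = 0.5)
  fake_pair <- list(snpA = snpA, snpB = snpB, n_informative_offspring = n_j + n_alt)
  fit <- .summarize_fit(chain, loglik, bounds, "simplified", fake_pair, config)
  fit$haplotype <- haplotype
  fit$n_transmitted <- n_j
  fit$n_alternative <- n_alt
  fit$n_informative_parents <- n_informative
  fit
}

#' Screen all four artificial haplotypes of a pair
#'
#' @inheritParams fit_simplified
#' @param haplotypes Haplotypes to screen (default all four).
#' @return Tibble with one row per haplotype: counts, posterior mean
#'   `alpha_j`, SD, log10 BF and the implied under/over-represented
#'   offspring count (`|alpha_j| * 2 * informative transmissions`).
#' @export
simplified_screen <- function(pair, haplotypes = gamete_labels(),
                              config = chain_simplified(), seed = NULL) {
  purrr::map_dfr(haplotypes, function(j) {
    fit <- fit_simplified(pair, j, config = config, seed = seed)
    tibble::tibble(
      snpA = pair$snpA, snpB = pair$snpB, haplotype = j,
      n_transmitted = fit$n_transmitted, n_alternative = fit$n_alternative,
      alpha_j = unname(fit$estimate), sd = unname(fit$sd),
      log10_bf = unname(fit$log10_bf),
      deviation_count = abs(unname(fit$estimate)) * 2 *
        (fit$n_transmitted + fit$n_alternative)
    )
  })
}

#' Promote simplified-screen candidates
#'
#' A screened artificial haplotype is promoted to full-model re-analysis
#' when it explains materially more distortion than the better of its two
#' component SNPs alone: the haplotype's |TRD| must exceed the single-SNP
#' |TRD| by at least `min_increase`, and its implied under/over-represented
#' offspring count (|TRD| x 2 x informative transmissions) must be no
#' smaller than the single SNP's.
#'
#' @param candidates Tibble with columns `ah_trd`, `ah_informative`
#'   (haplotype TRD estimate and informative transmission count) and
#'   `snp_trd`, `snp_informative` (same for the reference single SNP).
#' @param min_increase Minimum gain in |TRD| magnitude (default 0.05).
#' @return The input with columns `ah_deviation`, `snp_deviation` and
#'   logical `promoted` appended.
#' @export
promote_candidates <- function(candidates, min_increase = 0.05) {
  candidates |>
    dplyr::mutate(
      ah_deviation = abs(.data$ah_trd) * 2 * .data$ah_informative,
      snp_deviation = abs(.data$snp_trd) * 2 * .data$snp_informative,
      promoted = abs(.data$ah_trd) >= abs(.data$snp_trd) + min_increase &
        .data$ah_deviation >= .data$snp_deviation
    )
}
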