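# Recessive epistatic TRD: depletion of double-homozygous offspring.
#
# For a target artificial haplotype h the screen sums, over trios, the
# Mendelian probability that the offspring is homozygous for h at both loci
# (the product over loci and parents of each parent's transmission
# probability of the h allele), and flags pairs where that expectation is
# large yet no such offspring is observed -- while all other offspring
# classes in the carrier matings conform to Mendelian proportions.

# P(parent transmits the h allele at one locus): dose of h allele / 2
.h_transmission <- function(dose, h_allele) {
  hd <- if (h_allele == 1) dose else 2L - dose
  hd / 2
}

#' Expected and observed double-homozygous offspring
#'
#' @param pair An `epitrd_pair`.
#' @param haplotype Target gamete (`"AB"`, `"Ab"`, `"aB"` or `"ab"`); the
#'   target offspring class is the double homozygote for its two alleles.
#' @return List with `expected` (sum of per-trio Mendelian probabilities),
#'   `observed` (offspring count in the target class), `target_class`, and
#'   `breakdown`: a per-mating tibble of observed vs expected offspring in
#'   the target class restricted to carrier matings (both parents able to
#'   transmit the haplotype).
#' @export
expected_double_homozygotes <- function(pair, haplotype) {
  stopifnot(inherits(pair, "epitrd_pair"))
  h <- match.arg(haplotype, gamete_labels())
  ha <- .gamete_alleles[h, 1]
  hb <- .gamete_alleles[h, 2]
  target <- class_index(2L * ha, 2L * hb)
  cnt <- pair$counts
  per_mating <- cnt |>
    dplyr::group_by(.data$mating, .data$sire_class, .data$dam_class) |>
    dplyr::summarise(
      n_trios = sum(.data$n),
      observed = sum(.data$n[.data$off_class == target]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p_target = .h_transmission(.class_dosage[.data$sire_class, "A"], ha) *
        .h_transmission(.class_dosage[.data$dam_class, "A"], ha) *
        .h_transmission(.class_dosage[.data$sire_class, "B"], hb) *
        .h_transmission(.class_dosage[.data$dam_class, "B"], hb),
      expected = .data$n_trios * .data$p_target
    )
  list(
    expected = sum(per_mating$expected),
    observed = sum(per_mating$observed),
    target_class = two_locus_classes()[target],
    breakdown = dplyr::filter(per_mating, .data$p_target > 0)
  )
}

# Mendelian conformity of the non-target classes within carrier matings:
# |observed - expected| <= max(tolerance * expected, z * sqrt(expected)),
# with z set by a Bonferroni bound at familywise level 1% over all checked
# cells (a fixed per-cell z would reject true lethals just through the
# number of cells examined)
.mendelian_conformity <- function(pair, target, carrier_matings, tolerance) {
  if (!length(carrier_matings)) {
    return(TRUE)
  }
  cnt <- dplyr::filter(pair$counts, .data$mating %in% carrier_matings)
  mend <- .mendelian_all_matings()
  totals <- cnt |>
    dplyr::group_by(.data$mating) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  n_cells <- sum(vapply(totals$mating, function(m) {
    sum(mend[m, ] > 0) - (mend[m, target] > 0)
  }, numeric(1)))
  z <- stats::qnorm(1 - 0.01 / (2 * max(n_cells, 1)))
  for (i in seq_len(nrow(totals))) {
    m <- totals$mating[i]
    exp_all <- totals$n[i] * mend[m, ]
    obs_all <- numeric(9)
    sub <- cnt[cnt$mating == m, ]
    obs_all[sub$off_class] <- sub$n
    for (g in seq_len(9)) {
      if (g == target || exp_all[g] == 0) next
      if (abs(obs_all[g] - exp_all[g]) >
        max(tolerance * exp_all[g], z * sqrt(exp_all[g]))) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# frequency of haplotype h among parental gametes, assuming independence of
# the two loci (allele frequencies among distinct parents)
.haplotype_frequency <- function(pair, ha, hb) {
  tr <- pair$trios
  if (is.null(tr)) {
    # fall back to trio-weighted parent classes from the counts
    par_classes <- c(
      rep(pair$counts$sire_class, pair$counts$n),
      rep(pair$counts$dam_class, pair$counts$n)
    )
    d <- .class_dosage[par_classes, , drop = FALSE]
  } else {
    parents <- dplyr::bind_rows(
      dplyr::distinct(tr, id = .data$sire_id, class = .data$sire_class),
      dplyr::distinct(tr, id = .data$dam_id, class = .data$dam_class)
    )
    d <- .class_dosage[parents$class, , drop = FALSE]
  }
  fa <- mean(d[, "A"]) / 2
  fb <- mean(d[, "B"]) / 2
  (if (ha == 1) fa else 1 - fa) * (if (hb == 1) fb else 1 - fb)
}

#' Scan SNP pairs for recessive epistatic TRD
#'
#' Flags pairs with a depleted double-homozygous offspring class: expected
#' count at least `min_expected` under Mendelian transmission, zero
#' observed, and every other offspring class of the carrier matings within
#' Mendelian conformity (absolute deviation at most
#' `max(mendelian_tolerance * expected, 3 * sqrt(expected))`).
#'
#' @param pairs A single `epitrd_pair` or a list of them.
#' @param haplotypes Gametes to screen per pair (default all four).
#' @param min_expected Minimum expected unobserved double homozygotes
#'   (default 15).
#' @param mendelian_tolerance Relative tolerance of the conformity check
#'   (default 0.10).
#' @return Tibble with one row per (pair, haplotype): expected and observed
#'   counts, heterozygous-parent tallies, haplotype frequency, conformity
#'   flag, `flagged` status and the per-mating breakdown as a list column.
#' @export
recessive_scan <- function(pairs, haplotypes = gamete_labels(),
                           min_expected = 15, mendelian_tolerance = 0.10) {
  if (inherits(pairs, "epitrd_pair")) pairs <- list(pairs)
  purrr::map_dfr(pairs, function(pair) {
    purrr::map_dfr(haplotypes, function(h) {
      ha <- .gamete_alleles[h, 1]
      hb <- .gamete_alleles[h, 2]
      res <- expected_double_homozygotes(pair, h)
      target <- match(res$target_class, two_locus_classes())
      ok <- .mendelian_conformity(
        pair, target, res$breakdown$mating, mendelian_tolerance
      )
      tibble::tibble(
        snpA = pair$snpA, snpB = pair$snpB,
        haplotype = h, target_genotype = res$target_class,
        expected = res$expected, observed = res$observed,
        n_het_sires = pair$n_het_sires, n_het_dams = pair$n_het_dams,
        haplotype_frequency = .haplotype_frequency(pair, ha, hb),
        mendelian_ok = ok,
        flagged = res$expected >= min_expected & res$observed == 0 & ok,
        breakdown = list(res$breakdown)
      )
    })
  })
}
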