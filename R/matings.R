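# Two-locus genotype classes and Mendelian mating machinery.
#
# A two-locus genotype is one of the nine unphased classes over two biallelic
# loci A and B, in the fixed canonical order
#   AABB, AaBB, aaBB, AABb, AaBb, aaBb, AAbb, Aabb, aabb
# where the capital allele is whichever allele the 0/1/2 dosage coding counts.

#' Canonical two-locus genotype class labels
#'
#' The nine unphased genotype classes over two biallelic loci, in the fixed
#' canonical order used throughout the package (locus A is always the first
#' SNP of a pair as supplied by the caller).
#'
#' @return Character vector of length 9.
#' @export
#' @examples
#' two_locus_classes()
two_locus_classes <- function() {
  c("AABB", "AaBB", "aaBB", "AABb", "AaBb", "aaBb", "AAbb", "Aabb", "aabb")
}

# dosage (capital-allele count) at each locus for class index 1..9
.class_dosage <- local({
  gB <- rep(2:0, each = 3)
  gA <- rep(2:0, times = 3)
  cbind(A = gA, B = gB)
})

#' Map allele dosages to a two-locus class index
#'
#' @param dose_a,dose_b Capital-allele counts (0, 1 or 2) at locus A and B.
#' @return Integer class index 1..9 into [two_locus_classes()].
#' @export
class_index <- function(dose_a, dose_b) {
  stopifnot(all(dose_a %in% 0:2), all(dose_b %in% 0:2))
  as.integer(3L * (2L - dose_b) + (2L - dose_a) + 1L)
}

#' Allele dosages of a two-locus class
#'
#' @param class Integer class index 1..9, or a class label.
#' @return Two-column integer matrix (`A`, `B`) of capital-allele counts.
#' @export
class_dosage <- function(class) {
  if (is.character(class)) class <- match(class, two_locus_classes())
  stopifnot(all(class %in% 1:9))
  .class_dosage[class, , drop = FALSE]
}

# P(offspring dosage 0,1,2 | parent dosages) at one locus
.single_locus_mendelian <- function(sire_dose, dam_dose) {
  ts <- sire_dose / 2 # P(sire transmits capital allele)
  td <- dam_dose / 2
  c(`0` = (1 - ts) * (1 - td), `1` = ts * (1 - td) + (1 - ts) * td, `2` = ts * td)
}

#' Mendelian offspring distribution of a two-locus mating
#'
#' Probability of each of the nine offspring classes under Mendelian
#' segregation for an ordered (sire, dam) mating of two unlinked loci
#' (independent assortment: the two-locus distribution is the product of the
#' per-locus transmission distributions).
#'
#' @param sire,dam Two-locus genotype of each parent: class index 1..9 or a
#'   label from [two_locus_classes()].
#' @return Named numeric vector of length 9 summing to 1.
#' @export
#' @examples
#' mendelian_offspring_distribution("AaBb", "AaBb") * 16
mendelian_offspring_distribution <- function(sire, dam) {
  if (is.character(sire)) sire <- match(sire, two_locus_classes())
  if (is.character(dam)) dam <- match(dam, two_locus_classes())
  stopifnot(length(sire) == 1, length(dam) == 1, sire %in% 1:9, dam %in% 1:9)
  ds <- .class_dosage[sire, ]
  dd <- .class_dosage[dam, ]
  pa <- .single_locus_mendelian(ds[["A"]], dd[["A"]])
  pb <- .single_locus_mendelian(ds[["B"]], dd[["B"]])
  out <- pb[.class_dosage[, "B"] + 1L] * pa[.class_dosage[, "A"] + 1L]
  names(out) <- two_locus_classes()
  out
}

#' Ordered mating index
#'
#' @param sire,dam Class indices 1..9.
#' @return Integer in 1..81 identifying the ordered (sire, dam) mating.
#' @export
mating_index <- function(sire, dam) {
  as.integer((sire - 1L) * 9L + dam)
}

#' Enumerate all ordered two-locus matings
#'
#' All 81 ordered (sire, dam) two-locus genotype pairs, each with its
#' Mendelian offspring distribution and an informativeness flag. A mating is
#' informative when more than one offspring class has positive Mendelian
#' probability; the 16 uninformative matings are exactly those with both
#' parents homozygous at both loci.
#'
#' @return A tibble with one row per ordered mating: `mating` (index 1..81),
#'   `sire`, `dam` (class labels), `sire_class`, `dam_class` (indices),
#'   `mendelian` (list column of length-9 probability vectors) and
#'   `informative` (logical).
#' @export
#' @examples
#' m <- enumerate_matings()
#' sum(m$informative)
enumerate_matings <- function() {
  cls <- two_locus_classes()
  grid <- tidyr::expand_grid(sire_class = 1:9, dam_class = 1:9)
  grid |>
    dplyr::mutate(
      mating = mating_index(.data$sire_class, .data$dam_class),
      sire = cls[.data$sire_class],
      dam = cls[.data$dam_class],
      mendelian = purrr::map2(
        .data$sire_class, .data$dam_class,
        mendelian_offspring_distribution
      ),
      informative = purrr::map_lgl(.data$mendelian, ~ sum(.x > 0) > 1L)
    ) |>
    dplyr::select(
      "mating", "sire", "dam", "sire_class", "dam_class",
      "mendelian", "informative"
    ) |>
    dplyr::arrange(.data$mating)
}
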