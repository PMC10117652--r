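# Per-pair trio data: observed offspring counts split by ordered mating
# configuration, plus the tallies the scan pre-filters need.

.informative_mating_flags <- local({
  # informative <=> not both parents homozygous at both loci
  hom <- apply(.class_dosage, 1, function(d) all(d != 1L))
  flags <- logical(81)
  for (s in 1:9) for (d in 1:9) flags[(s - 1L) * 9L + d] <- !(hom[s] && hom[d])
  flags
})

#' Assemble pair trio data from per-trio genotype classes
#'
#' Lower-level constructor used by [extract_pair()] and the simulator:
#' takes per-trio two-locus classes (all already complete and Mendelian-
#' consistent) and tabulates them.
#'
#' @param trios Tibble with columns `sire_id`, `dam_id`, `offspring_id`,
#'   `sire_class`, `dam_class`, `off_class` (class indices 1..9).
#' @param snpA,snpB SNP identifiers (locus A is `snpA`).
#' @param excluded Optional tibble (`reason`, `n`) of excluded trios.
#' @param het_mode How a parent counts as heterozygous for the tallies:
#'   `"any"` (default; heterozygous at one locus or more) or `"both"`.
#' @param keep_trios Keep the per-trio table in the object (needed by the
#'   simplified artificial-haplotype screen and by [pair_to_tables()]).
#' @return An object of class `epitrd_pair`.
#' @export
pair_trio_data <- function(trios, snpA = "snpA", snpB = "snpB",
                           excluded = NULL, het_mode = c("any", "both"),
                           keep_trios = TRUE) {
  het_mode <- match.arg(het_mode)
  stopifnot(all(c("sire_id", "dam_id", "sire_class", "dam_class", "off_class")
  %in% names(trios)))
  mat <- mating_index(trios$sire_class, trios$dam_class)
  counts <- tibble::tibble(
    mating = mat,
    sire_class = trios$sire_class, dam_class = trios$dam_class,
    off_class = trios$off_class
  ) |>
    dplyr::count(.data$mating, .data$sire_class, .data$dam_class,
      .data$off_class,
      name = "n"
    ) |>
    dplyr::arrange(.data$mating, .data$off_class)
  is_het <- function(cls) {
    d <- .class_dosage[cls, , drop = FALSE]
    if (het_mode == "any") rowSums(d == 1L) >= 1L else rowSums(d == 1L) == 2L
  }
  sires <- dplyr::distinct(trios, .data$sire_id, .data$sire_class)
  dams <- dplyr::distinct(trios, .data$dam_id, .data$dam_class)
  if (is.null(excluded)) excluded <- tibble::tibble(reason = character(), n = integer())
  structure(
    list(
      snpA = snpA, snpB = snpB,
      counts = counts,
      n_trios = nrow(trios),
      n_informative_offspring = sum(.informative_mating_flags[mat]),
      n_het_sires = sum(is_het(sires$sire_class)),
      n_het_dams = sum(is_het(dams$dam_class)),
      het_mode = het_mode,
      n_excluded = sum(excluded$n),
      excluded = excluded,
      trios = if (keep_trios) tibble::as_tibble(trios) else NULL
    ),
    class = "epitrd_pair"
  )
}

#' @export
print.epitrd_pair <- function(x, ...) {
  cat(sprintf(
    "<epitrd_pair> %s x %s: %d trios (%d informative offspring), %d het sires, %d het dams, %d excluded\n",
    x$snpA, x$snpB, x$n_trios, x$n_informative_offspring,
    x$n_het_sires, x$n_het_dams, x$n_excluded
  ))
  invisible(x)
}

#' Extract two-locus trio data for one SNP pair
#'
#' Builds the per-pair observation table for a pair of SNPs: every trio with
#' complete calls at both SNPs in all three members is classified by its
#' ordered (sire, dam) mating configuration and offspring class. Trios with
#' a missing call are excluded; trios whose offspring class has zero
#' Mendelian probability under the parental mating are excluded as
#' Mendelian-inconsistent (the likelihood is undefined on impossible
#' outcomes). Both exclusions are tallied.
#'
#' @param genotypes An `epitrd_genotypes` object.
#' @param trios Trio table from [read_trios()].
#' @param snpA,snpB SNP identifiers; must be on different chromosomes unless
#'   `allow_same_chromosome = TRUE` (testing override).
#' @inheritParams pair_trio_data
#' @param allow_same_chromosome Permit intra-chromosomal pairs.
#' @return An `epitrd_pair` object.
#' @export
extract_pair <- function(genotypes, trios, snpA, snpB,
                         allow_same_chromosome = FALSE,
                         het_mode = c("any", "both"), keep_trios = TRUE) {
  het_mode <- match.arg(het_mode)
  stopifnot(inherits(genotypes, "epitrd_genotypes"))
  for (s in c(snpA, snpB)) {
    if (!s %in% genotypes$snp_ids) stop("SNP not found: ", s, call. = FALSE)
  }
  map <- genotypes$map
  chrA <- map$chrom[map$snp_id == snpA]
  chrB <- map$chrom[map$snp_id == snpB]
  if (!allow_same_chromosome && identical(chrA, chrB)) {
    stop(sprintf(
      "SNPs %s and %s are both on chromosome %s; the scan is restricted to inter-chromosomal pairs (use allow_same_chromosome = TRUE to override)",
      snpA, snpB, chrA
    ), call. = FALSE)
  }
  calls <- genotypes$calls
  usable <- trios$sire_id %in% rownames(calls) &
    trios$dam_id %in% rownames(calls) &
    trios$offspring_id %in% rownames(calls)
  t2 <- trios[usable, ]
  g <- function(ids, snp) calls[match(ids, rownames(calls)), snp]
  d <- tibble::tibble(
    offspring_id = t2$offspring_id, sire_id = t2$sire_id, dam_id = t2$dam_id,
    sA = g(t2$sire_id, snpA), sB = g(t2$sire_id, snpB),
    dA = g(t2$dam_id, snpA), dB = g(t2$dam_id, snpB),
    oA = g(t2$offspring_id, snpA), oB = g(t2$offspring_id, snpB)
  )
  complete <- stats::complete.cases(d[, c("sA", "sB", "dA", "dB", "oA", "oB")])
  n_missing <- sum(!complete)
  d <- d[complete, ]
  d$sire_class <- class_index(d$sA, d$sB)
  d$dam_class <- class_index(d$dA, d$dB)
  d$off_class <- class_index(d$oA, d$oB)
  # Mendelian consistency: offspring class must be feasible under the mating
  mend <- .mendelian_all_matings()
  feasible <- mend[cbind(mating_index(d$sire_class, d$dam_class), d$off_class)] > 0
  n_inconsistent <- sum(!feasible)
  excluded <- tibble::tibble(
    reason = c("missing_call", "mendelian_inconsistent"),
    n = c(n_missing, n_inconsistent)
  )
  pair_trio_data(
    d[feasible, c(
      "offspring_id", "sire_id", "dam_id",
      "sire_class", "dam_class", "off_class"
    )],
    snpA = snpA, snpB = snpB, excluded = excluded,
    het_mode = het_mode, keep_trios = keep_trios
  )
}

# 81 x 9 Mendelian table, memoised
.mendelian_cache <- new.env(parent = emptyenv())
.mendelian_all_matings <- function() {
  if (is.null(.mendelian_cache$m)) {
    m <- matrix(0, 81, 9)
    for (s in 1:9) {
      for (d in 1:9) {
        m[mating_index(s, d), ] <- mendelian_offspring_distribution(s, d)
      }
    }
    .mendelian_cache$m <- m
  }
  .mendelian_cache$m
}

#' Aggregated count matrix of a pair
#'
#' @param pair An `epitrd_pair` object.
#' @return List with `counts` (matings x 9 matrix), `mendelian` (matching
#'   Mendelian probabilities), `sire_class`, `dam_class`, `mating`.
#' @export
pair_count_matrix <- function(pair) {
  stopifnot(inherits(pair, "epitrd_pair"))
  cnt <- pair$counts
  mats <- sort(unique(cnt$mating))
  m <- matrix(0, length(mats), 9,
    dimnames = list(NULL, two_locus_classes())
  )
  m[cbind(match(cnt$mating, mats), cnt$off_class)] <- cnt$n
  sire <- ((mats - 1L) %/% 9L) + 1L
  dam <- ((mats - 1L) %% 9L) + 1L
  list(
    counts = m,
    mendelian = .mendelian_all_matings()[mats, , drop = FALSE],
    sire_class = sire, dam_class = dam, mating = mats
  )
}

#' Convert simulated pair data back to genotype and trio tables
#'
#' Expands an `epitrd_pair` that retains its per-trio table into a
#' two-SNP `epitrd_genotypes` object plus the matching trio table, so the
#' file-reading path and [extract_pair()] can be exercised round-trip.
#'
#' @param pair An `epitrd_pair` with `trios` retained.
#' @param chromA,chromB Chromosome labels for the two SNPs.
#' @param posA,posB Base-pair positions.
#' @return List with elements `genotypes` and `trios`.
#' @export
pair_to_tables <- function(pair, chromA = "1", chromB = "2",
                           posA = 1000L, posB = 2000L) {
  stopifnot(inherits(pair, "epitrd_pair"))
  if (is.null(pair$trios)) stop("pair does not retain per-trio records", call. = FALSE)
  tr <- pair$trios
  sires <- dplyr::distinct(tr, id = .data$sire_id, class = .data$sire_class)
  dams <- dplyr::distinct(tr, id = .data$dam_id, class = .data$dam_class)
  offs <- tibble::tibble(id = tr$offspring_id, class = tr$off_class)
  all_animals <- dplyr::bind_rows(sires, dams, offs)
  dose <- class_dosage(all_animals$class)
  calls <- cbind(dose[, "A"], dose[, "B"])
  rownames(calls) <- all_animals$id
  colnames(calls) <- c(pair$snpA, pair$snpB)
  map <- tibble::tibble(
    snp_id = c(pair$snpA, pair$snpB),
    chrom = c(chromA, chromB), pos = as.integer(c(posA, posB))
  )
  list(
    genotypes = genotype_set(calls, map),
    trios = tibble::tibble(
      offspring_id = tr$offspring_id,
      sire_id = tr$sire_id, dam_id = tr$dam_id
    )
  )
}
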