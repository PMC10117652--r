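# Allelic (gamete-transmission) two-locus TRD model.
#
# Each parent transmits one of the four artificial-haplotype gametes
# AB, Ab, aB, ab (canonical order). Transmission is distorted by two direct
# terms (beta_A, beta_B, each in [-0.5, 0.5]: 0.5 + beta is the marginal
# transmission probability of the capital allele from a heterozygous parent)
# and six heterozygous-pairwise epistatic terms beta_{x/y}, one per unordered
# gamete pair, in [-1, 1]. The unnormalized weight of gamete g from a parent
# is the product over that parent's heterozygous loci of (0.5 +/- beta) times
# a pairwise factor (1 +/- beta_{g/g'}) where g' is the competing gamete
# (the complement for double-heterozygous parents); the sign is + for the
# canonically earlier gamete of the pair. Homozygous loci contribute no
# factor (any constant cancels in the normalization).

#' Artificial-haplotype gamete labels
#' @return Character vector `c("AB","Ab","aB","ab")` (canonical order).
#' @export
gamete_labels <- function() c("AB", "Ab", "aB", "ab")

# gamete -> capital-allele indicator at (A, B); rows follow gamete_labels()
.gamete_alleles <- matrix(
  c(
    1, 1,
    1, 0,
    0, 1,
    0, 0
  ),
  ncol = 2, byrow = TRUE, dimnames = list(c("AB", "Ab", "aB", "ab"), c("A", "B"))
)

#' Names of the allelic model parameters
#' @return Character vector of length 8 (canonical order).
#' @export
allelic_param_names <- function() {
  c(
    "beta_A", "beta_B",
    "beta_AB_Ab", "beta_AB_aB", "beta_AB_ab",
    "beta_Ab_aB", "beta_Ab_ab", "beta_aB_ab"
  )
}

#' Parameter vector for the allelic TRD model
#'
#' Two direct gamete-transmission parameters (bounded by \[-0.5, 0.5\]) and
#' the six heterozygous pairwise epistatic parameters (bounded by \[-1, 1\]),
#' one per unordered pair of artificial-haplotype gametes.
#'
#' @param beta_A,beta_B Direct transmission distortion at each locus.
#' @param beta_AB_Ab,beta_AB_aB,beta_AB_ab,beta_Ab_aB,beta_Ab_ab,beta_aB_ab
#'   Pairwise epistatic distortion between the named gametes; positive values
#'   favor the canonically earlier gamete of the pair.
#' @return Named numeric vector of length 8.
#' @export
allelic_params <- function(beta_A = 0, beta_B = 0,
                           beta_AB_Ab = 0, beta_AB_aB = 0, beta_AB_ab = 0,
                           beta_Ab_aB = 0, beta_Ab_ab = 0, beta_aB_ab = 0) {
  p <- c(
    beta_A = beta_A, beta_B = beta_B,
    beta_AB_Ab = beta_AB_Ab, beta_AB_aB = beta_AB_aB, beta_AB_ab = beta_AB_ab,
    beta_Ab_aB = beta_Ab_aB, beta_Ab_ab = beta_Ab_ab, beta_aB_ab = beta_aB_ab
  )
  if (any(!is.finite(p)) || any(abs(p[1:2]) > 0.5) || any(abs(p[3:8]) > 1)) {
    stop("allelic TRD parameters out of bounds (direct: [-0.5,0.5]; epistatic: [-1,1])",
      call. = FALSE
    )
  }
  p
}

# index of beta_{gi/gj} (i < j in canonical order) within params[3..8]
.pair_slot <- matrix(0L, 4, 4)
.pair_slot[1, 2] <- 1L
.pair_slot[1, 3] <- 2L
.pair_slot[1, 4] <- 3L
.pair_slot[2, 3] <- 4L
.pair_slot[2, 4] <- 5L
.pair_slot[3, 4] <- 6L

# signed pairwise factor for gamete i competing against gamete j
.pair_factor <- function(i, j, params) {
  if (i < j) 1 + params[2L + .pair_slot[i, j]] else 1 - params[2L + .pair_slot[j, i]]
}

#' Gamete-transmission probabilities of one parent
#'
#' Probability that a parent of the given two-locus genotype transmits each
#' feasible artificial-haplotype gamete under the allelic TRD model.
#'
#' @param parent Two-locus genotype (class index 1..9 or label).
#' @param params Parameter vector from [allelic_params()].
#' @return Named probability vector over the feasible gametes (length 1, 2
#'   or 4).
#' @export
#' @examples
#' gamete_probabilities("AaBb", allelic_params(beta_AB_ab = 1))
gamete_probabilities <- function(parent, params) {
  w <- .gamete_weights(parent, params)
  w <- w[.gamete_feasible(parent)]
  s <- sum(w)
  if (s <= 0) stop("degenerate parent: all gamete weights are zero", call. = FALSE)
  w / s
}

# logical feasibility of each of the 4 gametes for a parent class
.gamete_feasible <- function(parent) {
  if (is.character(parent)) parent <- match(parent, two_locus_classes())
  dose <- .class_dosage[parent, ]
  okA <- switch(dose[["A"]] + 1L, c(FALSE, TRUE), c(TRUE, TRUE), c(TRUE, FALSE))
  okB <- switch(dose[["B"]] + 1L, c(FALSE, TRUE), c(TRUE, TRUE), c(TRUE, FALSE))
  # okX[1] = capital allele allowed, okX[2] = lowercase allowed
  vapply(1:4, function(g) {
    a <- .gamete_alleles[g, 1]
    b <- .gamete_alleles[g, 2]
    (if (a == 1) okA[1] else okA[2]) && (if (b == 1) okB[1] else okB[2])
  }, logical(1)) |> setNames(gamete_labels())
}

# unnormalized weights over all 4 gametes (0 where infeasible)
.gamete_weights <- function(parent, params) {
  if (is.character(parent)) parent <- match(parent, two_locus_classes())
  dose <- .class_dosage[parent, ]
  hetA <- dose[["A"]] == 1L
  hetB <- dose[["B"]] == 1L
  feas <- .gamete_feasible(parent)
  idx <- which(feas)
  w <- numeric(4)
  names(w) <- gamete_labels()
  if (length(idx) == 1L) {
    w[idx] <- 1
    return(w)
  }
  for (g in idx) {
    f <- 1
    if (hetA) f <- f * (if (.gamete_alleles[g, 1] == 1) 0.5 + params[["beta_A"]] else 0.5 - params[["beta_A"]])
    if (hetB) f <- f * (if (.gamete_alleles[g, 2] == 1) 0.5 + params[["beta_B"]] else 0.5 - params[["beta_B"]])
    # competing gamete: the complement (double het) or the only other feasible
    comp <- if (length(idx) == 4L) 5L - g else idx[idx != g]
    w[g] <- f * .pair_factor(g, comp, params)
  }
  w
}

#' Offspring-class probabilities under the allelic TRD model
#'
#' Sums sire-gamete by dam-gamete transmission products over all gamete
#' pairs yielding each offspring class. Parental origin never enters the
#' likelihood: the two reciprocal double-heterozygous origin classes are
#' summed into the single unphased AaBb class.
#'
#' @param sire,dam Parental two-locus genotypes (index or label).
#' @param params Parameter vector from [allelic_params()].
#' @return Named probability vector over the nine offspring classes.
#' @export
offspring_probabilities_allelic <- function(sire, dam, params) {
  ps <- .gamete_dist4(sire, params)
  pd <- .gamete_dist4(dam, params)
  out <- numeric(9)
  for (gs in 1:4) {
    if (ps[gs] == 0) next
    for (gd in 1:4) {
      if (pd[gd] == 0) next
      k <- class_index(
        .gamete_alleles[gs, 1] + .gamete_alleles[gd, 1],
        .gamete_alleles[gs, 2] + .gamete_alleles[gd, 2]
      )
      out[k] <- out[k] + ps[gs] * pd[gd]
    }
  }
  setNames(out, two_locus_classes())
}

# normalized gamete distribution padded to length 4
.gamete_dist4 <- function(parent, params) {
  w <- .gamete_weights(parent, params)
  s <- sum(w)
  if (s <= 0) stop("degenerate parent: all gamete weights are zero", call. = FALSE)
  w / s
}

# vectorized gamete weights over a draw matrix (n x 8): returns n x 4
.gamete_weight_matrix <- function(parent, par_matrix) {
  if (is.character(parent)) parent <- match(parent, two_locus_classes())
  dose <- .class_dosage[parent, ]
  hetA <- dose[["A"]] == 1L
  hetB <- dose[["B"]] == 1L
  feas <- .gamete_feasible(parent)
  idx <- which(feas)
  n <- nrow(par_matrix)
  w <- matrix(0, n, 4, dimnames = list(NULL, gamete_labels()))
  if (length(idx) == 1L) {
    w[, idx] <- 1
    return(w)
  }
  for (g in idx) {
    f <- rep(1, n)
    if (hetA) f <- f * (if (.gamete_alleles[g, 1] == 1) 0.5 + par_matrix[, 1] else 0.5 - par_matrix[, 1])
    if (hetB) f <- f * (if (.gamete_alleles[g, 2] == 1) 0.5 + par_matrix[, 2] else 0.5 - par_matrix[, 2])
    comp <- if (length(idx) == 4L) 5L - g else idx[idx != g]
    pf <- if (g < comp) {
      1 + par_matrix[, 2L + .pair_slot[g, comp]]
    } else {
      1 - par_matrix[, 2L + .pair_slot[comp, g]]
    }
    w[, g] <- f * pf
  }
  w
}

#' Allelic-model probabilities for many parameter draws
#'
#' Vectorized form of [offspring_probabilities_allelic()] over a matrix of
#' parameter draws (used by property checks).
#'
#' @param sire,dam Parental genotypes (index or label).
#' @param par_matrix Numeric matrix with 8 columns, one draw per row.
#' @return Matrix of probabilities (draws x 9 classes).
#' @export
offspring_probability_matrix_allelic <- function(sire, dam, par_matrix) {
  ws <- .gamete_weight_matrix(sire, par_matrix)
  wd <- .gamete_weight_matrix(dam, par_matrix)
  ws <- ws / rowSums(ws)
  wd <- wd / rowSums(wd)
  out <- matrix(0, nrow(par_matrix), 9,
    dimnames = list(NULL, two_locus_classes())
  )
  for (gs in 1:4) {
    for (gd in 1:4) {
      k <- class_index(
        .gamete_alleles[gs, 1] + .gamete_alleles[gd, 1],
        .gamete_alleles[gs, 2] + .gamete_alleles[gd, 2]
      )
      out[, k] <- out[, k] + ws[, gs] * wd[, gd]
    }
  }
  out
}

#' Log-likelihood of pair trio data under the allelic model
#'
#' @inheritParams log_likelihood_genotypic
#' @param params Parameter vector from [allelic_params()].
#' @return Scalar log-likelihood; `-Inf` if an observed class has zero
#'   probability.
#' @export
log_likelihood_allelic <- function(pair, params) {
  cnt <- pair_count_matrix(pair)
  if (sum(cnt$counts) == 0) stop("empty pair data: no offspring counts", call. = FALSE)
  ll <- 0
  for (i in seq_len(nrow(cnt$counts))) {
    obs <- cnt$counts[i, ]
    keep <- obs > 0
    if (!any(keep)) next
    p <- offspring_probabilities_allelic(cnt$sire_class[i], cnt$dam_class[i], params)
    if (any(p[keep] == 0)) {
      return(-Inf)
    }
    ll <- ll + sum(obs[keep] * log(p[keep]))
  }
  ll
}
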