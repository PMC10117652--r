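# Genotypic two-locus TRD model.
#
# Offspring-class probabilities carry eight distortion parameters: additive
# and dominance direct terms at each locus (alpha_A, delta_A, alpha_B,
# delta_B) and four epistatic terms (aa_e, ad_e, da_e, dd_e:
# additive-by-additive, additive-by-dominance, dominance-by-additive,
# dominance-by-dominance). For the double-heterozygous mating the
# unnormalized weight of offspring class g is
#
#   w(g) = base(g) + coef(g) . p,    base = 16 x Mendelian = (1,2,1,2,4,2,1,2,1)
#
# and for any other mating the base becomes 16 x Mendelian(g | mating) with
# the coefficient rows unchanged, restricted to Mendelian-feasible classes.
# Negative weights are clipped to zero first; the vector is then normalized
# to sum to one.
#
# The coefficient table is a fixed model constant. Note the epistatic
# columns are not plain products of the additive/dominance contrast codes:
# the ad/da/dd rows follow the model's own (negated-product) sign
# convention, and are kept verbatim.

#' Parameter vector for the genotypic TRD model
#'
#' Constructs (and validates) the 8-parameter vector of the genotypic
#' two-locus distortion model. All parameters live in \[-1, 1\]; all zero is
#' the Mendelian null.
#'
#' @param alpha_A,delta_A Additive and dominance direct distortion at locus A.
#' @param alpha_B,delta_B Additive and dominance direct distortion at locus B.
#' @param aa_e,ad_e,da_e,dd_e Additive-by-additive, additive-by-dominance,
#'   dominance-by-additive and dominance-by-dominance epistatic distortion.
#' @return Named numeric vector of length 8.
#' @export
#' @examples
#' genotypic_params(aa_e = 0.8)
genotypic_params <- function(alpha_A = 0, delta_A = 0, alpha_B = 0, delta_B = 0,
                             aa_e = 0, ad_e = 0, da_e = 0, dd_e = 0) {
  p <- c(
    alpha_A = alpha_A, alpha_B = alpha_B, delta_A = delta_A, delta_B = delta_B,
    aa_e = aa_e, ad_e = ad_e, da_e = da_e, dd_e = dd_e
  )
  if (any(!is.finite(p)) || any(abs(p) > 1)) {
    stop("genotypic TRD parameters must be finite and within [-1, 1]", call. = FALSE)
  }
  p
}

#' Names of the genotypic model parameters
#' @return Character vector of length 8 (canonical order).
#' @export
genotypic_param_names <- function() {
  c("alpha_A", "alpha_B", "delta_A", "delta_B", "aa_e", "ad_e", "da_e", "dd_e")
}

#' Coefficient table of the genotypic model
#'
#' The fixed 9 x 8 integer matrix of multipliers of
#' (alpha_A, alpha_B, delta_A, delta_B, aa_e, ad_e, da_e, dd_e) per offspring
#' class, plus the double-heterozygous base constants as an attribute.
#'
#' @return Integer matrix with one row per class of [two_locus_classes()]
#'   and attribute `base` (the 16-scaled Mendelian constants).
#' @export
genotypic_coefficients <- function() {
  coef <- matrix(
    c(
      # alphaA alphaB deltaA deltaB  aa  ad  da  dd
      +1, +1, -1, -1, +1, +1, +1, -1, # AABB
      0, +1, +1, -1, 0, 0, -1, +1, # AaBB
      -1, +1, -1, -1, -1, -1, +1, -1, # aaBB
      +1, 0, -1, +1, 0, -1, 0, +1, # AABb
      0, 0, +1, +1, 0, 0, 0, -1, # AaBb
      -1, 0, -1, +1, 0, +1, 0, +1, # aaBb
      +1, -1, -1, -1, -1, +1, -1, -1, # AAbb
      0, -1, +1, -1, 0, 0, +1, +1, # Aabb
      -1, -1, -1, -1, +1, -1, -1, -1 # aabb
    ),
    nrow = 9, byrow = TRUE,
    dimnames = list(two_locus_classes(), genotypic_param_names())
  )
  structure(coef, base = c(1, 2, 1, 2, 4, 2, 1, 2, 1))
}

.geno_cache <- new.env(parent = emptyenv())
.geno_coef <- function() {
  if (is.null(.geno_cache$coef)) .geno_cache$coef <- genotypic_coefficients()
  .geno_cache$coef
}

# weights for a draw matrix (n x 8) under one mating; returns n x 9
.genotypic_weights <- function(mendelian, par_matrix) {
  base <- 16 * mendelian
  w <- matrix(base, nrow = nrow(par_matrix), ncol = 9, byrow = TRUE) +
    par_matrix %*% t(.geno_coef())
  w[, base == 0] <- 0
  w[w < 0] <- 0
  w
}

#' Offspring-class probabilities under the genotypic TRD model
#'
#' Adapts the double-heterozygous equations to an arbitrary mating: the
#' 16-scaled Mendelian probability of each feasible class is the base
#' constant, the coefficient rows are unchanged, infeasible classes have
#' probability zero, negative weights are clipped to zero, and the vector is
#' renormalized.
#'
#' @param sire,dam Parental two-locus genotypes (index or label), or
#'   alternatively `mating` as an index 1..81.
#' @param params Parameter vector from [genotypic_params()].
#' @param mating Optional ordered mating index (overrides `sire`/`dam`).
#' @return Named probability vector over the nine offspring classes.
#' @export
#' @examples
#' offspring_probabilities("AaBb", "AaBb", genotypic_params(aa_e = 1)) * 16
offspring_probabilities <- function(sire, dam, params, mating = NULL) {
  if (!is.null(mating)) {
    sire <- ((mating - 1L) %/% 9L) + 1L
    dam <- ((mating - 1L) %% 9L) + 1L
  }
  mend <- mendelian_offspring_distribution(sire, dam)
  w <- drop(.genotypic_weights(mend, matrix(params, nrow = 1)))
  s <- sum(w)
  if (s <= 0) {
    stop("degenerate mating: all offspring-class weights clipped to zero", call. = FALSE)
  }
  setNames(w / s, two_locus_classes())
}

#' Genotypic-model probabilities for many parameter draws
#'
#' Vectorized form of [offspring_probabilities()] over a matrix of parameter
#' draws (used by property checks and plotting).
#'
#' @param sire,dam Parental genotypes (index or label).
#' @param par_matrix Numeric matrix with 8 columns, one draw per row.
#' @return Matrix of probabilities (draws x 9 classes); rows whose weights
#'   are entirely clipped are `NaN`.
#' @export
offspring_probability_matrix <- function(sire, dam, par_matrix) {
  mend <- mendelian_offspring_distribution(sire, dam)
  w <- .genotypic_weights(mend, par_matrix)
  sweep(w, 1, rowSums(w), "/")
}

#' Log-likelihood of pair trio data under the genotypic model
#'
#' Sum over matings and offspring classes of `count * log(probability)`.
#' Returns `-Inf` when any observed class has zero probability (e.g. clipped
#' away), so samplers reject such parameter states.
#'
#' @param pair A [extract_pair()] / [simulate_offspring()] result.
#' @param params Parameter vector from [genotypic_params()].
#' @return Scalar log-likelihood.
#' @export
log_likelihood_genotypic <- function(pair, params) {
  cnt <- pair_count_matrix(pair)
  if (sum(cnt$counts) == 0) stop("empty pair data: no offspring counts", call. = FALSE)
  ll <- 0
  for (i in seq_len(nrow(cnt$counts))) {
    obs <- cnt$counts[i, ]
    keep <- obs > 0
    if (!any(keep)) next
    p <- offspring_probabilities(cnt$sire_class[i], cnt$dam_class[i], params)
    if (any(p[keep] == 0)) {
      return(-Inf)
    }
    ll <- ll + sum(obs[keep] * log(p[keep]))
  }
  ll
}
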