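# Genome-scan orchestration: pre-filters, deviation screen, two-stage
# chains, epistatic/direct Bayes-factor filtering, effect categorization,
# top-fraction selection and linked-SNP collapsing.

#' Scan configuration
#'
#' Thresholds of the filtering cascade. The defaults are the values used
#' for a cattle-scale analysis (hundreds of thousands of trios); for small
#' synthetic datasets scale `min_abs_deviation` to the same per-trio rate
#' (about 0.35% of trios).
#'
#' @param min_informative_offspring Minimum informative offspring per pair.
#' @param min_het_sires,min_het_dams Heterozygous-parent pre-filter: a pair
#'   passes with at least `min_het_sires` heterozygous sires **or** at
#'   least `min_het_dams` heterozygous dams.
#' @param min_abs_deviation Minimum |observed - expected| offspring in some
#'   (mating, class) cell.
#' @param min_rel_deviation Minimum |observed - expected| / expected in the
#'   same cell.
#' @param bf_threshold Minimum Bayes factor (natural scale) for a relevant
#'   epistatic effect.
#' @param epi_direct_bf_ratio Minimum ratio of the maximum epistatic to the
#'   maximum direct Bayes factor.
#' @param max_cv Maximum posterior coefficient of variation of significant
#'   epistatic effects.
#' @param top_fraction Fraction of pairs kept per effect category in the
#'   multiple-test correction.
#' @param linked_window_bp Partner SNPs on one chromosome within this
#'   distance of each other are treated as one physically linked region.
#' @return List of class `epitrd_scan_config`.
#' @export
scan_config <- function(min_informative_offspring = 1000,
                        min_het_sires = 20, min_het_dams = 50,
                        min_abs_deviation = 1000, min_rel_deviation = 0.10,
                        bf_threshold = 1000, epi_direct_bf_ratio = 1000,
                        max_cv = 0.20, top_fraction = 0.001,
                        linked_window_bp = 1e7) {
  cfg <- list(
    min_informative_offspring = min_informative_offspring,
    min_het_sires = min_het_sires, min_het_dams = min_het_dams,
    min_abs_deviation = min_abs_deviation,
    min_rel_deviation = min_rel_deviation,
    bf_threshold = bf_threshold,
    epi_direct_bf_ratio = epi_direct_bf_ratio,
    max_cv = max_cv, top_fraction = top_fraction,
    linked_window_bp = linked_window_bp
  )
  if (any(unlist(cfg) <= 0)) stop("all scan thresholds must be positive", call. = FALSE)
  structure(cfg, class = "epitrd_scan_config")
}

#' Pre-filter a pair on informativeness
#'
#' Passes when the pair has at least `min_informative_offspring`
#' informative offspring and at least `min_het_sires` heterozygous sires
#' or at least `min_het_dams` heterozygous dams.
#'
#' @param pair An `epitrd_pair`.
#' @param config A [scan_config()].
#' @return List with `pass` and a character vector `reasons` (empty when
#'   passing).
#' @export
prefilter <- function(pair, config = scan_config()) {
  reasons <- character()
  if (pair$n_informative_offspring < config$min_informative_offspring) {
    reasons <- c(reasons, sprintf(
      "informative offspring %d < %d",
      pair$n_informative_offspring, config$min_informative_offspring
    ))
  }
  if (pair$n_het_sires < config$min_het_sires &&
    pair$n_het_dams < config$min_het_dams) {
    reasons <- c(reasons, sprintf(
      "het sires %d < %d and het dams %d < %d",
      pair$n_het_sires, config$min_het_sires,
      pair$n_het_dams, config$min_het_dams
    ))
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Deviation screen
#'
#' Compares observed offspring counts per (mating, offspring class) cell
#' against Mendelian expectations. A pair passes when some cell deviates by
#' at least `min_abs_deviation` offspring **and** by at least
#' `min_rel_deviation` of the expected count. The relative deviation is
#' reported both against the expected and against the observed count.
#'
#' @inheritParams prefilter
#' @return List with `pass`, `max_abs_deviation`, `max_rel_deviation`
#'   (relative to expected, at the maximal-deviation cell) and a `cells`
#'   tibble of all screened cells.
#' @export
deviation_screen <- function(pair, config = scan_config()) {
  cnt <- pair_count_matrix(pair)
  totals <- rowSums(cnt$counts)
  expected <- cnt$mendelian * totals
  dev <- cnt$counts - expected
  keep <- cnt$mendelian > 0
  cells <- tibble::tibble(
    mating = rep(cnt$mating, 9)[as.vector(keep)],
    off_class = rep(seq_len(9), each = nrow(expected))[as.vector(keep)],
    observed = cnt$counts[keep],
    expected = expected[keep],
    deviation = dev[keep]
  ) |>
    dplyr::mutate(
      rel_vs_expected = abs(.data$deviation) / .data$expected,
      rel_vs_observed = ifelse(.data$observed > 0,
        abs(.data$deviation) / .data$observed, NA_real_
      ),
      pass = abs(.data$deviation) >= config$min_abs_deviation &
        abs(.data$deviation) >= config$min_rel_deviation * .data$expected
    )
  i <- which.max(abs(cells$deviation))
  list(
    pass = any(cells$pass),
    max_abs_deviation = if (length(i)) abs(cells$deviation[i]) else 0,
    max_rel_deviation = if (length(i)) cells$rel_vs_expected[i] else 0,
    cells = cells
  )
}

.effect_terms <- function(model) {
  if (model == "genotypic") {
    list(
      direct = c("alpha_A", "alpha_B", "delta_A", "delta_B"),
      epistatic = c("aa_e", "ad_e", "da_e", "dd_e")
    )
  } else {
    list(
      direct = c("beta_A", "beta_B"),
      epistatic = allelic_param_names()[3:8]
    )
  }
}

#' Effect category of a fit
#'
#' The effect with the maximum epistatic Bayes factor: for the genotypic
#' model one of `additive_by_additive`,
#' `additive_by_dominance_or_reverse`, `dominance_by_dominance`; for the
#' allelic model the winning pairwise term.
#'
#' @param fit An `epitrd_fit`.
#' @return Character scalar.
#' @export
effect_category <- function(fit) {
  terms <- .effect_terms(fit$model)
  epi <- fit$log10_bf[match(terms$epistatic, fit$params)]
  win <- terms$epistatic[which.max(epi)]
  if (fit$model == "genotypic") {
    switch(win,
      aa_e = "additive_by_additive",
      ad_e = ,
      da_e = "additive_by_dominance_or_reverse",
      dd_e = "dominance_by_dominance"
    )
  } else {
    win
  }
}

#' Epistatic relevance filter
#'
#' Passes when the maximum epistatic Bayes factor reaches `bf_threshold`,
#' exceeds the maximum direct Bayes factor by more than
#' `epi_direct_bf_ratio` (on the BF scale; when direct effects are entirely
#' absent the ratio passes by convention), and every significant epistatic
#' parameter has a posterior coefficient of variation at most `max_cv`.
#'
#' @param fit An `epitrd_fit` (genotypic or allelic).
#' @param config A [scan_config()].
#' @return List with `pass`, `reasons`, `max_epi_bf` and `max_direct_bf`
#'   (log10 scale).
#' @export
epistatic_filter <- function(fit, config = scan_config()) {
  terms <- .effect_terms(fit$model)
  epi_i <- match(terms$epistatic, fit$params)
  dir_i <- match(terms$direct, fit$params)
  max_epi <- max(fit$log10_bf[epi_i])
  max_dir <- max(fit$log10_bf[dir_i])
  thr <- log10(config$bf_threshold)
  ratio <- log10(config$epi_direct_bf_ratio)
  reasons <- character()
  if (!(max_epi >= thr)) {
    reasons <- c(reasons, sprintf("max epistatic log10 BF %.2f < %.2f", max_epi, thr))
  }
  ratio_ok <- if (is.infinite(max_epi) && is.infinite(max_dir)) {
    FALSE
  } else if (is.infinite(max_dir) && max_dir < 0) {
    TRUE # direct effects absent
  } else {
    (max_epi - max_dir) > ratio
  }
  if (!ratio_ok) {
    reasons <- c(reasons, sprintf(
      "epistatic/direct log10 BF ratio %.2f <= %.2f", max_epi - max_dir, ratio
    ))
  }
  sig <- epi_i[fit$log10_bf[epi_i] >= thr]
  bad_cv <- sig[!is.na(fit$cv[sig]) & fit$cv[sig] > config$max_cv]
  if (length(bad_cv)) {
    reasons <- c(reasons, sprintf(
      "CV > %.2f for %s", config$max_cv,
      paste(fit$params[bad_cv], collapse = ", ")
    ))
  }
  list(
    pass = length(reasons) == 0, reasons = reasons,
    max_epi_bf = max_epi, max_direct_bf = max_dir
  )
}

.fit_row <- function(fit, prefix = NULL) {
  est <- setNames(as.list(fit$estimate), paste0("est_", fit$params))
  bfs <- setNames(as.list(fit$log10_bf), paste0("bf_", fit$params))
  tibble::as_tibble(c(est, bfs))
}

#' Fit the requested model(s) to a pair at a scan stage
#'
#' @param pair An `epitrd_pair` (should already pass the pre-filters).
#' @param model `"genotypic"`, `"allelic"` or `"both"` (the genotypic fit
#'   then drives filtering and categorization; DIC is reported for both).
#' @param stage `"preliminary"` or `"accurate"`.
#' @param config A [scan_config()].
#' @param chain_preliminary,chain_accurate Chain configurations per stage.
#' @param seed Optional integer seed.
#' @return One-row tibble (a scan row): identifiers, stage, posterior
#'   summaries of the driving model, `lr`, `dic_genotypic`/`dic_allelic`,
#'   `max_epi_bf`, `max_direct_bf`, `category`, `filter_pass`,
#'   `filter_reasons`, and the fit object(s) in list columns.
#' @export
run_pair <- function(pair, model = c("genotypic", "allelic", "both"),
                     stage = c("preliminary", "accurate"),
                     config = scan_config(),
                     chain_preliminary = epitrd::chain_preliminary(),
                     chain_accurate = epitrd::chain_accurate(),
                     seed = NULL) {
  model <- match.arg(model)
  stage <- match.arg(stage)
  chain <- if (stage == "preliminary") chain_preliminary else chain_accurate
  fits <- list()
  tryCatch(
    {
      if (model %in% c("genotypic", "both")) {
        fits$genotypic <- fit_pair(pair, "genotypic", config = chain, seed = seed)
      }
      if (model %in% c("allelic", "both")) {
        fits$allelic <- fit_pair(pair, "allelic", config = chain, seed = seed)
      }
    },
    error = function(e) {
      stop(sprintf("pair %s x %s: %s", pair$snpA, pair$snpB, conditionMessage(e)),
        call. = FALSE
      )
    }
  )
  main <- if (!is.null(fits$genotypic)) fits$genotypic else fits$allelic
  filt <- epistatic_filter(main, config)
  dplyr::bind_cols(
    tibble::tibble(
      snpA = pair$snpA, snpB = pair$snpB, stage = stage, model = main$model,
      n_informative_offspring = pair$n_informative_offspring,
      lr = main$log10_lr,
      dic_genotypic = if (!is.null(fits$genotypic)) fits$genotypic$dic else NA_real_,
      dic_allelic = if (!is.null(fits$allelic)) fits$allelic$dic else NA_real_,
      max_epi_bf = filt$max_epi_bf, max_direct_bf = filt$max_direct_bf,
      category = effect_category(main),
      filter_pass = filt$pass,
      filter_reasons = paste(filt$reasons, collapse = "; "),
      fit = list(main),
      fit_allelic = if (!is.null(fits$genotypic) && !is.null(fits$allelic)) {
        list(fits$allelic)
      } else {
        list(NULL)
      }
    ),
    .fit_row(main)
  )
}

#' Multiple-test selection of top pairs per effect category
#'
#' Within each category, keeps the `ceiling(top_fraction * n)` rows with
#' the highest maximum epistatic Bayes factor; ties are broken by pair
#' identifier order.
#'
#' @param rows Scan-row tibble (must carry `category`, `max_epi_bf`,
#'   `snpA`, `snpB`).
#' @param config A [scan_config()].
#' @return `rows` with a logical `selected` column appended.
#' @export
select_top <- function(rows, config = scan_config()) {
  if (nrow(rows) == 0) {
    return(dplyr::mutate(rows, selected = logical(0)))
  }
  rows |>
    dplyr::group_by(.data$category) |>
    dplyr::arrange(
      dplyr::desc(.data$max_epi_bf), .data$snpA, .data$snpB,
      .by_group = TRUE
    ) |>
    dplyr::mutate(
      selected = dplyr::row_number() <= ceiling(config$top_fraction * dplyr::n())
    ) |>
    dplyr::ungroup()
}

#' Collapse pairs that share a SNP interacting with a linked region
#'
#' When one SNP appears in several rows whose partner SNPs lie on one
#' chromosome within `linked_window_bp` of each other (single-linkage
#' chaining), only the row with the highest epistatic Bayes factor in each
#' cluster is kept.
#'
#' @param rows Scan-row tibble (`snpA`, `snpB`, `max_epi_bf`).
#' @param map SNP map tibble (`snp_id`, `chrom`, `pos`).
#' @param config A [scan_config()].
#' @return The surviving rows.
#' @export
collapse_linked <- function(rows, map, config = scan_config()) {
  if (nrow(rows) <= 1) {
    return(rows)
  }
  rows <- dplyr::mutate(rows, .row_id = dplyr::row_number())
  drop <- logical(nrow(rows))
  anchors <- unique(c(rows$snpA, rows$snpB))
  for (anchor in anchors) {
    hit <- rows$snpA == anchor | rows$snpB == anchor
    if (sum(hit) < 2) next
    sub <- rows[hit, ]
    partner <- ifelse(sub$snpA == anchor, sub$snpB, sub$snpA)
    pm <- map[match(partner, map$snp_id), ]
    for (chr in unique(pm$chrom)) {
      on_chr <- which(pm$chrom == chr)
      if (length(on_chr) < 2) next
      ord <- on_chr[order(pm$pos[on_chr])]
      gaps <- diff(pm$pos[ord])
      cluster <- cumsum(c(0, gaps > config$linked_window_bp))
      for (cl in unique(cluster)) {
        members <- ord[cluster == cl]
        if (length(members) < 2) next
        bfs <- sub$max_epi_bf[members]
        keep_local <- members[order(-bfs, sub$snpA[members], sub$snpB[members])][1]
        drop[sub$.row_id[setdiff(members, keep_local)]] <- TRUE
      }
    }
  }
  dplyr::select(rows[!drop, ], -".row_id")
}

#' Scan a list of assembled pairs
#'
#' The full cascade on pre-assembled pair data: informativeness pre-filter,
#' deviation screen, preliminary chain, epistatic/direct Bayes-factor and
#' CV filter, accurate chain on survivors (overwriting the preliminary
#' statistics), effect categorization, per-category top-fraction selection
#' and (when a map is supplied) linked-SNP collapsing.
#'
#' @param pairs List of `epitrd_pair` objects.
#' @param model `"genotypic"`, `"allelic"` or `"both"`.
#' @param config A [scan_config()].
#' @param chain_preliminary,chain_accurate Chain configurations.
#' @param run_accurate Run the accurate stage on preliminary survivors.
#' @param map Optional SNP map for [collapse_linked()].
#' @param seed Optional integer base seed (per-pair seeds are derived as
#'   `seed + pair index`).
#' @param quiet Suppress per-stage progress messages.
#' @return Tibble with one row per pair: pre-filter and deviation-screen
#'   results for every pair, posterior statistics for pairs that reached
#'   the chains, `filter_pass`, `category`, `selected` and `kept` (selected
#'   and surviving the linked-SNP collapse).
#' @export
trd_scan_pairs <- function(pairs, model = c("genotypic", "allelic", "both"),
                           config = scan_config(),
                           chain_preliminary = epitrd::chain_preliminary(),
                           chain_accurate = epitrd::chain_accurate(),
                           run_accurate = TRUE, map = NULL, seed = NULL,
                           quiet = FALSE) {
  model <- match.arg(model)
  say <- function(...) if (!quiet) message(sprintf(...))
  base <- purrr::imap_dfr(pairs, function(pair, i) {
    pre <- prefilter(pair, config)
    dev <- deviation_screen(pair, config)
    tibble::tibble(
      pair_index = as.integer(i), snpA = pair$snpA, snpB = pair$snpB,
      n_informative_offspring = pair$n_informative_offspring,
      n_het_sires = pair$n_het_sires, n_het_dams = pair$n_het_dams,
      prefilter_pass = pre$pass,
      prefilter_reasons = paste(pre$reasons, collapse = "; "),
      deviation_pass = dev$pass,
      max_abs_deviation = dev$max_abs_deviation,
      max_rel_deviation = dev$max_rel_deviation
    )
  })
  say("pairs: %d; pre-filter survivors: %d; deviation-screen survivors: %d",
    nrow(base), sum(base$prefilter_pass),
    sum(base$prefilter_pass & base$deviation_pass)
  )
  todo <- which(base$prefilter_pass & base$deviation_pass)
  fit_rows <- purrr::map_dfr(todo, function(i) {
    run_pair(pairs[[i]], model, "preliminary",
      config = config,
      chain_preliminary = chain_preliminary, chain_accurate = chain_accurate,
      seed = if (is.null(seed)) NULL else seed + i
    ) |>
      dplyr::mutate(pair_index = as.integer(i))
  })
  if (nrow(fit_rows) && run_accurate) {
    surv <- which(fit_rows$filter_pass)
    say("preliminary-chain survivors: %d", length(surv))
    for (k in surv) {
      i <- fit_rows$pair_index[k]
      acc <- run_pair(pairs[[i]], model, "accurate",
        config = config,
        chain_preliminary = chain_preliminary, chain_accurate = chain_accurate,
        seed = if (is.null(seed)) NULL else seed + i
      ) |>
        dplyr::mutate(pair_index = as.integer(i))
      fit_rows[k, names(acc)] <- acc
    }
  }
  if (nrow(fit_rows)) {
    out <- dplyr::left_join(
      base,
      dplyr::select(fit_rows, -dplyr::any_of(c(
        "snpA", "snpB",
        "n_informative_offspring"
      ))),
      by = "pair_index"
    )
  } else {
    out <- dplyr::mutate(base,
      filter_pass = FALSE, category = NA_character_,
      max_epi_bf = NA_real_, max_direct_bf = NA_real_
    )
  }
  out$filter_pass[is.na(out$filter_pass)] <- FALSE
  candidates <- dplyr::filter(out, .data$filter_pass)
  say("post-filter candidates: %d", nrow(candidates))
  sel <- select_top(candidates, config)
  out$selected <- out$pair_index %in% sel$pair_index[sel$selected]
  kept_rows <- dplyr::filter(out, .data$selected)
  if (!is.null(map) && nrow(kept_rows) > 1) {
    kept_rows <- collapse_linked(kept_rows, map, config)
  }
  out$kept <- out$pair_index %in% kept_rows$pair_index
  say("selected: %d; kept after linked-SNP collapse: %d",
    sum(out$selected), sum(out$kept)
  )
  out
}

#' Genome-wide two-locus TRD scan
#'
#' Assembles pair data from genotype and trio tables and runs the full
#' filtering cascade ([trd_scan_pairs()]).
#'
#' @param genotypes An `epitrd_genotypes`.
#' @param trios Trio table ([read_trios()]).
#' @param pairs Optional tibble (`snpA`, `snpB`) restricting the scan;
#'   defaults to all inter-chromosomal pairs.
#' @inheritParams trd_scan_pairs
#' @inheritParams extract_pair
#' @return See [trd_scan_pairs()].
#' @export
trd_scan <- function(genotypes, trios, model = c("genotypic", "allelic", "both"),
                     pairs = NULL, config = scan_config(),
                     chain_preliminary = epitrd::chain_preliminary(),
                     chain_accurate = epitrd::chain_accurate(),
                     run_accurate = TRUE, seed = NULL, quiet = FALSE,
                     allow_same_chromosome = FALSE, het_mode = "any") {
  if (is.null(pairs)) pairs <- candidate_pairs(genotypes$map)
  pair_list <- purrr::pmap(
    list(pairs$snpA, pairs$snpB),
    function(a, b) {
      extract_pair(genotypes, trios, a, b,
        allow_same_chromosome = allow_same_chromosome,
        het_mode = het_mode, keep_trios = FALSE
      )
    }
  )
  trd_scan_pairs(pair_list,
    model = model, config = config,
    chain_preliminary = chain_preliminary, chain_accurate = chain_accurate,
    run_accurate = run_accurate, map = genotypes$map, seed = seed,
    quiet = quiet
  )
}

#' Candidate SNP pairs for a scan
#'
#' All inter-chromosomal SNP pairs, optionally restricted to pairs that
#' include at least one SNP from a caller-supplied list (e.g. SNPs already
#' flagged with single-locus distortion, the default restriction of the
#' simplified artificial-haplotype screen).
#'
#' @param map SNP map tibble (`snp_id`, `chrom`, `pos`).
#' @param include_snps Optional SNP identifiers; keep only pairs containing
#'   at least one of them (`full_scan = TRUE` overrides).
#' @param full_scan Ignore `include_snps`.
#' @return Tibble with columns `snpA`, `snpB`.
#' @export
candidate_pairs <- function(map, include_snps = NULL, full_scan = FALSE) {
  grid <- tidyr::expand_grid(snpA = map$snp_id, snpB = map$snp_id) |>
    dplyr::filter(.data$snpA < .data$snpB) |>
    dplyr::left_join(
      dplyr::select(map, snpA = "snp_id", chromA = "chrom"),
      by = "snpA"
    ) |>
    dplyr::left_join(
      dplyr::select(map, snpB = "snp_id", chromB = "chrom"),
      by = "snpB"
    ) |>
    dplyr::filter(.data$chromA != .data$chromB)
  if (!is.null(include_snps) && !full_scan) {
    grid <- dplyr::filter(
      grid,
      .data$snpA %in% include_snps | .data$snpB %in% include_snps
    )
  }
  dplyr::select(grid, "snpA", "snpB")
}
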