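# Bayesian inference: Metropolis-Hastings sampling with flat priors over a
# bounded parametric space, Savage-Dickey Bayes factors, DIC and likelihood
# ratios.

#' Markov-chain configuration
#'
#' @param n_iter Total iterations (full update sweeps over all parameters).
#' @param burn_in Iterations discarded before retention; must be < `n_iter`.
#' @param proposal_sd Gaussian random-walk proposal standard deviation,
#'   recycled per parameter.
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param tune Auto-tune proposal standard deviations during burn-in toward
#'   a 20--40% acceptance rate.
#' @param tune_interval Sweeps between tuning adjustments.
#' @return A list of class `epitrd_chain_config`.
#' @export
chain_config <- function(n_iter, burn_in, proposal_sd = 0.05, thin = 1L,
                         tune = TRUE, tune_interval = 200L) {
  stopifnot(burn_in < n_iter, n_iter >= 1, proposal_sd > 0, thin >= 1)
  structure(
    list(
      n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
      proposal_sd = proposal_sd, thin = as.integer(thin),
      tune = tune, tune_interval = as.integer(tune_interval)
    ),
    class = "epitrd_chain_config"
  )
}

#' Chain presets
#'
#' The default chain lengths of the scan stages: the preliminary genome-scan
#' chain (11,000 sweeps, 1,000 burn-in), the accurate chain for selected
#' regions (550,000 sweeps, 50,000 burn-in) and the simplified
#' artificial-haplotype chain (110,000 sweeps, 10,000 burn-in).
#'
#' @param ... Overrides passed to [chain_config()].
#' @return A `epitrd_chain_config`.
#' @name chain_presets
NULL

#' @rdname chain_presets
#' @export
chain_preliminary <- function(...) {
  do.call(chain_config, utils::modifyList(list(n_iter = 11000L, burn_in = 1000L), list(...)))
}

#' @rdname chain_presets
#' @export
chain_accurate <- function(...) {
  do.call(chain_config, utils::modifyList(list(n_iter = 550000L, burn_in = 50000L), list(...)))
}

#' @rdname chain_presets
#' @export
chain_simplified <- function(...) {
  do.call(chain_config, utils::modifyList(list(n_iter = 110000L, burn_in = 10000L), list(...)))
}

#' Metropolis-Hastings sampler for an arbitrary log-likelihood
#'
#' Single-chain sampler with a flat prior over a box-shaped parametric
#' space: per-iteration single-parameter Gaussian random-walk updates in
#' fixed cyclic order, proposals reflected at the bounds, acceptance by
#' likelihood ratio. The initial state is the all-zero (Mendelian null)
#' vector, which must have finite likelihood.
#'
#' This is the R reference implementation; the model-specific fitters in
#' [fit_pair()] run the same algorithm (same RNG consumption) in compiled
#' code and produce bit-identical chains under the same seed.
#'
#' @param loglik Function of a numeric parameter vector returning the
#'   log-likelihood.
#' @param lower,upper Numeric bounds per parameter.
#' @param config A [chain_config()].
#' @param seed Optional integer seed (applied via [set.seed()]).
#' @param init Optional initial state (defaults to all zeros).
#' @return List of class `epitrd_chain` with `draws` (kept sweeps x
#'   parameters), `ll` (log-likelihood per kept sweep), `acceptance_rate`
#'   and the final `proposal_sd`.
#' @export
mh_sample <- function(loglik, lower, upper, config = chain_preliminary(),
                      seed = NULL, init = NULL) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  np <- length(lower)
  if (!is.null(seed)) set.seed(seed)
  sd_p <- rep_len(config$proposal_sd, np)
  cur <- if (is.null(init)) numeric(np) else as.numeric(init)
  cur_ll <- loglik(cur)
  if (!is.finite(cur_ll)) {
    stop("log-likelihood is not finite at the starting state; check the data for impossible counts",
      call. = FALSE
    )
  }
  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  draws <- matrix(NA_real_, n_keep, np)
  ll_out <- numeric(n_keep)
  n_acc <- n_try <- integer(np)
  accepted <- proposed <- 0L
  kept <- 0L
  for (it in seq_len(config$n_iter)) {
    for (k in seq_len(np)) {
      x <- cur[k] + sd_p[k] * rnorm(1)
      while (x < lower[k] || x > upper[k]) {
        x <- if (x > upper[k]) 2 * upper[k] - x else 2 * lower[k] - x
      }
      prop <- cur
      prop[k] <- x
      new_ll <- loglik(prop)
      u <- runif(1)
      proposed <- proposed + 1L
      n_try[k] <- n_try[k] + 1L
      if (is.finite(new_ll) && log(u) < new_ll - cur_ll) {
        cur <- prop
        cur_ll <- new_ll
        accepted <- accepted + 1L
        n_acc[k] <- n_acc[k] + 1L
      }
    }
    if (config$tune && it <= config$burn_in && it %% config$tune_interval == 0L) {
      rate <- ifelse(n_try > 0, n_acc / n_try, 0)
      sd_p <- ifelse(rate < 0.2, sd_p * 0.8, ifelse(rate > 0.4, sd_p * 1.25, sd_p))
      sd_p <- pmin(pmax(sd_p, 1e-4), (upper - lower) / 2)
      n_acc[] <- 0L
      n_try[] <- 0L
    }
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L && kept < n_keep) {
      kept <- kept + 1L
      draws[kept, ] <- cur
      ll_out[kept] <- cur_ll
    }
  }
  structure(
    list(
      draws = draws, ll = ll_out,
      acceptance_rate = accepted / proposed, proposal_sd = sd_p
    ),
    class = "epitrd_chain"
  )
}

#' Savage-Dickey Bayes factor for one parameter
#'
#' Evidence against the point null (parameter = 0) under a flat prior on a
#' bounded interval: prior density at zero (1/width) divided by the
#' posterior density at zero, estimated by a Gaussian kernel density with
#' Silverman's bandwidth evaluated at zero. Returned on the log10 scale.
#'
#' @param draws Numeric vector of post-burn-in draws of one parameter.
#' @param lower,upper Prior bounds of that parameter.
#' @return log10 Bayes factor. If the estimated posterior density at zero
#'   underflows to zero the result is `Inf`, with attribute `n_near_zero`
#'   giving the number of draws within one bandwidth of zero.
#' @export
bayes_factor <- function(draws, lower = -1, upper = 1) {
  stopifnot(length(draws) >= 2, upper > lower)
  prior0 <- 1 / (upper - lower)
  bw <- tryCatch(bw.nrd0(draws), error = function(e) 0)
  if (!is.finite(bw) || bw <= 0) bw <- max(1e-8, sd(draws))
  if (!is.finite(bw) || bw <= 0) bw <- 1e-8
  post0 <- mean(dnorm(0, mean = draws, sd = bw))
  if (post0 == 0) {
    return(structure(Inf, n_near_zero = sum(abs(draws) < bw)))
  }
  log10(prior0) - log10(post0)
}

#' Deviance information criterion from a chain
#'
#' `DIC = 2 * mean(D) - D(posterior mean)` with deviance
#' `D(theta) = -2 * loglik(theta)`; the plug-in point is the vector of
#' post-burn-in posterior means clipped to the bounds.
#'
#' @param chain An `epitrd_chain` (must carry `ll` per kept draw).
#' @param loglik Log-likelihood function for the plug-in evaluation.
#' @param lower,upper Bounds used to clip the posterior mean.
#' @return Scalar DIC.
#' @export
dic <- function(chain, loglik, lower = NULL, upper = NULL) {
  stopifnot(length(chain$ll) >= 2)
  theta_hat <- colMeans(chain$draws)
  if (!is.null(lower)) theta_hat <- pmax(theta_hat, lower)
  if (!is.null(upper)) theta_hat <- pmin(theta_hat, upper)
  d_hat <- -2 * loglik(theta_hat)
  if (!is.finite(d_hat)) {
    stop("deviance undefined at the posterior mean (a fitted class has probability zero)",
      call. = FALSE
    )
  }
  2 * mean(-2 * chain$ll) - d_hat
}

#' log10 likelihood ratio against the Mendelian null
#'
#' @param loglik Log-likelihood function.
#' @param theta_hat Parameter vector (typically posterior means).
#' @return `(loglik(theta_hat) - loglik(0)) / ln(10)`.
#' @export
likelihood_ratio <- function(loglik, theta_hat) {
  l1 <- loglik(theta_hat)
  l0 <- loglik(numeric(length(theta_hat)))
  if (!is.finite(l1) || !is.finite(l0)) {
    stop("likelihood ratio undefined: non-finite log-likelihood", call. = FALSE)
  }
  (l1 - l0) / log(10)
}

.model_bounds <- function(model) {
  switch(model,
    genotypic = list(
      params = genotypic_param_names(),
      lower = rep(-1, 8), upper = rep(1, 8)
    ),
    allelic = list(
      params = allelic_param_names(),
      lower = c(-0.5, -0.5, rep(-1, 6)), upper = c(0.5, 0.5, rep(1, 6))
    ),
    stop("unknown model: ", model, call. = FALSE)
  )
}

#' Fit a two-locus TRD model to one SNP pair
#'
#' Runs the Metropolis-Hastings chain for the genotypic or allelic model on
#' aggregated pair trio data and summarizes the posterior: per-parameter
#' mean, SD, coefficient of variation and Savage-Dickey log10 Bayes factor,
#' plus the model-level log10 likelihood ratio against the Mendelian null
#' and the DIC.
#'
#' @param pair An `epitrd_pair` object.
#' @param model `"genotypic"` or `"allelic"`.
#' @param config A [chain_config()] (defaults to the preliminary preset).
#' @param seed Optional integer seed.
#' @param engine `"cpp"` (default) or `"r"` (reference sampler; identical
#'   chains under the same seed).
#' @return An object of class `epitrd_fit`; see [tidy.epitrd_fit()] and
#'   [glance.epitrd_fit()].
#' @export
fit_pair <- function(pair, model = c("genotypic", "allelic"),
                     config = chain_preliminary(), seed = NULL,
                     engine = c("cpp", "r")) {
  model <- match.arg(model)
  engine <- match.arg(engine)
  stopifnot(inherits(pair, "epitrd_pair"))
  cnt <- pair_count_matrix(pair)
  if (sum(cnt$counts) == 0) stop("empty pair data: no offspring counts", call. = FALSE)
  b <- .model_bounds(model)
  loglik <- if (model == "genotypic") {
    function(p) .geno_loglik_cpp(cnt$counts, cnt$mendelian, p)
  } else {
    function(p) {
      .allelic_loglik_cpp(
        cnt$counts, cnt$sire_class |> .dose_a(), cnt$sire_class |> .dose_b(),
        cnt$dam_class |> .dose_a(), cnt$dam_class |> .dose_b(), p
      )
    }
  }
  if (!is.null(seed)) set.seed(seed)
  if (engine == "cpp") {
    res <- .mh_core_cpp(
      if (model == "genotypic") 1L else 2L,
      cnt$counts, cnt$mendelian,
      .dose_a(cnt$sire_class), .dose_b(cnt$sire_class),
      .dose_a(cnt$dam_class), .dose_b(cnt$dam_class),
      b$lower, b$upper, rep_len(config$proposal_sd, 8),
      config$n_iter, config$burn_in, config$thin,
      config$tune, config$tune_interval
    )
    chain <- structure(
      list(
        draws = res$draws, ll = res$ll,
        acceptance_rate = res$acceptance_rate, proposal_sd = res$proposal_sd
      ),
      class = "epitrd_chain"
    )
  } else {
    chain <- mh_sample(loglik, b$lower, b$upper, config)
  }
  colnames(chain$draws) <- b$params
  .summarize_fit(chain, loglik, b, model, pair, config)
}

.dose_a <- function(cls) as.integer(.class_dosage[cls, "A"])
.dose_b <- function(cls) as.integer(.class_dosage[cls, "B"])

.summarize_fit <- function(chain, loglik, bounds, model, pair, config) {
  est <- setNames(colMeans(chain$draws), bounds$params)
  sds <- setNames(apply(chain$draws, 2, sd), bounds$params)
  cv <- ifelse(abs(est) > 0, sds / abs(est), NA_real_)
  bf <- setNames(vapply(
    seq_along(est),
    function(k) as.numeric(bayes_factor(chain$draws[, k], bounds$lower[k], bounds$upper[k])),
    numeric(1)
  ), bounds$params)
  theta_hat <- pmin(pmax(est, bounds$lower), bounds$upper)
  structure(
    list(
      model = model,
      snpA = pair$snpA, snpB = pair$snpB,
      params = bounds$params,
      lower = bounds$lower, upper = bounds$upper,
      chain = chain,
      config = config,
      estimate = est, sd = sds, cv = cv, log10_bf = bf,
      log10_lr = likelihood_ratio(loglik, theta_hat),
      dic = dic(chain, loglik, bounds$lower, bounds$upper),
      acceptance_rate = chain$acceptance_rate,
      n_kept = nrow(chain$draws),
      n_informative_offspring = pair$n_informative_offspring,
      loglik = loglik
    ),
    class = "epitrd_fit"
  )
}

#' @export
print.epitrd_fit <- function(x, ...) {
  cat(sprintf(
    "<epitrd_fit> %s model, %s x %s: %d kept draws, acceptance %.2f\n",
    x$model, x$snpA, x$snpB, x$n_kept, x$acceptance_rate
  ))
  print(tidy(x), n = length(x$params))
  cat(sprintf("log10 LR = %.2f, DIC = %.2f\n", x$log10_lr, x$dic))
  invisible(x)
}

#' Dump a chain as TSV
#'
#' Writes kept draws (iteration index plus one column per parameter) for
#' external diagnostics.
#'
#' @param fit An `epitrd_fit`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_chain_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "epitrd_fit"))
  out <- data.frame(iteration = seq_len(nrow(fit$chain$draws)), fit$chain$draws)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
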