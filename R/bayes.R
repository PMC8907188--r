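#' Inverse logit (logistic) function
#'
#' `inv_logit(x) = 1 / (1 + exp(-x))`, numerically stable over the whole
#' double range (large negative arguments underflow gracefully to 0, large
#' positive ones saturate at 1 without overflow).
#'
#' @param x Finite numeric vector on the logit scale.
#' @return Probabilities in (0, 1) (0/1 only by floating underflow).
#' @examples
#' inv_logit(0)      # 0.5
#' inv_logit(-0.31)  # ~0.42
#' @export
inv_logit <- function(x) {
  if (any(is.na(x))) stop("inv_logit: NaN/NA input", call. = FALSE)
  stats::plogis(x)
}

#' Beta-Binomial log probability mass
#'
#' The Beta-Binomial likelihood used for per-participant intervention counts,
#' parameterised by the mean response probability `p` and scale `phi` through
#' the Beta shapes `alpha = p * phi`, `beta = (1 - p) * phi`; its mean is
#' `N * p` and small `phi` gives strong over-dispersion relative to the
#' Binomial (`phi = 2` with `p = 0.5` is uniform on `0..N`; `phi -> Inf`
#' recovers the Binomial).
#'
#' @param k Integer count(s), `0 <= k <= N`.
#' @param N Number of trials.
#' @param p Mean response probability in (0, 1).
#' @param phi Positive scale.
#' @return Log pmf value(s).
#' @export
beta_binomial_logpmf <- function(k, N, p, phi) {
  stopifnot(phi > 0, p > 0, p < 1, N >= 1)
  if (any(k != floor(k)) || any(k < 0) || any(k > N))
    stop("beta_binomial_logpmf: k must be an integer in 0..N", call. = FALSE)
  a <- p * phi
  b <- (1 - p) * phi
  lchoose(N, k) + lbeta(k + a, N - k + b) - lbeta(a, b)
}

#' Prior specification
#'
#' The weakly informative prior families used by the analysis models:
#' `normal(mean, sd)` for regression coefficients, `gamma(shape, rate)` for
#' the Beta-Binomial scale, and `dirichlet(concentrations)` for the simplex
#' action weights.
#'
#' @param family One of `"normal"`, `"gamma"`, `"dirichlet"`.
#' @param ... Named parameters: `mean`/`sd`, `shape`/`rate`, or
#'   `concentrations`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(family = c("normal", "gamma", "dirichlet"), ...) {
  family <- match.arg(family)
  pars <- list(...)
  ok <- switch(family,
    normal = isTRUE(pars$sd > 0) && is.numeric(pars$mean),
    gamma = isTRUE(pars$shape > 0) && isTRUE(pars$rate > 0),
    dirichlet = length(pars$concentrations) >= 2 &&
      all(pars$concentrations > 0))
  if (!ok) stop("prior_spec: invalid parameters for family ", family,
                call. = FALSE)
  structure(list(family = family, pars = pars), class = "prior_spec")
}

default_priors <- function() {
  list(coef = prior_spec("normal", mean = 0, sd = 10),
       phi = prior_spec("gamma", shape = 2, rate = 0.1),
       b = prior_spec("dirichlet", concentrations = c(1, 1, 1)),
       u = prior_spec("normal", mean = 0, sd = 1))
}

#' Equal-tail prior credible interval
#'
#' Computed by quantile-function (CDF) inversion. For a Dirichlet prior the
#' per-component marginal intervals are returned (component j is marginally
#' `Beta(a_j, a_0 - a_j)`).
#'
#' @param prior A [prior_spec()].
#' @param mass Central probability mass in (0, 1), e.g. 0.95.
#' @return Numeric `c(lower, upper)`, or a 2-column matrix for Dirichlet.
#' @examples
#' prior_interval(prior_spec("normal", mean = 0, sd = 10), 0.95)  # -19.6, 19.6
#' prior_interval(prior_spec("gamma", shape = 2, rate = 0.1), 0.95)
#' @export
prior_interval <- function(prior, mass = 0.95) {
  stopifnot(inherits(prior, "prior_spec"), mass > 0, mass < 1)
  lo <- (1 - mass) / 2
  hi <- 1 - lo
  switch(prior$family,
    normal = stats::qnorm(c(lo, hi), prior$pars$mean, prior$pars$sd),
    gamma = stats::qgamma(c(lo, hi), shape = prior$pars$shape,
                          rate = prior$pars$rate),
    dirichlet = {
      a <- prior$pars$concentrations
      t(vapply(seq_along(a), function(j)
        stats::qbeta(c(lo, hi), a[j], sum(a) - a[j]), numeric(2)))
    })
}

#' MCMC run configuration
#'
#' Total iterations per chain and chain count, with the conventional
#' half-warmup split (warmup draws are discarded; kept draws per chain are
#' `iterations - warmup`).
#'
#' @param iterations Total iterations per chain (default 2000; the per-trial
#'   action model defaults to 8000 since it carries many more parameters).
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param warmup Warmup iterations per chain (default `iterations / 2`).
#' @param seed Integer seed for the sampler RNG streams.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 2000L, chains = 4L, warmup = NULL,
                        seed = 1L) {
  if (is.null(warmup)) warmup <- iterations %/% 2L
  stopifnot(chains >= 2L, iterations > warmup, warmup >= 0L)
  structure(list(iterations = as.integer(iterations),
                 chains = as.integer(chains),
                 warmup = as.integer(warmup), seed = as.integer(seed)),
            class = "mcmc_config")
}

# Run a JAGS model and collect draws into a posterior_draws object.
run_jags <- function(model_string, data, monitor, mcmc, model_tag) {
  inits <- lapply(seq_len(mcmc$chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (mcmc$seed %% 100000L) * 13L + ch))
  adapt <- min(500L, mcmc$warmup)
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = mcmc$chains,
                          n.adapt = adapt, quiet = TRUE)
  if (mcmc$warmup > adapt)
    stats::update(jm, mcmc$warmup - adapt, progress.bar = "none")
  keep <- mcmc$iterations - mcmc$warmup
  samp <- rjags::coda.samples(jm, monitor, n.iter = keep,
                              progress.bar = "none")
  draws_from_coda(samp, mcmc, model_tag)
}

draws_from_coda <- function(samp, mcmc, model_tag) {
  mats <- lapply(samp, as.matrix)
  df <- do.call(rbind, lapply(seq_along(mats), function(ch)
    cbind(data.frame(.chain = ch, .iter = seq_len(nrow(mats[[ch]]))),
          as.data.frame(mats[[ch]]))))
  posterior_draws(df, meta = list(model = model_tag,
                                  iterations = mcmc$iterations,
                                  chains = mcmc$chains, warmup = mcmc$warmup,
                                  seed = mcmc$seed))
}

#' Posterior draws container
#'
#' @param draws Data frame with `.chain`, `.iter` and one column per
#'   parameter.
#' @param meta Named list of sampler metadata (model tag, iterations, chains,
#'   warmup, seed).
#' @return An object of class `posterior_draws`.
#' @export
posterior_draws <- function(draws, meta = list()) {
  stopifnot(is.data.frame(draws), all(c(".chain", ".iter") %in% names(draws)))
  if (length(unique(draws$.chain)) < 2L)
    stop("posterior_draws: need >= 2 chains for diagnostics", call. = FALSE)
  structure(list(draws = draws,
                 params = setdiff(names(draws), c(".chain", ".iter")),
                 meta = meta),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws:", nrow(x$draws), "draws x", length(x$params),
      "parameters (", x$meta$chains, "chains,", x$meta$iterations,
      "iterations, warmup", x$meta$warmup, ")\n")
  print(posterior_summary(x), digits = 3)
  invisible(x)
}

#' @export
as.data.frame.posterior_draws <- function(x, ...) x$draws

jags_normal <- function(p) sprintf("dnorm(%g, %g)", p$pars$mean,
                                   1 / p$pars$sd^2)
jags_gamma <- function(p) sprintf("dgamma(%g, %g)", p$pars$shape, p$pars$rate)

check_count_data <- function(dataset, need) {
  stopifnot(is.data.frame(dataset), all(need %in% names(dataset)))
  if (nrow(dataset) > 0L) {
    N <- unique(dataset$N)
    stopifnot(length(N) == 1L, all(dataset$resp >= 0), all(dataset$resp <= N))
  }
  invisible(dataset)
}

#' Fit the Beta-Binomial logistic model of counts on proprandom
#'
#' Per-participant intervention counts `resp` out of `N` trials follow a
#' Beta-Binomial whose mean probability is `inv_logit(beta0 + beta1 *
#' proprandom)`; the Beta mixing (scale `phi`) absorbs within-participant
#' over-dispersion. Priors: Normal(0, 10) on the coefficients, Gamma(2, 0.1)
#' on `phi`. A zero-row dataset yields prior-only draws.
#'
#' @param dataset Data frame with columns `resp`, `proprandom`, `N` (constant).
#' @param priors List with `prior_spec` elements `coef` and `phi`.
#' @param mcmc An [mcmc_config()].
#' @param likelihood `"betabinomial"` (default) or `"binomial"` (no mixing;
#'   used for the over-dispersion posterior predictive comparison).
#' @return A `posterior_draws` over `beta0`, `beta1` (and `phi` for the
#'   Beta-Binomial likelihood), with an `rhat` element in `meta` and a
#'   diagnostic warning attached if any split-chain Rhat exceeds 1.05.
#' @export
fit_model_a <- function(dataset, priors = default_priors(),
                        mcmc = mcmc_config(),
                        likelihood = c("betabinomial", "binomial")) {
  likelihood <- match.arg(likelihood)
  check_count_data(dataset, c("resp", "proprandom", "N"))
  stopifnot(nrow(dataset) == 0L ||
              (all(dataset$proprandom >= 0) && all(dataset$proprandom <= 1)))
  fit_count_model(dataset, x_cols = "proprandom",
                  coef_names = c("beta0", "beta1"), priors = priors,
                  mcmc = mcmc, likelihood = likelihood, model_tag = "a")
}

#' Fit the Beta-Binomial logistic model of counts on RLLevel
#'
#' As [fit_model_a()] but with linear predictor `gamma0 + gamma1 * M +
#' gamma2 * H`, where `M` and `H` are the Medium and High dummies of the
#' three-level learning factor (None is the reference).
#'
#' @param dataset Data frame with columns `resp`, `M`, `H`, `N`; a `group`
#'   column may stand in for the dummies.
#' @inheritParams fit_model_a
#' @return A `posterior_draws` over `gamma0`, `gamma1`, `gamma2` (and `phi`).
#' @export
fit_model_b <- function(dataset, priors = default_priors(),
                        mcmc = mcmc_config(),
                        likelihood = c("betabinomial", "binomial")) {
  likelihood <- match.arg(likelihood)
  if (!all(c("M", "H") %in% names(dataset)) && "group" %in% names(dataset)) {
    dataset$M <- as.integer(dataset$group == "Medium")
    dataset$H <- as.integer(dataset$group == "High")
  }
  check_count_data(dataset, c("resp", "M", "H", "N"))
  stopifnot(nrow(dataset) == 0L ||
              (all(dataset$M %in% 0:1) && all(dataset$H %in% 0:1)))
  fit_count_model(dataset, x_cols = c("M", "H"),
                  coef_names = c("gamma0", "gamma1", "gamma2"),
                  priors = priors, mcmc = mcmc, likelihood = likelihood,
                  model_tag = "b")
}

fit_count_model <- function(dataset, x_cols, coef_names, priors, mcmc,
                            likelihood, model_tag) {
  ncoef <- length(coef_names)
  lin <- paste0(coef_names[1L],
                if (ncoef > 1L)
                  paste0(" + ", coef_names[-1L], " * X[i, ",
                         seq_len(ncoef - 1L), "]", collapse = ""))
  prior_lines <- paste0(
    paste0("  ", coef_names, " ~ ", jags_normal(priors$coef),
           collapse = "\n"),
    if (likelihood == "betabinomial")
      paste0("\n  phi ~ ", jags_gamma(priors$phi)))
  n <- nrow(dataset)
  if (n == 0L) {
    ms <- paste0("model {\n", prior_lines, "\n}\n")
    dat <- list()
  } else {
    # Beta-Binomial handled on the marginal scale (Poisson zeros trick on the
    # log pmf, binomial coefficient dropped as a constant): avoids latent
    # per-subject probabilities, whose full conditionals have unbounded
    # density at the boundary for small phi.
    lik <- if (likelihood == "betabinomial") paste0(
      "    a[i] <- p[i] * phi\n",
      "    b[i] <- (1 - p[i]) * phi\n",
      "    ll[i] <- loggam(phi) - loggam(a[i]) - loggam(b[i]) +\n",
      "      loggam(resp[i] + a[i]) + loggam(N - resp[i] + b[i]) -\n",
      "      loggam(N + phi)\n",
      "    zeros[i] ~ dpois(-ll[i])")
    else
      "    resp[i] ~ dbin(p[i], N)"
    ms <- paste0(
      "model {\n  for (i in 1:n) {\n    logit(p[i]) <- ", lin, "\n",
      lik, "\n  }\n", prior_lines, "\n}\n")
    dat <- list(n = n, N = dataset$N[1L], resp = dataset$resp,
                X = as.matrix(dataset[, x_cols, drop = FALSE]))
    if (likelihood == "betabinomial") dat$zeros <- rep(0L, n)
    if (ncoef == 1L) dat$X <- NULL
  }
  monitor <- c(coef_names, if (likelihood == "betabinomial") "phi")
  out <- run_jags(ms, dat, monitor, mcmc, model_tag)
  out$meta$likelihood <- likelihood
  out$meta$data_n <- n
  attach_diagnostics(out)
}

attach_diagnostics <- function(draws, threshold = 1.05) {
  r <- rhat(draws)
  draws$meta$rhat <- r
  bad <- r[is.finite(r) & r > threshold]
  if (length(bad))
    warning("MCMC diagnostic: split-chain Rhat > ", threshold, " for ",
            paste(names(bad), collapse = ", "), call. = FALSE)
  draws
}

#' Per-draw response probabilities by learning level
#'
#' Transforms each posterior draw of the RLLevel model into the implied
#' response probabilities `p_none = inv_logit(gamma0)`, `p_medium =
#' inv_logit(gamma0 + gamma1)`, `p_high = inv_logit(gamma0 + gamma2)`. The
#' transform is applied draw by draw (not to posterior means), so summaries
#' of the result are the exact posterior summaries of the probabilities.
#'
#' @param draws A `posterior_draws` from [fit_model_b()].
#' @return A `posterior_draws` over `p_none`, `p_medium`, `p_high`.
#' @export
derived_probabilities <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"),
            all(c("gamma0", "gamma1", "gamma2") %in% draws$params))
  d <- draws$draws
  out <- data.frame(.chain = d$.chain, .iter = d$.iter,
                    p_none = inv_logit(d$gamma0),
                    p_medium = inv_logit(d$gamma0 + d$gamma1),
                    p_high = inv_logit(d$gamma0 + d$gamma2))
  posterior_draws(out, meta = c(draws$meta, list(derived = "rllevel_probs")))
}

#' Fit the simplex-constrained Bernoulli action-effect model
#'
#' Per-trial binary responses `y_i ~ Bernoulli(inv_logit(u_id + b_vl*vl +
#' b_pl*pl + b_bu*bu))`. Because the three action indicators sum to 1 on
#' every row, the action weights are identified through the constraint
#' `b >= 0, sum(b) = 1`, imposed exactly via a Dirichlet(1,1,1) prior (uniform
#' over the simplex); subject effects `u_k ~ Normal(0, 1)`. Every posterior
#' draw of `b` lies on the simplex by construction.
#'
#' @param trials Data frame with columns `id`, `vl`, `pl`, `bu`, `y`; each row
#'   must have exactly one of `vl`/`pl`/`bu` equal to 1.
#' @param priors List with `prior_spec` elements `b` (dirichlet) and `u`
#'   (normal).
#' @param mcmc An [mcmc_config()]; defaults to 8000 iterations and 4 chains
#'   (the model has one parameter per subject, so it needs longer runs than
#'   the count models).
#' @return A `posterior_draws` over `b_vl`, `b_pl`, `b_bu` and `u[k]`.
#' @export
fit_action_model <- function(trials, priors = default_priors(),
                             mcmc = mcmc_config(iterations = 8000L)) {
  stopifnot(is.data.frame(trials),
            all(c("id", "vl", "pl", "bu", "y") %in% names(trials)),
            nrow(trials) >= 1L)
  onehot <- trials$vl + trials$pl + trials$bu
  bad <- which(onehot != 1L |
                 !(trials$vl %in% 0:1 & trials$pl %in% 0:1 &
                     trials$bu %in% 0:1))
  if (length(bad))
    stop("fit_action_model: row ", bad[1L],
         " violates the one-hot action constraint", call. = FALSE)
  stopifnot(all(trials$y %in% 0:1))
  id <- as.integer(factor(trials$id))
  K <- max(id)
  ms <- paste0(
    "model {\n",
    "  for (i in 1:n) {\n",
    "    logit(p[i]) <- u[id[i]] + b[1] * vl[i] + b[2] * pl[i] + b[3] * bu[i]\n",
    "    y[i] ~ dbern(p[i])\n",
    "  }\n",
    "  for (k in 1:K) { u[k] ~ ", jags_normal(priors$u), " }\n",
    "  b ~ ddirch(alpha)\n",
    "}\n")
  dat <- list(n = nrow(trials), K = K, id = id, vl = trials$vl,
              pl = trials$pl, bu = trials$bu, y = trials$y,
              alpha = priors$b$pars$concentrations)
  out <- run_jags(ms, dat, c("b", "u"), mcmc, "c")
  names(out$draws) <- sub("^b\\[1\\]$", "b_vl", names(out$draws))
  names(out$draws) <- sub("^b\\[2\\]$", "b_pl", names(out$draws))
  names(out$draws) <- sub("^b\\[3\\]$", "b_bu", names(out$draws))
  out$params <- setdiff(names(out$draws), c(".chain", ".iter"))
  out$meta$data_n <- nrow(trials)
  out$meta$n_subjects <- K
  attach_diagnostics(out)
}

#' Posterior summary table
#'
#' Mean, SD, equal-tail 95% interval and `Prob > threshold` (the fraction of
#' draws strictly greater than the threshold; `threshold = 0` for regression
#' coefficients, `0.5` for probabilities and simplex weights).
#'
#' @param draws A `posterior_draws` (or data frame of draws).
#' @param threshold Exceedance threshold (default 0).
#' @param params Optional subset of parameter names.
#' @return Data frame with columns `parameter`, `mean`, `sd`, `q2.5`,
#'   `q97.5`, `prob_gt`.
#' @export
posterior_summary <- function(draws, threshold = 0, params = NULL) {
  d <- if (inherits(draws, "posterior_draws")) draws$draws else draws
  stopifnot(is.data.frame(d), nrow(d) > 0L)
  cols <- setdiff(names(d), c(".chain", ".iter"))
  if (!is.null(params)) cols <- intersect(cols, params)
  out <- do.call(rbind, lapply(cols, function(p) {
    x <- d[[p]]
    data.frame(parameter = p, mean = mean(x), sd = stats::sd(x),
               q2.5 = unname(stats::quantile(x, 0.025)),
               q97.5 = unname(stats::quantile(x, 0.975)),
               prob_gt = mean(x > threshold))
  }))
  attr(out, "threshold") <- threshold
  out
}

#' Posterior predictive simulation of intervention counts
#'
#' Simulates new per-participant counts from the fitted count model's
#' likelihood at the observed covariates: posterior draws and dataset rows
#' are cycled so that `n_sims` simulated `resp` values are produced (4000 is
#' the default used for the model-fit histograms).
#'
#' @param draws A `posterior_draws` from [fit_model_a()] or [fit_model_b()].
#' @param dataset The dataset the model was fitted to.
#' @param n_sims Number of simulated observations.
#' @return Integer vector of length `n_sims`.
#' @export
posterior_predictive_resp <- function(draws, dataset, n_sims = 4000L) {
  stopifnot(inherits(draws, "posterior_draws"), n_sims >= 0L)
  if (n_sims == 0L) return(integer(0))
  stopifnot(nrow(dataset) >= 1L)
  d <- draws$draws
  N <- dataset$N[1L]
  di <- rep_len(sample.int(nrow(d)), n_sims)
  ri <- rep_len(sample.int(nrow(dataset)), n_sims)
  if (all(c("beta0", "beta1") %in% draws$params)) {
    eta <- d$beta0[di] + d$beta1[di] * dataset$proprandom[ri]
  } else {
    eta <- d$gamma0[di] + d$gamma1[di] * dataset$M[ri] +
      d$gamma2[di] * dataset$H[ri]
  }
  p <- inv_logit(eta)
  if (identical(draws$meta$likelihood, "binomial")) {
    stats::rbinom(n_sims, N, p)
  } else {
    theta <- stats::rbeta(n_sims, p * d$phi[di], (1 - p) * d$phi[di])
    stats::rbinom(n_sims, N, theta)
  }
}

#' Posterior predictive simulation of per-trial responses
#'
#' For the action-effect model: simulates binary responses at the observed
#' trial covariates (16000 is the default used for the model check), and can
#' also return the per-trial posterior predictive mean response probability.
#'
#' @param draws A `posterior_draws` from [fit_action_model()].
#' @param trials The per-trial dataset the model was fitted to.
#' @param n_sims Number of simulated observations (`"mean_prob"` ignores it).
#' @param type `"y"` for simulated 0/1 responses, `"mean_prob"` for the
#'   per-trial posterior mean of the response probability (one value per
#'   observed trial).
#' @return Integer vector (`"y"`) or numeric vector of length `nrow(trials)`.
#' @export
posterior_predictive_y <- function(draws, trials, n_sims = 16000L,
                                   type = c("y", "mean_prob")) {
  type <- match.arg(type)
  stopifnot(inherits(draws, "posterior_draws"),
            all(c("b_vl", "b_pl", "b_bu") %in% draws$params))
  d <- draws$draws
  id <- as.integer(factor(trials$id))
  ucols <- paste0("u[", id, "]")
  if (type == "mean_prob") {
    B <- as.matrix(d[, c("b_vl", "b_pl", "b_bu")])
    X <- t(as.matrix(trials[, c("vl", "pl", "bu")]))
    U <- as.matrix(d[, paste0("u[", seq_len(max(id)), "]")])
    eta <- B %*% X + U[, id, drop = FALSE]
    return(colMeans(inv_logit(eta)))
  }
  if (n_sims == 0L) return(integer(0))
  di <- rep_len(sample.int(nrow(d)), n_sims)
  ri <- rep_len(sample.int(nrow(trials)), n_sims)
  eta <- d$b_vl[di] * trials$vl[ri] + d$b_pl[di] * trials$pl[ri] +
    d$b_bu[di] * trials$bu[ri] +
    as.numeric(d[cbind(di, match(ucols[ri], names(d)))])
  stats::rbinom(n_sims, 1L, inv_logit(eta))
}

#' Point-biserial correlation with Fisher-z confidence interval
#'
#' The Pearson correlation between a binary 0/1 vector and a continuous
#' vector, used as a one-number posterior predictive fit summary; the 95%
#' interval uses the Fisher z-transform.
#'
#' @param binary 0/1 vector (not constant).
#' @param continuous Numeric vector of the same length (>= 3).
#' @param conf Confidence level (default 0.95).
#' @return List with `r`, `ci` (length 2) and `n`.
#' @export
point_biserial <- function(binary, continuous, conf = 0.95) {
  stopifnot(length(binary) == length(continuous), length(binary) >= 3L,
            all(binary %in% 0:1))
  if (stats::sd(binary) == 0 || stats::sd(continuous) == 0)
    stop("point_biserial: correlation undefined for constant input",
         call. = FALSE)
  r <- stats::cor(binary, continuous)
  z <- atanh(r)
  se <- 1 / sqrt(length(binary) - 3)
  crit <- stats::qnorm(1 - (1 - conf) / 2)
  list(r = r, ci = tanh(c(z - crit * se, z + crit * se)), n = length(binary))
}

#' Split-chain potential scale reduction (Rhat)
#'
#' Each chain is split in half and the classical potential-scale-reduction
#' statistic computed over the resulting half-chains; values near 1 indicate
#' that the chains are comparable and mixed. Parameters with zero total
#' variance (constant draws) return `NA`, the documented sentinel for the
#' degenerate case.
#'
#' @param draws A `posterior_draws`, or a numeric matrix with one column per
#'   chain.
#' @return Named numeric vector of Rhat values (single unnamed value for a
#'   matrix input).
#' @export
rhat <- function(draws) {
  if (is.matrix(draws)) {
    if (ncol(draws) < 2L) stop("rhat: need >= 2 chains", call. = FALSE)
    return(split_rhat(draws))
  }
  stopifnot(inherits(draws, "posterior_draws"))
  d <- draws$draws
  chains <- sort(unique(d$.chain))
  if (length(chains) < 2L) stop("rhat: need >= 2 chains", call. = FALSE)
  vapply(stats::setNames(draws$params, draws$params), function(p) {
    m <- vapply(chains, function(ch) d[[p]][d$.chain == ch],
                numeric(sum(d$.chain == chains[1L])))
    split_rhat(m)
  }, numeric(1))
}

split_rhat <- function(m) {
  n <- nrow(m)
  if (n < 4L) stop("rhat: need >= 4 draws per chain", call. = FALSE)
  half <- n %/% 2L
  halves <- do.call(cbind, lapply(seq_len(ncol(m)), function(j)
    cbind(m[seq_len(half), j], m[(n - half + 1L):n, j])))
  if (stats::var(as.vector(halves)) == 0) return(NA_real_)
  nh <- nrow(halves)
  W <- mean(apply(halves, 2L, stats::var))
  B <- nh * stats::var(colMeans(halves))
  if (W == 0) return(Inf)
  sqrt(((nh - 1) / nh * W + B / nh) / W)
}
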