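#' Specify an input distribution for the Monte Carlo engine
#'
#' @param family One of `"point"`, `"normal"`, `"lognormal"`,
#'   `"triangular"`, `"uniform"`.
#' @param ... Family parameters: `value` (point); `mean`, `sd` (normal);
#'   `meanlog`, `sdlog` (lognormal); `min`, `mode`, `max` (triangular);
#'   `min`, `max` (uniform).
#' @param lower,upper Optional truncation bounds (applied by rejection).
#' @return A list of class `dist_spec`.
#' @export
dist_spec <- function(family = c("point", "normal", "lognormal",
                                 "triangular", "uniform"),
                      ..., lower = -Inf, upper = Inf) {
  family <- match.arg(family)
  pars <- list(...)
  need <- switch(family,
    point = "value", normal = c("mean", "sd"),
    lognormal = c("meanlog", "sdlog"),
    triangular = c("min", "mode", "max"), uniform = c("min", "max"))
  if (!all(need %in% names(pars))) {
    stop("family '", family, "' requires parameter(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (lower >= upper) stop("truncation bounds must satisfy lower < upper",
                           call. = FALSE)
  if (family == "normal" && pars$sd < 0) {
    stop("normal sd must be nonnegative", call. = FALSE)
  }
  if (family == "triangular" &&
      !(pars$min <= pars$mode && pars$mode <= pars$max && pars$min < pars$max)) {
    stop("triangular requires min <= mode <= max with min < max",
         call. = FALSE)
  }
  if (family == "uniform" && pars$min >= pars$max) {
    stop("uniform requires min < max", call. = FALSE)
  }
  structure(list(family = family, pars = pars, lower = lower, upper = upper),
            class = "dist_spec")
}

# Inverse CDF of the triangular distribution.
qtriangular <- function(p, min, mode, max) {
  f <- (mode - min) / (max - min)
  ifelse(p < f,
         min + sqrt(p * (max - min) * (mode - min)),
         max - sqrt((1 - p) * (max - min) * (max - mode)))
}

#' Draw from a `dist_spec`
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n` (point masses return the value
#'   recycled); truncation bounds are enforced by rejection.
#' @export
sample_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$pars
  draw <- function(m) {
    switch(spec$family,
      point = rep(p$value, m),
      normal = stats::rnorm(m, p$mean, p$sd),
      lognormal = stats::rlnorm(m, p$meanlog, p$sdlog),
      triangular = qtriangular(stats::runif(m), p$min, p$mode, p$max),
      uniform = stats::runif(m, p$min, p$max))
  }
  x <- draw(n)
  for (i in seq_len(1000)) {
    bad <- which(x < spec$lower | x > spec$upper)
    if (length(bad) == 0) break
    x[bad] <- draw(length(bad))
  }
  if (any(x < spec$lower | x > spec$upper)) {
    stop("rejection sampling failed to satisfy truncation bounds",
         call. = FALSE)
  }
  x
}

#' Default exposure-factor distributions for a receptor
#'
#' Body weight: normal, mean at the deterministic default, CV 0.2,
#' truncated at zero. Ingestion rate: triangular, mode at the default,
#' limbs at +/-50%. Exposure frequency: triangular (180, 350, 365)
#' days/year. All other factors are point masses at the deterministic
#' defaults.
#'
#' @param profile An [exposure_profile()].
#' @return Named list of [dist_spec()]s keyed by exposure-factor name.
#' @export
default_exposure_dists <- function(profile) {
  stopifnot(inherits(profile, "exposure_profile"))
  fixed <- c("ingestion_rate", "exposure_frequency", "body_weight",
             "exposure_duration", "skin_area", "adherence_factor",
             "dermal_absorption", "inhalation_rate", "pef")
  out <- lapply(fixed, function(nm) dist_spec("point", value = profile[[nm]]))
  names(out) <- fixed
  out$body_weight <- dist_spec("normal", mean = profile$body_weight,
                               sd = 0.2 * profile$body_weight, lower = 0)
  out$ingestion_rate <- dist_spec(
    "triangular", min = 0.5 * profile$ingestion_rate,
    mode = profile$ingestion_rate, max = 1.5 * profile$ingestion_rate)
  out$exposure_frequency <- dist_spec("triangular", min = 180, mode = 350,
                                      max = 365)
  out
}

#' Concentration distributions from an observed table
#'
#' One truncated-normal spec per element with the column mean and
#' standard deviation; columns with zero spread become point masses.
#'
#' @param conc A concentration table.
#' @param elements Elements to include; default all element columns.
#' @return Named list of [dist_spec()]s keyed by element.
#' @export
conc_dists_from_table <- function(conc, elements = NULL) {
  conc <- as_concentration_table(conc)
  if (is.null(elements)) elements <- conc_elements(conc)
  m <- conc_matrix(conc, elements)
  out <- lapply(elements, function(el) {
    mu <- mean(m[, el])
    sd <- if (nrow(m) > 1) stats::sd(m[, el]) else 0
    if (sd == 0) dist_spec("point", value = mu)
    else dist_spec("normal", mean = mu, sd = sd, lower = 0)
  })
  stats::setNames(out, elements)
}

#' Monte Carlo simulation of HI or TCR
#'
#' Samples element concentrations and exposure factors from the supplied
#' distributions, propagates each draw through the deterministic dose
#' equations, and summarizes the endpoint distribution together with
#' Spearman rank-correlation sensitivities of the endpoint to each
#' varying input. The non-carcinogenic averaging time tracks the drawn
#' exposure duration (`ED * 365` days); the carcinogenic averaging time
#' stays fixed at 70 years. With every distribution a point mass, the
#' result equals the deterministic model exactly.
#'
#' @param conc_dists Named list of [dist_spec()]s keyed by element.
#' @param exposure_dists Named list of [dist_spec()]s keyed by
#'   exposure-factor name; defaults to [default_exposure_dists()] for
#'   the chosen receptor profile.
#' @param tox A [load_toxicology()] table.
#' @param receptor `"child"` or `"adult"` (selects the base profile for
#'   any factor without a spec).
#' @param endpoint `"HI"` or `"TCR"`.
#' @param n Number of iterations (default 10000).
#' @param seed Mandatory RNG seed.
#' @param profile Base [exposure_profile()]; defaults to the receptor's
#'   entry in [default_exposure_profiles()].
#' @param es Element grouping (REY/HM membership, reserved for
#'   group-restricted runs).
#' @param safety_limit Exceedance threshold; defaults to 1 for HI and
#'   1e-6 for TCR.
#' @return A list of class `mcs_result`: `receptor`, `endpoint`,
#'   `n_iterations`, `seed`, `mean`, `sd`, `percentiles` (5, 25, 50, 75,
#'   95), `exceedance_prob`, `sensitivity` (named Spearman rho, `NA` for
#'   degenerate inputs) and the raw `draws`.
#' @export
run_mcs <- function(conc_dists, exposure_dists = NULL,
                    tox = default_toxicology(),
                    receptor = c("child", "adult"),
                    endpoint = c("HI", "TCR"),
                    n = 10000, seed,
                    profile = NULL, es = element_set(),
                    safety_limit = NULL) {
  receptor <- match.arg(receptor)
  endpoint <- match.arg(endpoint)
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory for Monte Carlo runs", call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (is.null(profile)) profile <- default_exposure_profiles()[[receptor]]
  if (is.null(exposure_dists)) exposure_dists <- default_exposure_dists(profile)
  for (d in c(conc_dists, exposure_dists)) {
    stopifnot(inherits(d, "dist_spec"))
  }
  if (is.null(safety_limit)) {
    safety_limit <- if (endpoint == "HI") 1 else 1e-6
  }
  elements <- names(conc_dists)
  set.seed(as.integer(seed))

  C <- vapply(conc_dists, sample_dist, numeric(n), n = n)
  if (n == 1) C <- matrix(C, nrow = 1, dimnames = list(NULL, elements))

  factor_names <- c("ingestion_rate", "exposure_frequency",
                    "exposure_duration", "body_weight", "skin_area",
                    "adherence_factor", "dermal_absorption",
                    "inhalation_rate", "pef")
  f <- lapply(factor_names, function(nm) {
    if (!is.null(exposure_dists[[nm]])) sample_dist(exposure_dists[[nm]], n)
    else rep(profile[[nm]], n)
  })
  names(f) <- factor_names
  f$unit_conversion <- profile$unit_conversion
  at_nc <- f$exposure_duration * 365
  at_ca <- profile$averaging_time_ca

  draws <- if (endpoint == "HI") {
    rfd <- tox_values(tox, "rfd", elements)
    add <- Reduce(`+`, lapply(hr_pathways, function(pw) {
      dose_rate(C, f, pw, at_nc)
    }))
    rowSums(sweep(add, 2, rfd, "/"))
  } else {
    csf <- tox_values(tox, "csf", elements, required = FALSE)
    csf[is.na(csf)] <- 0
    ladd <- dose_rate(C, f, "ingestion", at_ca)
    rowSums(sweep(ladd, 2, csf, "*"))
  }

  inputs <- c(stats::setNames(lapply(elements, function(el) C[, el]),
                              paste0("conc_", elements)),
              f[factor_names])
  sd_draws <- stats::sd(draws)
  sensitivity <- vapply(inputs, function(v) {
    sv <- stats::sd(v)
    if (is.na(sv) || sv == 0 || is.na(sd_draws) || sd_draws == 0) NA_real_
    else suppressWarnings(stats::cor(v, draws, method = "spearman"))
  }, numeric(1))

  qs <- stats::quantile(draws, probs = c(0.05, 0.25, 0.50, 0.75, 0.95),
                        names = TRUE, type = 7)
  structure(
    list(receptor = receptor, endpoint = endpoint,
         n_iterations = n, seed = as.integer(seed),
         mean = mean(draws), sd = stats::sd(draws),
         percentiles = qs,
         exceedance_prob = mean(draws > safety_limit),
         safety_limit = safety_limit,
         sensitivity = sensitivity,
         draws = draws),
    class = "mcs_result")
}

#' Rank inputs by sensitivity
#'
#' Orders the Monte Carlo input variables by the absolute Spearman rank
#' correlation of their draws with the endpoint; degenerate (point-mass)
#' inputs are dropped and ties break alphabetically by variable name.
#'
#' @param result An [run_mcs()] result.
#' @return Data.frame: `variable`, `rho`, `abs_rho`, ordered descending.
#' @export
sensitivity_ranking <- function(result) {
  stopifnot(inherits(result, "mcs_result"))
  s <- result$sensitivity[!is.na(result$sensitivity)]
  out <- data.frame(variable = names(s), rho = unname(s),
                    abs_rho = abs(unname(s)), stringsAsFactors = FALSE)
  out <- out[order(-out$abs_rho, out$variable), , drop = FALSE]
  rownames(out) <- NULL
  out
}
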