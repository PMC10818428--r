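#' Pearson correlation matrix across elements
#'
#' Pairwise Pearson correlations of element concentrations across
#' samples; strong positive inter-REY correlations indicate shared
#' provenance and co-occurrence.
#'
#' @param conc A concentration table with at least 3 samples.
#' @param elements Elements to correlate; default all element columns.
#' @return List of class `correlation_matrix`: `elements`, `r`
#'   (symmetric matrix), `n` (sample count). Constant columns yield `NA`
#'   entries with a warning.
#' @export
pearson_matrix <- function(conc, elements = NULL) {
  conc <- as_concentration_table(conc)
  if (is.null(elements)) elements <- conc_elements(conc)
  m <- conc_matrix(conc, elements, require_positive = FALSE)
  if (nrow(m) < 3) stop("need at least 3 samples for correlations",
                        call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant element column(s), correlations undefined (NA): ",
            paste(elements[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(m, method = "pearson"))
  structure(list(elements = elements, r = r, n = nrow(m)),
            class = "correlation_matrix")
}

#' Ryan-Joiner normality statistic
#'
#' Correlation between the ordered sample and Blom normal scores
#' \eqn{b_i = \Phi^{-1}((i - 3/8)/(n + 1/4))}, a probability-plot
#' correlation test of normality closely related to Shapiro-Wilk. The
#' statistic lies in (0, 1]; values below the critical value at
#' alpha = 0.05 reject normality. The critical value uses the standard
#' approximation \eqn{CV_{0.05} = 1.0063 - 0.1288/\sqrt{n} - 0.6118/n +
#' 1.3505/n^2}.
#'
#' @param x Numeric vector, n >= 4, not constant.
#' @return List of class `ryan_joiner`: `statistic`, `n`,
#'   `critical_value`, `normal` (logical pass at alpha = 0.05).
#' @export
ryan_joiner <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("missing values not allowed", call. = FALSE)
  n <- length(x)
  if (n < 4) stop("Ryan-Joiner test needs n >= 4", call. = FALSE)
  if (stats::sd(x) == 0) stop("input is constant; normality undefined",
                              call. = FALSE)
  b <- stats::qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4))
  statistic <- stats::cor(sort(x), b)
  cv <- 1.0063 - 0.1288 / sqrt(n) - 0.6118 / n + 1.3505 / n^2
  structure(list(statistic = statistic, n = n, critical_value = cv,
                 normal = statistic >= cv),
            class = "ryan_joiner")
}
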