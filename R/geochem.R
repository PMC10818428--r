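#' Normalize REY concentrations to a reference composition
#'
#' Divides each sample's REY concentrations element-wise by a reference
#' composition (UCC for crust-normalized spider patterns, NASC for
#' anomaly calculation). A ratio above 1 marks enrichment relative to
#' the reference.
#'
#' @param conc A concentration table (see [as_concentration_table()]).
#' @param ref A [load_reference_set()] covering all 15 REYs.
#' @param elements Elements to normalize; defaults to the full REY set.
#' @return Long data.frame of class `rey_pattern`: `sample_id`,
#'   `element`, `ratio`, plus attribute `reference_name`.
#' @export
normalize_rey <- function(conc, ref, elements = element_set()$reys) {
  conc <- as_concentration_table(conc)
  m <- conc_matrix(conc, elements)
  rv <- ref_values(ref, elements, context = "normalization")
  ratios <- sweep(m, 2, rv, "/")
  out <- data.frame(
    sample_id = rep(rownames(ratios), times = length(elements)),
    element = rep(elements, each = nrow(ratios)),
    ratio = as.vector(ratios),
    stringsAsFactors = FALSE
  )
  attr(out, "reference_name") <- ref$name
  class(out) <- c("rey_pattern", "data.frame")
  out
}

#' Cerium and europium anomalies from a shale-normalized pattern
#'
#' The anomaly is the ratio of the measured normalized concentration to
#' the value interpolated geometrically from the flanking elements:
#' \deqn{Ce/Ce^{*} = Ce_N / \sqrt{La_N \cdot Pr_N}, \qquad
#'       Eu/Eu^{*} = Eu_N / \sqrt{Sm_N \cdot Gd_N}}
#' where the subscript N denotes NASC-normalized concentrations. Values
#' above 1 are positive anomalies, below 1 negative.
#'
#' @param pattern A `rey_pattern` from [normalize_rey()], normalized to
#'   NASC (any reference works arithmetically; NASC is conventional).
#' @return Data.frame: `sample_id`, `ce_anomaly`, `eu_anomaly`.
#' @export
rey_anomalies <- function(pattern) {
  need <- c("La", "Ce", "Pr", "Sm", "Eu", "Gd")
  wide <- split(pattern, pattern$sample_id)
  res <- lapply(wide, function(d) {
    v <- stats::setNames(d$ratio, d$element)
    if (!all(need %in% names(v))) {
      stop("pattern for sample '", d$sample_id[1], "' lacks element(s): ",
           paste(setdiff(need, names(v)), collapse = ", "), call. = FALSE)
    }
    if (any(v[need] <= 0)) {
      stop("nonpositive normalized value in sample '", d$sample_id[1], "'",
           call. = FALSE)
    }
    data.frame(
      sample_id = d$sample_id[1],
      ce_anomaly = unname(v["Ce"] / sqrt(v["La"] * v["Pr"])),
      eu_anomaly = unname(v["Eu"] / sqrt(v["Sm"] * v["Gd"])),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  # preserve input sample order rather than split()'s alphabetical order
  out <- out[match(unique(pattern$sample_id), out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resource-prospectivity metrics for REYs
#'
#' Partitions the total REY content into light/heavy and
#' critical/excessive groups and computes the two screening parameters
#' used to judge ash as a secondary REY source: the critical percentage
#' (share of total REY held by the critical group Eu, Tb, Nd, Dy, Y, Er)
#' and the outlook coefficient (critical-to-excessive ratio; excessive =
#' Ce, Yb, Ho, Tm, Lu). Material with critical percentage >= 30% and
#' outlook >= 0.7 is flagged as promising.
#'
#' @param conc A concentration table with all 15 REYs.
#' @param es Element grouping, defaults to [element_set()].
#' @return Data.frame per sample: `sample_id`, `sum_rey`, `sum_lrey`,
#'   `sum_hrey`, `lrey_hrey_ratio`, `sum_critical`, `sum_excessive`,
#'   `pct_critical`, `outlook`, `promising`.
#' @export
rey_prospectivity <- function(conc, es = element_set()) {
  conc <- as_concentration_table(conc)
  m <- conc_matrix(conc, es$reys)
  grp_sum <- function(els) rowSums(m[, els, drop = FALSE])
  sum_rey <- grp_sum(es$reys)
  sum_critical <- grp_sum(es$critical)
  sum_excessive <- grp_sum(es$excessive)
  pct_critical <- 100 * sum_critical / sum_rey
  outlook <- sum_critical / sum_excessive
  data.frame(
    sample_id = rownames(m),
    sum_rey = unname(sum_rey),
    sum_lrey = unname(grp_sum(es$lreys)),
    sum_hrey = unname(grp_sum(es$hreys)),
    lrey_hrey_ratio = unname(grp_sum(es$lreys) / grp_sum(es$hreys)),
    sum_critical = unname(sum_critical),
    sum_excessive = unname(sum_excessive),
    pct_critical = unname(pct_critical),
    outlook = unname(outlook),
    promising = unname(pct_critical >= 30 & outlook >= 0.7),
    stringsAsFactors = FALSE
  )
}
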