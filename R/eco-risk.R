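#' Enrichment factor relative to a crustal background
#'
#' Double ratio of element x to the reference element (Mn by default) in
#' the sample versus the background composition:
#' \deqn{EF = (C_x/C_{Mn})_{sample} / (C_x/C_{Mn})_{UCC}}
#' EF is invariant under uniform dilution of a sample, which is why it is
#' preferred over raw ratios for combustion residues. Classified into
#' five enrichment levels from minimal (<2) to extremely high (>= 40).
#'
#' @param conc A concentration table that includes the reference element.
#' @param ref A background [load_reference_set()] (UCC).
#' @param elements Elements to score; defaults to every element present
#'   in both the table and the reference set (minus the reference
#'   element itself).
#' @return Long data.frame: `sample_id`, `element`, `ef`, `ef_class`.
#' @export
enrichment_factor <- function(conc, ref, elements = NULL) {
  conc <- as_concentration_table(conc)
  ref_el <- ref$ef_reference
  if (!ref_el %in% names(conc)) {
    stop("concentration table lacks the EF reference element '", ref_el, "'",
         call. = FALSE)
  }
  if (is.null(elements)) {
    elements <- setdiff(intersect(conc_elements(conc), names(ref$values)),
                        ref_el)
  }
  m <- conc_matrix(conc, elements)
  ref_conc <- conc_matrix(conc, ref_el)[, 1]
  bg <- ref_values(ref, elements, context = "enrichment factor")
  bg_ref <- ref_values(ref, ref_el, context = "enrichment factor")
  ef <- sweep(m / ref_conc, 2, bg / bg_ref, "/")
  data.frame(
    sample_id = rep(rownames(m), times = length(elements)),
    element = rep(elements, each = nrow(m)),
    ef = as.vector(ef),
    ef_class = classify_ef(as.vector(ef)),
    stringsAsFactors = FALSE
  )
}

#' Geoaccumulation index
#'
#' \deqn{I_{geo} = \log_2[C_x / (1.5\, C_N)]}
#' where \eqn{C_N} is the background (UCC) concentration and the factor
#' 1.5 absorbs natural background fluctuation. Zero at 1.5x background,
#' 1 at 3x background; classified into seven classes from unpolluted
#' (<= 0) to extremely polluted (> 5).
#'
#' @inheritParams enrichment_factor
#' @return Long data.frame: `sample_id`, `element`, `igeo`, `igeo_class`.
#' @export
geoaccumulation <- function(conc, ref, elements = NULL) {
  conc <- as_concentration_table(conc)
  if (is.null(elements)) {
    elements <- intersect(conc_elements(conc), names(ref$values))
  }
  m <- conc_matrix(conc, elements)
  bg <- ref_values(ref, elements, context = "geoaccumulation index")
  igeo <- log2(sweep(m, 2, 1.5 * bg, "/"))
  data.frame(
    sample_id = rep(rownames(m), times = length(elements)),
    element = rep(elements, each = nrow(m)),
    igeo = as.vector(igeo),
    igeo_class = classify_igeo(as.vector(igeo)),
    stringsAsFactors = FALSE
  )
}

#' Hakanson potential ecological risk index
#'
#' Per-element risk coefficient \eqn{E_r = T_r \cdot C_x / C_N} (toxicity
#' response coefficient times the ratio of measured concentration to the
#' UCC background) summed over the requested elements into the risk
#' index \eqn{RI = \sum_i E_{r,i}}. Samples are classified into four
#' levels: low (RI < 150), moderate (150 <= RI <= 300), high
#' (300 < RI < 600) and very high (RI >= 600).
#'
#' @param conc A concentration table.
#' @param ref Background [load_reference_set()] (UCC).
#' @param tox A [load_toxicology()] table providing `tr`.
#' @param elements Elements to include; defaults to all elements of the
#'   table that carry a toxicity response coefficient.
#' @param es Element grouping used for the REY/HM split of RI.
#' @return List of class `eco_risk`: `$er` (long data.frame `sample_id`,
#'   `element`, `er`, `share`) and `$ri` (per sample: `ri_rey`, `ri_hm`,
#'   `ri_total`, `risk_class`).
#' @export
ecological_risk <- function(conc, ref, tox, elements = NULL,
                            es = element_set()) {
  conc <- as_concentration_table(conc)
  if (is.null(elements)) {
    have_tr <- tox$element[!is.na(tox$tr)]
    elements <- intersect(conc_elements(conc), have_tr)
  }
  m <- conc_matrix(conc, elements)
  bg <- ref_values(ref, elements, context = "ecological risk")
  tr <- tox_values(tox, "tr", elements)
  er <- sweep(sweep(m, 2, bg, "/"), 2, tr, "*")
  ri_total <- rowSums(er)
  is_rey <- elements %in% es$reys
  ri_rey <- rowSums(er[, is_rey, drop = FALSE])
  ri_hm <- rowSums(er[, elements %in% es$hms, drop = FALSE])
  er_long <- data.frame(
    sample_id = rep(rownames(m), times = length(elements)),
    element = rep(elements, each = nrow(m)),
    er = as.vector(er),
    share = as.vector(er / ri_total),
    stringsAsFactors = FALSE
  )
  ri <- data.frame(
    sample_id = rownames(m),
    ri_rey = unname(ri_rey),
    ri_hm = unname(ri_hm),
    ri_total = unname(ri_total),
    risk_class = classify_ri(unname(ri_total)),
    stringsAsFactors = FALSE
  )
  structure(list(er = er_long, ri = ri), class = "eco_risk")
}

#' Ordinal classification of EF, Igeo and RI values
#'
#' Bin boundaries follow the standard contamination-assessment
#' literature; `breaks` can be overridden for local conventions.
#'
#' @param x Numeric vector of index values.
#' @param breaks,labels Override the default bins.
#' @return Ordered factor of class labels.
#' @export
classify_ef <- function(x,
                        breaks = c(-Inf, 2, 5, 20, 40, Inf),
                        labels = c("minimal", "moderate", "significant",
                                   "very high", "extremely high")) {
  cut(x, breaks = breaks, labels = labels, right = FALSE, ordered_result = TRUE)
}

#' @rdname classify_ef
#' @export
classify_igeo <- function(x,
                          breaks = c(-Inf, 0, 1, 2, 3, 4, 5, Inf),
                          labels = c("unpolluted",
                                     "unpolluted to moderately polluted",
                                     "moderately polluted",
                                     "moderately to heavily polluted",
                                     "heavily polluted",
                                     "heavily to extremely polluted",
                                     "extremely polluted")) {
  cut(x, breaks = breaks, labels = labels, right = TRUE, ordered_result = TRUE)
}

#' @rdname classify_ef
#' @export
classify_ri <- function(x) {
  # low < 150; moderate 150..300 (closed); high (300, 600); very high >= 600
  out <- ifelse(x < 150, "low",
         ifelse(x <= 300, "moderate",
         ifelse(x < 600, "high", "very high")))
  factor(out, levels = c("low", "moderate", "high", "very high"),
         ordered = TRUE)
}
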