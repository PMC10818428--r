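# Core dose-rate kernel shared by the deterministic model and the Monte
# Carlo engine. `C` is a concentration (mg/kg) scalar/vector/matrix, `f` a
# list of exposure factors (scalars or draw vectors), `at` the averaging
# time in days. Returns a dose in mg per kg body weight per day.
dose_rate <- function(C, f, pathway, at) {
  switch(pathway,
    ingestion = C * f$ingestion_rate * f$exposure_frequency *
      f$exposure_duration / (f$body_weight * at) * f$unit_conversion,
    dermal = C * f$skin_area * f$adherence_factor * f$dermal_absorption *
      f$exposure_frequency * f$exposure_duration /
      (f$body_weight * at) * f$unit_conversion,
    inhalation = C * f$inhalation_rate * f$exposure_frequency *
      f$exposure_duration / (f$pef * f$body_weight * at),
    stop("unknown pathway: ", pathway, call. = FALSE)
  )
}

hr_pathways <- c("ingestion", "dermal", "inhalation")

#' Average daily dose per pathway
#'
#' USEPA residential-soil dose equations for incidental ingestion,
#' dermal contact and inhalation of resuspended particles:
#' \deqn{ADD_{ing} = \frac{C \cdot IR \cdot EF \cdot ED}{BW \cdot AT} \times 10^{-6}}
#' \deqn{ADD_{derm} = \frac{C \cdot SA \cdot AF \cdot ABS \cdot EF \cdot ED}{BW \cdot AT} \times 10^{-6}}
#' \deqn{ADD_{inh} = \frac{C \cdot InhR \cdot EF \cdot ED}{PEF \cdot BW \cdot AT}}
#' with AT the non-carcinogenic averaging time (`ED * 365` d) for
#' `add_nc` and the lifetime 70 * 365 d for `ladd_ca`.
#'
#' @param conc A concentration table (mg/kg).
#' @param profile An [exposure_profile()].
#' @param pathways Subset of `"ingestion"`, `"dermal"`, `"inhalation"`.
#' @param elements Elements to score; default all element columns.
#' @return Long data.frame: `sample_id`, `receptor`, `element`,
#'   `pathway`, `add_nc`, `ladd_ca` (both mg kg^-1 day^-1).
#' @export
daily_dose <- function(conc, profile, pathways = hr_pathways,
                       elements = NULL) {
  conc <- as_concentration_table(conc)
  stopifnot(inherits(profile, "exposure_profile"))
  pathways <- match.arg(pathways, hr_pathways, several.ok = TRUE)
  if (is.null(elements)) elements <- conc_elements(conc)
  m <- conc_matrix(conc, elements, require_positive = FALSE)
  if (any(m < 0)) stop("negative concentration", call. = FALSE)
  out <- lapply(pathways, function(pw) {
    add_nc <- dose_rate(m, profile, pw, profile$averaging_time_nc)
    ladd_ca <- dose_rate(m, profile, pw, profile$averaging_time_ca)
    data.frame(
      sample_id = rep(rownames(m), times = length(elements)),
      receptor = profile$receptor,
      element = rep(elements, each = nrow(m)),
      pathway = pw,
      add_nc = as.vector(add_nc),
      ladd_ca = as.vector(ladd_ca),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

# Split an element vector into REY / HM partial sums of a per-element matrix.
split_sums <- function(mat, elements, es) {
  list(rey = rowSums(mat[, elements %in% es$reys, drop = FALSE]),
       hm = rowSums(mat[, elements %in% es$hms, drop = FALSE]))
}

#' Non-carcinogenic hazard quotients and hazard index
#'
#' For each element the hazard quotient HQ is the summed-pathway
#' non-carcinogenic average daily dose divided by the oral reference
#' dose; the hazard index HI sums HQ over elements. The single oral RfD
#' is applied to all three pathways. HI > 1 flags potential
#' non-carcinogenic concern.
#'
#' @param conc A concentration table (mg/kg).
#' @param profiles A single [exposure_profile()] or a list of them
#'   (default both receptors from [default_exposure_profiles()]).
#' @param tox A [load_toxicology()] table providing `rfd`.
#' @param elements Elements to score; default: all element columns with
#'   an RfD in `tox`.
#' @param es Element grouping for the REY/HM partial sums.
#' @return List of class `health_risk`: `$hq` (long: `sample_id`,
#'   `receptor`, `element`, `hq`) and `$summary` (per sample and
#'   receptor: `hi`, `hi_rey`, `hi_hm`).
#' @export
hazard <- function(conc, profiles = default_exposure_profiles(),
                   tox = default_toxicology(), elements = NULL,
                   es = element_set()) {
  conc <- as_concentration_table(conc)
  if (inherits(profiles, "exposure_profile")) profiles <- list(profiles)
  if (is.null(elements)) {
    elements <- intersect(conc_elements(conc),
                          tox$element[!is.na(tox$rfd)])
  }
  m <- conc_matrix(conc, elements, require_positive = FALSE)
  rfd <- tox_values(tox, "rfd", elements)
  per_receptor <- lapply(profiles, function(p) {
    add <- Reduce(`+`, lapply(hr_pathways, function(pw) {
      dose_rate(m, p, pw, p$averaging_time_nc)
    }))
    hq <- sweep(add, 2, rfd, "/")
    parts <- split_sums(hq, elements, es)
    list(
      hq = data.frame(
        sample_id = rep(rownames(m), times = length(elements)),
        receptor = p$receptor,
        element = rep(elements, each = nrow(m)),
        hq = as.vector(hq),
        stringsAsFactors = FALSE),
      summary = data.frame(
        sample_id = rownames(m),
        receptor = p$receptor,
        hi = unname(rowSums(hq)),
        hi_rey = unname(parts$rey),
        hi_hm = unname(parts$hm),
        stringsAsFactors = FALSE)
    )
  })
  structure(
    list(hq = do.call(rbind, lapply(per_receptor, `[[`, "hq")),
         summary = do.call(rbind, lapply(per_receptor, `[[`, "summary"))),
    class = "health_risk")
}

#' Carcinogenic risk and target cancer risk
#'
#' Per-element cancer risk CR is the lifetime average daily ingestion
#' dose (averaged over 70 years) times the oral cancer slope factor;
#' TCR sums CR over elements. Elements without an established CSF
#' (`NA` in the toxicology table) contribute zero. The conventional
#' acceptability band is 1e-6 to 1e-4.
#'
#' @inheritParams hazard
#' @param elements Elements to score; default: all element columns
#'   present in `tox` (CSF may be `NA`).
#' @return List of class `health_risk`: `$cr` (long) and `$summary`
#'   (per sample and receptor: `tcr`, `tcr_rey`, `tcr_hm`, and logical
#'   flags `above_1e6`, `above_1e4`).
#' @export
cancer_risk <- function(conc, profiles = default_exposure_profiles(),
                        tox = default_toxicology(), elements = NULL,
                        es = element_set()) {
  conc <- as_concentration_table(conc)
  if (inherits(profiles, "exposure_profile")) profiles <- list(profiles)
  if (is.null(elements)) {
    elements <- intersect(conc_elements(conc), tox$element)
  }
  m <- conc_matrix(conc, elements, require_positive = FALSE)
  csf <- tox_values(tox, "csf", elements, required = FALSE)
  csf[is.na(csf)] <- 0
  per_receptor <- lapply(profiles, function(p) {
    ladd <- dose_rate(m, p, "ingestion", p$averaging_time_ca)
    cr <- sweep(ladd, 2, csf, "*")
    parts <- split_sums(cr, elements, es)
    tcr <- rowSums(cr)
    list(
      cr = data.frame(
        sample_id = rep(rownames(m), times = length(elements)),
        receptor = p$receptor,
        element = rep(elements, each = nrow(m)),
        cr = as.vector(cr),
        stringsAsFactors = FALSE),
      summary = data.frame(
        sample_id = rownames(m),
        receptor = p$receptor,
        tcr = unname(tcr),
        tcr_rey = unname(parts$rey),
        tcr_hm = unname(parts$hm),
        above_1e6 = unname(tcr > 1e-6),
        above_1e4 = unname(tcr > 1e-4),
        stringsAsFactors = FALSE)
    )
  })
  structure(
    list(cr = do.call(rbind, lapply(per_receptor, `[[`, "cr")),
         summary = do.call(rbind, lapply(per_receptor, `[[`, "summary"))),
    class = "health_risk")
}

#' Mean share of a risk component in the total
#'
#' Utility for headline aggregates such as "REYs account for 2.6% of the
#' mean hazard index": the ratio of the mean of a component column to
#' the mean of the corresponding total, in percent.
#'
#' @param component Numeric vector (e.g. per-sample REY HI).
#' @param total Numeric vector of the same length (total HI).
#' @return Percentage (scalar).
#' @export
risk_share <- function(component, total) {
  stopifnot(length(component) == length(total), length(total) > 0)
  100 * mean(component) / mean(total)
}
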