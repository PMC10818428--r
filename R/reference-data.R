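#' Element groupings used throughout the package
#'
#' Returns the canonical element sets: the 15 rare earth elements plus
#' yttrium (REYs, promethium excluded as it has no stable isotope and
#' scandium treated separately), their light/heavy partition, the
#' demand-based critical and excessive subgroups used in resource
#' evaluation, and the heavy metal(loid)s covered by the shipped
#' toxicology tables.
#'
#' @return A list of class `element_set` with character vectors
#'   `reys`, `lreys`, `hreys`, `critical`, `excessive` and `hms`.
#' @examples
#' es <- element_set()
#' setdiff(es$reys, c(es$lreys, es$hreys))  # empty: the partition covers all
#' @export
element_set <- function() {
  es <- list(
    reys = c("La", "Ce", "Pr", "Nd", "Sm", "Eu", "Gd",
             "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Y"),
    lreys = c("La", "Ce", "Pr", "Nd", "Sm", "Eu", "Gd"),
    hreys = c("Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Y"),
    critical = c("Eu", "Tb", "Nd", "Dy", "Y", "Er"),
    excessive = c("Ce", "Yb", "Ho", "Tm", "Lu"),
    hms = c("As", "Cr", "V", "Pb", "Ni", "Mn", "Ba",
            "Cd", "Cu", "Mo", "Co", "Hg", "Zn")
  )
  class(es) <- "element_set"
  es
}

#' Load a reference composition (background/normalization values)
#'
#' Reads a per-element reference composition, either one of the shipped
#' sets or a user CSV with columns `element,value` (optionally `unit`,
#' `source`). Shipped sets:
#' \describe{
#'   \item{`"ucc_rudnick_gao_2003"`}{Upper Continental Crust average
#'     composition, the background for enrichment factor, geoaccumulation
#'     index and ecological risk.}
#'   \item{`"nasc_gromet_1984"`}{North American Shale Composite, the
#'     normalization basis for Ce and Eu anomalies.}
#' }
#'
#' @param name_or_path Name of a shipped set or path to a CSV file.
#' @param ef_reference Reference element for the enrichment factor
#'   (default `"Mn"`).
#' @return A list of class `reference_set` with fields `name`, `values`
#'   (named numeric vector, mg/kg), `ef_reference` and `source`.
#' @export
load_reference_set <- function(name_or_path, ef_reference = "Mn") {
  builtin <- c("ucc_rudnick_gao_2003", "nasc_gromet_1984")
  if (name_or_path %in% builtin) {
    path <- system.file("extdata", paste0(name_or_path, ".csv"),
                        package = "reyrisk", mustWork = TRUE)
    name <- name_or_path
  } else {
    if (!file.exists(name_or_path)) {
      stop("reference set not found: '", name_or_path,
           "' is neither a shipped set (",
           paste(builtin, collapse = ", "), ") nor an existing file",
           call. = FALSE)
    }
    path <- name_or_path
    name <- basename(path)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("element", "value") %in% names(tab))) {
    stop("reference CSV must have columns 'element' and 'value'", call. = FALSE)
  }
  if (anyDuplicated(tab$element)) {
    stop("duplicated element in reference set: ",
         paste(unique(tab$element[duplicated(tab$element)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- stats::setNames(as.numeric(tab$value), tab$element)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    bad <- names(vals)[!is.finite(vals) | vals <= 0]
    stop("reference values must be strictly positive; offending element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(name = name, values = vals, ef_reference = ef_reference,
         source = if ("source" %in% names(tab)) tab$source[1] else NA_character_),
    class = "reference_set"
  )
}

#' Write a reference set back to CSV
#'
#' Inverse of [load_reference_set()]: the written file reloads to the
#' same values.
#'
#' @param ref A `reference_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reference_set <- function(ref, path) {
  stopifnot(inherits(ref, "reference_set"))
  utils::write.csv(
    data.frame(element = names(ref$values), value = unname(ref$values),
               unit = "mg/kg", source = ref$source),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Look up reference values for a set of elements, failing loudly when one is
# missing (a silent NA would propagate into every downstream index).
ref_values <- function(ref, elements, context = "requested index") {
  missing <- setdiff(elements, names(ref$values))
  if (length(missing) > 0) {
    stop("reference set '", ref$name, "' lacks element(s) required for ",
         context, ": ", paste(missing, collapse = ", "), call. = FALSE)
  }
  ref$values[elements]
}

#' Load or fetch the toxicology table (Tr, RfD, CSF)
#'
#' The shipped table combines Hakanson-type toxicity response coefficients
#' `tr` (dimensionless) with oral reference doses `rfd`
#' (mg kg^-1 day^-1) and oral cancer slope factors `csf`
#' ((mg kg^-1 day^-1)^-1). All 15 REYs share `rfd = 0.02` and
#' `csf = 3.2e-12`; a worst-case species is assumed for Cr (as Cr(VI)),
#' Hg (as Hg(II)) and As (inorganic). Elements with no established oral
#' CSF carry `NA` and contribute zero cancer risk.
#'
#' @param path Optional path to a user CSV with columns
#'   `element,tr,rfd,csf`; default loads the shipped table.
#' @return A data.frame of class `toxicology_table` with columns
#'   `element`, `tr`, `rfd`, `csf`.
#' @export
load_toxicology <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "toxicology.csv",
                        package = "reyrisk", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("element", "tr", "rfd", "csf")
  if (!all(need %in% names(tab))) {
    stop("toxicology CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[, intersect(c(need, "source"), names(tab))]
  for (col in c("tr", "rfd", "csf")) tab[[col]] <- as.numeric(tab[[col]])
  if (any(!is.na(tab$rfd) & tab$rfd <= 0)) {
    stop("reference doses must be strictly positive", call. = FALSE)
  }
  class(tab) <- c("toxicology_table", "data.frame")
  tab
}

#' @rdname load_toxicology
#' @export
default_toxicology <- function() load_toxicology()

#' Write a toxicology table to CSV
#'
#' @param tox A `toxicology_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_toxicology <- function(tox, path) {
  utils::write.csv(as.data.frame(tox), path, row.names = FALSE)
  invisible(path)
}

# Named lookup with a loud error; used by eco_risk and health_risk.
tox_values <- function(tox, column, elements, required = TRUE) {
  idx <- match(elements, tox$element)
  if (anyNA(idx)) {
    stop("toxicology table lacks element(s): ",
         paste(elements[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  vals <- stats::setNames(tox[[column]][idx], elements)
  if (required && anyNA(vals)) {
    stop("no '", column, "' value for element(s): ",
         paste(elements[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  vals
}

#' Construct an exposure profile for a receptor
#'
#' Bundles the USEPA residential-soil exposure factors for one receptor.
#' Non-carcinogenic doses are averaged over `exposure_duration * 365`
#' days; carcinogenic (lifetime) doses over a fixed 70 * 365 days for
#' both receptors.
#'
#' @param receptor `"child"` or `"adult"`.
#' @param ingestion_rate Ash/soil ingestion rate, mg/day.
#' @param exposure_frequency Days of exposure per year.
#' @param exposure_duration Exposure duration, years.
#' @param body_weight kg.
#' @param skin_area Exposed skin surface, cm^2.
#' @param adherence_factor Ash-to-skin adherence, mg/cm^2.
#' @param dermal_absorption Dimensionless absorbed fraction.
#' @param inhalation_rate m^3/day.
#' @param pef Particulate emission factor, m^3/kg.
#' @return A list of class `exposure_profile`; `averaging_time_nc` and
#'   `averaging_time_ca` (days) and the mg-to-kg `unit_conversion` are
#'   derived fields.
#' @export
exposure_profile <- function(receptor,
                             ingestion_rate,
                             exposure_frequency,
                             exposure_duration,
                             body_weight,
                             skin_area,
                             adherence_factor,
                             dermal_absorption,
                             inhalation_rate,
                             pef = 1.36e9) {
  receptor <- match.arg(receptor, c("child", "adult"))
  p <- list(
    receptor = receptor,
    ingestion_rate = ingestion_rate,
    exposure_frequency = exposure_frequency,
    exposure_duration = exposure_duration,
    body_weight = body_weight,
    averaging_time_nc = exposure_duration * 365,
    averaging_time_ca = 70 * 365,
    skin_area = skin_area,
    adherence_factor = adherence_factor,
    dermal_absorption = dermal_absorption,
    inhalation_rate = inhalation_rate,
    pef = pef,
    unit_conversion = 1e-6
  )
  num <- vapply(p[-1], is.numeric, logical(1))
  if (!all(num) || any(unlist(p[-1]) <= 0)) {
    stop("all exposure factors must be positive numbers", call. = FALSE)
  }
  class(p) <- "exposure_profile"
  p
}

#' Default child and adult exposure profiles
#'
#' USEPA residential-soil defaults: ingestion rate 200/100 mg/day,
#' exposure frequency 350 days/year, exposure duration 6/24 years, body
#' weight 15/70 kg, skin area 2373/6032 cm^2, adherence factor
#' 0.2/0.07 mg/cm^2, dermal absorption 0.001, inhalation rate
#' 7.6/20 m^3/day, particulate emission factor 1.36e9 m^3/kg
#' (child/adult respectively).
#'
#' @return Named list with `child` and `adult` [exposure_profile()]s.
#' @examples
#' default_exposure_profiles()$child$averaging_time_nc  # 2190 days
#' @export
default_exposure_profiles <- function() {
  list(
    child = exposure_profile("child",
      ingestion_rate = 200, exposure_frequency = 350, exposure_duration = 6,
      body_weight = 15, skin_area = 2373, adherence_factor = 0.2,
      dermal_absorption = 0.001, inhalation_rate = 7.6),
    adult = exposure_profile("adult",
      ingestion_rate = 100, exposure_frequency = 350, exposure_duration = 24,
      body_weight = 70, skin_area = 6032, adherence_factor = 0.07,
      dermal_absorption = 0.001, inhalation_rate = 20)
  )
}
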