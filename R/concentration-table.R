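#' Validate a concentration table
#'
#' A concentration table is a wide data.frame: one row per sample with a
#' `sample_id` column, an optional `type` column (`"fly"` or `"bottom"`)
#' and one numeric column per element, all in mg/kg dry weight.
#'
#' @param x A data.frame.
#' @return `x` with class `concentration_table` prepended.
#' @export
as_concentration_table <- function(x) {
  x <- as.data.frame(x)
  if (!"sample_id" %in% names(x)) {
    stop("concentration table requires a 'sample_id' column", call. = FALSE)
  }
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id)) {
    stop("duplicated sample_id: ",
         paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  elems <- conc_elements(x)
  for (el in elems) {
    v <- x[[el]]
    if (!is.numeric(v)) stop("element column '", el, "' is not numeric",
                             call. = FALSE)
    if (anyNA(v)) stop("missing concentration for element '", el, "'",
                       call. = FALSE)
  }
  if (!inherits(x, "concentration_table")) {
    class(x) <- c("concentration_table", class(x))
  }
  x
}

# Element columns = everything except the id/label columns.
conc_elements <- function(conc) {
  setdiff(names(conc), c("sample_id", "type"))
}

# Extract a samples x elements numeric matrix for the requested elements,
# with positivity checks that name the offending sample/element.
conc_matrix <- function(conc, elements, require_positive = TRUE) {
  missing <- setdiff(elements, names(conc))
  if (length(missing) > 0) {
    stop("concentration table lacks element(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(as.data.frame(conc)[, elements, drop = FALSE])
  rownames(m) <- conc$sample_id
  if (require_positive && any(m <= 0)) {
    bad <- which(m <= 0, arr.ind = TRUE)[1, ]
    stop("nonpositive concentration for sample '", rownames(m)[bad[1]],
         "', element '", elements[bad[2]], "'", call. = FALSE)
  }
  m
}

#' Read a concentration table from CSV (wide or long)
#'
#' Wide form: `sample_id,type,La,Ce,...`; long form:
#' `sample_id,element,concentration` (plus optional `type`), which is
#' pivoted to wide.
#'
#' @param path CSV file path.
#' @return A [as_concentration_table()] data.frame.
#' @export
read_concentrations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("element", "concentration") %in% names(tab))) {
    wide <- stats::reshape(
      tab[, c("sample_id", "element", "concentration")],
      direction = "wide", idvar = "sample_id",
      timevar = "element", v.names = "concentration")
    names(wide) <- sub("^concentration\\.", "", names(wide))
    if ("type" %in% names(tab)) {
      wide$type <- tab$type[match(wide$sample_id, tab$sample_id)]
      wide <- wide[, c("sample_id", "type",
                       setdiff(names(wide), c("sample_id", "type")))]
    }
    rownames(wide) <- NULL
    tab <- wide
  }
  as_concentration_table(tab)
}

#' Write a concentration table to CSV (wide)
#'
#' @param conc A concentration table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concentrations <- function(conc, path) {
  utils::write.csv(as.data.frame(conc), path, row.names = FALSE)
  invisible(path)
}
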