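# Shared fixtures: published group-mean REY vectors (mg/kg) for fly and
# bottom ash, and helpers to build small concentration tables in code.

serbia_fly_means <- function() {
  synthetic_default_means()$fly[element_set()$reys]
}

serbia_bottom_means <- function() {
  synthetic_default_means()$bottom[element_set()$reys]
}

# One-row concentration table from a named numeric vector.
conc_row <- function(values, sample_id = "S1", type = NULL) {
  d <- data.frame(sample_id = sample_id, t(values), check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (!is.null(type)) d <- cbind(d[1], type = type, d[-1])
  as_concentration_table(d)
}

# Lumped total-REY concentration split over the mean Serbian REY pattern;
# every REY shares one RfD/CSF, so the split does not affect HI or TCR.
lumped_rey_conc <- function(total, sample_id = "S1") {
  pattern <- (serbia_fly_means() + serbia_bottom_means()) / 2
  conc_row(pattern * total / sum(pattern), sample_id = sample_id)
}
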