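# Shared builders for small deterministic model setups.

# flat life table: constant annual death probability over [from, to]
flat_life_table <- function(q, from = 55, to = 100) {
  life_table(from:to, rep(q, to - from + 1), country = "toy", sex = "all")
}

toy_life_table <- function() {
  life_table(60:62, c(0.010, 0.011, 0.012), country = "toy", sex = "all")
}

# parameter bundle with every probability overridable; starts from the
# bundled defaults so cost cells stay the printed values
toy_params <- function(country = "GER", sex = "female",
                       crc_death = NULL, stay = NULL, alt_rec = NULL,
                       utility = NULL) {
  p <- default_parameters(country, sex)
  if (!is.null(crc_death)) p$stages$crc_death_prob <- crc_death
  if (!is.null(stay)) p$stages$stay_prob <- stay
  if (!is.null(alt_rec)) p$stages$alt_recurrence_prob <- alt_rec
  if (!is.null(utility)) p$stages$utility <- utility
  p
}

toy_config <- function(...) {
  study_config("GER", "female", ...)
}

synthetic_tables <- function() {
  cells <- c("ESP_male", "FRA_male", "GER_male",
             "ESP_female", "FRA_female", "GER_female")
  out <- lapply(cells, function(nm) {
    synthesize_life_table(
      gompertz_makeham_defaults(sub("_.*", "", nm), sub(".*_", "", nm)),
      country = sub("_.*", "", nm), sex = sub(".*_", "", nm))
  })
  names(out) <- cells
  out
}
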