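# General-mortality life tables: CSV reader for national period tables,
# a deterministic Gompertz-Makeham synthesizer for download-free use,
# and actuarial helpers (annual death probability, remaining life
# expectancy).

#' Construct a life table
#'
#' A life table holds the annual probability of death `q(a)` for a
#' contiguous range of integer ages for one country, sex and reference
#' year. Beyond the terminal age the model forces `q = 1`, which guarantees
#' absorption of any cohort within the simulation horizon.
#'
#' @param age Integer vector of ages, contiguous.
#' @param qx Annual death probabilities, same length as `age`, in \[0, 1\].
#' @param country,sex,reference_year Provenance labels.
#' @return An object of class `lb_life_table`.
#' @export
life_table <- function(age, qx, country = "synthetic", sex = "all",
                       reference_year = 2019L) {
  age <- as.integer(age)
  if (length(age) != length(qx) || length(age) == 0)
    stop("age and qx must be non-empty vectors of equal length",
         call. = FALSE)
  if (any(diff(age) != 1L))
    stop("ages must form a contiguous integer range (no gaps)",
         call. = FALSE)
  if (any(qx < 0 | qx > 1) || anyNA(qx))
    stop("qx values must lie in [0, 1]", call. = FALSE)
  structure(
    list(country = country, sex = sex, reference_year = reference_year,
         age = age, qx = as.numeric(qx)),
    class = "lb_life_table"
  )
}

#' Read a life table from CSV
#'
#' The expected layout is comma-separated with a header and period decimal
#' separators: either columns `age,qx` or `age,sex,qx` (one row per single
#' year of age; with a `sex` column, `sex` must be supplied to select the
#' rows). Gaps in the age range and out-of-range probabilities are errors,
#' never silently interpolated.
#'
#' @param path CSV file path.
#' @param country,sex,reference_year Provenance labels; `sex` also selects
#'   rows when the file carries a `sex` column.
#' @return An `lb_life_table`.
#' @export
load_life_table <- function(path, country = NULL, sex = NULL,
                            reference_year = 2019L) {
  if (!file.exists(path)) stop("life table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "qx") %in% names(df)))
    stop("life table CSV must have columns (age, qx) or (age, sex, qx)",
         call. = FALSE)
  if ("sex" %in% names(df)) {
    if (is.null(sex))
      stop("file has a sex column; supply sex = \"male\" or \"female\"",
           call. = FALSE)
    df <- df[df$sex == sex, , drop = FALSE]
    if (nrow(df) == 0) stop("no rows for sex = ", sex, call. = FALSE)
  }
  df <- df[order(df$age), , drop = FALSE]
  life_table(df$age, df$qx,
             country = country %||% "file", sex = sex %||% "all",
             reference_year = reference_year)
}

#' Write a life table to CSV
#'
#' @param table An `lb_life_table`.
#' @param path Output CSV path (columns `age,qx`).
#' @return `path`, invisibly.
#' @export
write_life_table <- function(table, path) {
  utils::write.csv(data.frame(age = table$age, qx = table$qx),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Gompertz-Makeham parameters and synthetic life tables
#'
#' The synthetic generator emulates the age-exponential structure of
#' national period life tables with a Gompertz-Makeham hazard
#' `mu(a) = lambda + alpha * exp(beta * a)`: a small age-independent
#' (Makeham) component plus an exponentially increasing senescent
#' component. The annual death probability is the exact one-year
#' integral of the hazard,
#' `q(a) = 1 - exp(-(lambda + alpha/beta * exp(beta*a) * (exp(beta)-1)))`,
#' with `q` forced to 1 at the terminal age. The construction is fully
#' deterministic.
#'
#' @param makeham_lambda Age-independent hazard component (per year, >= 0).
#' @param gompertz_alpha Senescent hazard scale (per year, > 0).
#' @param gompertz_beta Senescent hazard growth rate (1/year, > 0).
#' @return `gompertz_makeham_params()` returns a parameter object;
#'   `synthesize_life_table()` returns an `lb_life_table`.
#' @export
#' @examples
#' gm <- gompertz_makeham_defaults("ESP", "female")
#' lt <- synthesize_life_table(gm)
#' remaining_life_expectancy(lt, 60)
gompertz_makeham_params <- function(makeham_lambda, gompertz_alpha,
                                    gompertz_beta) {
  if (makeham_lambda < 0) stop("makeham_lambda must be >= 0", call. = FALSE)
  if (gompertz_alpha <= 0) stop("gompertz_alpha must be > 0", call. = FALSE)
  if (gompertz_beta <= 0) stop("gompertz_beta must be > 0", call. = FALSE)
  structure(list(makeham_lambda = makeham_lambda,
                 gompertz_alpha = gompertz_alpha,
                 gompertz_beta = gompertz_beta),
            class = "lb_gm_params")
}

# Fitted synthetic defaults: alpha chosen by root-finding so that remaining
# life expectancy at 60 matches realistic 2019 period values, ordered
# ESP >= FRA >= GER within sex and female > male (targets: male
# 23.6/23.4/22.0 y, female 27.6/27.5/25.6 y; lambda = 5e-4; beta 0.092
# male, 0.105 female). These are repo constants, not published values.
.GM_DEFAULTS <- list(
  ESP_male   = c(5e-04, 2.77836112e-05, 0.092),
  FRA_male   = c(5e-04, 2.84511281e-05, 0.092),
  GER_male   = c(5e-04, 3.35862971e-05, 0.092),
  ESP_female = c(5e-04, 6.02432193e-06, 0.105),
  FRA_female = c(5e-04, 6.10569566e-06, 0.105),
  GER_female = c(5e-04, 7.82980620e-06, 0.105)
)

#' @rdname gompertz_makeham_params
#' @param country,sex Cell selecting one of the six fitted parameter sets.
#' @export
gompertz_makeham_defaults <- function(country = c("ESP", "FRA", "GER"),
                                      sex = c("male", "female")) {
  country <- match.arg(country)
  sex <- match.arg(sex)
  v <- .GM_DEFAULTS[[paste(country, sex, sep = "_")]]
  gompertz_makeham_params(v[1], v[2], v[3])
}

#' @rdname gompertz_makeham_params
#' @param params An `lb_gm_params` object.
#' @param terminal_age Last tabulated age; `q(terminal_age) = 1`.
#' @param country,sex Provenance labels for the resulting table.
#' @export
synthesize_life_table <- function(params, terminal_age = 100,
                                  country = "synthetic", sex = "all") {
  stopifnot(inherits(params, "lb_gm_params"))
  ages <- 0:terminal_age
  h <- with(params,
            makeham_lambda + (gompertz_alpha / gompertz_beta) *
              exp(gompertz_beta * ages) * (exp(gompertz_beta) - 1))
  qx <- 1 - exp(-h)
  qx[length(qx)] <- 1
  life_table(ages, qx, country = country, sex = sex)
}

#' Annual death probability at a given age
#'
#' Looks up `q(age)` in the table; ages beyond the tabulated terminal age
#' return 1 (forced absorption).
#'
#' @param table An `lb_life_table`.
#' @param age Age in whole years, `>= 0`.
#' @return Probability of dying within one year.
#' @export
death_prob <- function(table, age) {
  if (any(age < 0)) stop("age must be >= 0", call. = FALSE)
  lo <- table$age[1]
  if (any(age < lo))
    stop("age below the table's first tabulated age (", lo, ")",
         call. = FALSE)
  i <- pmin(as.integer(age) - lo + 1L, length(table$qx))
  out <- table$qx[i]
  out[age > table$age[length(table$age)]] <- 1
  out
}

#' Remaining (curtate) life expectancy from a life table
#'
#' Sums the survival products `sum_k prod_{j<k} (1 - q(age + j))` up to the
#' terminal age. With `half_cycle = TRUE` one half year is added, giving the
#' trapezoidal (complete) expectation. Intended for validating synthetic
#' tables against published national life expectancies.
#'
#' @param table An `lb_life_table`.
#' @param age Starting age, within the table.
#' @param half_cycle Logical; add 0.5 years (trapezoid correction).
#' @return Expected remaining years of life.
#' @export
remaining_life_expectancy <- function(table, age, half_cycle = FALSE) {
  if (age < table$age[1] || age > table$age[length(table$age)])
    stop("age outside the table", call. = FALSE)
  horizon <- table$age[length(table$age)] - age + 1L
  q <- death_prob(table, age + seq_len(horizon) - 1L)
  sum(cumprod(1 - q)) + if (half_cycle) 0.5 else 0
}

#' Convert a wide (sex-columned) life table to the package layout
#'
#' National statistics offices commonly publish period life tables with one
#' column of annual death probabilities per sex. This helper converts a CSV
#' with columns `age, male, female` (period decimal separators) into the
#' long `age, sex, qx` layout that [load_life_table()] reads.
#'
#' @param path_in Wide-format CSV path.
#' @param path_out Output CSV path.
#' @return `path_out`, invisibly.
#' @export
convert_wide_life_table <- function(path_in, path_out) {
  df <- utils::read.csv(path_in, stringsAsFactors = FALSE)
  need <- c("age", "male", "female")
  if (!all(need %in% names(df)))
    stop("wide life table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  long <- rbind(
    data.frame(age = df$age, sex = "male", qx = df$male),
    data.frame(age = df$age, sex = "female", qx = df$female)
  )
  utils::write.csv(long, path_out, row.names = FALSE, quote = FALSE)
  invisible(path_out)
}

#' @export
print.lb_life_table <- function(x, ...) {
  cat(sprintf("<life table> %s / %s / %d: ages %d-%d, q(%d) = %.5f\n",
              x$country, x$sex, x$reference_year,
              x$age[1], x$age[length(x$age)],
              x$age[1], x$qx[1]))
  invisible(x)
}
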