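# One-way deterministic sensitivity analysis: vary every independent cost
# and medical model parameter by +/-10%, rerun both comparison arms, and
# record the swing of the cost per QALY gained (tornado diagram).

# A perturbable parameter is a name plus getter/setter closures over the
# (params, config) pair; the setter returns the modified pair. Perturbed
# probabilities re-enter the usual competing-risk composition unchanged.
.sa_parameter_list <- function(params, config) {
  out <- list()
  add <- function(name, value, set, kind) {
    out[[name]] <<- list(name = name, base = value, set = set, kind = kind)
  }
  for (s in .LIVING) {
    stg <- .STAGES[s]
    add(paste0("utility_", stg), params$stages$utility[s],
        local({ si <- s; function(pc, v) {
          pc$params$stages$utility[si] <- v; pc } }), "prob")
    add(paste0("crc_death_prob_", stg), params$stages$crc_death_prob[s],
        local({ si <- s; function(pc, v) {
          pc$params$stages$crc_death_prob[si] <- v; pc } }), "prob")
    for (tier in c("cost_initial", "cost_followup", "cost_advanced"))
      add(paste0(tier, "_", stg), params$stages[[tier]][s],
          local({ si <- s; ti <- tier; function(pc, v) {
            pc$params$stages[[ti]][si] <- v; pc } }), "cost")
  }
  rec <- .recurrence_probs(params, config)
  for (s in 1:3) {
    stg <- .STAGES[s]
    add(paste0("recurrence_prob_", stg), rec[s],
        local({ si <- s; function(pc, v) {
          # write through the active parameterization
          if (pc$config$recurrence_source == "three_year_derived")
            pc$params$stages$stay_prob[si] <- 1 - v
          else pc$params$stages$alt_recurrence_prob[si] <- v
          pc } }), "prob")
  }
  add("lb_test_cost", params$lb_test_cost,
      function(pc, v) { pc$params$lb_test_cost <- v; pc }, "cost")
  add("start_age", config$start_age,
      function(pc, v) { pc$config$start_age <- as.integer(round(v)); pc },
      "age")
  out
}

.clip_value <- function(v, kind, name) {
  if (kind == "prob") {
    if (v < 0 || v > 1)
      warning(sprintf("%s perturbed to %.4f; clipped into [0, 1]", name, v),
              call. = FALSE)
    v <- min(max(v, 0), 1)
  } else if (kind == "cost" && v < 0) {
    warning(sprintf("%s perturbed below 0; clipped at 0", name),
            call. = FALSE)
    v <- 0
  }
  v
}

#' One-way sensitivity analysis on the cost per QALY gained
#'
#' Varies each independent model parameter by `+/-delta` (default 10%)
#' around its base value - stage utilities, active recurrence
#' probabilities, CRC death probabilities, every cost cell, the NGS-LB
#' test cost, and the start age (perturbed in years, rounded to integers) -
#' reruns both comparison arms with the perturbed value, and records the
#' resulting C/QALYG of `comparator` versus `baseline`. Perturbed
#' probabilities and utilities are clipped into \[0, 1\] with a warning;
#' clipped or unused parameters simply show their (possibly zero) swing.
#'
#' The reported `max_abs_pct_change` is
#' `max(|ICER_low - ICER_base|, |ICER_high - ICER_base|) / ICER_base * 100`;
#' both one-sided ICERs are retained so alternative conventions can be
#' audited. Entries are sorted by decreasing swing, ties alphabetically.
#'
#' @param config An `lb_config`.
#' @param table An `lb_life_table`.
#' @param params An `lb_params`.
#' @param comparator The active strategy (an `lb_comparator`).
#' @param baseline The baseline strategy; default standard care.
#' @param parameters Optional character vector restricting the parameter
#'   set (names as produced by the default list).
#' @param delta Relative perturbation; default 0.10.
#' @return An object of class `lb_tornado`: data frame with columns
#'   `parameter`, `base_value`, `low_value`, `high_value`, `icer_low`,
#'   `icer_high`, `pct_change_low`, `pct_change_high`,
#'   `max_abs_pct_change`, with the baseline ICER as attribute
#'   `baseline_icer`.
#' @export
one_way_sa <- function(config, table, params, comparator,
                       baseline = comparator_spec("standard care"),
                       parameters = NULL, delta = 0.10) {
  icer_for <- function(cfg, prm) {
    base_acc <- summarize_outcomes(run_cohort(cfg, table, prm, baseline),
                                   prm, baseline, cfg)
    comp_acc <- summarize_outcomes(run_cohort(cfg, table, prm, comparator),
                                   prm, comparator, cfg)
    compute_icer(base_acc, comp_acc, cfg$wtp_threshold)$icer_cqalyg
  }
  base_icer <- icer_for(config, params)
  plist <- .sa_parameter_list(params, config)
  if (!is.null(parameters)) {
    missing <- setdiff(parameters, names(plist))
    if (length(missing))
      stop("unknown parameter(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    plist <- plist[parameters]
  }
  rows <- lapply(plist, function(pp) {
    vals <- vapply(c(1 - delta, 1 + delta), function(f) {
      v <- .clip_value(pp$base * f, pp$kind, pp$name)
      pc <- pp$set(list(params = params, config = config), v)
      # lb_test_cost lives on the comparator specs as well
      cmp <- comparator; bs <- baseline
      if (pp$name == "lb_test_cost") {
        cmp$lb_test_cost <- v
        bs$lb_test_cost <- v
      }
      local_icer <- {
        icer_for2 <- function(cfg, prm) {
          b <- summarize_outcomes(run_cohort(cfg, table, prm, bs),
                                  prm, bs, cfg)
          cc <- summarize_outcomes(run_cohort(cfg, table, prm, cmp),
                                   prm, cmp, cfg)
          compute_icer(b, cc, cfg$wtp_threshold)$icer_cqalyg
        }
        icer_for2(pc$config, pc$params)
      }
      c(v, local_icer)
    }, numeric(2))
    pct <- (vals[2, ] - base_icer) / base_icer * 100
    data.frame(parameter = pp$name, base_value = pp$base,
               low_value = vals[1, 1], high_value = vals[1, 2],
               icer_low = vals[2, 1], icer_high = vals[2, 2],
               pct_change_low = pct[1], pct_change_high = pct[2],
               max_abs_pct_change = max(abs(pct)),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    out <- data.frame(parameter = character(), base_value = numeric(),
                      low_value = numeric(), high_value = numeric(),
                      icer_low = numeric(), icer_high = numeric(),
                      pct_change_low = numeric(), pct_change_high = numeric(),
                      max_abs_pct_change = numeric(),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("lb_tornado", "data.frame"),
                     baseline_icer = base_icer))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(-out$max_abs_pct_change, out$parameter), ]
  rownames(out) <- NULL
  structure(out, class = c("lb_tornado", "data.frame"),
            baseline_icer = base_icer)
}

#' Tornado report: CSV and diagram
#'
#' Writes the ordered sensitivity table to CSV and draws the tornado
#' diagram (horizontal bars from the low- to the high-perturbation ICER
#' around the baseline). Ordering is deterministic: decreasing swing, ties
#' alphabetical.
#'
#' @param entries An `lb_tornado` from [one_way_sa()].
#' @param csv_path Optional CSV output path.
#' @param plot_path Optional plot file path (format by extension, e.g.
#'   `.pdf` or `.png`).
#' @param top Number of parameters to draw; default all with nonzero swing.
#' @return List with `data` (the entries) and `plot` (a ggplot object, or
#'   `NULL` for an empty entry set), invisibly.
#' @export
tornado_report <- function(entries, csv_path = NULL, plot_path = NULL,
                           top = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(entries), csv_path, row.names = FALSE)
  if (nrow(entries) == 0)
    return(invisible(list(data = entries, plot = NULL)))
  base_icer <- attr(entries, "baseline_icer")
  d <- as.data.frame(entries)
  if (is.null(top)) top <- sum(d$max_abs_pct_change > 0)
  d <- utils::head(d, max(top, 1L))
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  d$lo <- pmin(d$icer_low, d$icer_high)
  d$hi <- pmax(d$icer_low, d$icer_high)
  p <- ggplot2::ggplot(d) +
    ggplot2::geom_segment(
      ggplot2::aes(x = lo, xend = hi,
                   y = parameter, yend = parameter),
      linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_icer, linetype = 2) +
    ggplot2::labs(x = "cost per QALY gained (EUR)", y = NULL,
                  title = "One-way sensitivity of the C/QALYG",
                  subtitle = sprintf("baseline ICER %.2f EUR/QALY",
                                     base_icer)) +
    ggplot2::theme_minimal()
  if (!is.null(plot_path))
    ggplot2::ggsave(plot_path, p, width = 7, height = 5)
  invisible(list(data = entries, plot = p))
}
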