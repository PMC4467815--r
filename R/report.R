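utils::globalVariables(c("delta_qalys", "delta_cost"))

# Tabular exports mirroring the model's headline tables, a tidy trace
# export, and an optional cost-effectiveness plane plot. Rounding
# (EUR to units, QALYs to three decimals) happens only here; every
# upstream quantity is kept at full precision.

#' Tidy per-cycle trace of both strategies
#'
#' @param ce A `phoscea_ce` result from [run_ce()].
#' @return A tibble with one row per (strategy, arm, cycle, state),
#'   carrying raw and half-cycle-corrected occupancy (fractions of the
#'   entering cohort, i.e. arm occupancy times arm fraction).
#' @export
tidy_trace <- function(ce) {
  rows <- list()
  for (s in c("cb", "lc")) {
    run <- ce$runs[[s]]
    for (i in seq_along(run$arms)) {
      arm <- run$arms[[i]]
      tr <- run$traces[[i]]
      raw <- aggregate_states(tr$occupancy, arm$dialysis_mix) * arm$fraction
      corr <- aggregate_states(tr$corrected, arm$dialysis_mix) * arm$fraction
      for (st in colnames(raw)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          strategy = s, arm = arm$subgroup, cycle = 0:tr$cycles, state = st,
          occupancy = unname(raw[, st]),
          corrected = c(NA_real_, unname(corr[, st])))
      }
    }
  }
  do.call(rbind, rows)
}

#' Headline results table (cohort of 1,000 patients)
#'
#' Mirrors the base-case results layout: therapy-response counts,
#' discounted health outcomes, cost components in EUR thousand, and
#' the incremental comparison.
#'
#' @param ce A `phoscea_ce` result.
#' @param digits_qalys Decimals for QALY rows (reporting only).
#' @return A tibble with columns `row`, `cb`, `lc`, `difference`
#'   (character, formatted for reporting).
#' @export
results_table <- function(ce, digits_qalys = 1) {
  p <- ce$params
  n <- p$settings$cohort_size
  ef <- p$efficacy
  fl <- classify_first_line(n, ef$response_rate_cb_predialysis)
  sl <- assign_second_line(fl$non_responders, ef$response_rate_lc_predialysis)
  resp_cb <- fl$responders
  resp_lc <- fl$responders + sl$lc_responders
  num <- function(v, d = 0) formatC(v, format = "f", digits = d, big.mark = ",")
  eur_k <- function(v) num(v / 1000, 0)
  icer <- ce$incremental$icer_per_qaly
  tibble::tibble(
    row = c("Responders in predialysis", "Life years", "Dialysis free years",
            "QALYs", "Total costs (EUR thousand)", "Drug costs (EUR thousand)",
            "Dialysis costs (EUR thousand)", "Cost per QALY gained",
            "NMB (EUR thousand)"),
    cb = c(num(resp_cb), num(ce$cb$life_years, digits_qalys), "0",
           num(ce$cb$qalys, digits_qalys), eur_k(ce$cb$total_cost),
           eur_k(ce$cb$drug_cost), eur_k(ce$cb$dialysis_cost), "", ""),
    lc = c(num(resp_lc), num(ce$lc$life_years, digits_qalys),
           num(ce$dialysis_free_years), num(ce$lc$qalys, digits_qalys),
           eur_k(ce$lc$total_cost), eur_k(ce$lc$drug_cost),
           eur_k(ce$lc$dialysis_cost), "", ""),
    difference = c(num(resp_lc - resp_cb),
                   num(ce$incremental$delta_ly, digits_qalys),
                   num(ce$dialysis_free_years),
                   num(ce$incremental$delta_qalys, 2),
                   eur_k(ce$incremental$delta_cost), "", "",
                   if (is.character(icer)) icer else paste0("EUR ", num(icer)),
                   eur_k(ce$incremental$nmb))
  )
}

#' Export full-precision results as JSON
#'
#' Writes per-strategy and incremental blocks (cohort and per-patient)
#' at full precision.
#'
#' @param ce A `phoscea_ce` result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
export_results_json <- function(ce, path) {
  strip <- function(r) r[c("life_years", "dialysis_free_life_years", "qalys",
                           "drug_cost", "dialysis_cost", "total_cost",
                           "per_patient")]
  out <- list(
    cb = strip(ce$cb), lc = strip(ce$lc),
    incremental = unclass(ce$incremental),
    dialysis_free_years = ce$dialysis_free_years,
    settings = ce$params$settings
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Cost-effectiveness plane of a PSA
#'
#' Scatter of the incremental points (QALYs gained vs incremental cost)
#' from [run_psa()]. Requires ggplot2; plotting is a convenience and no
#' analysis result depends on it.
#'
#' @param psa A `phoscea_psa` result.
#' @param lambda Threshold line to draw (EUR/QALY); `NULL` for none.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, lambda = 30000) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_ce_plane needs the ggplot2 package", call. = FALSE)
  }
  gg <- ggplot2::ggplot(psa$points,
                        ggplot2::aes(x = delta_qalys, y = delta_cost / 1000)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "#2171b5") +
    ggplot2::labs(x = "Incremental QALYs (LC - CB)",
                  y = "Incremental cost (EUR thousand)",
                  title = sprintf("Cost-effectiveness plane (%d iterations)",
                                  nrow(psa$points))) +
    ggplot2::theme_minimal()
  if (!is.null(lambda)) {
    gg <- gg + ggplot2::geom_abline(slope = lambda / 1000, intercept = 0,
                                    linetype = "dashed", colour = "grey40")
  }
  gg
}
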