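#' Per-trust match report
#'
#' Tabulates, per trust and in total: records available for matching,
#' records with null/neither identifier, matched records and the match rate
#' (matched / available, rounded half-up to the nearest integer percent —
#' the rounding convention under which the published per-trust rates are
#' self-consistent). The input is either a tibble of link results carrying
#' a `trust` column and a `method` column, or a precomputed counts table
#' with columns `trust`, `n_available`, `n_no_identifier`, `n_matched`
#' (e.g. the published counts of a study report).
#'
#' Published tables of this kind are not always internally consistent
#' (`n_no_identifier + n_matched` can exceed `n_available`); the report
#' therefore carries a `consistent` flag per row instead of refusing such
#' input.
#'
#' @param x link results (with `trust`, `method`) or a counts table.
#' @return tibble of class `edlink_match_report`: one row per trust plus a
#'   `"Total"` row, columns `trust`, `n_available`, `n_no_identifier`,
#'   `n_matched`, `match_rate_pct` (`NA` when `n_available` is 0),
#'   `consistent`. Attributes: `no_identifier_pct` (overall, one decimal)
#'   and, when results were supplied, `pathway_counts`
#'   (`n_cad_date`, `n_callsign`) with `pathway_shares_pct` expressed as a
#'   percentage of all available records, one decimal.
#' @export
compute_match_report <- function(x) {
  from_results <- "method" %in% names(x)
  if (from_results) {
    if (!"trust" %in% names(x)) {
      stop("every link result must be labelled with a trust", call. = FALSE)
    }
    counts <- x |>
      dplyr::group_by(.data$trust) |>
      dplyr::summarise(
        n_available = dplyr::n(),
        n_no_identifier = sum(.data$method == "no_identifier"),
        n_matched = sum(.data$method %in% c("cad_date", "callsign_datetime")),
        .groups = "drop"
      )
    pathway <- c(
      n_cad_date = sum(x$method == "cad_date"),
      n_callsign = sum(x$method == "callsign_datetime")
    )
  } else {
    need <- c("trust", "n_available", "n_no_identifier", "n_matched")
    if (!all(need %in% names(x))) {
      stop(sprintf("counts table needs columns: %s", paste(need, collapse = ", ")),
           call. = FALSE)
    }
    counts <- tibble::as_tibble(x[, need])
    pathway <- NULL
  }

  total <- tibble::tibble(
    trust = "Total",
    n_available = sum(counts$n_available),
    n_no_identifier = sum(counts$n_no_identifier),
    n_matched = sum(counts$n_matched)
  )
  report <- dplyr::bind_rows(counts, total) |>
    dplyr::mutate(
      match_rate_pct = ifelse(
        .data$n_available > 0,
        round_half_up(100 * .data$n_matched / .data$n_available),
        NA_real_
      ),
      consistent = .data$n_no_identifier + .data$n_matched <= .data$n_available
    )
  attr(report, "no_identifier_pct") <- if (total$n_available > 0) {
    round_half_up(100 * total$n_no_identifier / total$n_available, 1)
  } else NA_real_
  if (!is.null(pathway)) {
    attr(report, "pathway_counts") <- pathway
    attr(report, "pathway_shares_pct") <- round_half_up(
      100 * pathway / total$n_available, 1
    )
  }
  class(report) <- c("edlink_match_report", class(report))
  report
}

#' Pathway shares as percentages of all available records
#'
#' Expresses the CAD+date and call-sign match counts as shares of the total
#' records available for matching, rounded half-up to one decimal. (Shares
#' of *available* records, not of matched records, is how such splits are
#' conventionally quoted in linkage reports.)
#'
#' @param n_cad_date,n_callsign matches made by each pathway.
#' @param n_available total records available for matching.
#' @return named numeric vector `c(cad_date = ..., callsign = ...)`.
#' @export
pathway_shares <- function(n_cad_date, n_callsign, n_available) {
  c(
    cad_date = round_half_up(100 * n_cad_date / n_available, 1),
    callsign = round_half_up(100 * n_callsign / n_available, 1)
  )
}

#' @export
print.edlink_match_report <- function(x, ...) {
  cat("Match report (matched / available, % rounded to nearest integer)\n")
  df <- as.data.frame(x)
  df$match_rate_pct <- ifelse(is.na(df$match_rate_pct), "-",
                              sprintf("%d%%", as.integer(df$match_rate_pct)))
  print(df, row.names = FALSE)
  cat(sprintf("Records with no identifier: %.1f%% of available\n",
              attr(x, "no_identifier_pct")))
  pc <- attr(x, "pathway_counts")
  if (!is.null(pc)) {
    sh <- attr(x, "pathway_shares_pct")
    cat(sprintf("Pathways: CAD+date %d (%.1f%%), call sign %d (%.1f%%)\n",
                pc[["n_cad_date"]], sh[["n_cad_date"]],
                pc[["n_callsign"]], sh[["n_callsign"]]))
  }
  invisible(x)
}

#' Analyse unmatched rows for identifier and demographic trends
#'
#' Flags any exact identifier value (CAD or call sign) occurring at least
#' `flag_threshold` times among the unmatched rows — the signature of a
#' sentinel being recorded in an identifier field (e.g. "136" for Mental
#' Health Act cases) — and tabulates time-of-day (24 hourly bins) and age
#' (0-4, 5-17, 18-64, 65+) distributions, against the matched rows when
#' supplied.
#'
#' @param unmatched cleaned ED rows that failed to link (need `cad`,
#'   `call_sign`, `raw` fields via `cad_number`/`cad_call_sign`,
#'   `ed_arrival_datetime`, `age`).
#' @param flag_threshold minimum count for a value to be flagged
#'   (default 20).
#' @param matched optional cleaned ED rows that linked, for comparison
#'   histograms.
#' @return list of class `edlink_trend_report`: `flagged_values`
#'   (tibble `field`, `value`, `n`, `threshold`), `time_of_day` (hour bin
#'   counts by group), `age_bands` (age band counts by group).
#' @export
analyse_unmatched <- function(unmatched, flag_threshold = 20, matched = NULL) {
  flag_field <- function(values, field) {
    values <- values[!is.na(values)]
    if (length(values) == 0) return(NULL)
    tab <- table(values)
    hit <- tab[tab >= flag_threshold]
    if (length(hit) == 0) return(NULL)
    tibble::tibble(field = field, value = names(hit), n = as.integer(hit),
                   threshold = flag_threshold)
  }
  # flag on the raw CAD-field token so sentinel values are reported as
  # recorded, alongside the parsed call sign
  cad_values <- if ("cad" %in% names(unmatched)) as.character(unmatched$cad)
  flagged <- dplyr::bind_rows(
    flag_field(cad_values, "cad"),
    flag_field(unmatched[["call_sign"]], "call_sign")
  )
  if (is.null(flagged) || nrow(flagged) == 0) {
    flagged <- tibble::tibble(field = character(), value = character(),
                              n = integer(), threshold = integer())
  }

  hist_group <- function(rows, group) {
    if (is.null(rows) || nrow(rows) == 0) return(NULL)
    tibble::tibble(
      group = group,
      hour = as.integer(format(rows$ed_arrival_datetime, "%H", tz = "UTC"))
    ) |>
      dplyr::count(.data$group, .data$hour, name = "n") |>
      tidyr::complete(group = group, hour = 0:23, fill = list(n = 0L))
  }
  age_group <- function(rows, group) {
    if (is.null(rows) || nrow(rows) == 0 || !"age" %in% names(rows)) return(NULL)
    band <- cut(rows$age, breaks = c(-Inf, 4, 17, 64, Inf),
                labels = c("0-4", "5-17", "18-64", "65+"))
    tibble::tibble(group = group, age_band = band) |>
      dplyr::count(.data$group, .data$age_band, name = "n", .drop = FALSE)
  }

  structure(
    list(
      flagged_values = flagged,
      time_of_day = dplyr::bind_rows(hist_group(unmatched, "unmatched"),
                                     hist_group(matched, "matched")),
      age_bands = dplyr::bind_rows(age_group(unmatched, "unmatched"),
                                   age_group(matched, "matched")),
      flag_threshold = flag_threshold,
      n_unmatched = nrow(unmatched)
    ),
    class = "edlink_trend_report"
  )
}

#' @export
print.edlink_trend_report <- function(x, ...) {
  cat(sprintf("Trend report over %d unmatched row(s), flag threshold %d\n",
              x$n_unmatched, x$flag_threshold))
  if (nrow(x$flagged_values)) {
    cat("Over-represented identifier values:\n")
    print(as.data.frame(x$flagged_values), row.names = FALSE)
  } else {
    cat("No identifier value reached the flag threshold\n")
  }
  invisible(x)
}

#' Score link results against synthetic ground truth
#'
#' The confusion counts deterministic linkage studies usually cannot
#' compute on real data (re-identification being barred): a result is a
#' true link iff its ambulance record equals the ground-truth pair; an
#' unmatched row whose truth pair exists is a false non-link; a matched row
#' with no or a different truth pair is a false link.
#'
#' @param results LinkResult tibble from [link_all()].
#' @param truth GroundTruth tibble (`ed_row_id`, `amb_id`) from
#'   [generate_ed_extract()].
#' @return list of class `edlink_truth_evaluation`: `true_links`,
#'   `false_links`, `false_non_links`, `true_non_links`, `precision`,
#'   `recall` (`NA` when the denominator is 0).
#' @export
evaluate_against_truth <- function(results, truth) {
  joined <- dplyr::left_join(results, truth, by = "ed_row_id",
                             suffix = c("", "_true"))
  linked <- !is.na(joined$amb_id)
  has_truth <- !is.na(joined$amb_id_true)
  tl <- sum(linked & has_truth & joined$amb_id == joined$amb_id_true)
  fl <- sum(linked) - tl
  fnl <- sum(!linked & has_truth)
  tnl <- sum(!linked & !has_truth)
  structure(
    list(
      true_links = tl, false_links = fl,
      false_non_links = fnl, true_non_links = tnl,
      precision = if (tl + fl > 0) tl / (tl + fl) else NA_real_,
      recall = if (tl + fnl > 0) tl / (tl + fnl) else NA_real_
    ),
    class = "edlink_truth_evaluation"
  )
}

#' @export
print.edlink_truth_evaluation <- function(x, ...) {
  cat(sprintf(
    "Truth evaluation: TL=%d FL=%d FNL=%d TNL=%d | precision=%s recall=%s\n",
    x$true_links, x$false_links, x$false_non_links, x$true_non_links,
    ifelse(is.na(x$precision), "undefined", sprintf("%.4f", x$precision)),
    ifelse(is.na(x$recall), "undefined", sprintf("%.4f", x$recall))
  ))
  invisible(x)
}
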