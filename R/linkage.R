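#' Configuration for the deterministic linkage algorithm
#'
#' @param time_tolerance_minutes corroboration window for the call-sign
#'   pathway: a candidate ambulance record is accepted only if its recorded
#'   ED arrival is within this many minutes of the ED-recorded arrival.
#'   Hand-over delays make the true gap hard to bound, so the window is a
#'   surfaced parameter (default 120) and is logged in every report.
#' @param allow_consecutive_dates also try the previous calendar date, for
#'   patient care that crossed midnight (the CAD number is generated at the
#'   emergency call, which always precedes ED arrival, so only arrival date
#'   minus one day is tried).
#' @param require_site_agreement_callsign the call-sign pathway only
#'   considers candidates conveyed to the ED row's own site (call-sign
#'   collisions across sites are plausible). Default `TRUE`.
#' @param cmp_site_cad how the CAD pathway treats a site mismatch:
#'   `"flag"` (default; paramedic destination errors exist, so the link is
#'   kept and flagged), `"ignore"`, or `"require"` (reject the candidate).
#' @return an object of class `edlink_link_config`.
#' @export
link_config <- function(time_tolerance_minutes = 120,
                        allow_consecutive_dates = TRUE,
                        require_site_agreement_callsign = TRUE,
                        cmp_site_cad = c("flag", "ignore", "require")) {
  cmp_site_cad <- match.arg(cmp_site_cad)
  if (!is.numeric(time_tolerance_minutes) || time_tolerance_minutes <= 0) {
    stop("`time_tolerance_minutes` must be positive", call. = FALSE)
  }
  structure(
    list(
      time_tolerance_minutes = time_tolerance_minutes,
      allow_consecutive_dates = isTRUE(allow_consecutive_dates),
      require_site_agreement_callsign = isTRUE(require_site_agreement_callsign),
      cmp_site_cad = cmp_site_cad
    ),
    class = "edlink_link_config"
  )
}

#' Index ambulance records for linkage
#'
#' Builds the two lookups the algorithm needs: `(CAD, incident date)`, which
#' is unique by construction of the CAD system — records violating that
#' uniqueness are data errors and are quarantined from CAD matching rather
#' than guessed — and `(call sign, incident date)`, under which several
#' conveyances by one crew shift may legitimately appear.
#'
#' @param ambulance tibble from [generate_ambulance_dataset()] (or any table
#'   with `amb_id`, `cad_number`, `incident_date`, `call_sign`,
#'   `ed_arrival`, `destination_site`).
#' @return an object of class `edlink_amb_index`.
#' @export
build_index <- function(ambulance) {
  n <- nrow(ambulance)
  cad_key <- paste(ambulance$cad_number, as.character(ambulance$incident_date))
  dup_keys <- unique(cad_key[duplicated(cad_key)])
  quarantined <- which(cad_key %in% dup_keys)
  if (length(quarantined)) {
    warning(sprintf(
      "%d ambulance record(s) share a (CAD, date) key; quarantined from CAD matching",
      length(quarantined)), call. = FALSE)
  }
  by_cad <- new.env(parent = emptyenv(), size = max(16L, n))
  keep <- setdiff(seq_len(n), quarantined)
  for (i in keep) assign(cad_key[i], i, envir = by_cad)

  by_cs <- new.env(parent = emptyenv(), size = max(16L, n))
  cs_key <- paste(ambulance$call_sign, as.character(ambulance$incident_date))
  ord <- order(ambulance$ed_arrival)
  for (i in ord) {
    k <- cs_key[i]
    assign(k, c(if (exists(k, envir = by_cs)) get(k, envir = by_cs), i), envir = by_cs)
  }

  structure(
    list(
      ambulance = ambulance,
      by_cad_date = by_cad,
      by_callsign_date = by_cs,
      quarantined = ambulance$amb_id[quarantined],
      n = n
    ),
    class = "edlink_amb_index"
  )
}

# scalar CAD+date kernel: returns list(i, flags) or NULL
.match_cad <- function(cad, date, site, index, cfg) {
  flags <- character(0)
  i <- NULL
  k <- paste(cad, as.character(date))
  if (exists(k, envir = index$by_cad_date)) {
    i <- get(k, envir = index$by_cad_date)
  } else if (cfg$allow_consecutive_dates) {
    k1 <- paste(cad, as.character(date - 1))
    if (exists(k1, envir = index$by_cad_date)) {
      i <- get(k1, envir = index$by_cad_date)
      flags <- c(flags, "consecutive_date_used")
    }
  }
  if (is.null(i)) return(NULL)
  amb_site <- index$ambulance$destination_site[i]
  if (!is.na(site) && !identical(site, amb_site)) {
    if (cfg$cmp_site_cad == "require") return(NULL)
    if (cfg$cmp_site_cad == "flag") flags <- c(flags, "site_disagreement")
  }
  list(i = i, flags = flags)
}

# scalar call-sign kernel: nearest candidate by ED-arrival time within the
# tolerance window; an exact tie is ambiguous and yields no match
.match_callsign <- function(call_sign, date, site, arrival, index, cfg) {
  k0 <- paste(call_sign, as.character(date))
  cand <- if (exists(k0, envir = index$by_callsign_date)) {
    get(k0, envir = index$by_callsign_date)
  }
  if (cfg$allow_consecutive_dates) {
    k1 <- paste(call_sign, as.character(date - 1))
    if (exists(k1, envir = index$by_callsign_date)) {
      cand <- c(cand, get(k1, envir = index$by_callsign_date))
    }
  }
  if (is.null(cand)) return(NULL)
  if (cfg$require_site_agreement_callsign && !is.na(site)) {
    cand <- cand[index$ambulance$destination_site[cand] == site]
  }
  if (length(cand) == 0) return(NULL)
  gap <- abs(as.numeric(index$ambulance$ed_arrival[cand]) - as.numeric(arrival)) / 60
  ok <- gap <= cfg$time_tolerance_minutes
  if (!any(ok)) return(NULL)
  cand <- cand[ok]
  gap <- gap[ok]
  best <- which(gap == min(gap))
  if (length(best) > 1) return(list(i = NULL, flags = "ambiguous_candidates"))
  list(i = cand[best], flags = character(0))
}

.result_row <- function(ed_row_id, amb_id, method, flags) {
  tibble::tibble(
    ed_row_id = ed_row_id, amb_id = amb_id, method = method,
    flags = paste(flags, collapse = ";")
  )
}

#' Match one cleaned ED row through the CAD+date pathway
#'
#' Looks up the row's parsed CAD against `(CAD, ED arrival date)`, then —
#' when consecutive dates are allowed — `(CAD, arrival date - 1)` for care
#' that crossed midnight. No times are compared: CAD plus date alone is
#' unique. Site handling follows `cfg$cmp_site_cad`.
#'
#' @param row one-row tibble with `cad`, `ed_arrival_datetime`,
#'   `hospital_site`, `row_id`.
#' @param index an [build_index()] result.
#' @param cfg an [link_config()].
#' @return a one-row LinkResult tibble, or `NULL` when no match.
#' @export
match_cad_date <- function(row, index, cfg = link_config()) {
  if (is.na(row$cad)) return(NULL)
  m <- .match_cad(row$cad, as.Date(row$ed_arrival_datetime, tz = "UTC"),
                  row$hospital_site, index, cfg)
  if (is.null(m)) return(NULL)
  .result_row(row$row_id, index$ambulance$amb_id[m$i], "cad_date", m$flags)
}

#' Match one cleaned ED row through the call-sign pathway
#'
#' Candidates are the ambulance records sharing the row's call sign on the
#' arrival date (and the previous date, for midnight crossings), restricted
#' to the same site when configured. The candidate whose ambulance-recorded
#' ED arrival is nearest the ED-recorded arrival is accepted if within the
#' tolerance window; two equidistant candidates are ambiguous and yield no
#' match. Times corroborate only — they are never a standalone key.
#'
#' @inheritParams match_cad_date
#' @return a one-row LinkResult tibble, or `NULL`.
#' @export
match_callsign <- function(row, index, cfg = link_config()) {
  if (is.na(row$call_sign)) return(NULL)
  m <- .match_callsign(row$call_sign, as.Date(row$ed_arrival_datetime, tz = "UTC"),
                       row$hospital_site, row$ed_arrival_datetime, index, cfg)
  if (is.null(m) || is.null(m$i)) return(NULL)
  .result_row(row$row_id, index$ambulance$amb_id[m$i], "callsign_datetime", m$flags)
}

#' Link every cleaned ED row to an ambulance record
#'
#' Two-pathway deterministic linkage: a row with no parsed identifier is
#' unlinkable (`no_identifier`); otherwise the CAD+date pathway is run
#' first and, only when it yields nothing, the call-sign pathway — so a
#' match on either identifier suffices, with CAD taking precedence. Every
#' input row yields exactly one result; the procedure is deterministic.
#' Several ED rows may link to one ambulance record (duplicate
#' registrations); such ambulance records are flagged in the tallies.
#'
#' @param rows cleaned ED rows (see [clean_extract()]): need `row_id`,
#'   `cad`, `call_sign`, `parse_status`, `ed_arrival_datetime`,
#'   `hospital_site`.
#' @param ambulance ambulance records (or a prebuilt [build_index()]).
#' @param cfg an [link_config()].
#' @return list with `results` (tibble `ed_row_id`, `amb_id`, `method`,
#'   `flags`, one row per input) and `tallies` (per-site counts by method,
#'   plus `n_multi_linked_amb`, the number of ambulance records receiving
#'   more than one ED link). The config is attached as attribute
#'   `link_config`.
#' @export
link_all <- function(rows, ambulance, cfg = link_config()) {
  index <- if (inherits(ambulance, "edlink_amb_index")) ambulance else build_index(ambulance)
  n <- nrow(rows)
  amb_id <- rep(NA_character_, n)
  method <- character(n)
  flags <- character(n)

  cad <- rows$cad
  cs <- rows$call_sign
  status <- rows$parse_status
  site <- rows$hospital_site
  arrival <- rows$ed_arrival_datetime
  adate <- as.Date(arrival, tz = "UTC")

  for (i in seq_len(n)) {
    if (status[i] == "none") {
      method[i] <- "no_identifier"
      next
    }
    m <- if (!is.na(cad[i])) .match_cad(cad[i], adate[i], site[i], index, cfg)
    if (!is.null(m)) {
      amb_id[i] <- index$ambulance$amb_id[m$i]
      method[i] <- "cad_date"
      flags[i] <- paste(m$flags, collapse = ";")
      next
    }
    m <- if (!is.na(cs[i])) {
      .match_callsign(cs[i], adate[i], site[i], arrival[i], index, cfg)
    }
    if (!is.null(m) && !is.null(m$i)) {
      amb_id[i] <- index$ambulance$amb_id[m$i]
      method[i] <- "callsign_datetime"
      flags[i] <- paste(m$flags, collapse = ";")
    } else {
      method[i] <- "unmatched"
      if (!is.null(m)) flags[i] <- paste(m$flags, collapse = ";")
    }
  }

  results <- tibble::tibble(
    ed_row_id = rows$row_id, amb_id = amb_id, method = method, flags = flags
  )
  linked <- results$amb_id[!is.na(results$amb_id)]
  tallies <- results |>
    dplyr::mutate(site = site) |>
    dplyr::count(.data$site, .data$method, name = "n") |>
    tidyr::pivot_wider(names_from = "method", values_from = "n", values_fill = 0L)
  attr(tallies, "n_multi_linked_amb") <- sum(table(linked) > 1)
  attr(results, "link_config") <- cfg
  list(results = results, tallies = tallies)
}
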