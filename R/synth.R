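#' Simulation configuration for a paired ambulance/ED study
#'
#' Describes one simulated service area: how many emergency incidents occur
#' over a date range, how many ED sites receive patients, and the corruption
#' processes that make real extracts hard to link (timestamp jitter between
#' the ambulance and ED systems, journeys crossing midnight, crews conveying
#' several patients in one shift, paramedics recording the wrong destination).
#'
#' CAD incident numbers reset at midnight and are assigned sequentially from 1
#' within each service day, so a day can hold at most 6999 incidents — every
#' genuine CAD then satisfies the "1-4 digit number under 7000" cleaning rule.
#'
#' @param n_incidents total number of emergency incidents over the date range.
#' @param date_start,date_end first and last service day (`Date` or
#'   "YYYY-MM-DD" strings); `date_start <= date_end`.
#' @param n_sites number of ED sites patients can be conveyed to.
#' @param conveyed_fraction proportion of incidents conveyed to an ED
#'   (default 0.70: roughly 30% of patients have their care completed
#'   without ED conveyance).
#' @param midnight_crossing_fraction proportion of conveyances whose care
#'   starts before midnight and whose ED arrival falls on the next day.
#' @param multi_patient_shift_rate probability that a conveyance is brought
#'   in by the same crew (same call sign, same ED) as the previous
#'   conveyance of that day, emulating multi-patient crew shifts.
#' @param timestamp_jitter_minutes half-width of the uniform offset between
#'   the ambulance-recorded and ED-recorded arrival time, in minutes.
#' @param site_swap_rate probability that the ED row records the wrong
#'   hospital site (paramedic destination entry error). Default 0.
#' @param registry_size number of call signs in the generated fleet registry.
#' @param seed integer seed; the same config and seed give byte-identical
#'   datasets.
#'
#' @return an object of class `edlink_sim_config` (a named list).
#' @export
sim_config <- function(n_incidents,
                       date_start,
                       date_end = date_start,
                       n_sites = 13,
                       conveyed_fraction = 0.70,
                       midnight_crossing_fraction = 0.04,
                       multi_patient_shift_rate = 0.05,
                       timestamp_jitter_minutes = 10,
                       site_swap_rate = 0,
                       registry_size = 300,
                       seed = 1L) {
  date_start <- as.Date(date_start)
  date_end <- as.Date(date_end)
  if (is.na(date_start) || is.na(date_end) || date_start > date_end) {
    stop("`date_start` must be on or before `date_end`", call. = FALSE)
  }
  if (!is.numeric(n_incidents) || n_incidents < 1) {
    stop("`n_incidents` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(n_sites) || n_sites < 1) {
    stop("`n_sites` must be a positive integer", call. = FALSE)
  }
  assert_proportion(conveyed_fraction, "conveyed_fraction")
  if (conveyed_fraction == 0) {
    stop("`conveyed_fraction` must be in (0, 1]", call. = FALSE)
  }
  assert_proportion(midnight_crossing_fraction, "midnight_crossing_fraction")
  assert_proportion(multi_patient_shift_rate, "multi_patient_shift_rate")
  assert_proportion(site_swap_rate, "site_swap_rate")
  if (timestamp_jitter_minutes < 0) {
    stop("`timestamp_jitter_minutes` must be non-negative", call. = FALSE)
  }
  structure(
    list(
      n_incidents = as.integer(n_incidents),
      date_start = date_start,
      date_end = date_end,
      n_sites = as.integer(n_sites),
      conveyed_fraction = conveyed_fraction,
      midnight_crossing_fraction = midnight_crossing_fraction,
      multi_patient_shift_rate = multi_patient_shift_rate,
      timestamp_jitter_minutes = timestamp_jitter_minutes,
      site_swap_rate = site_swap_rate,
      registry_size = as.integer(registry_size),
      seed = as.integer(seed)
    ),
    class = "edlink_sim_config"
  )
}

#' Generate a call-sign registry
#'
#' Call signs identify an ambulance crew's vehicle shift: a letter block
#' followed by zero-padded digits (canonical length 4, e.g. "Q087"). The
#' ambulance service holds the list of all possible call signs; the cleaning
#' stage uses it to verify call signs parsed out of ED free text.
#'
#' @param size number of distinct call signs.
#' @param seed integer seed.
#' @return character vector of call-sign tokens, sorted.
#' @export
generate_callsign_registry <- function(size = 300, seed = 1L) {
  grid <- as.vector(outer(LETTERS, sprintf("%03d", 1:999), paste0))
  if (size > length(grid)) {
    stop("requested registry size exceeds the call-sign namespace", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), sort(sample(grid, size)))
}

#' Generate a ground-truthed ambulance conveyance dataset
#'
#' One row per patient conveyed to an ED. CAD numbers are assigned
#' sequentially from 1 within each service day in call-time order (the CAD
#' system resets at midnight); conveyance to an ED happens with probability
#' `conveyed_fraction`, so CAD sequences in the output may have gaps where
#' care was completed without conveyance. Call signs are drawn per day from
#' the generated registry; with probability `multi_patient_shift_rate` a
#' conveyance reuses the previous crew's call sign and destination,
#' emulating a crew bringing several patients to one ED in a shift.
#'
#' @param config an [sim_config()] object.
#' @return a tibble with columns `amb_id`, `cad_number`, `incident_date`,
#'   `call_sign`, `call_time`, `ed_arrival`, `destination_site`, `age`,
#'   `gender`. The call-sign registry is attached as attribute
#'   `callsign_registry` and the config as `sim_config`.
#' @export
generate_ambulance_dataset <- function(config) {
  stopifnot(inherits(config, "edlink_sim_config"))
  withr::with_seed(config$seed, {
    registry <- generate_callsign_registry(config$registry_size, config$seed)
    days <- seq(config$date_start, config$date_end, by = "day")
    day_idx <- sort(sample(seq_along(days), config$n_incidents, replace = TRUE))
    counts <- tabulate(day_idx, nbins = length(days))
    if (any(counts > 6999L)) {
      stop(sprintf(
        "capacity error: %d incidents on %s exceed the 6999 daily CAD capacity",
        max(counts), days[which.max(counts)]
      ), call. = FALSE)
    }

    sites <- sprintf("ED%02d", seq_len(config$n_sites))
    rows <- vector("list", length(days))
    for (d in seq_along(days)) {
      n_d <- counts[d]
      if (n_d == 0L) next
      day <- days[d]
      crossing <- stats::runif(n_d) < config$midnight_crossing_fraction
      # call times: midnight-crossers start 23:00-23:59, others 00:00-21:59
      call_min <- ifelse(
        crossing,
        23 * 60 + sample.int(60, n_d, replace = TRUE) - 1L,
        sample.int(22 * 60, n_d, replace = TRUE) - 1L
      )
      ord <- order(call_min)
      call_min <- call_min[ord]
      crossing <- crossing[ord]
      cad <- seq_len(n_d)                       # sequential within the day
      conveyed <- stats::runif(n_d) < config$conveyed_fraction
      travel <- 20 + round(stats::runif(n_d) * 70)   # 20-90 min call to ED door

      site <- sample(sites, n_d, replace = TRUE)
      sign_pool <- sample(registry)
      call_sign <- character(n_d)
      pool_i <- 0L
      prev <- 0L
      for (i in seq_len(n_d)) {
        if (!conveyed[i]) next
        reuse <- prev > 0L && stats::runif(1) < config$multi_patient_shift_rate
        if (reuse) {
          call_sign[i] <- call_sign[prev]
          site[i] <- site[prev]
          # second patient of the shift: picked up after the previous drop-off
          call_min[i] <- call_min[prev] + travel[prev] + 10 + round(stats::runif(1) * 50)
        } else {
          pool_i <- pool_i + 1L
          if (pool_i > length(sign_pool)) {
            stop("call-sign registry too small for the daily crew demand", call. = FALSE)
          }
          call_sign[i] <- sign_pool[pool_i]
        }
        prev <- i
      }

      arrive_min <- call_min + travel
      # crew-shift chains can drift late: clamp so non-crossers stay on the
      # service day and crossers arrive no later than the following day,
      # keeping call time strictly before ED arrival
      cap <- ifelse(crossing, 2 * 24 * 60 - 1, 24 * 60 - 1)
      arrive_min <- pmin(arrive_min, cap)
      call_min <- pmin(call_min, arrive_min - 5)
      base <- as.POSIXct(paste(day, "00:00:00"), tz = "UTC")
      rows[[d]] <- tibble::tibble(
        cad_number = cad[conveyed],
        incident_date = day,
        call_sign = call_sign[conveyed],
        call_time = floor_minute(base + call_min[conveyed] * 60),
        ed_arrival = floor_minute(base + arrive_min[conveyed] * 60),
        destination_site = site[conveyed],
        age = sample(0:99, sum(conveyed), replace = TRUE,
                     prob = c(rep(1, 18), rep(1.4, 47), rep(2.2, 35))),
        gender = sample(c("F", "M"), sum(conveyed), replace = TRUE)
      )
    }
    amb <- dplyr::bind_rows(rows)
    amb <- dplyr::mutate(amb,
      amb_id = sprintf("AMB%06d", dplyr::row_number()),
      .before = 1
    )
    attr(amb, "callsign_registry") <- registry
    attr(amb, "sim_config") <- config
    amb
  })
}

# clinical category vocabularies used when populating ED fields
.ed_vocab <- list(
  ethnicity = c("White", "Black", "Asian", "Mixed", "Other"),
  first_ed_location = c("Resus", "Majors", "Minors", "Paediatrics"),
  diagnosis = c("injury", "cardiac", "respiratory", "abdominal",
                "neurological", "infection", "other"),
  specialty_referral = c("none", "medicine", "surgery", "orthopaedics",
                         "paediatrics", "psychiatry"),
  outcome = c("admitted", "discharged", "transferred", "referred"),
  outcome_destination = c("ward", "home", "other_hospital", "clinic"),
  pathology = c("FBC", "U&E", "troponin", "CRP", "glucose"),
  imaging = c("XR chest", "XR limb", "CT head", "USS", "none"),
  treatment = c("analgesia", "dressing", "nebuliser", "fluids", "none")
)

# render a (cad, call_sign) pair into one of the free-text layouts seen in
# combined identifier fields
render_identifier_freetext <- function(cad, call_sign, layout) {
  switch(layout,
    cad_label = sprintf("CAD%d, %s", cad, call_sign),
    callsign_label = sprintf("%d, Call sign %s", cad, call_sign),
    slash = sprintf("%s/%d", call_sign, cad),
    stop(sprintf("unknown free-text layout '%s'", layout), call. = FALSE)
  )
}

#' Generate one trust's ED extract, with ground truth
#'
#' Builds the ED attendance rows a trust would extract for the conveyances
#' arriving at its sites, then applies the trust's recording behaviour:
#' identifier fields laid out per `identifier_mode` and `format_mix`, both
#' identifiers blanked with probability `null_identifier_rate`, the CAD
#' field replaced by a misuse sentinel (e.g. "136" for Mental Health Act
#' cases, which then carry a mental-health diagnosis) with probability
#' `misuse_rate`, ED arrival jittered against the ambulance clock, variables
#' the trust does not collect omitted, duplicate rows injected, and a
#' proportion of absent cells mis-coded "NULL" instead of the "XXXX"
#' sentinel (`extract_error_rate`).
#'
#' @param ambulance output of [generate_ambulance_dataset()].
#' @param profile a [trust_profile()].
#' @param config the [sim_config()] used to generate `ambulance`.
#' @return a list with elements `rows` (tibble of ED rows, columns per the
#'   trust's availability; in-memory missing values are `NA`) and `truth`
#'   (tibble `ed_row_id`, `amb_id`: one pair per non-duplicate row, kept
#'   even when the row's identifiers were blanked). Attributes on `rows`
#'   record the injected corruption: `n_duplicates_injected`,
#'   `duplicate_row_ids`, `n_null_injected`, `n_misuse_injected`,
#'   `n_extract_errors`, `trust`.
#' @export
generate_ed_extract <- function(ambulance, profile, config) {
  stopifnot(inherits(profile, "edlink_trust_profile"),
            inherits(config, "edlink_sim_config"))
  if (nrow(ambulance) == 0) stop("ambulance dataset is empty", call. = FALSE)
  src <- dplyr::filter(ambulance, .data$destination_site %in% profile$site_ids)
  if (nrow(src) == 0) {
    warning(sprintf("no conveyances to the sites of trust %s; empty extract",
                    profile$trust_name), call. = FALSE)
    return(list(
      rows = tibble::tibble(row_id = character()),
      truth = tibble::tibble(ed_row_id = character(), amb_id = character())
    ))
  }

  withr::with_seed(derive_seed(config$seed, profile$trust_name), {
    n <- nrow(src)
    row_id <- sprintf("%s-%06d", profile$trust_name, seq_len(n))

    site <- src$destination_site
    swap <- stats::runif(n) < config$site_swap_rate
    if (any(swap) && config$n_sites > 1) {
      all_sites <- sprintf("ED%02d", seq_len(config$n_sites))
      site[swap] <- vapply(site[swap], function(s) {
        sample(setdiff(all_sites, s), 1)
      }, character(1))
    }

    jit <- config$timestamp_jitter_minutes
    arrival <- floor_minute(src$ed_arrival + stats::runif(n, -jit, jit) * 60)

    vocab_col <- function(v) sample(.ed_vocab[[v]], n, replace = TRUE)
    ed <- tibble::tibble(
      row_id = row_id,
      hospital_site = site,
      ed_arrival_datetime = arrival,
      ethnicity = vocab_col("ethnicity"),
      age = as.integer(src$age),
      gender = src$gender,
      gp_practice_id = sprintf("P%05d", sample.int(600, n, replace = TRUE)),
      first_ed_location = vocab_col("first_ed_location"),
      blue_light_journey = sample(c("Y", "N"), n, replace = TRUE, prob = c(.3, .7)),
      pathology = vocab_col("pathology"),
      imaging = vocab_col("imaging"),
      treatment = vocab_col("treatment"),
      diagnosis = vocab_col("diagnosis"),
      specialty_referral = vocab_col("specialty_referral"),
      outcome = vocab_col("outcome"),
      outcome_destination = vocab_col("outcome_destination"),
      departure_datetime = floor_minute(arrival + (30 + round(stats::runif(n) * 330)) * 60)
    )

    # identifier fields per recording mode
    if (profile$identifier_mode == "separate_fields") {
      ed$cad_number <- as.character(src$cad_number)
      ed$call_sign <- src$call_sign
    } else if (profile$identifier_mode == "cad_only") {
      ed$cad_number <- as.character(src$cad_number)
    } else { # combined_freetext
      layouts <- sample(names(profile$format_mix), n, replace = TRUE,
                        prob = unname(profile$format_mix))
      ed$cad_call_sign <- vapply(seq_len(n), function(i) {
        render_identifier_freetext(src$cad_number[i], src$call_sign[i], layouts[i])
      }, character(1))
    }
    id_cols <- intersect(c("cad_number", "call_sign", "cad_call_sign"), names(ed))

    # blank both identifiers (unregistered patients, walk-outs, blank fields)
    u <- stats::runif(n)
    nulled <- u < profile$null_identifier_rate
    for (col in id_cols) ed[[col]][nulled] <- NA_character_

    # sentinel misuse: CAD field carries a non-incident token
    misused <- rep(FALSE, n)
    if (!is.null(profile$misuse_sentinel) && profile$misuse_rate > 0) {
      cad_col <- if ("cad_number" %in% id_cols) "cad_number" else "cad_call_sign"
      misused <- !nulled & stats::runif(n) < profile$misuse_rate
      ed[[cad_col]][misused] <- profile$misuse_sentinel
      if ("call_sign" %in% id_cols) ed$call_sign[misused] <- NA_character_
      ed$diagnosis[misused] <- "mental_health"
    }

    # drop variables the trust does not collect
    keep <- c("row_id", intersect(ed_variables(), profile$available_variables))
    keep <- intersect(names(ed), c(keep, id_cols))
    ed <- ed[, unique(c("row_id", setdiff(keep, "row_id")))]

    # mis-coded absent cells: literal "NULL" where "XXXX" belongs
    n_err <- 0L
    if (profile$extract_error_rate > 0) {
      char_cols <- setdiff(names(ed)[vapply(ed, is.character, logical(1))], "row_id")
      for (col in char_cols) {
        hit <- is.na(ed[[col]]) & stats::runif(n) < profile$extract_error_rate
        ed[[col]][hit] <- "NULL"
        n_err <- n_err + sum(hit)
      }
    }

    truth <- tibble::tibble(ed_row_id = row_id, amb_id = src$amb_id)

    # duplicate injection: exact copies under a fresh row id, appended after
    # the originals so deduplication always retains the ground-truthed row
    dup_ids <- character(0)
    if (profile$duplicate_rate > 0) {
      dup <- which(stats::runif(n) < profile$duplicate_rate)
      if (length(dup)) {
        extra <- ed[dup, ]
        extra$row_id <- paste0(ed$row_id[dup], "-D1")
        dup_ids <- extra$row_id
        ed <- dplyr::bind_rows(ed, extra)
      }
    }

    attr(ed, "n_duplicates_injected") <- length(dup_ids)
    attr(ed, "duplicate_row_ids") <- dup_ids
    attr(ed, "n_null_injected") <- sum(nulled)
    attr(ed, "n_misuse_injected") <- sum(misused)
    attr(ed, "n_extract_errors") <- n_err
    attr(ed, "trust") <- profile$trust_name
    list(rows = ed, truth = truth)
  })
}
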