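# small hand-built fixtures shared across test files

# an ambulance table with explicit values for rule-level linkage tests
tiny_ambulance <- function() {
  ts <- function(x) as.POSIXct(x, tz = "UTC")
  tibble::tibble(
    amb_id = c("A1", "A2", "A3", "A4"),
    cad_number = c(123L, 123L, 55L, 55L),
    incident_date = as.Date(c("2014-05-02", "2014-05-03", "2014-05-02", "2014-05-02")),
    call_sign = c("Q987", "Q987", "R100", "R100"),
    call_time = ts(c("2014-05-02 09:40", "2014-05-03 11:00",
                     "2014-05-02 09:30", "2014-05-02 15:40")),
    ed_arrival = ts(c("2014-05-02 10:25", "2014-05-03 11:45",
                      "2014-05-02 10:25", "2014-05-02 16:40")),
    destination_site = c("ED01", "ED01", "ED02", "ED02"),
    age = c(40L, 62L, 8L, 77L),
    gender = c("F", "M", "M", "F")
  )
}

# a cleaned ED row ready for the matchers
ed_row <- function(row_id = "r1", cad = NA, call_sign = NA,
                   arrival = "2014-05-02 10:30", site = "ED01",
                   parse_status = NULL) {
  status <- parse_status %||% dplyr::case_when(
    !is.na(cad) && !is.na(call_sign) ~ "both",
    !is.na(cad) ~ "cad_only",
    !is.na(call_sign) ~ "callsign_only",
    TRUE ~ "none"
  )
  tibble::tibble(
    row_id = row_id,
    cad = as.integer(cad),
    call_sign = as.character(call_sign),
    parse_status = status,
    ed_arrival_datetime = as.POSIXct(arrival, tz = "UTC"),
    hospital_site = site
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# run the whole pipeline for one trust profile; returns evaluation pieces
run_pipeline <- function(config, profile) {
  amb <- generate_ambulance_dataset(config)
  ex <- generate_ed_extract(amb, profile, config)
  reg <- attr(amb, "callsign_registry")
  cl <- clean_extract(ex$rows, reg)
  lk <- link_all(cl$rows, amb)
  list(amb = amb, extract = ex, cleaned = cl, linked = lk,
       eval = evaluate_against_truth(lk$results, ex$truth))
}

# a clean (corruption-free) study configuration
clean_config <- function(n_incidents = 400, seed = 1, n_sites = 3, days = 10) {
  sim_config(
    n_incidents = n_incidents,
    date_start = "2014-05-01",
    date_end = as.character(as.Date("2014-05-01") + days - 1),
    n_sites = n_sites,
    conveyed_fraction = 1,
    midnight_crossing_fraction = 0,
    multi_patient_shift_rate = 0.05,
    timestamp_jitter_minutes = 0,
    registry_size = max(300, ceiling(n_incidents / days) + 100),
    seed = seed
  )
}

# a profile covering all sites with no corruption
clean_profile <- function(n_sites = 3, mode = "separate_fields") {
  trust_profile(
    "Test", site_ids = sprintf("ED%02d", seq_len(n_sites)),
    identifier_mode = mode
  )
}
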