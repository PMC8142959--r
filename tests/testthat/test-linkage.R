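test_that("the index keys distinct (cad, date) pairs and quarantines clashes", {
  amb <- tiny_ambulance()
  expect_warning(idx <- build_index(amb), "quarantined")
  # A3 and A4 share (55, 2014-05-02): both quarantined from CAD lookup
  expect_setequal(idx$quarantined, c("A3", "A4"))
  # but both remain reachable through the call-sign lookup
  r <- ed_row(call_sign = "R100", arrival = "2014-05-02 16:45", site = "ED02")
  m <- match_callsign(r, idx)
  expect_equal(m$amb_id, "A4")

  empty <- build_index(tiny_ambulance()[0, ])
  expect_equal(empty$n, 0)
  expect_equal(length(empty$quarantined), 0)
})

test_that("CAD+date matches on the arrival date with no time comparison", {
  idx <- suppressWarnings(build_index(tiny_ambulance()))
  m <- match_cad_date(ed_row(cad = 123, arrival = "2014-05-02 10:30"), idx)
  expect_equal(m$amb_id, "A1")
  expect_equal(m$method, "cad_date")
  expect_equal(m$flags, "")
  # a wildly different time of day still matches: date alone corroborates
  m2 <- match_cad_date(ed_row(cad = 123, arrival = "2014-05-02 23:59"), idx)
  expect_equal(m2$amb_id, "A1")
})

test_that("midnight crossings match the previous date and are flagged", {
  idx <- suppressWarnings(build_index(tiny_ambulance()))
  m <- match_cad_date(ed_row(cad = 55, arrival = "2014-05-03 00:20", site = "ED02"), idx)
  expect_null(m)  # (55, 2014-05-02) is quarantined; no consecutive-date rescue
  amb <- tiny_ambulance()[1:2, ]
  idx2 <- build_index(amb)
  m2 <- match_cad_date(ed_row(cad = 123, arrival = "2014-05-04 00:20"), idx2)
  expect_equal(m2$amb_id, "A2")
  expect_match(m2$flags, "consecutive_date_used")
  # a two-day gap never matches
  expect_null(match_cad_date(ed_row(cad = 123, arrival = "2014-05-05 00:20"), idx2))
  # and the rescue can be disabled
  cfg <- link_config(allow_consecutive_dates = FALSE)
  expect_null(match_cad_date(ed_row(cad = 123, arrival = "2014-05-04 00:20"), idx2, cfg))
})

test_that("CAD site disagreement is flagged by default and rejected on demand", {
  idx <- build_index(tiny_ambulance()[1:2, ])
  r <- ed_row(cad = 123, arrival = "2014-05-02 10:30", site = "ED09")
  m <- match_cad_date(r, idx)
  expect_equal(m$amb_id, "A1")
  expect_match(m$flags, "site_disagreement")
  expect_null(match_cad_date(r, idx, link_config(cmp_site_cad = "require")))
  m3 <- match_cad_date(r, idx, link_config(cmp_site_cad = "ignore"))
  expect_equal(m3$flags, "")
})

test_that("call-sign pathway picks the nearest candidate within the window", {
  idx <- suppressWarnings(build_index(tiny_ambulance()))
  # candidates on R100/2014-05-02 arrive 10:25 and 16:40; ED arrival 16:45
  m <- match_callsign(ed_row(call_sign = "R100", arrival = "2014-05-02 16:45",
                             site = "ED02"), idx)
  expect_equal(m$amb_id, "A4")
  expect_equal(m$method, "callsign_datetime")
  # exactly at the 120-minute tolerance: fine; 131 minutes away: out of window
  m2 <- match_callsign(ed_row(call_sign = "R100", arrival = "2014-05-02 18:40",
                              site = "ED02"), idx)
  expect_equal(m2$amb_id, "A4")
  expect_null(match_callsign(ed_row(call_sign = "R100", arrival = "2014-05-02 18:51",
                                    site = "ED02"), idx,
                             link_config(time_tolerance_minutes = 130)))
})

test_that("equidistant call-sign candidates are ambiguous and unmatched", {
  ts <- function(x) as.POSIXct(x, tz = "UTC")
  amb <- tibble::tibble(
    amb_id = c("B1", "B2"), cad_number = c(9L, 10L),
    incident_date = as.Date("2014-05-02"), call_sign = "Q001",
    call_time = ts(c("2014-05-02 09:00", "2014-05-02 10:20")),
    ed_arrival = ts(c("2014-05-02 10:00", "2014-05-02 11:00")),
    destination_site = "ED01", age = c(30L, 40L), gender = c("F", "M")
  )
  idx <- build_index(amb)
  row <- ed_row(call_sign = "Q001", arrival = "2014-05-02 10:30")
  expect_null(match_callsign(row, idx))
  res <- link_all(dplyr::mutate(row, cad = NA_integer_), amb)
  expect_equal(res$results$method, "unmatched")
  expect_match(res$results$flags, "ambiguous_candidates")
})

test_that("call-sign site agreement is required by default", {
  idx <- suppressWarnings(build_index(tiny_ambulance()[3:4, ]))
  r <- ed_row(call_sign = "R100", arrival = "2014-05-02 16:45", site = "ED05")
  expect_null(match_callsign(r, idx))
  m <- match_callsign(r, idx, link_config(require_site_agreement_callsign = FALSE))
  expect_equal(m$amb_id, "A4")
})

test_that("CAD precedence: the CAD pathway is run first when both identifiers parse", {
  amb <- tiny_ambulance()[1:2, ]
  rows <- dplyr::bind_rows(
    ed_row("r1", cad = 123, call_sign = "Q987", arrival = "2014-05-02 10:30"),
    ed_row("r2", cad = 999, call_sign = "Q987", arrival = "2014-05-02 10:30"),
    ed_row("r3", arrival = "2014-05-02 10:30")
  )
  res <- link_all(rows, amb)$results
  expect_equal(res$method, c("cad_date", "callsign_datetime", "no_identifier"))
  expect_equal(res$amb_id, c("A1", "A1", NA))
})

test_that("link_all yields exactly one result per row, partitioned by method", {
  cfg <- clean_config(n_incidents = 300, seed = 33)
  amb <- generate_ambulance_dataset(cfg)
  prof <- trust_profile("T", sprintf("ED%02d", 1:3), null_identifier_rate = 0.3)
  ex <- generate_ed_extract(amb, prof, cfg)
  cl <- clean_extract(ex$rows, attr(amb, "callsign_registry"))
  lk <- link_all(cl$rows, amb)
  expect_equal(nrow(lk$results), nrow(cl$rows))
  expect_equal(sum(table(lk$results$method)), nrow(cl$rows))
  expect_true(all(is.na(lk$results$amb_id) ==
                    (lk$results$method %in% c("unmatched", "no_identifier"))))
  # per-site tallies conserve the total
  expect_equal(sum(dplyr::select(lk$tallies, -site)), nrow(cl$rows))
})

test_that("indexed linkage equals the naive all-pairs oracle on small instances", {
  for (seed in 1:5) {
    cfg <- sim_config(
      n_incidents = 250, date_start = "2014-05-01", date_end = "2014-05-06",
      n_sites = 3, conveyed_fraction = 0.8,
      midnight_crossing_fraction = 0.1, multi_patient_shift_rate = 0.15,
      timestamp_jitter_minutes = 30, seed = seed
    )
    amb <- generate_ambulance_dataset(cfg)
    prof <- trust_profile("T", sprintf("ED%02d", 1:3),
                          identifier_mode = "combined_freetext",
                          null_identifier_rate = 0.15)
    ex <- generate_ed_extract(amb, prof, cfg)
    cl <- clean_extract(ex$rows, attr(amb, "callsign_registry"))
    cfg_link <- link_config(time_tolerance_minutes = c(60, 120, 240)[seed %% 3 + 1])
    got <- suppressWarnings(link_all(cl$rows, amb, cfg_link))$results
    want <- naive_link_all(cl$rows, amb, cfg_link)
    expect_equal(got$amb_id, want$amb_id, info = paste("seed", seed))
    expect_equal(got$method, want$method, info = paste("seed", seed))
  }
})

test_that("call-sign matches are monotone in the time tolerance", {
  cfg <- sim_config(n_incidents = 600, date_start = "2014-05-01",
                    date_end = "2014-05-06", n_sites = 3,
                    multi_patient_shift_rate = 0.2,
                    timestamp_jitter_minutes = 90, seed = 41)
  amb <- generate_ambulance_dataset(cfg)
  # drop CADs so everything exercises the call-sign pathway
  prof <- trust_profile("T", sprintf("ED%02d", 1:3))
  ex <- generate_ed_extract(amb, prof, cfg)
  cl <- clean_extract(ex$rows, attr(amb, "callsign_registry"))
  cl$rows$cad <- NA_integer_
  cl$rows$parse_status <- ifelse(is.na(cl$rows$call_sign), "none", "callsign_only")
  counts <- vapply(c(5, 15, 30, 60, 120, 360), function(tol) {
    res <- link_all(cl$rows, amb, link_config(time_tolerance_minutes = tol))$results
    sum(res$method == "callsign_datetime")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[6], counts[1])
})

test_that("removing CADs never contradicts ground truth more than the CAD pathway", {
  # under midnight-crossing and jitter corruption the CAD pathway is the one
  # exposed to date-collision false links; the corroborated call-sign
  # pathway on the same rows must not exceed its contradiction count
  for (seed in c(3, 8)) {
    cfg <- sim_config(n_incidents = 3000, date_start = "2014-05-01",
                      date_end = "2014-05-15", n_sites = 3,
                      midnight_crossing_fraction = 0.1,
                      timestamp_jitter_minutes = 20,
                      multi_patient_shift_rate = 0.1, seed = seed)
    amb <- generate_ambulance_dataset(cfg)
    ex <- generate_ed_extract(amb, clean_profile(3), cfg)
    cl <- clean_extract(ex$rows, attr(amb, "callsign_registry"))
    ev_cad <- evaluate_against_truth(link_all(cl$rows, amb)$results, ex$truth)
    nocad <- cl$rows
    nocad$cad <- NA_integer_
    nocad$parse_status <- ifelse(is.na(nocad$call_sign), "none", "callsign_only")
    ev_cs <- evaluate_against_truth(link_all(nocad, amb)$results, ex$truth)
    expect_lte(ev_cs$false_links, ev_cad$false_links)
    expect_gt(ev_cad$false_links, 0)  # the corruption really bites the CAD path
  }
})
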