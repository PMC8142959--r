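registry_q <- c("Q987", "R100", "A001")

test_that("the three published free-text layouts all parse to the same pair", {
  for (txt in c("CAD123, Q987", "123, Call sign Q987", "Q987/123")) {
    p <- parse_identifiers(txt, registry = registry_q)
    expect_equal(p$cad, 123L, info = txt)
    expect_equal(p$call_sign, "Q987", info = txt)
    expect_equal(p$parse_status, "both", info = txt)
  }
})

test_that("missing sentinels and empty fields yield parse_status none", {
  for (txt in list("XXXX", "", NA_character_, "NULL")) {
    p <- parse_identifiers(txt, registry = registry_q)
    expect_true(is.na(p$cad))
    expect_true(is.na(p$call_sign))
    expect_equal(p$parse_status, "none")
  }
})

test_that("the under-7000 rule excludes large numeric tokens from CAD", {
  p <- parse_identifiers("7421, Q987", registry = registry_q)
  expect_true(is.na(p$cad))
  expect_equal(p$call_sign, "Q987")
  expect_equal(p$parse_status, "callsign_only")
  # boundary behaviour
  expect_equal(parse_identifiers("6999", registry = registry_q)$cad, 6999L)
  expect_true(is.na(parse_identifiers("7000", registry = registry_q)$cad))
  # 5-digit strings are never CAD candidates, even with a small value
  expect_true(is.na(parse_identifiers("00123", registry = registry_q)$cad))
})

test_that("call signs not in the registry are rejected; only exact matches pass", {
  p <- parse_identifiers("123, Call sign Z999", registry = registry_q)
  expect_equal(p$cad, 123L)
  expect_true(is.na(p$call_sign))
  expect_equal(p$parse_status, "cad_only")
  expect_true(p$callsign_rejected)
  # canonicalisation: case and stray punctuation do not defeat an exact match
  expect_equal(parse_identifiers("q987/123", registry = registry_q)$call_sign, "Q987")
})

test_that("digits inside a call-sign token are never claimed as CAD", {
  p <- parse_identifiers("Q987", registry = registry_q)
  expect_true(is.na(p$cad))
  expect_equal(p$parse_status, "callsign_only")
})

test_that("leading zeros parse to the numeric CAD identity", {
  expect_equal(parse_identifiers("0123, Q987", registry = registry_q)$cad, 123L)
})

test_that("multiple CAD candidates take the first by position and are counted", {
  p <- parse_identifiers("55, 123, Q987", registry = registry_q)
  expect_equal(p$cad, 55L)
  expect_true(p$multi_cad)
})

test_that("separate CAD and call-sign fields parse through the same scanner", {
  p <- parse_identifiers(c("136", "55", "XXXX"), c("Q987", "XXXX", "XXXX"),
                         registry = registry_q)
  expect_equal(p$cad, c(136L, 55L, NA))
  expect_equal(p$call_sign, c("Q987", NA, NA))
  expect_equal(p$parse_status, c("both", "cad_only", "none"))
})

test_that("rendering any pair into each layout and re-parsing recovers it exactly", {
  set.seed(42)
  registry <- generate_callsign_registry(150, seed = 5)
  cads <- sample(1:6999, 60)
  signs <- sample(registry, 60, replace = TRUE)
  for (layout in c("cad_label", "callsign_label", "slash")) {
    txt <- vapply(seq_along(cads), function(i) {
      edlink:::render_identifier_freetext(cads[i], signs[i], layout)
    }, character(1))
    p <- parse_identifiers(txt, registry = registry)
    expect_equal(p$cad, as.integer(cads), info = layout)
    expect_equal(p$call_sign, signs, info = layout)
    expect_true(all(p$parse_status == "both"), info = layout)
  }
})

test_that("parsing is idempotent on its own canonical rendering", {
  p1 <- parse_identifiers("Q987 / 0123", registry = registry_q)
  p2 <- parse_identifiers(sprintf("%s/%d", p1$call_sign, p1$cad),
                          registry = registry_q)
  expect_equal(p1$cad, p2$cad)
  expect_equal(p1$call_sign, p2$call_sign)
})

test_that("parsed call signs are always registry members when a registry is given", {
  set.seed(7)
  registry <- generate_callsign_registry(50, seed = 2)
  junk <- c(sample(registry, 30, replace = TRUE),
            sprintf("Z%03d", 1:20), "hello", "CAD99")
  txt <- paste(sample(junk), sample(1:9999, length(junk)), sep = ", ")
  p <- parse_identifiers(txt, registry = registry)
  got <- p$call_sign[!is.na(p$call_sign)]
  expect_true(all(got %in% registry))
})

test_that("exact duplicate rows collapse to the first occurrence", {
  rows <- tibble::tibble(
    row_id = c("a", "b", "c"),
    x = c(1, 1, 1),
    t = as.POSIXct(c("2014-05-01 10:00", "2014-05-01 10:00", "2014-05-01 10:05"),
                   tz = "UTC")
  )
  dd <- deduplicate(rows)
  expect_equal(dd$n_removed, 1L)
  expect_equal(dd$rows$row_id, c("a", "c"))  # differing arrival time retained
})

test_that("deduplication removes exactly the generator-injected duplicates", {
  cfg <- clean_config(n_incidents = 400, seed = 23)
  amb <- generate_ambulance_dataset(cfg)
  prof <- trust_profile("T", sprintf("ED%02d", 1:3), duplicate_rate = 0.08)
  ex <- generate_ed_extract(amb, prof, cfg)
  dd <- deduplicate(ex$rows)
  expect_equal(dd$n_removed, attr(ex$rows, "n_duplicates_injected"))
  expect_setequal(dd$rows$row_id, ex$truth$ed_row_id)
})

test_that("clean_extract report counts are consistent with row-level results", {
  cfg <- clean_config(n_incidents = 500, seed = 25)
  amb <- generate_ambulance_dataset(cfg)
  reg <- attr(amb, "callsign_registry")
  prof <- trust_profile("T", sprintf("ED%02d", 1:3),
                        identifier_mode = "combined_freetext",
                        null_identifier_rate = 0.2, duplicate_rate = 0.05)
  ex <- generate_ed_extract(amb, prof, cfg)
  cl <- clean_extract(ex$rows, reg)
  r <- cl$report
  expect_equal(r$n_rows_in, nrow(ex$rows))
  expect_equal(r$n_rows_in - r$n_duplicates_removed, nrow(cl$rows))
  expect_equal(r$n_parsed_cad, sum(!is.na(cl$rows$cad)))
  expect_equal(r$n_parsed_callsign, sum(!is.na(cl$rows$call_sign)))
  expect_equal(r$n_neither, sum(cl$rows$parse_status == "none"))
  # rows after dedup partition into neither vs at-least-one-identifier
  expect_equal(r$n_neither + sum(cl$rows$parse_status != "none"), nrow(cl$rows))
  expect_true(all(unlist(r[-1]) <= r$n_rows_in))
})

test_that("a no-null single-layout free-text extract parses every row", {
  cfg <- clean_config(n_incidents = 200, seed = 27)
  amb <- generate_ambulance_dataset(cfg)
  reg <- attr(amb, "callsign_registry")
  prof <- trust_profile("T", sprintf("ED%02d", 1:3),
                        identifier_mode = "combined_freetext",
                        format_mix = c(cad_label = 1, callsign_label = 0, slash = 0))
  ex <- generate_ed_extract(amb, prof, cfg)
  cl <- clean_extract(ex$rows, reg)
  expect_equal(cl$report$n_parsed_cad, nrow(ex$rows))
  expect_equal(cl$report$n_parsed_callsign, nrow(ex$rows))
})

test_that("a CAD field full of '136' parses every row: flagging is downstream", {
  rows <- tibble::tibble(
    row_id = sprintf("r%02d", 1:40),
    hospital_site = "ED01",
    ed_arrival_datetime = as.POSIXct("2014-05-01 10:00", tz = "UTC") + 60 * (1:40),
    cad_number = "136"
  )
  cl <- clean_extract(rows, registry_q)
  expect_equal(cl$report$n_parsed_cad, 40L)
  expect_true(all(cl$rows$cad == 136L))
})

test_that("empty input yields empty output and a zeroed report", {
  cl <- clean_extract(tibble::tibble(row_id = character(),
                                     cad_number = character()), registry_q)
  expect_equal(nrow(cl$rows), 0)
  expect_true(all(unlist(cl$report) == 0))
})
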