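#' The 18 ED variables requested from every trust
#'
#' Canonical column order for an ED extract. Identifier recording differs by
#' trust: trusts with `identifier_mode = "combined_freetext"` replace the
#' `cad_number` and `call_sign` columns with a single unformatted
#' `cad_call_sign` free-text column, and CAD-only trusts omit `call_sign`.
#'
#' @return character vector of variable names in canonical order.
#' @export
ed_variables <- function() {
  c(
    "hospital_site", "ed_arrival_datetime", "ethnicity", "age", "gender",
    "gp_practice_id", "first_ed_location", "blue_light_journey", "pathology",
    "imaging", "treatment", "diagnosis", "specialty_referral", "outcome",
    "outcome_destination", "departure_datetime", "cad_number", "call_sign"
  )
}

#' Describe one trust's extract behaviour
#'
#' A generative description of how an acute trust records and extracts ED
#' attendances: which of the 18 requested variables it can supply, how it
#' records the two ambulance event identifiers, and the error processes
#' observed in real extracts (blank identifiers, sentinel misuse such as
#' "136" for Mental Health Act cases, duplicate rows, and mis-coded missing
#' cells).
#'
#' @param trust_name label, e.g. "Alpha".
#' @param site_ids ED site labels belonging to the trust.
#' @param available_variables subset of [ed_variables()] the trust supplies;
#'   must include `hospital_site` and `ed_arrival_datetime`.
#' @param identifier_mode one of `"separate_fields"` (CAD and call sign in
#'   their own columns), `"combined_freetext"` (both in one unformatted
#'   field), `"cad_only"`.
#' @param null_identifier_rate probability that a row has both identifiers
#'   blank.
#' @param format_mix named probabilities over the free-text layouts
#'   `cad_label` ("CAD123, Q987"), `callsign_label` ("123, Call sign Q987")
#'   and `slash` ("Q987/123"); must sum to 1 when
#'   `identifier_mode = "combined_freetext"`.
#' @param misuse_sentinel optional token written into the CAD field instead
#'   of an incident number (e.g. "136").
#' @param misuse_rate probability of sentinel misuse per row.
#' @param duplicate_rate probability that a row is duplicated in the extract.
#' @param extract_error_rate probability that an absent cell is mis-coded
#'   "NULL" instead of the "XXXX" sentinel.
#' @return an object of class `edlink_trust_profile` (a named list).
#' @export
trust_profile <- function(trust_name,
                          site_ids,
                          available_variables = ed_variables(),
                          identifier_mode = c("separate_fields",
                                              "combined_freetext", "cad_only"),
                          null_identifier_rate = 0,
                          format_mix = c(cad_label = 1 / 3,
                                         callsign_label = 1 / 3,
                                         slash = 1 / 3),
                          misuse_sentinel = NULL,
                          misuse_rate = 0,
                          duplicate_rate = 0,
                          extract_error_rate = 0) {
  identifier_mode <- match.arg(identifier_mode)
  if (!all(c("hospital_site", "ed_arrival_datetime") %in% available_variables)) {
    stop("every trust must supply `hospital_site` and `ed_arrival_datetime`",
         call. = FALSE)
  }
  if (!all(available_variables %in% ed_variables())) {
    stop("unknown variable in `available_variables`", call. = FALSE)
  }
  assert_proportion(null_identifier_rate, "null_identifier_rate")
  assert_proportion(misuse_rate, "misuse_rate")
  assert_proportion(duplicate_rate, "duplicate_rate")
  assert_proportion(extract_error_rate, "extract_error_rate")
  if (identifier_mode == "combined_freetext") {
    if (is.null(names(format_mix)) ||
        !all(names(format_mix) %in% c("cad_label", "callsign_label", "slash")) ||
        abs(sum(format_mix) - 1) > 1e-8) {
      stop("`format_mix` must be named probabilities over the three layouts summing to 1",
           call. = FALSE)
    }
  }
  structure(
    list(
      trust_name = trust_name,
      site_ids = site_ids,
      available_variables = available_variables,
      identifier_mode = identifier_mode,
      null_identifier_rate = null_identifier_rate,
      format_mix = format_mix,
      misuse_sentinel = misuse_sentinel,
      misuse_rate = misuse_rate,
      duplicate_rate = duplicate_rate,
      extract_error_rate = extract_error_rate
    ),
    class = "edlink_trust_profile"
  )
}

#' Preset trust profiles for a six-trust metropolitan study area
#'
#' Six acute trusts, Alpha-Foxtrot, managing thirteen EDs between them, each
#' with the variable availability and identifier-recording behaviour of one
#' observed extract style: two trusts record CAD and call sign in separate
#' fields, three combine both in one unformatted free-text field, and one
#' records CAD only (with occasional "136" Mental Health Act sentinel misuse
#' in that field). Null-identifier, duplicate and mis-coding rates are
#' plausible round values, not calibrated estimates.
#'
#' @return named list of [trust_profile()] objects.
#' @export
trust_profiles <- function() {
  v <- ed_variables()
  drop <- function(...) setdiff(v, c(...))
  list(
    Alpha = trust_profile(
      "Alpha", site_ids = c("ED01", "ED02"),
      available_variables = drop("treatment"),
      identifier_mode = "separate_fields",
      null_identifier_rate = 0.10, extract_error_rate = 0.01
    ),
    Bravo = trust_profile(
      "Bravo", site_ids = c("ED03", "ED04"),
      available_variables = drop("pathology", "imaging", "treatment"),
      identifier_mode = "combined_freetext",
      null_identifier_rate = 0.15,
      format_mix = c(cad_label = 0.5, callsign_label = 0.3, slash = 0.2)
    ),
    Charlie = trust_profile(
      "Charlie", site_ids = c("ED05", "ED06"),
      available_variables = drop("pathology"),
      identifier_mode = "separate_fields",
      null_identifier_rate = 0.001, duplicate_rate = 0.01
    ),
    Delta = trust_profile(
      "Delta", site_ids = c("ED07", "ED08"),
      available_variables = drop("pathology", "specialty_referral"),
      identifier_mode = "combined_freetext",
      null_identifier_rate = 0.19,
      format_mix = c(cad_label = 0.3, callsign_label = 0.3, slash = 0.4)
    ),
    Echo = trust_profile(
      "Echo", site_ids = c("ED09", "ED10", "ED11", "ED12"),
      available_variables = drop("first_ed_location", "specialty_referral"),
      identifier_mode = "combined_freetext",
      null_identifier_rate = 0.08,
      format_mix = c(cad_label = 0.4, callsign_label = 0.4, slash = 0.2),
      extract_error_rate = 0.01
    ),
    Foxtrot = trust_profile(
      "Foxtrot", site_ids = "ED13",
      available_variables = drop("first_ed_location", "specialty_referral",
                                 "outcome_destination", "call_sign"),
      identifier_mode = "cad_only",
      null_identifier_rate = 0.45,
      misuse_sentinel = "136", misuse_rate = 0.002
    )
  )
}
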