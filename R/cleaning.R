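#' Parse CAD and call-sign identifiers out of raw ED fields
#'
#' Implements the cleaning rules used to recover the two ambulance event
#' identifiers from messy ED extracts. The raw field(s) are scanned as a
#' token stream in any order:
#'
#' * a **CAD** candidate is the first purely numeric token of 1-4 digits
#'   whose value is under 7000 (genuine CAD incident numbers reset daily and
#'   never reach 7000); leading zeros are allowed ("0123" is CAD 123);
#'   digits embedded in a call-sign token (the 987 in "Q987") are never
#'   claimed as a CAD;
#' * a **call-sign** candidate is the first letters-then-digits token that,
#'   after canonicalisation (uppercase, punctuation stripped), is an exact
#'   member of the fleet registry — only exact matches are accepted;
#' * the label words "CAD" and "Call sign" are stripped case-insensitively
#'   before scanning, so the common combined layouts "CAD123, Q987",
#'   "123, Call sign Q987" and "Q987/123" all parse to the same pair.
#'
#' Unparseable content yields `parse_status = "none"`, never an error.
#'
#' @param raw_cad_field character vector: the CAD field, or the single
#'   combined free-text field.
#' @param raw_callsign_field optional character vector: the call-sign field
#'   for trusts recording identifiers separately.
#' @param registry character vector of valid call signs (see
#'   [generate_callsign_registry()]); `NULL` skips registry verification.
#' @return tibble with one row per input: `cad` (integer or `NA`),
#'   `call_sign` (canonical token or `NA`), `parse_status` (`"both"`,
#'   `"cad_only"`, `"callsign_only"`, `"none"`), `raw` (original text),
#'   `callsign_rejected` (a letters-then-digits token was present but none
#'   passed registry verification), `multi_cad` (more than one CAD
#'   candidate appeared).
#' @export
parse_identifiers <- function(raw_cad_field, raw_callsign_field = NULL,
                              registry = NULL) {
  n <- length(raw_cad_field)
  if (!is.null(raw_callsign_field) && length(raw_callsign_field) != n) {
    stop("identifier fields must have equal length", call. = FALSE)
  }
  piece <- function(x) ifelse(is_missing_value(x), "", x)
  raw <- if (is.null(raw_callsign_field)) {
    piece(raw_cad_field)
  } else {
    trimws(paste(piece(raw_cad_field), piece(raw_callsign_field)))
  }

  cad <- rep(NA_integer_, n)
  call_sign <- rep(NA_character_, n)
  rejected <- logical(n)
  multi <- logical(n)

  # strip label words, then tokenise on anything non-alphanumeric
  stripped <- gsub("(?i)call[ _-]*sign", " ", raw, perl = TRUE)
  stripped <- gsub("(?i)\\bCAD(?![a-z])", " ", stripped, perl = TRUE)
  token_sets <- regmatches(stripped, gregexpr("[A-Za-z]*[0-9]+", stripped))

  for (i in seq_len(n)) {
    toks <- token_sets[[i]]
    if (length(toks) == 0) next
    numeric <- grepl("^[0-9]+$", toks)
    cad_ok <- numeric & nchar(toks) <= 4 &
      suppressWarnings(as.integer(toks)) < 7000L
    if (any(cad_ok)) {
      cad[i] <- as.integer(toks[which(cad_ok)[1]])
      multi[i] <- sum(cad_ok) > 1
    }
    cs_pattern <- !numeric & grepl("^[A-Za-z]+[0-9]+$", toks)
    if (any(cs_pattern)) {
      cand <- toupper(gsub("[^A-Za-z0-9]", "", toks[cs_pattern]))
      hit <- if (is.null(registry)) rep(TRUE, length(cand)) else cand %in% registry
      if (any(hit)) {
        call_sign[i] <- cand[which(hit)[1]]
      } else {
        rejected[i] <- TRUE
      }
    }
  }

  status <- dplyr::case_when(
    !is.na(cad) & !is.na(call_sign) ~ "both",
    !is.na(cad) ~ "cad_only",
    !is.na(call_sign) ~ "callsign_only",
    TRUE ~ "none"
  )
  tibble::tibble(
    cad = cad, call_sign = call_sign, parse_status = status,
    raw = raw, callsign_rejected = rejected, multi_cad = multi
  )
}

#' Remove exact duplicate rows
#'
#' Rows identical on every column except the stable row id are collapsed to
#' their first occurrence; order is otherwise preserved.
#'
#' @param rows tibble with a `row_id` column.
#' @param id_col name of the stable id column.
#' @return list with `rows` (deduplicated) and `n_removed`.
#' @export
deduplicate <- function(rows, id_col = "row_id") {
  if (nrow(rows) == 0) return(list(rows = rows, n_removed = 0L))
  payload <- rows[, setdiff(names(rows), id_col), drop = FALSE]
  dup <- duplicated(payload)
  list(rows = rows[!dup, ], n_removed = sum(dup))
}

#' Clean an ED extract: deduplicate and parse identifiers
#'
#' Runs [deduplicate()] then [parse_identifiers()] over the extract's
#' identifier field(s) (`cad_number`/`call_sign`, or the combined
#' `cad_call_sign`), attaching the parsed columns to every row and
#' returning a cleaning report whose counts are consistent with the
#' row-level results.
#'
#' @param rows ED rows as returned by [read_extract()] or
#'   [generate_ed_extract()].
#' @param registry call-sign registry for verification (`NULL` to skip).
#' @return list with `rows` (deduplicated rows plus `cad`, `call_sign`,
#'   `parse_status`, `callsign_rejected`, `multi_cad`) and `report`, a
#'   tibble of class `edlink_cleaning_report` with `n_rows_in`,
#'   `n_duplicates_removed`, `n_parsed_cad`, `n_parsed_callsign`,
#'   `n_callsigns_rejected_by_registry`, `n_multi_cad_candidates`,
#'   `n_neither`.
#' @export
clean_extract <- function(rows, registry = NULL) {
  n_in <- nrow(rows)
  dd <- deduplicate(rows)
  rows <- dd$rows
  if (n_in == 0) {
    parsed <- parse_identifiers(character(0), registry = registry)
  } else if ("cad_call_sign" %in% names(rows)) {
    parsed <- parse_identifiers(rows$cad_call_sign, registry = registry)
  } else if ("cad_number" %in% names(rows)) {
    cs <- if ("call_sign" %in% names(rows)) rows$call_sign else NULL
    parsed <- parse_identifiers(rows$cad_number, cs, registry = registry)
  } else {
    parsed <- parse_identifiers(rep(NA_character_, nrow(rows)), registry = registry)
  }
  out <- dplyr::bind_cols(rows, parsed[, c("cad", "call_sign", "parse_status",
                                           "callsign_rejected", "multi_cad")],
                          .name_repair = "minimal")
  # an extract with separate fields already has a call_sign column: keep the
  # parsed (verified) one under the canonical name
  if (sum(names(out) == "call_sign") == 2) {
    first <- which(names(out) == "call_sign")[1]
    names(out)[first] <- "call_sign_raw"
  }
  report <- tibble::tibble(
    n_rows_in = n_in,
    n_duplicates_removed = dd$n_removed,
    n_parsed_cad = sum(!is.na(parsed$cad)),
    n_parsed_callsign = sum(!is.na(parsed$call_sign)),
    n_callsigns_rejected_by_registry = sum(parsed$callsign_rejected),
    n_multi_cad_candidates = sum(parsed$multi_cad),
    n_neither = sum(parsed$parse_status == "none")
  )
  class(report) <- c("edlink_cleaning_report", class(report))
  list(rows = out, report = report)
}
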