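#' Transfer-format specification for an ED extract
#'
#' The project transfer specification fixes, for each trust, the exact file
#' layout an extract must follow: column titles and order, the "XXXX"
#' sentinel for absent data, the date/time convention, and the delimiter.
#' Exact adherence is required; [validate_extract()] reports every
#' deviation.
#'
#' @param columns ordered character vector of expected column titles
#'   (including the leading `row_id`).
#' @param missing_sentinel literal written for an absent datum. Default
#'   `"XXXX"`.
#' @param datetime_dialect `"iso8601"` (`2014-05-02T10:30:00`) or `"dmy_hm"`
#'   (`02/05/2014 10:30`), applied to all `*_datetime` columns.
#' @param delimiter single field-separator character.
#' @param filename_pattern template with `{trust}` and `{extract_date}`
#'   slots, used when naming extract files.
#' @return an object of class `edlink_format_spec`.
#' @export
ed_format_spec <- function(columns = c("row_id", ed_variables()),
                           missing_sentinel = "XXXX",
                           datetime_dialect = c("iso8601", "dmy_hm"),
                           delimiter = ",",
                           filename_pattern = "{trust}_{extract_date}.csv") {
  datetime_dialect <- match.arg(datetime_dialect)
  if (anyDuplicated(columns)) stop("column titles must be unique", call. = FALSE)
  if (!nzchar(missing_sentinel)) stop("missing sentinel must be non-empty", call. = FALSE)
  if (nchar(delimiter) != 1) stop("delimiter must be one character", call. = FALSE)
  structure(
    list(
      columns = columns,
      missing_sentinel = missing_sentinel,
      datetime_dialect = datetime_dialect,
      delimiter = delimiter,
      filename_pattern = filename_pattern
    ),
    class = "edlink_format_spec"
  )
}

#' Format spec matching one trust's extract columns
#'
#' Builds the expected column list from the trust's available variables,
#' substituting the single `cad_call_sign` column for trusts that record
#' both identifiers in one free-text field and dropping `call_sign` for
#' CAD-only trusts.
#'
#' @param profile a [trust_profile()].
#' @param ... passed to [ed_format_spec()].
#' @return an `edlink_format_spec`.
#' @export
ed_format_spec_for <- function(profile, ...) {
  stopifnot(inherits(profile, "edlink_trust_profile"))
  cols <- intersect(ed_variables(), profile$available_variables)
  if (profile$identifier_mode == "combined_freetext") {
    cols <- setdiff(cols, c("cad_number", "call_sign"))
    cols <- c(cols, "cad_call_sign")
  } else if (profile$identifier_mode == "cad_only") {
    cols <- setdiff(cols, "call_sign")
  }
  ed_format_spec(columns = c("row_id", cols), ...)
}

datetime_format <- function(dialect) {
  switch(dialect,
    iso8601 = "%Y-%m-%dT%H:%M:%S",
    dmy_hm = "%d/%m/%Y %H:%M",
    stop(sprintf("unknown datetime dialect '%s'", dialect), call. = FALSE)
  )
}

datetime_columns <- function(columns) {
  grep("_datetime$", columns, value = TRUE)
}

new_violation <- function(rule, column, row, detail) {
  tibble::tibble(rule = rule, column = column, row = row, detail = detail)
}

#' Validate an extract file against the transfer specification
#'
#' Checks delimiter, column titles and order, the missing-data sentinel and
#' the date/time convention, reporting every violation with its locus.
#' Common real-world extract errors — "NULL" instead of "XXXX", renamed
#' fields, re-ordered columns — each trigger exactly one rule. The file is
#' never modified; the same file and spec always give the same report.
#'
#' @param path extract file.
#' @param spec an [ed_format_spec()].
#' @return an object of class `edlink_validation_report`: list with
#'   `file_ok`, `violations` (tibble `rule`, `column`, `row`, `detail`;
#'   `row` is the 1-based data row, `NA` for file-level rules), `counts`
#'   (violations per rule) and `path`.
#' @export
validate_extract <- function(path, spec) {
  stopifnot(inherits(spec, "edlink_format_spec"))
  if (!file.exists(path) || dir.exists(path)) {
    stop(errorCondition(sprintf("cannot read extract file '%s'", path),
                        class = c("edlink_io_error", "error")))
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0 || !nzchar(first)) {
    stop(errorCondition(sprintf("extract file '%s' is empty", path),
                        class = c("edlink_io_error", "error")))
  }

  violations <- list()
  add <- function(v) violations[[length(violations) + 1L]] <<- v

  # delimiter: the header must split into >1 field under the spec delimiter
  # (single-column specs aside); a header splitting only under ; or tab is
  # reported as a delimiter violation
  header_fields <- scan(text = first, what = character(), sep = spec$delimiter,
                        quiet = TRUE, strip.white = FALSE)
  if (length(spec$columns) > 1 && length(header_fields) == 1) {
    alt <- c(";", "\t", "|")
    found <- alt[vapply(alt, function(d) {
      length(scan(text = first, what = character(), sep = d, quiet = TRUE)) > 1
    }, logical(1))]
    add(new_violation("delimiter", NA_character_, NA_integer_,
                      sprintf("header does not split under '%s'%s", spec$delimiter,
                              if (length(found)) sprintf(" (splits under '%s')", found[1]) else "")))
    return(finish_report(violations, path))
  }

  missing_cols <- setdiff(spec$columns, header_fields)
  unexpected <- setdiff(header_fields, spec$columns)
  for (m in missing_cols) {
    add(new_violation("column_title", m, NA_integer_,
                      sprintf("expected column '%s' not found in header", m)))
  }
  for (u in unexpected) {
    add(new_violation("column_title", u, NA_integer_,
                      sprintf("unexpected column '%s' in header", u)))
  }
  if (length(missing_cols) == 0 && length(unexpected) == 0 &&
      !identical(header_fields, spec$columns)) {
    off <- which(header_fields != spec$columns)
    add(new_violation("column_order", paste(header_fields[off], collapse = ", "),
                      NA_integer_,
                      sprintf("columns out of order: found [%s] where [%s] expected",
                              paste(header_fields[off], collapse = ", "),
                              paste(spec$columns[off], collapse = ", "))))
  }

  cells <- readr::read_delim(
    path, delim = spec$delimiter, col_types = readr::cols(.default = "c"),
    na = character(), show_col_types = FALSE, progress = FALSE
  )

  # wrong missing-data marker, per offending cell
  bad_markers <- c("NULL", "null", "Null", "NA", "N/A", "")
  for (col in names(cells)) {
    bad <- which(!is.na(cells[[col]]) & cells[[col]] %in% bad_markers)
    for (r in bad) {
      add(new_violation("missing_sentinel", col, r,
                        sprintf("'%s' used instead of '%s'", cells[[col]][r],
                                spec$missing_sentinel)))
    }
  }

  # date/time convention, per unparseable non-sentinel cell
  fmt <- datetime_format(spec$datetime_dialect)
  for (col in intersect(datetime_columns(spec$columns), names(cells))) {
    x <- cells[[col]]
    check <- which(!is.na(x) & x != spec$missing_sentinel & !x %in% bad_markers)
    parsed <- as.POSIXct(x[check], format = fmt, tz = "UTC")
    for (r in check[is.na(parsed)]) {
      add(new_violation("datetime_convention", col, r,
                        sprintf("'%s' does not follow the %s convention",
                                x[r], spec$datetime_dialect)))
    }
  }

  finish_report(violations, path)
}

finish_report <- function(violations, path) {
  v <- if (length(violations)) dplyr::bind_rows(violations) else
    new_violation(character(), character(), integer(), character())
  structure(
    list(
      file_ok = nrow(v) == 0,
      violations = v,
      counts = dplyr::count(v, .data$rule, name = "n"),
      path = path
    ),
    class = "edlink_validation_report"
  )
}

#' @export
print.edlink_validation_report <- function(x, ...) {
  cat(sprintf("Extract validation: %s\n", x$path))
  if (x$file_ok) {
    cat("  conformant: no violations\n")
  } else {
    cat(sprintf("  %d violation(s):\n", nrow(x$violations)))
    print(x$counts)
  }
  invisible(x)
}

#' Read an ED extract under the transfer specification
#'
#' Maps the missing-data sentinel to `NA`, parses `*_datetime` columns under
#' the spec dialect and `age` to integer, and preserves row order. In strict
#' mode any validation violation rejects the file; otherwise the rows are
#' returned best-effort with one warning per violation.
#'
#' @param path extract file.
#' @param spec an [ed_format_spec()].
#' @param strict reject on any violation?
#' @return tibble of ED rows. The validation report is attached as attribute
#'   `validation`.
#' @export
read_extract <- function(path, spec, strict = FALSE) {
  report <- validate_extract(path, spec)
  if (strict && !report$file_ok) {
    cond <- errorCondition(
      sprintf("extract '%s' rejected: %d violation(s) of the transfer specification",
              path, nrow(report$violations)),
      class = c("edlink_validation_error", "error")
    )
    cond$report <- report
    stop(cond)
  }
  if (!report$file_ok) {
    purrr::pwalk(report$violations, function(rule, column, row, detail) {
      warning(sprintf("[%s] %s", rule, detail), call. = FALSE)
    })
  }
  cells <- readr::read_delim(
    path, delim = spec$delimiter, col_types = readr::cols(.default = "c"),
    na = character(), show_col_types = FALSE, progress = FALSE
  )
  for (col in names(cells)) {
    cells[[col]][is_missing_value(cells[[col]], spec$missing_sentinel)] <- NA_character_
  }
  fmt <- datetime_format(spec$datetime_dialect)
  for (col in intersect(datetime_columns(names(cells)), names(cells))) {
    cells[[col]] <- as.POSIXct(cells[[col]], format = fmt, tz = "UTC")
  }
  if ("age" %in% names(cells)) {
    cells$age <- suppressWarnings(as.integer(cells$age))
  }
  attr(cells, "validation") <- report
  cells
}

#' Write ED rows as a specification-conformant extract
#'
#' Serialises absent values as the missing sentinel and datetimes under the
#' spec dialect. `read_extract(write_extract(rows))` round-trips losslessly.
#'
#' @param rows tibble carrying every spec column.
#' @param spec an [ed_format_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_extract <- function(rows, spec, path) {
  stopifnot(inherits(spec, "edlink_format_spec"))
  absent <- setdiff(spec$columns, names(rows))
  if (length(absent)) {
    stop(sprintf("rows are missing spec column(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  out <- rows[, spec$columns]
  fmt <- datetime_format(spec$datetime_dialect)
  for (col in names(out)) {
    if (inherits(out[[col]], "POSIXct")) {
      out[[col]] <- format(out[[col]], fmt, tz = "UTC")
    } else if (!is.character(out[[col]])) {
      out[[col]] <- as.character(out[[col]])
    }
    out[[col]][is.na(out[[col]])] <- spec$missing_sentinel
  }
  readr::write_delim(out, path, delim = spec$delimiter, na = spec$missing_sentinel)
  invisible(path)
}

#' Corrupt an extract file for validator fault-injection
#'
#' Reproduces the extract errors seen in practice so that validator coverage
#' can be exercised: renaming a header field, swapping two columns, or
#' rewriting sentinel cells as "NULL".
#'
#' @param path conformant extract file (modified in place).
#' @param type `"rename_column"`, `"swap_columns"` or `"null_sentinel"`.
#' @param columns for `rename_column` one column; for `swap_columns` two.
#' @param sentinel the sentinel being replaced when `type = "null_sentinel"`.
#' @return `path`, invisibly.
#' @export
corrupt_extract_file <- function(path, type = c("rename_column", "swap_columns",
                                                "null_sentinel"),
                                 columns = NULL, sentinel = "XXXX") {
  type <- match.arg(type)
  lines <- readLines(path, warn = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (type == "rename_column") {
    i <- match(columns[1], header)
    if (is.na(i)) stop("column not present", call. = FALSE)
    header[i] <- paste0(header[i], "_v2")
    lines[1] <- paste(header, collapse = ",")
  } else if (type == "swap_columns") {
    i <- match(columns, header)
    if (anyNA(i) || length(i) != 2) stop("need two present columns", call. = FALSE)
    header[i] <- header[rev(i)]
    lines[1] <- paste(header, collapse = ",")
  } else {
    lines[-1] <- gsub(sentinel, "NULL", lines[-1], fixed = TRUE)
  }
  writeLines(lines, path)
  invisible(path)
}
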