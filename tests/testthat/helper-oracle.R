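# Independent naive all-pairs linker: applies the linkage rules by direct
# scans over the full ambulance table, with no index and no shared code with
# link_all(). Used as the brute-force oracle on small instances.
naive_link_all <- function(rows, ambulance, cfg = link_config()) {
  amb_cad <- ambulance$cad_number
  amb_date <- ambulance$incident_date
  amb_cs <- ambulance$call_sign
  amb_site <- ambulance$destination_site
  amb_arr <- as.numeric(ambulance$ed_arrival)

  naive_cad <- function(cad, adate, site) {
    for (d in c(adate, if (cfg$allow_consecutive_dates) adate - 1)) {
      cand <- which(amb_cad == cad & amb_date == d)
      if (length(cand) > 1) next      # duplicated key: excluded from CAD matching
      if (length(cand) == 1) {
        if (cfg$cmp_site_cad == "require" && amb_site[cand] != site) {
          return(NA_integer_)          # site rejection is terminal
        }
        return(cand)
      }
    }
    NA_integer_
  }

  naive_callsign <- function(cs, adate, site, arr) {
    dates <- c(adate, if (cfg$allow_consecutive_dates) adate - 1)
    cand <- which(amb_cs == cs & amb_date %in% dates)
    if (cfg$require_site_agreement_callsign) cand <- cand[amb_site[cand] == site]
    if (length(cand) == 0) return(NA_integer_)
    gap <- abs(amb_arr[cand] - as.numeric(arr)) / 60
    keep <- gap <= cfg$time_tolerance_minutes
    cand <- cand[keep]; gap <- gap[keep]
    if (length(cand) == 0) return(NA_integer_)
    nearest <- which(gap == min(gap))
    if (length(nearest) > 1) return(NA_integer_)   # ambiguous tie
    cand[nearest]
  }

  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    arr <- rows$ed_arrival_datetime[i]
    adate <- as.Date(arr, tz = "UTC")
    site <- rows$hospital_site[i]
    amb_id <- NA_character_
    method <- "unmatched"
    if (rows$parse_status[i] == "none") {
      method <- "no_identifier"
    } else {
      j <- if (!is.na(rows$cad[i])) naive_cad(rows$cad[i], adate, site) else NA_integer_
      if (!is.na(j)) {
        amb_id <- ambulance$amb_id[j]
        method <- "cad_date"
      } else if (!is.na(rows$call_sign[i])) {
        j <- naive_callsign(rows$call_sign[i], adate, site, arr)
        if (!is.na(j)) {
          amb_id <- ambulance$amb_id[j]
          method <- "callsign_datetime"
        }
      }
    }
    out[[i]] <- data.frame(ed_row_id = rows$row_id[i], amb_id = amb_id,
                           method = method, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
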