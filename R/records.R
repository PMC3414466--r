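#' Read and write seamount assessment records
#'
#' Records travel as a long table, one row per observation:
#' `seamount, domain (indicator|threat), item, status (present|absent|DD),
#' quality (H|M|L, empty for data-deficient rows)`. The same content is
#' accepted as JSON: an array of objects
#' `{"seamount": ..., "indicators": {item: {"status":..., "quality":...}},
#' "threats": {...}}`.
#'
#' @param path file path; `.json` is read/written as JSON, anything else as
#'   CSV.
#' @return `read_seamount_records()` returns the long record tibble;
#'   `write_seamount_records()` returns `path` invisibly.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write_seamount_records(case_study_seamounts(), tmp)
#' identical(read_seamount_records(tmp), case_study_seamounts())
#' @export
read_seamount_records <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    out <- purrr::map_dfr(raw, function(rec) {
      one <- function(domain, obs) {
        purrr::imap_dfr(obs, function(o, item) {
          tibble::tibble(
            seamount = rec$seamount, domain = domain, item = item,
            status = o$status,
            quality = if (is.null(o$quality)) NA_character_ else o$quality
          )
        })
      }
      dplyr::bind_rows(one("indicator", rec$indicators),
                       one("threat", rec$threats))
    })
  } else {
    out <- readr::read_csv(path, col_types = readr::cols(
      seamount = readr::col_character(), domain = readr::col_character(),
      item = readr::col_character(), status = readr::col_character(),
      quality = readr::col_character()
    ))
    out <- tibble::as_tibble(out)
  }
  check_records_frame(out)
  out
}

#' @rdname read_seamount_records
#' @param data long record tibble (as returned by
#'   [case_study_seamounts()] or [read_seamount_records()]).
#' @export
write_seamount_records <- function(data, path) {
  check_records_frame(data)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- lapply(split(data, factor(data$seamount, unique(data$seamount))),
                   function(d) {
      obs_list <- function(dd) {
        out <- lapply(seq_len(nrow(dd)), function(i) {
          o <- list(status = dd$status[i])
          if (!is.na(dd$quality[i])) o$quality <- dd$quality[i]
          o
        })
        stats::setNames(out, dd$item)
      }
      list(seamount = d$seamount[1],
           indicators = obs_list(d[d$domain == "indicator", ]),
           threats = obs_list(d[d$domain == "threat", ]))
    })
    jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    readr::write_csv(data, path, na = "")
  }
  invisible(path)
}

#' Validate seamount records against the catalogs
#'
#' Structural checks: every indicator slot and every activity must be
#' accounted for (possibly as data-deficient), OR-pairs must have at most
#' one member recorded, quality grades belong only on scored
#' (present/absent) observations, and item ids must exist in the catalogs.
#' A seamount recorded as natural (naturalness present) while some fishing
#' or mining activity is present is internally inconsistent but occurs in
#' published assessments, so it is flagged as a warning, not an error.
#'
#' @param data long record tibble.
#' @param indicators indicator catalog, see [ebsa_indicators()].
#' @param threats threat catalog, see [ebsa_threats()].
#' @return A tibble of issues with columns `seamount`, `severity`
#'   (`"error"`/`"warning"`), `message`; zero rows when the records are
#'   clean.
#' @examples
#' validate_records(case_study_seamounts())   # 1 warning (Sedlo), 0 errors
#' @export
validate_records <- function(data, indicators = ebsa_indicators(),
                             threats = ebsa_threats()) {
  check_records_frame(data)
  slots <- indicator_slots(indicators)
  issues <- list()
  add <- function(seamount, severity, message) {
    issues[[length(issues) + 1]] <<-
      tibble::tibble(seamount = seamount, severity = severity, message = message)
  }

  for (sm in unique(data$seamount)) {
    d <- data[data$seamount == sm, ]
    ind <- d[d$domain == "indicator", ]
    thr <- d[d$domain == "threat", ]

    bad_ind <- setdiff(ind$item, indicators$item)
    for (b in bad_ind) add(sm, "error", sprintf("unknown indicator id '%s'", b))
    bad_thr <- setdiff(thr$item, threats$item)
    for (b in bad_thr) add(sm, "error", sprintf("unknown threat id '%s'", b))

    ind <- ind[ind$item %in% indicators$item, ]
    slot_of <- stats::setNames(
      ifelse(is.na(indicators$pair), indicators$item, indicators$pair),
      indicators$item
    )
    ind_slot <- slot_of[ind$item]
    for (s in setdiff(slots, ind_slot)) {
      add(sm, "error", sprintf("missing indicator slot '%s'", s))
    }
    dup <- unique(ind_slot[duplicated(ind_slot)])
    for (s in dup) {
      pair_members <- indicators$item[!is.na(indicators$pair) & indicators$pair == s]
      if (length(pair_members) > 0) {
        add(sm, "error",
            sprintf("both members of OR-pair '%s' are recorded; score only one", s))
      } else {
        add(sm, "error", sprintf("duplicate rows for indicator '%s'", s))
      }
    }
    for (t in setdiff(threats$item, thr$item)) {
      add(sm, "error", sprintf("missing threat '%s'", t))
    }
    for (t in unique(thr$item[duplicated(thr$item)])) {
      add(sm, "error", sprintf("duplicate rows for threat '%s'", t))
    }

    scored <- d$status %in% c("present", "absent")
    bad_grade <- d[!scored & !is.na(d$quality), ]
    for (i in seq_len(nrow(bad_grade))) {
      add(sm, "error",
          sprintf("'%s' is data-deficient but carries quality grade '%s'",
                  bad_grade$item[i], bad_grade$quality[i]))
    }
    no_grade <- d[scored & is.na(d$quality), ]
    for (i in seq_len(nrow(no_grade))) {
      add(sm, "error",
          sprintf("scored observation '%s' lacks a quality grade",
                  no_grade$item[i]))
    }

    nat <- ind[ind$item == "naturalness" & ind$status == "present", ]
    if (nrow(nat) > 0 && any(thr$status == "present")) {
      add(sm, "warning",
          paste("naturalness is present although at least one fishing or",
                "mining activity is present"))
    }
  }

  if (length(issues) == 0) {
    return(tibble::tibble(seamount = character(), severity = character(),
                          message = character()))
  }
  dplyr::bind_rows(issues)
}

stop_on_invalid <- function(data, ...) {
  rep <- validate_records(data, ...)
  errs <- rep[rep$severity == "error", ]
  if (nrow(errs) > 0) {
    rlang::abort(
      paste0("invalid seamount record(s):\n",
             paste(sprintf("- [%s] %s", errs$seamount, errs$message),
                   collapse = "\n")),
      class = "seamountEBSA_invalid_record"
    )
  }
  invisible(data)
}
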