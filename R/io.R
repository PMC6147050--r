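#' Read long-format scan-sampling data
#'
#' Reads a denormalized events CSV with header
#' `individual_id,sex,birth_date,group_id,litter_id,scan_id,scan_date,event_index,behaviour`
#' (dates ISO-8601) and returns typed tables: one row per sampling event, one
#' per individual, one per scan session. Behaviour labels must come from
#' [behaviour_categories()] unless an ethogram `mapping` is supplied, in which
#' case raw labels are collapsed on read.
#'
#' Scan-session metadata that cannot be recovered from the events file itself
#' (group size at the scan, pup presence) is read from `scans_path` when
#' given; otherwise `group_size` is left as the number of observed
#' (nonbreeding) individuals and `pups_present` as `NA`.
#'
#' @param path events CSV file.
#' @param scans_path optional scan-session CSV with header
#'   `scan_id,group_id,date,group_size,pups_present`.
#' @param mapping optional ethogram mapping for [collapse_ethogram()].
#' @return list with tibbles `events` (individual_id, scan_id, event_index,
#'   behaviour), `individuals` (individual_id, sex, birth_date, group_id,
#'   litter_id, is_breeder) and `scans` (scan_id, group_id, date, group_size,
#'   pups_present).
#' @export
read_events <- function(path, scans_path = NULL, mapping = NULL) {
  cols <- c("individual_id", "sex", "birth_date", "group_id", "litter_id",
            "scan_id", "scan_date", "event_index", "behaviour")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(event_index = "integer"))
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0)
    stop("events file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.null(mapping)) df$behaviour <- collapse_ethogram(df$behaviour, mapping)

  bad <- which(!df$behaviour %in% behaviour_categories())
  if (length(bad) > 0)
    stop("unknown behaviour label '", df$behaviour[bad[1]], "' at row ",
         bad[1], " of ", path)
  if (!all(df$sex %in% c("F", "M")))
    stop("sex must be 'F' or 'M' in ", path)
  key <- paste(df$individual_id, df$scan_id, df$event_index)
  if (anyDuplicated(key))
    stop("duplicate (individual_id, scan_id, event_index) at row ",
         which(duplicated(key))[1], " of ", path)

  events <- tibble::tibble(
    individual_id = as.character(df$individual_id),
    scan_id = as.character(df$scan_id),
    event_index = df$event_index,
    behaviour = df$behaviour
  )
  individuals <- dplyr::distinct(tibble::tibble(
    individual_id = as.character(df$individual_id),
    sex = df$sex,
    birth_date = as.Date(df$birth_date),
    group_id = as.character(df$group_id),
    litter_id = as.character(df$litter_id),
    is_breeder = FALSE
  ))
  if (anyDuplicated(individuals$individual_id))
    stop("inconsistent individual metadata (same id, different attributes) in ",
         path)

  if (!is.null(scans_path)) {
    scans <- read_scans(scans_path)
  } else {
    obs <- dplyr::distinct(df[, c("scan_id", "group_id", "scan_date",
                                  "individual_id")])
    scans <- dplyr::summarise(
      dplyr::group_by(tibble::as_tibble(obs), .data$scan_id, .data$group_id,
                      .data$scan_date),
      group_size = dplyr::n_distinct(.data$individual_id), .groups = "drop")
    scans <- tibble::tibble(
      scan_id = as.character(scans$scan_id),
      group_id = as.character(scans$group_id),
      date = as.Date(scans$scan_date),
      group_size = as.integer(scans$group_size),
      pups_present = NA
    )
  }
  list(events = events, individuals = individuals, scans = scans)
}

#' @rdname read_events
#' @param events,individuals,scans tables as returned by [read_events()] or
#'   the synthetic-data generator.
#' @export
write_events <- function(events, individuals, scans, path) {
  df <- dplyr::left_join(events, individuals, by = "individual_id")
  df <- dplyr::left_join(df, scans[, c("scan_id", "date")], by = "scan_id")
  out <- data.frame(
    individual_id = df$individual_id,
    sex = df$sex,
    birth_date = format(df$birth_date),
    group_id = df$group_id,
    litter_id = df$litter_id,
    scan_id = df$scan_id,
    scan_date = format(df$date),
    event_index = df$event_index,
    behaviour = df$behaviour
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write scan-session metadata
#' @param path CSV with header `scan_id,group_id,date,group_size,pups_present`.
#' @return tibble of scan sessions.
#' @export
read_scans <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(
    scan_id = as.character(df$scan_id),
    group_id = as.character(df$group_id),
    date = as.Date(df$date),
    group_size = as.integer(df$group_size),
    pups_present = as.logical(df$pups_present)
  )
}

#' @rdname read_scans
#' @param scans tibble of scan sessions.
#' @export
write_scans <- function(scans, path) {
  out <- data.frame(scan_id = scans$scan_id, group_id = scans$group_id,
                    date = format(scans$date), group_size = scans$group_size,
                    pups_present = scans$pups_present)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write body-mass records
#' @param path CSV with header `individual_id,date,mass_g`.
#' @return tibble with columns individual_id, date, mass_g.
#' @export
read_masses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("individual_id", "date", "mass_g") %in% names(df)))
    stop("mass file must have columns individual_id,date,mass_g: ", path)
  if (any(df$mass_g <= 0)) stop("non-positive mass in ", path)
  tibble::tibble(individual_id = as.character(df$individual_id),
                 date = as.Date(df$date), mass_g = as.numeric(df$mass_g))
}

#' @rdname read_masses
#' @param masses tibble of mass records.
#' @export
write_masses <- function(masses, path) {
  out <- data.frame(individual_id = masses$individual_id,
                    date = format(masses$date), mass_g = masses$mass_g)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pup presence at a scan session
#'
#' A scan session counts as having pups present when any group member
#' (including unweaned animals not in the analysis dataset) is under
#' `pup_age_days` days old on the scan date.
#'
#' @param scans scan-session tibble (scan_id, group_id, date).
#' @param members tibble of all group members with individual_id, group_id,
#'   birth_date.
#' @param pup_age_days age threshold in days defining a pup (default 40).
#' @return logical vector aligned with rows of `scans`.
#' @export
derive_pups_present <- function(scans, members, pup_age_days = 40) {
  vapply(seq_len(nrow(scans)), function(i) {
    m <- members[members$group_id == scans$group_id[i], ]
    if (nrow(m) == 0) return(FALSE)
    age <- as.numeric(scans$date[i] - m$birth_date)
    any(age >= 0 & age < pup_age_days)
  }, logical(1))
}
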