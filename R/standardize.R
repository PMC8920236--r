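env_columns <- c(
  "Source", "Station", "Latitude", "Longitude", "Year", "Date", "Datetime",
  "SampleID", "Tide", "BottomDepth", "Chl", "Secchi", "Temperature",
  "Turbidity", "Microcystis", "pH", "DO", "SalSurf", "SalBott",
  "SizeClass", "Volume"
)
catch_columns <- c("SampleID", "Taxname", "Lifestage", "Taxlifestage",
                   "CPUE", "Undersampled")
sample_level_columns <- setdiff(env_columns, "SampleID")

#' Construct the unique sample identifier
#'
#' `"{Source} {Station} {Datetime} {SizeClass}"` — unique across surveys and
#' human-auditable (the source data do not prescribe a construction).
#'
#' @param source,station,datetime,size_class Character vectors.
#' @return Character vector of sample IDs.
#' @export
make_sample_id <- function(source, station, datetime, size_class) {
  paste(source, station, datetime, size_class)
}

#' Read one survey's table into the standard long format
#'
#' Applies the reformatting pipeline of the integration: rename columns to
#' the standard names, pivot wide tables (one column per taxon) to long
#' (one row per sample x taxon/lifestage), replace species codes with
#' scientific names, and convert units to the standard (m^3, degrees C,
#' cm, individuals per m^3).
#'
#' @param path CSV path, or a data frame already in memory.
#' @param config Survey descriptor, a list with elements:
#'   \describe{
#'     \item{name}{Survey name, written to `Source`.}
#'     \item{size_class}{`"Micro"`, `"Meso"` or `"Macro"` (may instead be a
#'       mapped column).}
#'     \item{format}{`"long"` (default) or `"wide"`.}
#'     \item{columns}{Named character vector: standard name -> source column
#'       (sample-level fields plus, for long tables, `Taxname`/`Code`,
#'       `Lifestage`, `CPUE`).}
#'     \item{species_codes}{Optional data frame `Code`, `Taxname`,
#'       `Lifestage` used when the survey reports codes; for wide tables the
#'       taxon column names are treated as codes.}
#'     \item{units}{Optional named numeric vector of multiplicative factors
#'       applied to standard columns after renaming (e.g. `c(CPUE = 1000)`
#'       for counts reported per litre, `c(Secchi = 100)` for metres).}
#'   }
#' @return Tibble of long records with the standard sample-level columns plus
#'   `Taxname`, `Lifestage`, `Taxlifestage`, `CPUE`.
#' @export
read_survey <- function(path, config) {
  raw <- if (is.data.frame(path)) tibble::as_tibble(path) else read_zoop_csv(path)
  stopifnot(is.list(config), !is.null(config$name))
  fmt <- config$format %||% "long"
  cols <- config$columns %||% character()

  present <- intersect(unname(cols), names(raw))
  if (length(present) < length(cols)) {
    stop("survey '", config$name, "': source column(s) not found: ",
         paste(setdiff(unname(cols), names(raw)), collapse = ", "), call. = FALSE)
  }
  mapped <- raw
  names(mapped)[match(unname(cols), names(mapped))] <- names(cols)

  if (fmt == "wide") {
    sample_cols <- intersect(names(mapped), c(sample_level_columns, "Code"))
    taxon_cols <- setdiff(names(mapped), sample_cols)
    if (length(taxon_cols) == 0) {
      stop("survey '", config$name, "': wide table has no taxon columns",
           call. = FALSE)
    }
    # an empty wide cell is "no record for this category", not a measured NA
    mapped <- tidyr::pivot_longer(mapped, dplyr::all_of(taxon_cols),
                                  names_to = "Code", values_to = "CPUE",
                                  values_drop_na = TRUE)
  }

  if (!is.null(config$species_codes)) {
    codes <- tibble::as_tibble(config$species_codes)
    if (!"Code" %in% names(mapped)) {
      stop("survey '", config$name, "': species_codes given but no Code column",
           call. = FALSE)
    }
    i <- match(mapped$Code, codes$Code)
    if (anyNA(i)) {
      stop("survey '", config$name, "': unmapped species code(s): ",
           paste(sort(unique(mapped$Code[is.na(i)])), collapse = ", "),
           call. = FALSE)
    }
    mapped$Taxname <- codes$Taxname[i]
    mapped$Lifestage <- codes$Lifestage[i]
    mapped$Code <- NULL
  }

  for (req in c("Station", "Taxname", "CPUE")) {
    if (!req %in% names(mapped)) {
      stop("survey '", config$name, "': no mapping produced required column ",
           req, call. = FALSE)
    }
  }
  bad <- which(is.na(mapped$Station))
  if (length(bad) > 0) {
    stop("survey '", config$name, "': malformed row(s) missing Station at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  }

  units <- config$units %||% numeric()
  for (nm in names(units)) {
    if (nm %in% names(mapped)) mapped[[nm]] <- mapped[[nm]] * units[[nm]]
  }

  mapped$Source <- config$name
  if (!"SizeClass" %in% names(mapped)) mapped$SizeClass <- config$size_class
  if (!"Lifestage" %in% names(mapped)) mapped$Lifestage <- "Adult"
  if (!"Datetime" %in% names(mapped)) {
    if (!"Date" %in% names(mapped)) {
      stop("survey '", config$name, "': need a Date or Datetime mapping",
           call. = FALSE)
    }
    mapped$Datetime <- paste(mapped$Date, "00:00:00")
  }
  if (!"Date" %in% names(mapped)) {
    mapped$Date <- substr(mapped$Datetime, 1, 10)
  }
  mapped$Year <- as.integer(substr(mapped$Date, 1, 4))
  mapped$Taxlifestage <- paste(mapped$Taxname, mapped$Lifestage)
  if (!"Undersampled" %in% names(mapped)) mapped$Undersampled <- FALSE

  keep <- intersect(c(sample_level_columns, "Taxname", "Lifestage",
                      "Taxlifestage", "CPUE", "Undersampled"), names(mapped))
  mapped[, keep]
}

#' Replace pre-counting zeros with missing values
#'
#' Source surveys sometimes recorded CPUE = 0 in years before a category was
#' added to their counting list; the true abundance in those years is
#' unknown, so such zeros are recoded `NA`. Non-native taxa are the
#' exception: before their known introduction year the abundance really was
#' zero, and the 0 is kept. Nonzero values are never altered.
#'
#' @param records Long records with `Source`, `SizeClass`, `Year`, `Taxname`,
#'   `Lifestage`, `CPUE`.
#' @param lists A `zoop_taxa_lists` table.
#' @return `records` with the affected zeros recoded to `NA`.
#' @export
zeros_to_na <- function(records, lists) {
  if (!inherits(lists, "zoop_taxa_lists")) lists <- taxa_lists(lists)
  key_rec <- paste(records$Source, records$SizeClass, records$Taxname,
                   records$Lifestage)
  key_list <- paste(lists$Survey, lists$SizeClass, lists$Taxname,
                    lists$Lifestage)
  i <- match(key_rec, key_list)
  unknown <- is.na(i)
  if (any(unknown)) {
    warning("record(s) for categories absent from the taxa lists (kept as-is): ",
            paste(sort(unique(key_rec[unknown])), collapse = "; "),
            call. = FALSE)
  }
  counted <- rep(FALSE, nrow(records))
  idx <- which(!unknown)
  counted[idx] <- entry_counts_in_year(lists[i[idx], ], records$Year[idx])
  intro <- rep(NA_real_, nrow(records))
  intro[idx] <- lists$IntroYear[i[idx]]
  pre_intro <- !is.na(intro) & records$Year < intro
  recode <- !unknown & !counted & !pre_intro &
    !is.na(records$CPUE) & records$CPUE == 0
  records$CPUE[recode] <- NA_real_
  records
}

#' Bind survey records and split into environment and zooplankton tables
#'
#' Assigns `SampleID`, then splits the bound long table into sample-level
#' data (one row per sample, all environmental fields; fields unmeasured by
#' a survey are `NA`) and catch data (one row per sample x taxon/lifestage),
#' each keyed by `SampleID` so a join reconstructs the input.
#'
#' @param records Long records from [read_survey()] (one or several surveys,
#'   row-bound).
#' @return List with tibbles `environment` and `zooplankton`.
#' @export
bind_and_split <- function(records) {
  records <- tibble::as_tibble(records)
  for (col in sample_level_columns) {
    if (!col %in% names(records)) records[[col]] <- NA
  }
  if (nrow(records) == 0) {
    return(list(
      environment = tibble::as_tibble(
        stats::setNames(rep(list(logical(0)), length(env_columns)), env_columns)),
      zooplankton = tibble::as_tibble(
        stats::setNames(rep(list(logical(0)), length(catch_columns)), catch_columns))
    ))
  }
  records$SampleID <- make_sample_id(records$Source, records$Station,
                                     records$Datetime, records$SizeClass)
  env <- dplyr::distinct(records[, env_columns])
  if (anyDuplicated(env$SampleID)) {
    stop("SampleID collision: distinct samples map to ",
         env$SampleID[duplicated(env$SampleID)][1], call. = FALSE)
  }
  catch <- records[, catch_columns]
  key <- paste(catch$SampleID, catch$Taxlifestage)
  if (anyDuplicated(key)) {
    stop("duplicate catch record: ", key[duplicated(key)][1], call. = FALSE)
  }
  list(environment = env[, env_columns], zooplankton = catch)
}

#' Sampling effort per survey
#'
#' Effort is the mean number of sampling events (distinct station visits)
#' per station for each month of each year, averaged over the stations
#' sampled that month, then averaged to the requested timestep. Stations and
#' months with no sampling do not enter the means.
#'
#' @param env Environment table with `Source`, `Station`, `Date`, `Datetime`.
#' @param timestep `"year"` or `"month"`.
#' @return Tibble `Source`, `Year` (or `Month`), `Effort`.
#' @export
sampling_effort <- function(env, timestep = c("year", "month")) {
  timestep <- match.arg(timestep)
  ev <- dplyr::distinct(tibble::as_tibble(env)[, c("Source", "Station", "Datetime", "Date")])
  ev$Year <- as.integer(substr(ev$Date, 1, 4))
  ev$Month <- as.integer(substr(ev$Date, 6, 7))
  per_station <- dplyr::count(ev, .data$Source, .data$Station, .data$Year,
                              .data$Month, name = "n")
  per_month <- dplyr::summarise(
    dplyr::group_by(per_station, .data$Source, .data$Year, .data$Month),
    Effort = mean(.data$n), .groups = "drop")
  if (timestep == "year") {
    dplyr::summarise(dplyr::group_by(per_month, .data$Source, .data$Year),
                     Effort = mean(.data$Effort), .groups = "drop")
  } else {
    dplyr::summarise(dplyr::group_by(per_month, .data$Source, .data$Month),
                     Effort = mean(.data$Effort), .groups = "drop")
  }
}

#' Flag and impute unreliable flowmeter volumes
#'
#' A volume is deemed unreliable when its log deviates from the group median
#' log-volume by more than `k` robust standard deviations (MAD, floored at
#' 0.01 log units to avoid zero-spread degeneracy). Groups are samples of the
#' same survey and size class sharing a station (default) or a date; groups
#' with fewer than three volumes fall back to survey-wide statistics for
#' outlier detection. Flagged volumes are replaced with the mean of the
#' non-flagged volumes in their group; when no donor exists the volume is set
#' missing and logged un-imputable.
#'
#' @param env Environment table.
#' @param grouping `"station"` or `"date"`.
#' @param k Outlier threshold in MAD units (default 3).
#' @return List: `environment` (volumes imputed) and `log` (one row per
#'   replacement or un-imputable flag).
#' @export
qc_flowmeter <- function(env, grouping = c("station", "date"), k = 3) {
  grouping <- match.arg(grouping)
  env <- tibble::as_tibble(env)
  gcol <- if (grouping == "station") "Station" else "Date"
  grp <- paste(env$Source, env$SizeClass, env[[gcol]])
  logv <- log(env$Volume)
  flag <- rep(FALSE, nrow(env))
  for (g in unique(grp)) {
    rows <- which(grp == g & !is.na(logv))
    if (length(rows) == 0) next
    if (length(rows) >= 3) {
      ref <- logv[rows]
    } else {
      ref <- logv[env$Source == env$Source[rows[1]] &
                    env$SizeClass == env$SizeClass[rows[1]] & !is.na(logv)]
    }
    med <- stats::median(ref)
    s <- max(stats::mad(ref, center = med), 0.01)
    flag[rows] <- abs(logv[rows] - med) / s > k
  }
  log_rows <- list()
  for (i in which(flag)) {
    donors <- which(grp == grp[i] & !flag & !is.na(env$Volume))
    old <- env$Volume[i]
    if (length(donors) > 0) {
      env$Volume[i] <- mean(env$Volume[donors])
      status <- "imputed"
    } else {
      env$Volume[i] <- NA_real_
      status <- "unimputable"
    }
    log_rows[[length(log_rows) + 1]] <- tibble::tibble(
      SampleID = if ("SampleID" %in% names(env)) env$SampleID[i] else NA_character_,
      Group = grp[i], OldVolume = old, NewVolume = env$Volume[i],
      Donors = length(donors), Status = status)
  }
  list(environment = env,
       log = if (length(log_rows)) dplyr::bind_rows(log_rows) else
         tibble::tibble(SampleID = character(), Group = character(),
                        OldVolume = numeric(), NewVolume = numeric(),
                        Donors = integer(), Status = character()))
}
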