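#' Read/write the integration's CSV tables
#'
#' All tables are UTF-8, RFC 4180 CSV with missing values written as the
#' literal string "NA" (the convention of the source data ecosystem).
#'
#' @param path File path.
#' @param x Data frame to write.
#' @name zoop_io
NULL

#' @rdname zoop_io
#' @export
read_zoop_csv <- function(path) {
  readr::read_csv(path, na = "NA", show_col_types = FALSE, progress = FALSE)
}

#' @rdname zoop_io
#' @export
write_zoop_csv <- function(x, path) {
  readr::write_csv(x, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname zoop_io
#' @export
read_taxonomy <- function(path) {
  build_taxonomy(read_zoop_csv(path))
}

#' @rdname zoop_io
#' @export
write_taxonomy <- function(x, path) {
  stopifnot(inherits(x, "zoop_taxonomy"))
  write_zoop_csv(x$nodes[, c(rank_ladder, "Level", "Taxname")], path)
}

#' @rdname zoop_io
#' @export
read_taxa_lists <- function(path) {
  taxa_lists(read_zoop_csv(path))
}

#' @rdname zoop_io
#' @export
write_taxa_lists <- function(x, path) {
  write_zoop_csv(tibble::as_tibble(unclass_lists(x)), path)
}

unclass_lists <- function(x) {
  class(x) <- setdiff(class(x), "zoop_taxa_lists")
  x
}

#' Convert a taxa list between the long schema and the published wide schema
#'
#' The published schema has one row per taxon/lifestage with per-survey-group
#' year columns (`<prefix>start`, `<prefix>end`, `<prefix>start2`), an `Intro`
#' column, and logical presence columns `<Survey>_<SizeClass>` marking which
#' survey/size-class combinations count the category. `prefix_map` names the
#' surveys each year-column prefix applies to (e.g. the FMWT and STN surveys
#' share one set of year columns in the source data).
#'
#' @param wide Data frame in the published schema.
#' @param prefix_map Named list: year-column prefix -> character vector of
#'   survey names.
#' @return A `zoop_taxa_lists` long table.
#' @export
taxa_lists_from_published <- function(wide, prefix_map) {
  wide <- tibble::as_tibble(wide)
  out <- list()
  flag_cols <- grep("^[A-Za-z0-9]+_(Micro|Meso|Macro)$", names(wide), value = TRUE)
  for (prefix in names(prefix_map)) {
    scol <- paste0(prefix, "start")
    ecol <- paste0(prefix, "end")
    rcol <- paste0(prefix, "start2")
    if (!scol %in% names(wide)) next
    for (survey in prefix_map[[prefix]]) {
      flags <- flag_cols[startsWith(flag_cols, paste0(survey, "_"))]
      for (fc in flags) {
        size_class <- sub("^.*_", "", fc)
        keep <- !is.na(wide[[fc]]) & wide[[fc]] & !is.na(wide[[scol]])
        if (!any(keep)) next
        out[[length(out) + 1]] <- tibble::tibble(
          Survey = survey,
          SizeClass = size_class,
          Taxname = wide$Taxname[keep],
          Lifestage = wide$Lifestage[keep],
          StartYear = wide[[scol]][keep],
          EndYear = if (ecol %in% names(wide)) wide[[ecol]][keep] else NA_real_,
          RestartYear = if (rcol %in% names(wide)) wide[[rcol]][keep] else NA_real_,
          IntroYear = if ("Intro" %in% names(wide)) wide$Intro[keep] else NA_real_
        )
      }
    }
  }
  taxa_lists(dplyr::bind_rows(out))
}
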