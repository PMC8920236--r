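entry_covers_range <- function(entries, y0, y1) {
  main_to <- ifelse(is.na(entries$EndYear), Inf, entries$EndYear)
  covered <- entries$StartYear <= y0 & main_to >= y1
  has_restart <- !is.na(entries$RestartYear)
  # with a restart, counted years are [start, end] U [restart, Inf): the gap
  # [end+1, restart-1] must fall entirely outside the requested range
  gap_ok <- !has_restart |
    (entries$RestartYear <= y0) | (main_to >= y1)
  ifelse(has_restart,
         entries$StartYear <= y0 & gap_ok &
           (main_to >= y1 | entries$RestartYear <= y1),
         covered)
}

entry_intersects_range <- function(entries, y0, y1) {
  main_to <- ifelse(is.na(entries$EndYear), Inf, entries$EndYear)
  in_main <- entries$StartYear <= y1 & main_to >= y0
  in_restart <- !is.na(entries$RestartYear) & entries$RestartYear <= y1
  in_main | in_restart
}

#' Plan community-mode taxonomic harmonization
#'
#' Builds the mapping that makes catch comparable across surveys for
#' community-level analysis. For each taxon/lifestage not counted by every
#' survey, the plan rolls counts up to the lowest taxonomic rank at which all
#' surveys in scope have a counting category; constituent categories are
#' absorbed into the summed group (never double counted). Taxa with no rank
#' counted by all surveys are dropped (orphans). Life stages are planned
#' independently, as is each size class.
#'
#' A survey "counts" a clade at rank r only when its taxa list holds a
#' category at exactly that name and rank (the higher-rank "other" bin);
#' such bins exclude lower taxa counted separately, so the bin plus its
#' separately-counted descendants sum to the whole clade.
#'
#' @param lists A `zoop_taxa_lists` table.
#' @param tree A `zoop_taxonomy`.
#' @param surveys Character vector of surveys in scope.
#' @param size_class Single size class.
#' @param year_range Length-2 integer vector; categories whose counted years
#'   intersect this range are in scope.
#' @return A `zoop_plan` with elements `mapping` (one row per input category:
#'   `Survey`, `Taxname`, `Lifestage`, `Taxlifestage`, `Action`, `Target`,
#'   `TargetRank`, `Reason`), `orphans`, and metadata.
#' @export
plan_community <- function(lists, tree, surveys, size_class,
                           year_range = c(-Inf, Inf)) {
  if (length(surveys) == 0) stop("empty survey set", call. = FALSE)
  if (!inherits(lists, "zoop_taxa_lists")) lists <- taxa_lists(lists)
  y0 <- year_range[1]; y1 <- year_range[2]
  sub <- lists[lists$Survey %in% surveys & lists$SizeClass == size_class, ]
  sub <- sub[entry_intersects_range(sub, y0, y1), ]
  if (nrow(sub) == 0) {
    stop("no taxa-list entries for size class '", size_class,
         "' in the requested surveys/years", call. = FALSE)
  }

  listed <- function(survey, taxname, lifestage) {
    any(sub$Survey == survey & sub$Taxname == taxname &
          sub$Lifestage == lifestage)
  }

  units <- dplyr::distinct(sub[, c("Taxname", "Lifestage")])
  units$Target <- NA_character_
  units$TargetRank <- NA_character_
  for (i in seq_len(nrow(units))) {
    row <- taxon_row(tree, units$Taxname[i])
    own <- rank_index(row$Level)
    for (L in seq(own, 1)) {
      anc <- unname(unlist(row[, rank_ladder[L]]))
      # the ancestor must be a counting category (a node) at rank L
      j <- match(anc, tree$nodes$Taxname)
      if (L < own && (is.na(j) || rank_index(tree$nodes$Level[j]) != L)) next
      if (all(vapply(surveys, listed, logical(1), taxname = anc,
                     lifestage = units$Lifestage[i]))) {
        units$Target[i] <- anc
        units$TargetRank[i] <- rank_ladder[L]
        break
      }
    }
  }

  # categories whose clade is absorbed by a lower group root keep their own
  # root; roots are targets, so a root's target is itself (all-survey listed)
  mapping <- sub[, c("Survey", "Taxname", "Lifestage")]
  k <- match(paste(mapping$Taxname, mapping$Lifestage),
             paste(units$Taxname, units$Lifestage))
  mapping$Target <- units$Target[k]
  mapping$TargetRank <- units$TargetRank[k]
  dropped <- is.na(mapping$Target)
  n_members <- table(paste(units$Target, units$Lifestage))
  grouped <- !dropped &
    (mapping$Target != mapping$Taxname |
       n_members[paste(mapping$Target, mapping$Lifestage)] > 1)
  mapping$Action <- ifelse(dropped, "DROP", ifelse(grouped, "SUM_TO", "KEEP"))
  mapping$Reason <- ifelse(dropped, "no rank counted by all surveys",
                           ifelse(grouped, "rolled up to all-survey rank", "counted by all surveys"))
  mapping$Taxlifestage <- paste(mapping$Taxname, mapping$Lifestage)
  mapping <- mapping[, c("Survey", "Taxname", "Lifestage", "Taxlifestage",
                         "Action", "Target", "TargetRank", "Reason")]

  orphans <- dplyr::distinct(mapping[mapping$Action == "DROP",
                                     c("Taxname", "Lifestage", "Reason")])
  structure(list(mode = "community", nonexclusive = FALSE,
                 size_class = size_class, surveys = surveys,
                 year_range = c(y0, y1), mapping = tibble::as_tibble(mapping),
                 orphans = tibble::as_tibble(orphans)),
            class = "zoop_plan")
}

#' @export
print.zoop_plan <- function(x, ...) {
  acts <- table(x$mapping$Action)
  cat("<zoop_plan> mode:", x$mode,
      if (x$nonexclusive) "(non-exclusive; unsafe for community analysis)" else "",
      "\n  size class:", x$size_class,
      "| surveys:", paste(x$surveys, collapse = ", "),
      "\n  actions:", paste(names(acts), acts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Apply a harmonization plan to catch records
#'
#' Operates strictly within each sample: dropped categories are removed,
#' kept categories pass through, and each summed group's CPUE is the sum of
#' its constituent CPUEs present in that sample. Missing (`NA`) constituent
#' CPUEs encode "unknown, not counted" and are ignored in sums unless every
#' constituent is `NA`, in which case the group is `NA`
#' (`na_rule = "ignore"`); `na_rule = "propagate"` makes any `NA`
#' constituent poison its group.
#'
#' @param catch Catch records with `SampleID`, `Source`, `Taxname`,
#'   `Lifestage`, `Taxlifestage`, `CPUE` (and optionally `Undersampled`,
#'   propagated by any-of).
#' @param plan A `zoop_plan`.
#' @param na_rule `"ignore"` (default) or `"propagate"`.
#' @return Harmonized catch tibble, one row per (`SampleID`, output
#'   category).
#' @export
apply_plan <- function(catch, plan, na_rule = c("ignore", "propagate")) {
  na_rule <- match.arg(na_rule)
  stopifnot(inherits(plan, "zoop_plan"))
  catch <- tibble::as_tibble(catch)
  if (!"Source" %in% names(catch)) {
    stop("catch must carry a Source column (join with the environment table)",
         call. = FALSE)
  }
  if (!"Undersampled" %in% names(catch)) catch$Undersampled <- FALSE
  if (plan$nonexclusive) return(apply_plan_nonexclusive(catch, plan, na_rule))

  key <- paste(catch$Source, catch$Taxlifestage)
  pkey <- paste(plan$mapping$Survey, plan$mapping$Taxlifestage)
  i <- match(key, pkey)
  if (anyNA(i)) {
    stop("record category absent from plan: ",
         paste(utils::head(sort(unique(key[is.na(i)])), 5), collapse = "; "),
         call. = FALSE)
  }
  act <- plan$mapping$Action[i]
  tgt <- plan$mapping$Target[i]
  keep <- act != "DROP"
  out <- catch[keep, ]
  out$Taxname <- tgt[keep]
  out$Taxlifestage <- paste(out$Taxname, out$Lifestage)

  sum_cpue <- if (na_rule == "ignore") {
    function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  } else {
    function(x) sum(x)
  }
  dplyr::summarise(
    dplyr::group_by(out, .data$SampleID, .data$Source, .data$Taxname,
                    .data$Lifestage, .data$Taxlifestage),
    CPUE = sum_cpue(.data$CPUE),
    Undersampled = any(.data$Undersampled, na.rm = TRUE),
    .groups = "drop")
}

apply_plan_nonexclusive <- function(catch, plan, na_rule) {
  sum_cpue <- if (na_rule == "ignore") {
    function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  } else {
    function(x) sum(x)
  }
  groups <- plan$mapping[plan$mapping$Action == "SUM_TO", ]
  out <- list(catch)
  for (g in unique(groups$Target)) {
    for (ls in unique(groups$Lifestage[groups$Target == g])) {
      members <- groups[groups$Target == g & groups$Lifestage == ls, ]
      sel <- catch[paste(catch$Source, catch$Taxlifestage) %in%
                     paste(members$Survey, members$Taxlifestage), ]
      if (nrow(sel) == 0) next
      agg <- dplyr::summarise(
        dplyr::group_by(sel, .data$SampleID, .data$Source),
        CPUE = sum_cpue(.data$CPUE),
        Undersampled = any(.data$Undersampled, na.rm = TRUE),
        .groups = "drop")
      agg$Taxname <- g
      agg$Lifestage <- ls
      agg$Taxlifestage <- paste(g, ls)
      out[[length(out) + 1]] <- agg[, names(catch)]
    }
  }
  dplyr::bind_rows(out)
}

#' Plan taxa-of-interest harmonization (non-exclusive)
#'
#' For each requested taxon, emits a summed "All <taxon>" group collecting
#' every counting category inside the taxon's clade in each survey — the
#' group is comparable across surveys — while retaining all constituent
#' categories in the output. Because constituents are retained, organisms in
#' summed groups are double-counted: the result is for querying taxa of
#' interest, not for community-level analysis (the plan is flagged
#' non-exclusive).
#'
#' @param taxa Character vector of requested taxon names (all lifestages
#'   found for each are planned).
#' @param lists,tree,surveys,size_class,year_range As [plan_community()].
#' @return A non-exclusive `zoop_plan`.
#' @export
plan_taxa_of_interest <- function(taxa, lists, tree, surveys, size_class,
                                  year_range = c(-Inf, Inf)) {
  if (length(surveys) == 0) stop("empty survey set", call. = FALSE)
  if (!inherits(lists, "zoop_taxa_lists")) lists <- taxa_lists(lists)
  y0 <- year_range[1]; y1 <- year_range[2]
  sub <- lists[lists$Survey %in% surveys & lists$SizeClass == size_class, ]
  sub <- sub[entry_intersects_range(sub, y0, y1), ]

  rows <- list()
  for (x in taxa) {
    xrow <- taxon_row(tree, x)
    xlev <- rank_index(xrow$Level)
    in_clade <- vapply(sub$Taxname, function(tn) {
      trow <- taxon_row(tree, tn)
      rank_index(trow$Level) >= xlev &&
        identical(unname(unlist(trow[, rank_ladder[xlev]])), x)
    }, logical(1))
    if (!any(in_clade)) {
      warning("requested taxon counted by no survey: '", x, "'", call. = FALSE)
      next
    }
    members <- sub[in_clade, ]
    members$Target <- paste("All", x)
    members$TargetRank <- xrow$Level
    rows[[length(rows) + 1]] <- members
  }
  keep_all <- sub[, c("Survey", "Taxname", "Lifestage")]
  keep_all$Action <- "KEEP"
  keep_all$Target <- keep_all$Taxname
  keep_all$TargetRank <- NA_character_
  keep_all$Reason <- "constituents retained (non-exclusive)"
  mapping <- keep_all
  if (length(rows) > 0) {
    g <- dplyr::bind_rows(rows)[, c("Survey", "Taxname", "Lifestage",
                                    "Target", "TargetRank")]
    g$Action <- "SUM_TO"
    g$Reason <- "summed all-clade group"
    mapping <- dplyr::bind_rows(keep_all, g)
  }
  mapping$Taxlifestage <- paste(mapping$Taxname, mapping$Lifestage)
  structure(list(mode = "taxa_of_interest", nonexclusive = TRUE,
                 size_class = size_class, surveys = surveys,
                 year_range = c(y0, y1),
                 mapping = tibble::as_tibble(
                   mapping[, c("Survey", "Taxname", "Lifestage", "Taxlifestage",
                               "Action", "Target", "TargetRank", "Reason")]),
                 orphans = tibble::tibble(Taxname = character(),
                                          Lifestage = character(),
                                          Reason = character())),
            class = "zoop_plan")
}

#' Coarsen taxa lists to their lowest resolution over a period
#'
#' Taxonomic resolution of the surveys has changed through time; analyses of
#' change over time must not mistake a counting change for a diversity
#' change. This reduces each survey's list to the categories counted in
#' every year of `year_range`. Introduced species are the exception: a
#' species first counted within `intro_lag` years of its introduction is
#' retained from its first counted year onward (`intro_lag = Inf` retains
#' every introduced species).
#'
#' @param lists A `zoop_taxa_lists` table.
#' @param year_range Length-2 numeric.
#' @param intro_lag Non-negative number of years, possibly `Inf`.
#' @return The reduced `zoop_taxa_lists`.
#' @export
time_correct <- function(lists, year_range, intro_lag = 0) {
  if (!inherits(lists, "zoop_taxa_lists")) lists <- taxa_lists(lists)
  y0 <- year_range[1]; y1 <- year_range[2]
  if (y0 > y1) stop("inverted year range", call. = FALSE)
  if (intro_lag < 0) stop("intro_lag must be >= 0", call. = FALSE)
  covered <- entry_covers_range(lists, y0, y1)
  intro_ok <- !is.na(lists$IntroYear) &
    (lists$StartYear - lists$IntroYear) <= intro_lag
  out <- lists[covered | intro_ok, ]
  class(out) <- class(lists)
  out
}

#' Validate that harmonization conserves total catch
#'
#' Regresses harmonized per-sample total CPUE on the raw total (OLS with
#' intercept, plain R-squared), and checks exact per-sample equality after
#' excluding the plan's dropped categories from the raw side — harmonization
#' only ever moves catch between categories within a sample, so once orphans
#' are excluded the totals must agree to numerical precision.
#'
#' @param raw Catch records before harmonization (`SampleID`, `Source`,
#'   `Taxlifestage`, `CPUE`).
#' @param harmonized Output of [apply_plan()] on `raw`.
#' @param plan The `zoop_plan` that produced `harmonized`.
#' @return A `zoop_conservation` list: `per_sample` tibble (raw, harmonized,
#'   raw excluding drops), `slope`, `intercept`, `r_squared`,
#'   `max_rel_diff` (after exclusion), `n_samples`.
#' @export
validate_conservation <- function(raw, harmonized, plan) {
  stopifnot(inherits(plan, "zoop_plan"))
  raw <- tibble::as_tibble(raw)
  harmonized <- tibble::as_tibble(harmonized)
  if (!setequal(unique(raw$SampleID), unique(harmonized$SampleID))) {
    stop("sample sets differ between raw and harmonized tables", call. = FALSE)
  }
  tot <- function(x) {
    dplyr::summarise(dplyr::group_by(x, .data$SampleID),
                     Total = sum(.data$CPUE, na.rm = TRUE), .groups = "drop")
  }
  dropped <- plan$mapping[plan$mapping$Action == "DROP", ]
  raw_excl <- raw[!(paste(raw$Source, raw$Taxlifestage) %in%
                      paste(dropped$Survey, dropped$Taxlifestage)), ]
  per <- dplyr::full_join(
    dplyr::rename(tot(raw), Raw = "Total"),
    dplyr::rename(tot(harmonized), Harmonized = "Total"),
    by = "SampleID")
  per <- dplyr::full_join(
    per, dplyr::rename(tot(raw_excl), RawExclDrops = "Total"), by = "SampleID")
  per$RawExclDrops[is.na(per$RawExclDrops)] <- 0
  fit <- stats::lm(Harmonized ~ Raw, data = per)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((per$Harmonized - mean(per$Harmonized))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  rel <- abs(per$Harmonized - per$RawExclDrops) /
    pmax(abs(per$RawExclDrops), 1e-12)
  rel[per$Harmonized == per$RawExclDrops] <- 0
  structure(list(per_sample = per,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 max_rel_diff = max(rel),
                 n_samples = nrow(per)),
            class = "zoop_conservation")
}

#' @export
print.zoop_conservation <- function(x, ...) {
  cat("<zoop_conservation>", x$n_samples, "samples\n",
      sprintf("  harmonized ~ raw: slope %.6g, intercept %.3g, R^2 %.8f\n",
              x$slope, x$intercept, x$r_squared),
      sprintf("  max relative |delta| after excluding drops: %.3g\n",
              x$max_rel_diff))
  invisible(x)
}

#' Serialize a harmonization plan to an auditable CSV
#'
#' @param plan A `zoop_plan`.
#' @param path Output CSV path.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "zoop_plan"))
  m <- plan$mapping
  m$SizeClass <- plan$size_class
  m$Mode <- plan$mode
  write_zoop_csv(m, path)
}

#' Join harmonized catch into an analysis-ready community table
#'
#' Merges catch with the environment table (by `SampleID`), taxonomy (by the
#' output category name where it is a tree node), and an optional
#' undersampled list (by `Taxlifestage`, setting the `Undersampled` flag).
#'
#' @param catch Harmonized catch.
#' @param env Environment table.
#' @param tree A `zoop_taxonomy`.
#' @param undersampled Optional tibble with a `Taxlifestage` column.
#' @return Joined tibble.
#' @export
join_community <- function(catch, env, tree, undersampled = NULL) {
  out <- dplyr::left_join(catch,
                          env[, setdiff(names(env), c("Source", "SizeClass"))],
                          by = "SampleID")
  out <- dplyr::left_join(out, tree$nodes[, c("Taxname", "Level", rank_ladder)],
                          by = "Taxname")
  if (!is.null(undersampled)) {
    out$Undersampled <- out$Undersampled |
      out$Taxlifestage %in% undersampled$Taxlifestage
  }
  out
}
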