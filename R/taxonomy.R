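#' The fixed taxonomic rank ladder
#'
#' Ranks recognized by the integration, ordered from coarsest (Phylum) to
#' finest (Species). Intermediate ranks (suborder, subclass, ...) are not
#' modeled: surveys record their counting categories at these six ranks only.
#'
#' @format Character vector of length 6.
#' @export
rank_ladder <- c("Phylum", "Class", "Order", "Family", "Genus", "Species")

rank_index <- function(level) {
  i <- match(level, rank_ladder)
  if (anyNA(i)) {
    stop("unknown taxonomic rank(s): ",
         paste(unique(level[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  i
}

#' Build a taxonomy tree from rank-ladder nodes
#'
#' Each node carries a scientific name (`Taxname`), its own rank (`Level`),
#' and the names of its ancestors at every rank above its own. Ranks below a
#' node's own rank must be empty (`NA`). The builder validates ladder
#' consistency: a name may not have two different parents anywhere in the
#' input, and the name stored at a node's own rank must equal its `Taxname`.
#'
#' @param nodes Data frame with columns `Taxname`, `Level`, and
#'   `Phylum`, `Class`, `Order`, `Family`, `Genus`, `Species`.
#' @return An object of class `zoop_taxonomy`: the validated node table plus
#'   a lookup index, supporting [ancestor_at_level()] and [counted_rank()].
#' @examples
#' tax <- build_taxonomy(tibble::tribble(
#'   ~Taxname, ~Level, ~Phylum, ~Class, ~Order, ~Family, ~Genus, ~Species,
#'   "Tortanus", "Genus", "Arthropoda", "Copepoda", "Calanoida",
#'     "Tortanidae", "Tortanus", NA,
#'   "Tortanus dextrilobatus", "Species", "Arthropoda", "Copepoda",
#'     "Calanoida", "Tortanidae", "Tortanus", "Tortanus dextrilobatus"
#' ))
#' ancestor_at_level(tax, "Tortanus dextrilobatus", "Genus")
#' @export
build_taxonomy <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  needed <- c("Taxname", "Level", rank_ladder)
  missing_cols <- setdiff(needed, names(nodes))
  if (length(missing_cols) > 0) {
    stop("taxonomy is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(nodes) == 0) stop("taxonomy must contain at least one node", call. = FALSE)
  nodes <- dplyr::mutate(nodes, dplyr::across(dplyr::all_of(rank_ladder),
                                              ~ dplyr::na_if(as.character(.x), "")))
  lvl <- rank_index(nodes$Level)

  for (i in seq_len(nrow(nodes))) {
    above <- rank_ladder[seq_len(lvl[i])]
    below <- rank_ladder[-seq_len(lvl[i])]
    vals_above <- unlist(nodes[i, above])
    if (anyNA(vals_above)) {
      stop("node '", nodes$Taxname[i], "': empty required rank(s) ",
           paste(above[is.na(vals_above)], collapse = ", "), call. = FALSE)
    }
    if (length(below) && !all(is.na(unlist(nodes[i, below])))) {
      stop("node '", nodes$Taxname[i], "': ranks below its own level (",
           nodes$Level[i], ") must be empty", call. = FALSE)
    }
    if (!identical(unname(unlist(nodes[i, nodes$Level[i]])), nodes$Taxname[i])) {
      stop("node '", nodes$Taxname[i], "': Taxname must equal the name at rank ",
           nodes$Level[i], call. = FALSE)
    }
  }

  dup <- nodes$Taxname[duplicated(nodes$Taxname)]
  if (length(dup) > 0) {
    # duplicates allowed only if byte-identical ancestry
    for (d in unique(dup)) {
      rows <- nodes[nodes$Taxname == d, c("Level", rank_ladder)]
      if (nrow(dplyr::distinct(rows)) > 1) {
        stop("duplicate taxname with conflicting ancestry: '", d, "'",
             call. = FALSE)
      }
    }
    nodes <- dplyr::distinct(nodes, .data$Taxname, .keep_all = TRUE)
  }

  # one-parent rule: a name at rank r has a single name at rank r-1 across nodes
  for (r in 2:6) {
    child <- nodes[[rank_ladder[r]]]
    parent <- nodes[[rank_ladder[r - 1]]]
    keep <- !is.na(child)
    tab <- unique(data.frame(child = child[keep], parent = parent[keep]))
    bad <- tab$child[duplicated(tab$child)]
    if (length(bad) > 0) {
      stop("inconsistent parentage: '", bad[1], "' has multiple parents at rank ",
           rank_ladder[r - 1], call. = FALSE)
    }
  }

  structure(list(nodes = nodes), class = "zoop_taxonomy")
}

#' @export
print.zoop_taxonomy <- function(x, ...) {
  cat("<zoop_taxonomy>", nrow(x$nodes), "nodes;",
      paste0(names(table(x$nodes$Level)), ": ", table(x$nodes$Level),
             collapse = ", "), "\n")
  invisible(x)
}

taxon_row <- function(tree, taxname) {
  i <- match(taxname, tree$nodes$Taxname)
  if (is.na(i)) stop("taxon not in taxonomy: '", taxname, "'", call. = FALSE)
  tree$nodes[i, ]
}

#' Ancestor of a taxon at a given rank
#'
#' Returns the scientific name of the taxon's ancestor at rank `level`;
#' the taxon itself when `level` equals its own rank. Requesting a rank below
#' the taxon's own rank is an error (resolution can only be reduced).
#'
#' @param tree A `zoop_taxonomy` from [build_taxonomy()].
#' @param taxname Scientific name present in the tree.
#' @param level Target rank, one of [rank_ladder].
#' @return Scientific name at `level` (character scalar).
#' @export
ancestor_at_level <- function(tree, taxname, level) {
  stopifnot(inherits(tree, "zoop_taxonomy"))
  row <- taxon_row(tree, taxname)
  li <- rank_index(level)
  if (li > rank_index(row$Level)) {
    stop("rank ", level, " is below the rank of '", taxname, "' (",
         row$Level, ")", call. = FALSE)
  }
  unname(unlist(row[, rank_ladder[li]]))
}

#' Taxa list: per-survey counting categories with validity years
#'
#' Validates a taxa-list table. One row is a counting category: a survey,
#' size class, scientific name and life stage, with the first/last years the
#' category was counted. `EndYear = NA` means counted through the present.
#' `RestartYear` encodes a category removed and later re-added (the years
#' `EndYear+1 .. RestartYear-1` are a gap during which the category was not
#' counted). `IntroYear` is the introduction year for non-native taxa.
#'
#' @param lists Data frame with columns `Survey`, `SizeClass`, `Taxname`,
#'   `Lifestage`, `StartYear`, and optionally `EndYear`, `RestartYear`,
#'   `IntroYear` (missing optional columns are added as `NA`).
#' @return A validated tibble with class `zoop_taxa_lists`.
#' @export
taxa_lists <- function(lists) {
  lists <- tibble::as_tibble(lists)
  needed <- c("Survey", "SizeClass", "Taxname", "Lifestage", "StartYear")
  missing_cols <- setdiff(needed, names(lists))
  if (length(missing_cols) > 0) {
    stop("taxa list is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (opt in c("EndYear", "RestartYear", "IntroYear")) {
    if (!opt %in% names(lists)) lists[[opt]] <- NA_real_
  }
  bad <- !is.na(lists$EndYear) & lists$StartYear > lists$EndYear
  if (any(bad)) stop("StartYear > EndYear for: ",
                     paste(lists$Taxname[bad], collapse = ", "), call. = FALSE)
  bad <- !is.na(lists$RestartYear) &
    (is.na(lists$EndYear) | lists$RestartYear <= lists$EndYear)
  if (any(bad)) stop("RestartYear must exceed EndYear for: ",
                     paste(lists$Taxname[bad], collapse = ", "), call. = FALSE)
  key <- paste(lists$Survey, lists$SizeClass, lists$Taxname, lists$Lifestage)
  if (anyDuplicated(key)) {
    stop("duplicate taxa-list entry: ", key[duplicated(key)][1], call. = FALSE)
  }
  class(lists) <- c("zoop_taxa_lists", class(lists))
  lists
}

entry_counts_in_year <- function(entries, year) {
  in_main <- entries$StartYear <= year &
    (is.na(entries$EndYear) | year <= entries$EndYear)
  in_restart <- !is.na(entries$RestartYear) & year >= entries$RestartYear
  in_main | in_restart
}

#' Rank at which a survey counts a taxon in a given year
#'
#' A survey "counts" a queried taxon/lifestage either under its own name or
#' under a higher-rank category (a "spp." bin) containing it. The returned
#' rank is the finest (lowest) rank among the survey's matching categories
#' active in `year`; `NA` (not counted) when no category covers the query.
#'
#' @param lists A `zoop_taxa_lists` table (or coercible data frame).
#' @param tree A `zoop_taxonomy`.
#' @param survey,size_class,taxname,lifestage,year Query.
#' @return Rank name, or `NA_character_` when the taxon is not counted.
#' @export
counted_rank <- function(lists, tree, survey, size_class, taxname, lifestage, year) {
  if (!inherits(lists, "zoop_taxa_lists")) lists <- taxa_lists(lists)
  row <- taxon_row(tree, taxname)
  own <- rank_index(row$Level)
  cand <- lists[lists$Survey == survey & lists$SizeClass == size_class &
                  lists$Lifestage == lifestage, , drop = FALSE]
  if (nrow(cand) == 0) return(NA_character_)
  cand <- cand[entry_counts_in_year(cand, year), , drop = FALSE]
  if (nrow(cand) == 0) return(NA_character_)
  # ancestors of the query at each rank down to its own
  anc <- unname(unlist(row[, rank_ladder[seq_len(own)]]))
  hit <- match(cand$Taxname, anc)  # entry taxname == ancestor name at some rank
  # entry must itself sit at that rank in the tree (bin at rank r)
  ok <- !is.na(hit)
  if (!any(ok)) return(NA_character_)
  levels_hit <- hit[ok]
  entry_levels <- vapply(cand$Taxname[ok], function(tn) {
    rank_index(taxon_row(tree, tn)$Level)
  }, integer(1))
  valid <- entry_levels == levels_hit
  if (!any(valid)) return(NA_character_)
  rank_ladder[max(levels_hit[valid])]
}
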