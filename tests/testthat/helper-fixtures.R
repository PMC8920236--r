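# Small shared fixtures: a copepod-flavoured taxonomy, three surveys with
# differing taxa lists, and builders for catch tables.

fixture_taxonomy <- function() {
  build_taxonomy(tibble::tribble(
    ~Taxname, ~Level, ~Phylum, ~Class, ~Order, ~Family, ~Genus, ~Species,
    "Tortanus", "Genus", "Arthropoda", "Copepoda", "Calanoida",
      "Tortanidae", "Tortanus", NA,
    "Tortanus discaudatus", "Species", "Arthropoda", "Copepoda", "Calanoida",
      "Tortanidae", "Tortanus", "Tortanus discaudatus",
    "Tortanus dextrilobatus", "Species", "Arthropoda", "Copepoda", "Calanoida",
      "Tortanidae", "Tortanus", "Tortanus dextrilobatus",
    "Pseudodiaptomus forbesi", "Species", "Arthropoda", "Copepoda",
      "Calanoida", "Pseudodiaptomidae", "Pseudodiaptomus",
      "Pseudodiaptomus forbesi",
    "Acartiella sinensis", "Species", "Arthropoda", "Copepoda", "Calanoida",
      "Acartiidae", "Acartiella", "Acartiella sinensis",
    "Annelida", "Phylum", "Annelida", NA, NA, NA, NA, NA
  ))
}

fixture_lists <- function() {
  taxa_lists(tibble::tribble(
    ~Survey, ~SizeClass, ~Taxname, ~Lifestage, ~StartYear, ~EndYear,
      ~RestartYear, ~IntroYear,
    "S20mm", "Meso", "Tortanus discaudatus", "Adult", 1995, NA, NA, NA,
    "S20mm", "Meso", "Tortanus dextrilobatus", "Adult", 1995, NA, NA, NA,
    "S20mm", "Meso", "Tortanus", "Adult", 1995, NA, NA, NA,
    "S20mm", "Meso", "Pseudodiaptomus forbesi", "Adult", 1995, NA, NA, NA,
    "S20mm", "Meso", "Acartiella sinensis", "Adult", 1994, NA, NA, 1993,
    "S20mm", "Meso", "Annelida", "Adult", 1995, NA, NA, NA,
    "EMP", "Meso", "Tortanus", "Adult", 1990, NA, NA, NA,
    "EMP", "Meso", "Pseudodiaptomus forbesi", "Adult", 1990, NA, NA, NA,
    "EMP", "Meso", "Acartiella sinensis", "Adult", 1994, NA, NA, 1993,
    "FMWT", "Meso", "Tortanus", "Adult", 2005, NA, NA, NA,
    "FMWT", "Meso", "Pseudodiaptomus forbesi", "Adult", 2005, NA, NA, NA,
    "FMWT", "Meso", "Acartiella sinensis", "Adult", 2005, NA, NA, 1993
  ))
}

# one-sample catch table for harmonization unit tests
fixture_catch <- function(sample_id = "S20mm ST1 2010-06-01 08:00:00 Meso",
                          source = "S20mm",
                          cpue = c("Tortanus discaudatus Adult" = 2,
                                   "Tortanus dextrilobatus Adult" = 3,
                                   "Tortanus Adult" = 1,
                                   "Pseudodiaptomus forbesi Adult" = 4)) {
  taxname <- sub(" Adult$", "", names(cpue))
  tibble::tibble(SampleID = sample_id, Source = source, Taxname = taxname,
                 Lifestage = "Adult",
                 Taxlifestage = names(cpue), CPUE = unname(cpue),
                 Undersampled = FALSE)
}

# --- independent brute-force oracle -----------------------------------------
# Lowest rank counted by all surveys, by direct search over the rank ladder
# using only the node table. Returns NA when no rank is shared.
oracle_common_rank <- function(nodes, lists_df, surveys, taxname, lifestage) {
  ladder <- c("Phylum", "Class", "Order", "Family", "Genus", "Species")
  row <- nodes[nodes$Taxname == taxname, ]
  own <- match(row$Level, ladder)
  for (L in seq(own, 1)) {
    anc <- as.character(row[[ladder[L]]])
    anc_row <- nodes[nodes$Taxname == anc, ]
    if (nrow(anc_row) == 0 || match(anc_row$Level, ladder) != L) next
    ok <- TRUE
    for (s in surveys) {
      hit <- lists_df$Survey == s & lists_df$Taxname == anc &
        lists_df$Lifestage == lifestage
      if (!any(hit)) { ok <- FALSE; break }
    }
    if (ok) return(list(target = anc, rank = ladder[L]))
  }
  list(target = NA_character_, rank = NA_character_)
}

# random taxonomy skeleton + survey lists for property/oracle tests
random_instance <- function(n_surveys, n_categories) {
  ladder <- c("Phylum", "Class", "Order", "Family", "Genus", "Species")
  nodes <- list()
  for (p in 1:2) for (cl in 1:2) for (o in 1:2) for (f in 1:2) for (g in 1:2) {
    path <- c(paste0("P", p), paste0("P", p, "C", cl),
              paste0("P", p, "C", cl, "O", o),
              paste0("P", p, "C", cl, "O", o, "F", f),
              paste0("P", p, "C", cl, "O", o, "F", f, "G", g))
    for (L in seq_along(path)) {
      nodes[[path[L]]] <- c(path[seq_len(L)], rep(NA, 6 - L))
    }
    for (sp in 1:2) {
      nm <- paste0(path[5], "S", sp)
      nodes[[nm]] <- c(path, nm)
    }
  }
  node_df <- tibble::as_tibble(stats::setNames(
    as.data.frame(do.call(rbind, nodes), stringsAsFactors = FALSE), ladder))
  node_df$Taxname <- names(nodes)
  node_df$Level <- ladder[rowSums(!is.na(node_df[, ladder]))]
  pool <- sample(node_df$Taxname, n_categories)
  lists_df <- dplyr::bind_rows(lapply(paste0("SV", seq_len(n_surveys)),
    function(s) {
      tibble::tibble(Survey = s, SizeClass = "Meso",
                     Taxname = sample(pool, max(2, rbinom(1, length(pool), 0.6))),
                     Lifestage = "Adult", StartYear = 2000, EndYear = NA,
                     RestartYear = NA, IntroYear = NA)
    }))
  list(nodes = node_df, tree = build_taxonomy(node_df),
       lists = taxa_lists(lists_df),
       surveys = unique(lists_df$Survey))
}

# standardize + join Source back onto the catch table
integrate_sim <- function(sim) {
  recs <- dplyr::bind_rows(lapply(names(sim$surveys), function(nm) {
    read_survey(sim$surveys[[nm]], sim$configs[[nm]])
  }))
  recs <- zeros_to_na(recs, sim$lists)
  tabs <- bind_and_split(recs)
  catch <- dplyr::left_join(tabs$zooplankton,
                            tabs$environment[, c("SampleID", "Source")],
                            by = "SampleID")
  list(environment = tabs$environment, catch = catch)
}
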