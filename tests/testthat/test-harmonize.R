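test_that("plan_community rolls split genera to the all-survey rank", {
  tax <- fixture_taxonomy()
  lst <- fixture_lists()
  plan <- plan_community(lst, tax, c("S20mm", "EMP", "FMWT"), "Meso",
                         c(2005, 2020))
  m <- plan$mapping
  tort <- m[m$Taxname %in% c("Tortanus", "Tortanus discaudatus",
                             "Tortanus dextrilobatus"), ]
  expect_true(all(tort$Action == "SUM_TO"))
  expect_true(all(tort$Target == "Tortanus"))
  expect_true(all(tort$TargetRank == "Genus"))
  # counted identically everywhere: kept
  pf <- m[m$Taxname == "Pseudodiaptomus forbesi", ]
  expect_true(all(pf$Action == "KEEP"))
  # counted by one survey with no shared higher category: dropped
  ann <- m[m$Taxname == "Annelida", ]
  expect_equal(unique(ann$Action), "DROP")
  expect_equal(plan$orphans$Taxname, "Annelida")
})

test_that("identical taxa lists yield an all-KEEP plan with no orphans", {
  tax <- fixture_taxonomy()
  same <- taxa_lists(dplyr::bind_rows(lapply(c("A", "B"), function(s) {
    tibble::tibble(Survey = s, SizeClass = "Meso",
                   Taxname = c("Tortanus", "Pseudodiaptomus forbesi"),
                   Lifestage = "Adult", StartYear = 1990)
  })))
  plan <- plan_community(same, tax, c("A", "B"), "Meso")
  expect_true(all(plan$mapping$Action == "KEEP"))
  expect_equal(nrow(plan$orphans), 0)
  expect_error(plan_community(same, tax, character(), "Meso"), "empty survey")
})

test_that("apply_plan sums constituents within a sample and drops orphans", {
  tax <- fixture_taxonomy()
  lst <- fixture_lists()
  plan <- plan_community(lst, tax, c("S20mm", "EMP", "FMWT"), "Meso",
                         c(2005, 2020))
  catch <- fixture_catch()
  out <- apply_plan(catch, plan)
  expect_equal(out$CPUE[out$Taxlifestage == "Tortanus Adult"], 6)  # 2+3+1
  expect_equal(out$CPUE[out$Taxlifestage == "Pseudodiaptomus forbesi Adult"], 4)
  expect_equal(nrow(out), 2)

  # record not covered by the plan
  alien <- fixture_catch(cpue = c("Annelida Juvenile" = 1))
  expect_error(apply_plan(alien, plan), "absent from plan")
})

test_that("identity plans are no-ops", {
  tax <- fixture_taxonomy()
  same <- taxa_lists(dplyr::bind_rows(lapply(c("A", "B"), function(s) {
    tibble::tibble(Survey = s, SizeClass = "Meso",
                   Taxname = c("Tortanus", "Pseudodiaptomus forbesi"),
                   Lifestage = "Adult", StartYear = 1990)
  })))
  plan <- plan_community(same, tax, c("A", "B"), "Meso")
  catch <- fixture_catch(source = "A",
                         cpue = c("Tortanus Adult" = 1.5,
                                  "Pseudodiaptomus forbesi Adult" = 2.5))
  out <- apply_plan(catch, plan)
  expect_equal(dplyr::arrange(out[, names(catch)], Taxlifestage),
               dplyr::arrange(catch, Taxlifestage))
})

test_that("group sums treat NA as not-counted unless all constituents are NA", {
  tax <- fixture_taxonomy()
  lst <- fixture_lists()
  plan <- plan_community(lst, tax, c("S20mm", "EMP", "FMWT"), "Meso",
                         c(2005, 2020))
  catch <- fixture_catch(cpue = c("Tortanus discaudatus Adult" = NA,
                                  "Tortanus dextrilobatus Adult" = 3,
                                  "Tortanus Adult" = 1))
  out <- apply_plan(catch, plan)
  expect_equal(out$CPUE[out$Taxlifestage == "Tortanus Adult"], 4)
  # the switchable strict rule poisons the group instead
  out2 <- apply_plan(catch, plan, na_rule = "propagate")
  expect_true(is.na(out2$CPUE[out2$Taxlifestage == "Tortanus Adult"]))
  # all constituents unknown -> unknown group
  allna <- fixture_catch(cpue = c("Tortanus discaudatus Adult" = NA,
                                  "Tortanus Adult" = NA))
  out3 <- apply_plan(allna, plan)
  expect_true(is.na(out3$CPUE[out3$Taxlifestage == "Tortanus Adult"]))
})

test_that("harmonization never mixes samples and conserves catch per sample", {
  tax <- fixture_taxonomy()
  lst <- fixture_lists()
  plan <- plan_community(lst, tax, c("S20mm", "EMP", "FMWT"), "Meso",
                         c(2005, 2020))
  set.seed(42)
  cats <- c("Tortanus discaudatus Adult", "Tortanus dextrilobatus Adult",
            "Tortanus Adult", "Pseudodiaptomus forbesi Adult",
            "Annelida Adult")
  catch <- dplyr::bind_rows(lapply(1:25, function(i) {
    fixture_catch(sample_id = paste("S20mm ST1", sprintf("2010-06-%02d", i),
                                    "08:00:00 Meso"),
                  cpue = stats::setNames(round(stats::rlnorm(5, 1, 1), 3),
                                         cats))
  }))
  out <- apply_plan(catch, plan)

  # conservation: out + dropped = in, per sample
  tot <- function(x) tapply(x$CPUE, x$SampleID, sum, na.rm = TRUE)
  dropped <- catch[catch$Taxlifestage == "Annelida Adult", ]
  expect_equal(tot(out) + tot(dropped), tot(catch), tolerance = 1e-12)

  # exclusivity: each input record lands in exactly one output row or drops
  expect_equal(nrow(out), 25 * 2)

  # permuting sample order changes nothing
  perm <- catch[sample(nrow(catch)), ]
  out_perm <- apply_plan(perm, plan)
  ord <- function(x) dplyr::arrange(x, SampleID, Taxlifestage)
  expect_equal(ord(out_perm), ord(out))

  # idempotence: re-planning on the harmonized category set is a no-op
  lst2 <- taxa_lists(dplyr::bind_rows(lapply(c("S20mm", "EMP", "FMWT"),
    function(s) tibble::tibble(
      Survey = s, SizeClass = "Meso",
      Taxname = c("Tortanus", "Pseudodiaptomus forbesi"),
      Lifestage = "Adult", StartYear = 1990))))
  plan2 <- plan_community(lst2, tax, c("S20mm", "EMP", "FMWT"), "Meso")
  out2 <- apply_plan(out, plan2)
  expect_equal(ord(out2), ord(out))
})

test_that("plan_community agrees with the brute-force common-rank oracle", {
  set.seed(101)
  for (trial in 1:25) {
    inst <- random_instance(n_surveys = sample(2:4, 1),
                            n_categories = sample(6:14, 1))
    plan <- plan_community(inst$lists, inst$tree, inst$surveys, "Meso")
    units <- unique(plan$mapping[, c("Taxname", "Lifestage", "Target")])
    for (i in seq_len(nrow(units))) {
      want <- oracle_common_rank(inst$nodes, inst$lists, inst$surveys,
                                 units$Taxname[i], units$Lifestage[i])
      expect_identical(units$Target[i], want$target,
                       label = paste("trial", trial, units$Taxname[i]))
    }
  }
})

test_that("taxa-of-interest mode sums the clade and retains constituents", {
  tax <- fixture_taxonomy()
  lst <- fixture_lists()
  surveys <- c("S20mm", "EMP", "FMWT")
  plan <- plan_taxa_of_interest("Tortanus", lst, tax, surveys, "Meso",
                                c(2005, 2020))
  expect_true(plan$nonexclusive)
  catch <- fixture_catch()
  out <- apply_plan(catch, plan)
  expect_equal(out$CPUE[out$Taxlifestage == "All Tortanus Adult"], 6)
  for (tl in catch$Taxlifestage) {
    expect_equal(out$CPUE[out$Taxlifestage == tl],
                 catch$CPUE[catch$Taxlifestage == tl])
  }
  # the All-group equals the community-mode group on the same sample
  cplan <- plan_community(lst, tax, surveys, "Meso", c(2005, 2020))
  cout <- apply_plan(catch, cplan)
  expect_equal(out$CPUE[out$Taxlifestage == "All Tortanus Adult"],
               cout$CPUE[cout$Taxlifestage == "Tortanus Adult"])
  # degenerate: a taxon counted identically everywhere
  p2 <- plan_taxa_of_interest("Pseudodiaptomus forbesi", lst, tax, surveys,
                              "Meso", c(2005, 2020))
  o2 <- apply_plan(catch, p2)
  expect_equal(o2$CPUE[o2$Taxlifestage == "All Pseudodiaptomus forbesi Adult"],
               catch$CPUE[catch$Taxlifestage == "Pseudodiaptomus forbesi Adult"])
  # unknown everywhere -> warning, no group
  expect_warning(p3 <- plan_taxa_of_interest("Annelida", lst, tax,
                                             c("EMP", "FMWT"), "Meso"),
                 "no survey")
  expect_false(any(p3$mapping$Action == "SUM_TO"))
})

test_that("time_correct keeps only categories counted in every year, with the intro-lag exception", {
  lst <- taxa_lists(tibble::tribble(
    ~Survey, ~SizeClass, ~Taxname, ~Lifestage, ~StartYear, ~EndYear,
      ~RestartYear, ~IntroYear,
    "S", "Meso", "Tortanus", "Adult", 1990, NA, NA, NA,
    "S", "Meso", "Tortanus discaudatus", "Adult", 2000, NA, NA, NA,
    "S", "Meso", "Acartiella sinensis", "Adult", 1994, NA, NA, 1993,
    "S", "Meso", "Pseudodiaptomus forbesi", "Adult", 1990, 1995, 2005, NA))
  out <- time_correct(lst, c(1990, 2020), intro_lag = 2)
  # full-range genus bin survives; mid-series species promotion removed
  expect_true("Tortanus" %in% out$Taxname)
  expect_false("Tortanus discaudatus" %in% out$Taxname)
  # introduced 1993, first counted 1994: within the 2-year lag -> retained
  expect_true("Acartiella sinensis" %in% out$Taxname)
  # a removal/restart gap inside the range disqualifies
  expect_false("Pseudodiaptomus forbesi" %in% out$Taxname)

  # without the lag the introduced species is removed too
  out0 <- time_correct(lst, c(1990, 2020), intro_lag = 0)
  expect_false("Acartiella sinensis" %in% out0$Taxname)
  # infinite lag retains every introduced species
  outInf <- time_correct(lst, c(1990, 2020), intro_lag = Inf)
  expect_true("Acartiella sinensis" %in% outInf$Taxname)

  expect_error(time_correct(lst, c(2020, 1990)), "inverted")
})

test_that("time_correct is monotone: a wider range never adds native categories", {
  lst <- fixture_lists()
  narrow <- time_correct(lst, c(2006, 2010), intro_lag = 0)
  wide <- time_correct(lst, c(1990, 2020), intro_lag = 0)
  key <- function(x) paste(x$Survey, x$SizeClass, x$Taxname, x$Lifestage)
  expect_true(all(key(wide) %in% key(narrow)))
})

test_that("validate_conservation reports a perfect fit without drops and exact equality after drops", {
  tax <- fixture_taxonomy()
  lst <- fixture_lists()
  surveys <- c("S20mm", "EMP", "FMWT")
  plan <- plan_community(lst, tax, surveys, "Meso", c(2005, 2020))
  set.seed(7)
  cats <- c("Tortanus discaudatus Adult", "Tortanus dextrilobatus Adult",
            "Tortanus Adult", "Pseudodiaptomus forbesi Adult",
            "Annelida Adult")
  catch <- dplyr::bind_rows(lapply(1:30, function(i) {
    fixture_catch(sample_id = paste("S20mm ST1", sprintf("2012-01-%02d", i),
                                    "08:00:00 Meso"),
                  cpue = stats::setNames(round(stats::rlnorm(5, 1, 1), 3), cats))
  }))
  h <- apply_plan(catch, plan)
  rep <- validate_conservation(catch, h, plan)
  expect_equal(rep$n_samples, 30)
  expect_lt(rep$max_rel_diff, 1e-9)
  # per-sample delta between raw and harmonized equals the dropped catch
  drop_tot <- tapply(catch$CPUE[catch$Taxlifestage == "Annelida Adult"],
                     catch$SampleID[catch$Taxlifestage == "Annelida Adult"],
                     sum)
  delta <- with(rep$per_sample, Raw - Harmonized)
  expect_equal(as.numeric(delta[order(rep$per_sample$SampleID)]),
               as.numeric(drop_tot[order(names(drop_tot))]),
               tolerance = 1e-12)

  # mismatched sample sets are an alignment error
  expect_error(validate_conservation(catch[catch$SampleID !=
                                             catch$SampleID[1], ], h, plan),
               "sample sets differ")
})

test_that("plans serialize to an auditable CSV", {
  tax <- fixture_taxonomy()
  plan <- plan_community(fixture_lists(), tax, c("S20mm", "EMP", "FMWT"),
                         "Meso", c(2005, 2020))
  tdir <- withr::local_tempdir()
  write_plan(plan, file.path(tdir, "plan.csv"))
  back <- read_zoop_csv(file.path(tdir, "plan.csv"))
  expect_setequal(back$Action, c("KEEP", "SUM_TO", "DROP"))
  expect_equal(nrow(back), nrow(plan$mapping))
})
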