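test_that("group maxima follow the present activities", {
  m <- default_impact_matrix()
  # no activity present: every group at the very-low floor
  g0 <- group_max_impacts(all_absent_record(), m)
  expect_true(all(g0$max_impact == 1))
  # all activities present: column maxima
  g1 <- group_max_impacts(all_present_record(), m)
  expect_equal(as.integer(g1$max_impact), unname(apply(m, 2, max)))
  # Sedlo (pelagic longline only): maxima sum to 13 = 5 * 2.6
  gs <- group_max_impacts(case_study_seamounts() |>
                            dplyr::filter(seamount == "Sedlo"), m)
  expect_equal(sum(gs$max_impact), 13)
})

test_that("threat scores and categories match the published values", {
  ts <- threat_score(case_study_seamounts())
  exp <- published_results()
  ts <- ts[match(exp$seamount, ts$seamount), ]
  expect_equal(ts$threat_score, exp$threat, tolerance = 1e-9)
  expect_equal(ts$threat_category, exp$threat_cat)
  # no activities at all: score exactly 1, category none
  t0 <- threat_score(all_absent_record())
  expect_equal(t0$threat_raw, 1)
  expect_equal(t0$threat_category, "none")
})

test_that("threat score is monotone and bounded under random matrices", {
  set.seed(424)
  acts <- ebsa_threats()$item
  for (i in 1:20) {
    m <- matrix(sample(1:5, 45, replace = TRUE), 9, 5,
                dimnames = list(acts, ebsa_groups()$group))
    k <- sample(0:8, 1)
    present <- sample(acts, k)
    rec <- make_record("r", stats::setNames(rep("0H", 10), c(
      "vents", "macrophytes", "corals", "sponges", "aggregating_fish",
      "threatened_bottom_fish", "threatened_air_breathing",
      "threatened_visiting_pelagics", "naturalness", "depth_shallow")),
      stats::setNames(ifelse(acts %in% present, "1H", "0H"), acts))
    ts <- threat_score(rec, m)$threat_raw
    expect_gte(ts, 1)
    expect_lte(ts, 5)
    if (k == 0) expect_equal(ts, 1)
    # adding one more activity never decreases the score
    absent <- setdiff(acts, present)
    if (length(absent) > 0) {
      add <- sample(absent, 1)
      rec2 <- rec
      rec2$status[rec2$item == add & rec2$domain == "threat"] <- "present"
      expect_gte(threat_score(rec2, m)$threat_raw, ts)
    }
    # raising one matrix cell never decreases the score
    m2 <- m
    cell <- c(sample(9, 1), sample(5, 1))
    m2[cell[1], cell[2]] <- min(5, m2[cell[1], cell[2]] + 1)
    expect_gte(threat_score(rec, m2)$threat_raw, ts)
  }
})

test_that("data-deficient activities do not raise the threat score", {
  # Cobb has four DD activities yet scores from its present ones only
  cobb <- case_study_seamounts() |> dplyr::filter(seamount == "Cobb")
  expect_equal(threat_score(cobb)$threat_score, 2.60)
  # marking a present activity DD can only drop the score
  ros <- case_study_seamounts() |> dplyr::filter(seamount == "Rosemary")
  ros_dd <- ros
  ros_dd$status[ros_dd$domain == "threat"] <- "DD"
  ros_dd$quality[ros_dd$domain == "threat"] <- NA_character_
  expect_equal(threat_score(ros_dd)$threat_raw, 1)
})

test_that("matrix validation catches malformed matrices", {
  m <- default_impact_matrix()
  expect_equal(nrow(validate_matrix(m)), 0)
  bad <- m; bad[1, 1] <- 0
  expect_equal(nrow(validate_matrix(bad)), 1)
  frac <- m; frac[2, 3] <- 2.5
  expect_true(any(grepl("not an integer", validate_matrix(frac)$message)))
  expect_gt(nrow(validate_matrix(m[-1, ])), 0)
  expect_error(group_max_impacts(all_absent_record(), m[-1, ]),
               class = "seamountEBSA_bad_matrix")
})

test_that("impact matrices round-trip through CSV", {
  m <- default_impact_matrix()
  path <- withr::local_tempfile(fileext = ".csv")
  write_impact_matrix(m, path)
  expect_equal(read_impact_matrix(path), m)
})
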