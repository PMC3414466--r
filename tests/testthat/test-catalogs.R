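test_that("default catalogs have the published structure", {
  ind <- ebsa_indicators()
  slots <- unique(ifelse(is.na(ind$pair), ind$item, ind$pair))
  expect_length(slots, 10)

  by_typ <- table(ind$typology[is.na(ind$pair) | ind$variant == "threatened"])
  expect_equal(as.integer(by_typ[c("benthic", "benthopelagic", "pelagic",
                                   "historical", "geological")]),
               c(4L, 2L, 2L, 1L, 1L))
  expect_true(all(ind$weight[ind$typology == "benthic"] == 3))
  expect_setequal(ind$weight[ind$typology == "benthopelagic"], c(2, 1))
  # pair variants: threatened 2, plain 1
  expect_true(all(ind$weight[!is.na(ind$variant) &
                               ind$variant == "threatened"] == 2))
  expect_true(all(ind$weight[!is.na(ind$variant) & ind$variant == "plain"] == 1))
  # maximum achievable weight over the ten slots
  expect_equal(sum(ind$weight[is.na(ind$pair) | ind$variant == "threatened"]),
               21)

  thr <- ebsa_threats()
  expect_equal(nrow(thr), 9)
  expect_equal(sum(thr$kind == "mining"), 1)
  expect_equal(sum(thr$kind == "fishing"), 8)

  expect_equal(nrow(ebsa_groups()), 5)
  # catalogs are deterministic
  expect_identical(ebsa_indicators(), ind)
  expect_identical(ebsa_threats(), thr)
})

test_that("all case-study fixtures validate with zero errors", {
  recs <- case_study_seamounts()
  expect_equal(nrow(recs), 8 * 19)
  issues <- validate_records(recs)
  expect_equal(sum(issues$severity == "error"), 0)
  # Sedlo is the one internally inconsistent record: natural yet fished
  warnings <- issues[issues$severity == "warning", ]
  expect_equal(warnings$seamount, "Sedlo")
})

test_that("fixture transcription spot checks", {
  recs <- case_study_seamounts()
  obs <- function(sm, it) recs[recs$seamount == sm & recs$item == it, ]
  expect_equal(obs("Sedlo", "vents")$status, "absent")
  expect_equal(obs("Sedlo", "vents")$quality, "L")
  expect_equal(obs("Sedlo", "corals")$status, "present")
  expect_equal(obs("Sedlo", "threatened_visiting_pelagics")$status, "present")
  expect_equal(obs("Sedlo", "naturalness")$status, "present")
  # Rosemary: vents, sponges and the pelagic pair are data deficient
  expect_equal(obs("Rosemary", "vents")$status, "DD")
  expect_equal(obs("Rosemary", "sponges")$status, "DD")
  expect_equal(obs("Rosemary", "threatened_visiting_pelagics")$status, "DD")
  # Cobb: four data-deficient activities
  cobb_thr <- recs[recs$seamount == "Cobb" & recs$domain == "threat", ]
  expect_setequal(cobb_thr$item[cobb_thr$status == "DD"],
                  c("hook_and_line", "longline_pelagic", "purse_seine",
                    "mineral_extraction"))
})

test_that("records round-trip through CSV and JSON", {
  recs <- case_study_seamounts()
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_seamount_records(recs, path)
    back <- read_seamount_records(path)
    expect_equal(as.data.frame(back), as.data.frame(recs))
  }
})

test_that("packaged fixture files equal the in-code records", {
  recs <- case_study_seamounts()
  csv <- read_seamount_records(system.file(
    "extdata", "case_study_seamounts.csv", package = "seamountEBSA"))
  jsn <- read_seamount_records(system.file(
    "extdata", "case_study_seamounts.json", package = "seamountEBSA"))
  expect_equal(as.data.frame(csv), as.data.frame(recs))
  expect_equal(as.data.frame(jsn), as.data.frame(recs))
})

test_that("validation flags structural problems", {
  # both members of an OR-pair scored
  rec <- all_absent_record("bad")
  extra <- tibble::tibble(seamount = "bad", domain = "indicator",
                          item = "air_breathing", status = "present",
                          quality = "H")
  issues <- validate_records(dplyr::bind_rows(rec, extra))
  expect_true(any(grepl("OR-pair", issues$message)))
  expect_equal(sum(issues$severity == "error"), 1)

  # a near-empty record: everything missing except one data-deficient slot
  near_empty <- tibble::tibble(
    seamount = "void", domain = "indicator", item = "vents",
    status = "DD", quality = NA_character_)
  issues <- validate_records(near_empty)
  expect_equal(sum(issues$severity == "error"), 18)  # 9 slots + 9 threats

  # grade on a data-deficient observation
  rec2 <- all_absent_record("graded_dd")
  rec2$status[rec2$item == "vents"] <- "DD"
  issues <- validate_records(rec2)
  expect_true(any(grepl("data-deficient but carries", issues$message)))

  # unknown item id
  rec3 <- all_absent_record("alien")
  rec3$item[rec3$item == "vents"] <- "volcano_lairs"
  issues <- validate_records(rec3)
  expect_true(any(grepl("unknown indicator", issues$message)))
})
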