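test_that("portfolio mapping crosses the two categories, none on the low side", {
  expect_equal(as.character(portfolio_class("high", "low")), "highE_lowT")
  expect_equal(as.character(portfolio_class("low", "high")), "lowE_highT")
  expect_equal(as.character(portfolio_class("low", "none")), "lowE_lowT")
  expect_equal(as.character(portfolio_class("high", "none")), "highE_lowT")
  expect_equal(as.character(portfolio_class("high", "high")), "highE_highT")
  expect_error(portfolio_class("medium", "low"))
})

test_that("all four portfolio cells are reachable by constructed records", {
  pristine_rich <- all_present_record("p_rich") |>
    dplyr::mutate(status = ifelse(domain == "threat", "absent", status))
  pristine_poor <- all_absent_record("p_poor")
  fished_rich <- all_present_record("f_rich")
  fished_poor <- all_absent_record("f_poor") |>
    dplyr::mutate(status = ifelse(domain == "threat", "present", status))
  a <- suppressWarnings(assess_seamounts(dplyr::bind_rows(
    pristine_rich, pristine_poor, fished_rich, fished_poor)))
  expect_setequal(as.character(a$portfolio),
                  c("highE_lowT", "lowE_lowT", "highE_highT", "lowE_highT"))
})

test_that("the simulator is reproducible and respects its probabilities", {
  r1 <- simulate_seamounts(20, seed = 99)
  r2 <- simulate_seamounts(20, seed = 99)
  expect_identical(r1, r2)
  expect_equal(nrow(simulate_seamounts(0)), 0)
  expect_equal(dplyr::n_distinct(r1$seamount), 20)
  # all scored at high quality, no data deficiency
  expect_true(all(r1$status %in% c("present", "absent")))
  expect_true(all(r1$quality == "H"))
  # every record validates
  expect_equal(sum(validate_records(r1)$severity == "error"), 0)

  # extreme probabilities pin every slot
  all_on <- simulate_seamounts(3, p_indicator = 1, p_threatened = 1,
                               p_threat = 1, seed = 1)
  expect_true(all(all_on$status == "present"))
  expect_true(all(c("threatened_air_breathing",
                    "threatened_visiting_pelagics") %in% all_on$item))

  # mean number of present indicator slots ~ Binomial(10, 0.5)
  big <- simulate_seamounts(1000, seed = 2026)
  npresent <- big |>
    dplyr::filter(domain == "indicator", status == "present") |>
    dplyr::count(seamount) |>
    dplyr::pull(n)
  npresent <- c(npresent, rep(0, 1000 - length(npresent)))
  se <- sqrt(10 * 0.25 / 1000)
  expect_lt(abs(mean(npresent) - 5), 3 * se)
})

test_that("exact high-EBSA probability matches brute-force enumeration", {
  grid <- enumerate_indicator_patterns()
  pair_prob <- function(state, p, q) {
    c(absent = 1 - p, plain = p * (1 - q), threatened = p * q)[state]
  }
  for (pq in list(c(0.5, 0.5), c(0.3, 0.7), c(0.8, 0.2))) {
    p <- pq[1]; q <- pq[2]
    n_on <- rowSums(grid[, c("vents", "macrophytes", "corals", "sponges",
                             "aggregating_fish", "threatened_bottom_fish",
                             "naturalness", "depth_shallow")])
    prob <- p^n_on * (1 - p)^(8 - n_on) *
      pair_prob(grid$air, p, q) * pair_prob(grid$pel, p, q)
    expect_equal(sum(prob), 1, tolerance = 1e-12)
    oracle <- sum(prob[grid$W >= 11])
    expect_equal(ebsa_high_probability(p, q), unname(oracle),
                 tolerance = 1e-12)
  }
})

test_that("simulated portfolio proportions converge on the exact probability", {
  n <- 1500
  recs <- simulate_seamounts(n, seed = 314)
  props <- portfolio_proportions(recs)
  expect_equal(sum(props$prop), 1)
  expect_equal(levels(props$cell),
               c("lowE_lowT", "lowE_highT", "highE_lowT", "highE_highT"))
  p_exact <- ebsa_high_probability(0.5, 0.5)
  p_hat <- sum(props$prop[props$cell %in% c("highE_lowT", "highE_highT")])
  se <- sqrt(p_exact * (1 - p_exact) / n)
  expect_lt(abs(p_hat - p_exact), 3 * se)
})
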