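test_that("single-constraint fits behave as the arithmetic dictates", {
  fit <- fit_impact_matrix(tibble::tibble(
    activities = list("longline_pelagic"), score = 2.6))
  m <- as_impact_matrix(fit)
  expect_equal(sum(m["longline_pelagic", ]), 13)  # 5 * 2.6
  expect_equal(nrow(validate_matrix(m)), 0)
  expect_equal(fit$constraints$achieved, 2.6)
  # minimal severity + lexicographic: unconstrained rows sit at 1 and the
  # 13 units pile onto the last cells in group order
  expect_equal(unname(m["longline_pelagic", ]), c(1, 1, 1, 5, 5))

  # empty activity set can only support the floor score
  expect_error(
    fit_impact_matrix(tibble::tibble(activities = list(character(0)),
                                     score = 2.0)),
    class = "seamountEBSA_infeasible"
  )
  # ... but is fine at exactly 1
  fit0 <- fit_impact_matrix(tibble::tibble(
    activities = list(character(0)), score = 1.0))
  expect_equal(fit0$constraints$achieved, 1)
})

test_that("targets must be reachable rating sums", {
  expect_error(
    fit_impact_matrix(tibble::tibble(activities = list("purse_seine"),
                                     score = 2.53)),
    class = "seamountEBSA_bad_constraint"
  )
  expect_error(
    fit_impact_matrix(tibble::tibble(activities = list("purse_seine"),
                                     score = 5.2)),
    class = "seamountEBSA_bad_constraint"
  )
})

test_that("contradictory constraints report an unsatisfiable subset", {
  err <- tryCatch(
    fit_impact_matrix(tibble::tibble(
      name = c("low", "high"),
      activities = list("trawl_bottom", "trawl_bottom"),
      score = c(1.0, 5.0)
    )),
    error = identity
  )
  expect_s3_class(err, "seamountEBSA_infeasible")
  expect_match(conditionMessage(err), "unsatisfiable constraint subset")
})

test_that("solver agrees with exhaustive enumeration on reduced instances", {
  set.seed(11)
  acts <- c("gearA", "gearB", "gearC")
  grps <- c("g1", "g2", "g3")
  ratings <- 1:3
  n_checked <- 0
  for (i in 1:25) {
    cons <- random_small_constraints(acts, length(grps), ratings)
    oracle <- brute_force_fit(cons, acts, grps, ratings)
    got <- tryCatch(
      fit_impact_matrix(cons, activities = acts, groups = grps,
                        ratings = ratings),
      error = function(e) {
        expect_s3_class(e, "seamountEBSA_infeasible")
        NULL
      }
    )
    expect_equal(!is.null(got), oracle$feasible)
    if (oracle$feasible) {
      expect_equal(unname(as_impact_matrix(got)), unname(oracle$matrix))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 3)  # the random mix must exercise feasible systems
})

test_that("fit result methods expose the fit in tidy form", {
  fit <- fit_impact_matrix(tibble::tibble(
    activities = list(c("trawl_bottom", "purse_seine")), score = 3.0))
  td <- tidy(fit)
  expect_equal(nrow(td), 45)
  expect_setequal(unique(td$source), c("fitted", "prior"))
  expect_true(all(td$source[td$activity == "trawl_bottom"] == "fitted"))
  gl <- glance(fit)
  expect_equal(gl$n_constraints, 1)
  expect_equal(gl$max_constraint_error, 0)
  expect_output(print(fit), "Impact matrix fit")
})

test_that("the packaged default matrix satisfies every case-study constraint", {
  m <- default_impact_matrix()
  cons <- case_study_constraints()
  achieved <- vapply(cons$activities, function(a) {
    mean(apply(m[a, , drop = FALSE], 2, max))
  }, numeric(1))
  expect_equal(achieved, cons$score, tolerance = 1e-12)
  expect_equal(nrow(validate_matrix(m)), 0)
  # documented mineral-extraction prior row
  expect_equal(unname(m["mineral_extraction", ]), c(5, 5, 4, 2, 1))
})
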