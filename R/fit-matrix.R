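#' Reconstruct an impact matrix from published threat scores
#'
#' The published per-gear impact ratings are known only through the threat
#' scores they produce on documented activity sets. Each (activity set,
#' threat score) pair constrains the matrix: the per-group maxima over the
#' set must sum to `n_groups * score`. `fit_impact_matrix()` searches the
#' integer rating space by depth-first backtracking with constraint
#' propagation and returns the canonical solution under a tie-break
#' policy. The system is underdetermined (45 unknowns, a handful of
#' equality constraints), so the tie-break is part of the contract:
#' `"min_sum_lex"` (the default and currently only policy) picks the
#' matrix with the smallest total rating sum and, among those, the
#' lexicographically smallest in activity-major cell order — the least
#' severe matrix consistent with the evidence.
#'
#' Activities that appear in no constraint cannot be identified from the
#' scores; their rows are taken from `prior` (see
#' [default_impact_matrix()] for the documented prior used for seafloor
#' mineral extraction).
#'
#' @param constraints a tibble with a list-column `activities` (character
#'   vectors of activity ids) and a numeric column `score`, as returned by
#'   [read_score_constraints()]; a `name` column is used in messages when
#'   present.
#' @param activities character vector of activity ids (matrix rows);
#'   default the nine catalog activities.
#' @param groups character vector of ecological-group ids (matrix
#'   columns); default the five catalog groups.
#' @param ratings contiguous integer rating scale, default `1:5`.
#' @param prior named list or matrix giving rating rows for activities not
#'   covered by any constraint; activities missing from `prior` default to
#'   the minimum rating.
#' @param tie_break canonical-solution policy; only `"min_sum_lex"`.
#' @return An object of class `impact_fit`: see [tidy.impact_fit()] and
#'   [glance.impact_fit()]; `as_impact_matrix()` extracts the matrix.
#' @examples
#' fit <- fit_impact_matrix(tibble::tibble(
#'   activities = list("longline_pelagic"), score = 2.6
#' ))
#' sum(as_impact_matrix(fit)["longline_pelagic", ])  # 13 = 5 * 2.6
#' @export
fit_impact_matrix <- function(constraints,
                              activities = ebsa_threats()$item,
                              groups = ebsa_groups()$group,
                              ratings = 1:5,
                              prior = NULL,
                              tie_break = "min_sum_lex") {
  tie_break <- match.arg(tie_break)
  constraints <- normalise_constraints(constraints, activities, groups, ratings)

  rmin <- min(ratings)
  rmax <- max(ratings)
  ng <- length(groups)

  # an empty activity set forces every group maximum to rmin
  empty <- lengths(constraints$activities) == 0
  base_target <- ng * rmin
  if (any(empty & constraints$target != base_target)) {
    infeasible_error(constraints[empty & constraints$target != base_target, ],
                     "an empty activity set forces the minimum threat score")
  }
  work <- constraints[!empty, , drop = FALSE]

  con_acts <- sort(match(unique(unlist(work$activities)), activities))
  free_acts <- activities[con_acts]
  m <- matrix(rmin, nrow = length(activities), ncol = ng,
              dimnames = list(activities, groups))
  if (nrow(work) > 0) {
    sol <- solve_matrix_cells(work, free_acts, groups, rmin, rmax)
    if (is.null(sol)) {
      subset <- diagnose_infeasible(work, free_acts, groups, rmin, rmax)
      infeasible_error(subset, "no rating matrix satisfies these constraints")
    }
    m[free_acts, ] <- sol
  }
  for (a in setdiff(activities, free_acts)) {
    pr <- prior_row(prior, a, ng, groups)
    if (!is.null(pr)) m[a, ] <- pr
  }

  achieved <- purrr::map_dbl(constraints$activities, function(acts) {
    if (length(acts) == 0) return(rmin)
    mean(apply(m[acts, , drop = FALSE], 2, max))
  })
  structure(
    list(
      matrix = m,
      constraints = dplyr::mutate(constraints, achieved = achieved),
      fitted_activities = free_acts,
      prior_activities = setdiff(activities, free_acts),
      total_sum = sum(m[free_acts, ]),
      tie_break = tie_break,
      ratings = ratings
    ),
    class = "impact_fit"
  )
}

normalise_constraints <- function(constraints, activities, groups, ratings) {
  if (!is.data.frame(constraints)) {
    constraints <- tibble::tibble(
      activities = purrr::map(constraints, ~ as.character(.x$activities)),
      score = purrr::map_dbl(constraints, "score"),
      name = purrr::map_chr(constraints, ~ .x$name %||% NA_character_)
    )
  }
  constraints <- tibble::as_tibble(constraints)
  if (!"name" %in% names(constraints)) {
    constraints$name <- paste0("constraint_", seq_len(nrow(constraints)))
  }
  bad <- setdiff(unlist(constraints$activities), activities)
  if (length(bad) > 0) abort_bad_items(bad, "threat")
  ng <- length(groups)
  target <- constraints$score * ng
  if (any(abs(target - round(target)) > 0.005 * ng |
          round(target) < ng * min(ratings) | round(target) > ng * max(ratings))) {
    rlang::abort(
      sprintf("each target score times %d must be an integer between %d and %d",
              ng, ng * min(ratings), ng * max(ratings)),
      class = "seamountEBSA_bad_constraint"
    )
  }
  constraints$target <- as.integer(round(target))
  constraints
}

infeasible_error <- function(subset, why) {
  desc <- sprintf("  %s: {%s} -> %.2f", subset$name,
                  purrr::map_chr(subset$activities, paste, collapse = ", "),
                  subset$score)
  rlang::abort(
    paste0("no matrix exists: ", why, "\nunsatisfiable constraint subset:\n",
           paste(desc, collapse = "\n")),
    class = "seamountEBSA_infeasible"
  )
}

# identify a small unsatisfiable subset: try singletons, then grow greedily
diagnose_infeasible <- function(work, free_acts, groups, rmin, rmax) {
  for (i in seq_len(nrow(work))) {
    if (is.null(solve_matrix_cells(work[i, ], free_acts, groups, rmin, rmax))) {
      return(work[i, ])
    }
  }
  keep <- 1L
  for (i in seq_len(nrow(work))[-1]) {
    cand <- c(keep, i)
    if (is.null(solve_matrix_cells(work[cand, ], free_acts, groups,
                                   rmin, rmax))) {
      return(work[cand, ])
    }
    keep <- cand
  }
  work
}

prior_row <- function(prior, activity, ng, groups) {
  if (is.null(prior)) return(NULL)
  if (is.matrix(prior)) {
    if (activity %in% rownames(prior)) return(prior[activity, groups])
    return(NULL)
  }
  if (activity %in% names(prior)) return(prior[[activity]])
  NULL
}

# Backtracking search over the cells of the constrained activities,
# delegated to compiled code (src/solver.cpp): a branch-and-bound pass
# proves the minimal total rating sum, then a lexicographic pass in
# catalog cell order returns the canonical matrix at that sum. The search
# pass visits activities in an order that completes small constraints
# early (fail-first); the canonical order stays activity-major over the
# catalog, which is what the tie-break is defined on.
# Returns the solved sub-matrix (free activities x groups) or NULL.
solve_matrix_cells <- function(work, free_acts, groups, rmin, rmax) {
  na <- length(free_acts)
  if (na == 0) return(NULL)
  member_idx <- lapply(work$activities, function(a) match(a, free_acts))

  # greedy search order: repeatedly take the constraint with the fewest
  # activities not yet placed and append those activities
  remaining <- seq_len(na)
  order_out <- integer(0)
  sets <- lapply(member_idx, identity)
  while (length(remaining) > 0) {
    open <- vapply(sets, function(s) length(intersect(s, remaining)),
                   integer(1))
    open[open == 0] <- NA
    if (all(is.na(open))) {
      order_out <- c(order_out, remaining)
      break
    }
    pick <- which.min(open)
    add <- intersect(sets[[pick]], remaining)
    order_out <- c(order_out, add)
    remaining <- setdiff(remaining, add)
  }

  sol <- .solve_impact_cells(na, length(groups), as.integer(rmin),
                             as.integer(rmax), member_idx,
                             as.integer(work$target),
                             as.integer(order_out))
  if (is.null(sol)) return(NULL)
  dimnames(sol) <- list(free_acts, groups)
  sol
}

#' Read threat-score constraints from JSON
#'
#' Format: a JSON array of objects `{"name": ..., "activities": [...],
#' "score": x.xx}` (`name` optional).
#'
#' @param path JSON file path.
#' @return A tibble with columns `name`, `activities` (list-column),
#'   `score`.
#' @export
read_score_constraints <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tibble::tibble(
    name = purrr::imap_chr(raw, ~ .x$name %||% paste0("constraint_", .y)),
    activities = purrr::map(raw, ~ as.character(unlist(.x$activities))),
    score = purrr::map_dbl(raw, "score")
  )
}

#' @export
print.impact_fit <- function(x, ...) {
  cat(sprintf(
    "Impact matrix fit: %d activities x %d groups, %d constraint(s)\n",
    nrow(x$matrix), ncol(x$matrix), nrow(x$constraints)))
  cat(sprintf("tie-break: %s; fitted rating sum: %d\n",
              x$tie_break, as.integer(x$total_sum)))
  if (length(x$prior_activities) > 0) {
    cat("prior (unconstrained) rows:",
        paste(x$prior_activities, collapse = ", "), "\n")
  }
  print(x$matrix)
  invisible(x)
}

#' Tidy an impact-matrix fit
#'
#' One row per matrix cell, flagging whether the rating was identified by
#' the constraints or taken from the prior.
#'
#' @param x an `impact_fit` from [fit_impact_matrix()].
#' @param ... unused.
#' @return A tibble with columns `activity`, `group`, `rating`, `source`
#'   (`"fitted"`/`"prior"`).
#' @export
tidy.impact_fit <- function(x, ...) {
  m <- x$matrix
  tibble::tibble(
    activity = rep(rownames(m), times = ncol(m)),
    group = rep(colnames(m), each = nrow(m)),
    rating = as.integer(as.vector(m)),
    source = ifelse(rep(rownames(m), times = ncol(m)) %in% x$fitted_activities,
                    "fitted", "prior")
  ) |>
    dplyr::arrange(match(.data$activity, rownames(m)),
                   match(.data$group, colnames(m)))
}

#' Glance at an impact-matrix fit
#'
#' @inheritParams tidy.impact_fit
#' @return A one-row tibble: `n_constraints`, `n_fitted_activities`,
#'   `n_prior_activities`, `fitted_rating_sum`, `max_constraint_error`
#'   (largest absolute difference between a target score and the score the
#'   fitted matrix reproduces; 0 for a successful fit).
#' @export
glance.impact_fit <- function(x, ...) {
  tibble::tibble(
    n_constraints = nrow(x$constraints),
    n_fitted_activities = length(x$fitted_activities),
    n_prior_activities = length(x$prior_activities),
    fitted_rating_sum = as.integer(x$total_sum),
    max_constraint_error = max(abs(x$constraints$achieved -
                                     x$constraints$score), 0)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
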