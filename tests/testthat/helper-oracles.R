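# Independent brute-force oracles, deliberately written against the raw
# definitions rather than through the package's own code paths.

# enumerate every indicator configuration of the default catalog:
# 8 non-pair slots in {absent, present} x 2 pair slots in
# {absent, plain, threatened}; returns a tibble of configurations with the
# weight sum computed by direct summation of the catalog weights
enumerate_indicator_patterns <- function() {
  singles <- c(vents = 3, macrophytes = 3, corals = 3, sponges = 3,
               aggregating_fish = 2, threatened_bottom_fish = 1,
               naturalness = 1, depth_shallow = 1)
  single_states <- expand.grid(rep(list(c(FALSE, TRUE)), length(singles)))
  names(single_states) <- names(singles)
  pair_states <- expand.grid(air = c("absent", "plain", "threatened"),
                             pel = c("absent", "plain", "threatened"),
                             stringsAsFactors = FALSE)
  grid <- merge(cbind(single_states, idx1 = seq_len(nrow(single_states))),
                cbind(pair_states, idx2 = seq_len(nrow(pair_states))))
  pair_w <- c(absent = 0, plain = 1, threatened = 2)
  grid$W <- as.vector(as.matrix(grid[names(singles)]) %*% singles) +
    pair_w[grid$air] + pair_w[grid$pel]
  grid
}

# long record tibble for every enumerated pattern (one synthetic seamount
# per configuration), quality high everywhere
patterns_as_records <- function(grid) {
  singles <- c("vents", "macrophytes", "corals", "sponges",
               "aggregating_fish", "threatened_bottom_fish",
               "naturalness", "depth_shallow")
  n <- nrow(grid)
  ids <- sprintf("cfg_%04d", seq_len(n))
  single_rows <- do.call(rbind, lapply(singles, function(it) {
    data.frame(seamount = ids, domain = "indicator", item = it,
               status = ifelse(grid[[it]], "present", "absent"),
               quality = "H")
  }))
  pair_rows <- do.call(rbind, lapply(c("air", "pel"), function(p) {
    thr <- if (p == "air") "threatened_air_breathing" else
      "threatened_visiting_pelagics"
    pl <- if (p == "air") "air_breathing" else "visiting_pelagics"
    data.frame(
      seamount = ids, domain = "indicator",
      item = ifelse(grid[[p]] == "plain", pl, thr),
      status = ifelse(grid[[p]] == "absent", "absent", "present"),
      quality = "H"
    )
  }))
  thr_rows <- do.call(rbind, lapply(ebsa_threats()$item, function(it) {
    data.frame(seamount = ids, domain = "threat", item = it,
               status = "absent", quality = "H")
  }))
  tibble::as_tibble(rbind(single_rows, pair_rows, thr_rows))
}

# exhaustive reference solver for small impact-matrix instances:
# enumerates every rating matrix, returns list(feasible=, matrix=) where
# matrix is the min-sum then lexicographically-smallest (activity-major
# cell order) satisfying matrix
brute_force_fit <- function(constraints, activities, groups, ratings) {
  na <- length(activities)
  ng <- length(groups)
  cells <- expand.grid(rep(list(ratings), na * ng))
  # column j of cells = cell j in activity-major order: activity
  # ceiling(j/ng), group ((j-1) %% ng) + 1
  ok <- rep(TRUE, nrow(cells))
  for (k in seq_len(nrow(constraints))) {
    acts <- match(constraints$activities[[k]], activities)
    target <- round(constraints$score[k] * ng)
    if (length(acts) == 0) {
      ok <- ok & (target == ng * min(ratings))
      next
    }
    tot <- 0
    for (g in seq_len(ng)) {
      cols <- (acts - 1) * ng + g
      tot <- tot + do.call(pmax, cells[, cols, drop = FALSE])
    }
    ok <- ok & (tot == target)
  }
  if (!any(ok)) return(list(feasible = FALSE, matrix = NULL))
  feas <- cells[ok, , drop = FALSE]
  sums <- rowSums(feas)
  feas <- feas[sums == min(sums), , drop = FALSE]
  ord <- do.call(order, as.list(feas))
  best <- as.numeric(feas[ord[1], ])
  m <- matrix(best, nrow = na, ncol = ng, byrow = TRUE,
              dimnames = list(activities, groups))
  list(feasible = TRUE, matrix = m)
}

# random small constraint system over the given activities
random_small_constraints <- function(activities, ng, ratings) {
  k <- sample(1:3, 1)
  tibble::tibble(
    name = paste0("c", seq_len(k)),
    activities = lapply(seq_len(k), function(i) {
      sample(activities, sample(seq_along(activities), 1))
    }),
    score = replicate(k, sample(seq(ng * min(ratings), ng * max(ratings)),
                                1) / ng)
  )
}
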