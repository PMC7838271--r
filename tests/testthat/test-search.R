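test_that("solution-space counts are exact", {
  expect_equal(count_panels(8, 19, 5)$count, "78140160")
  expect_equal(count_panels(8, 16, 4)$count, "3057600")
  expect_equal(count_panels(1, 1, 1)$count, "1")
  # bignum path: C(188,19 choose is irrelevant) - value beyond 2^53
  big <- count_panels(188, 19, 10)
  expect_equal(nchar(big$count), 28)
  expect_gt(big$approx, 3.99e27)
  # against R's double arithmetic where it is exact
  expect_equal(count_panels(12, 7, 3)$approx, choose(12, 3) * prod(7:5))
  expect_error(count_panels(2, 2, 3), "exceeds")
})

test_that("counts agree with literal enumeration for all small instances", {
  for (F in 2:5) for (D in 2:5) for (n in 1:min(F, D, 3)) {
    fl <- paste0("f", 1:F)
    dt <- paste0("d", 1:D)
    pans <- enumerate_panels(fl, dt, n)
    expect_equal(length(pans), count_panels(F, D, n)$approx)
    # every panel distinct
    keys <- vapply(pans, function(p)
      paste(p$fluorophores, p$detectors, collapse = "|"), character(1))
    expect_equal(anyDuplicated(keys), 0L)
  }
})

test_that("valid-panel counting by subset permanents matches enumeration", {
  set.seed(5)
  for (rep in 1:5) {
    F <- sample(3:6, 1); D <- sample(3:6, 1); n <- sample(2:3, 1)
    n <- min(n, F, D)
    S <- manual_matrix(ifelse(runif(F * D) < 0.5, 0, round(runif(F * D), 2)),
                       paste0("f", 1:F), paste0("d", 1:D))
    literal <- sum(vapply(enumerate_panels(rownames(S), colnames(S), n),
                          is_valid_panel, logical(1), S = S))
    expect_equal(count_valid_panels(S, n), literal)
  }
})

test_that("exhaustive ranking equals the comparator-driven oracle sort", {
  set.seed(11)
  for (rep in 1:3) {
    F <- sample(4:5, 1); D <- sample(4:6, 1); n <- 3L
    lib <- generate_library(synthetic_spec(n_fluorophores = F,
                                           seed = 100 + rep))
    inst <- generate_instrument(laser_wavelengths = c(405, 488, 561),
                                detectors_per_laser = c(2, 2, 2)[1:3],
                                bandpass_width = 40)
    inst$detectors <- inst$detectors[seq_len(D)]
    S <- build_signal_matrix(lib, inst)
    res <- exhaustive_search(lib, inst, n, S = S)
    # oracle: score every enumerated panel, keep valid, merge-sort by the
    # pairwise comparator only
    pans <- enumerate_panels(lib, inst, n)
    scored <- Filter(function(x) x$score$valid,
                     lapply(pans, function(p)
                       list(panel = p, score = score_panel(p, S))))
    expect_equal(nrow(res$table), length(scored))
    if (!length(scored)) next
    oracle <- oracle_sort_scores(scored)
    for (i in seq_along(oracle)) {
      row_sc <- panel_score(res$table$within_eta_count[i],
                            res$table$geomean_signal[i],
                            res$table$mean_bleedthrough[i], eta = res$eta)
      expect_equal(compare_panels(row_sc, oracle[[i]]$score), "equivalent")
    }
  }
})

test_that("exhaustive output is totally ordered and ties share lowest rank", {
  lib <- generate_library(synthetic_spec(n_fluorophores = 5, seed = 2))
  inst <- generate_instrument(laser_wavelengths = c(488, 561),
                              detectors_per_laser = c(2, 2))
  res <- exhaustive_search(lib, inst, 2)
  tab <- res$table
  for (i in seq_len(nrow(tab) - 1L)) {
    a <- panel_score(tab$within_eta_count[i], tab$geomean_signal[i],
                     tab$mean_bleedthrough[i])
    b <- panel_score(tab$within_eta_count[i + 1], tab$geomean_signal[i + 1],
                     tab$mean_bleedthrough[i + 1])
    expect_true(compare_panels(b, a) != "A_better")
    if (compare_panels(a, b) == "equivalent")
      expect_equal(tab$rank[i + 1], tab$rank[i])
    else expect_equal(tab$rank[i + 1], i + 1L)
  }
})

test_that("empty-validity instances return an empty ranking, not an error", {
  S <- manual_matrix(rep(0, 4), c("f1", "f2"), c("d1", "d2"))
  lib <- paste0("f", 1:2)
  res <- exhaustive_search(S = S, lib, NULL, 2)
  expect_equal(nrow(res$table), 0L)
  expect_null(best_panel(res))
  expect_equal(res$n_valid, 0)
})

test_that("budget guard refuses huge spaces without force", {
  lib <- generate_library(synthetic_spec(n_fluorophores = 8, seed = 1))
  inst <- generate_instrument()
  expect_error(exhaustive_search(lib, inst, 5, budget = 1e6), "budget")
})

test_that("neighbor proposals change exactly one assignment (or permute two)", {
  lib <- paste0("f", 1:6)
  dts <- paste0("d", 1:6)
  pan <- panel(lib[1:3], dts[1:3])
  set.seed(1)
  moved_fl <- moved_dt <- 0L
  for (i in 1:200) {
    nb <- propose_neighbor(pan, lib, list(detectors =
      stats::setNames(as.list(dts), dts)))
    expect_s3_class(nb, "panel")
    expect_equal(nb$n, 3L)
    dfl <- length(setdiff(nb$fluorophores, pan$fluorophores))
    ddt <- length(setdiff(nb$detectors, pan$detectors))
    expect_lte(dfl + ddt, 1L)   # one new fluorophore OR one new detector
    if (dfl == 1L) moved_fl <- moved_fl + 1L
    if (ddt == 1L) moved_dt <- moved_dt + 1L
  }
  # both move types occur when resources are free
  expect_gt(moved_fl, 50L)
  expect_gt(moved_dt, 50L)
})

test_that("with no unused resources only detector permutations remain", {
  lib <- paste0("f", 1:3)
  dts <- paste0("d", 1:3)
  pan <- panel(lib, dts)
  set.seed(2)
  for (i in 1:50) {
    nb <- propose_neighbor(pan, lib, dts)
    expect_setequal(nb$fluorophores, lib)
    expect_setequal(nb$detectors, dts)
  }
})

test_that("energy is zero only for perfect panels and penalizes invalidity", {
  perfect <- manual_matrix(c(1, 0,
                             0, 1), c("f1", "f2"), c("d1", "d2"))
  pan <- panel(c("f1", "f2"), c("d1", "d2"))
  expect_equal(sa_energy(pan, perfect), 0)
  dead <- manual_matrix(rep(0, 4), c("f1", "f2"), c("d1", "d2"))
  expect_gte(sa_energy(pan, dead), 4)   # n * n penalty for all-zero signals
})

test_that("energy ordering respects tier-1 comparisons", {
  # any within-eta advantage must yield strictly lower energy, whatever the
  # lower tiers do (bounded contributions 0.5 + 0.25)
  set.seed(13)
  for (rep in 1:200) {
    n <- 4L
    w1 <- sample(0:n, 1); w2 <- sample(0:n, 1)
    g1 <- runif(1); g2 <- runif(1)
    b1 <- runif(1, 0, 2); b2 <- runif(1, 0, 2)
    E <- function(w, g, b) (n - w) + 0.5 * (1 - min(g, 1)) +
      0.25 * min(b, 1)
    if (w1 > w2) expect_lt(E(w1, g1, b1), E(w2, g2, b2))
  }
})

test_that("annealing is deterministic given a seed and never returns invalid", {
  lib <- generate_library(synthetic_spec(n_fluorophores = 6, seed = 4))
  inst <- generate_instrument(laser_wavelengths = c(405, 488, 561),
                              detectors_per_laser = c(2, 2, 2))
  S <- build_signal_matrix(lib, inst)
  r1 <- simulated_annealing(lib, inst, 3, seed = 99, S = S)
  r2 <- simulated_annealing(lib, inst, 3, seed = 99, S = S)
  expect_identical(r1$panel, r2$panel)
  expect_identical(r1$score, r2$score)
  expect_true(is_valid_panel(r1$panel, S))
  expect_equal(r1$iterations, 9206L)
  # RNG state of the caller is untouched
  set.seed(123); before <- runif(1)
  set.seed(123)
  invisible(simulated_annealing(lib, inst, 3, seed = 1, S = S))
  expect_equal(runif(1), before)
})

test_that("annealing signals when no valid panel exists", {
  S <- manual_matrix(rep(0, 6), c("f1", "f2"), c("d1", "d2", "d3"))
  lib <- fluorophore_library(list(
    generate_fluorophore("f1", 400, 450), generate_fluorophore("f2", 500, 550)))
  r <- simulated_annealing(lib, NULL, 2, seed = 1, S = S)
  expect_false(r$found)
  expect_null(r$panel)
  rm <- multistart_sa(lib, NULL, 2, params = sa_params(restarts = 3), S = S)
  expect_false(rm$found)
})

test_that("multistart equals single run for restarts = 1 and never loses to members", {
  lib <- generate_library(synthetic_spec(n_fluorophores = 6, seed = 4))
  inst <- generate_instrument(laser_wavelengths = c(405, 488, 561),
                              detectors_per_laser = c(2, 2, 2))
  S <- build_signal_matrix(lib, inst)
  single <- simulated_annealing(lib, inst, 3, seed = 5, S = S)
  multi1 <- multistart_sa(lib, inst, 3,
                          params = sa_params(restarts = 1, seed = 5), S = S)
  expect_identical(multi1$panel, single$panel)
  best8 <- multistart_sa(lib, inst, 3,
                         params = sa_params(restarts = 8, seed = 5), S = S)
  for (i in 0:7) {
    run <- simulated_annealing(lib, inst, 3, seed = 5 + i, S = S)
    if (run$found)
      expect_true(compare_panels(best8$score, run$score) != "B_better")
  }
  # monotone-ish in restarts under the same seed stream
  best4 <- multistart_sa(lib, inst, 3,
                         params = sa_params(restarts = 4, seed = 5), S = S)
  expect_true(compare_panels(best8$score, best4$score) != "B_better")
})
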