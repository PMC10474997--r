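.tt <- function(states, ...) transition_table(states, ...)

test_that("permutation preserves each species' transition multiset, every draw", {
  set.seed(3)
  codes <- c("--", "++", "-+", "+-")
  states <- cbind(A = sample(codes, 15, TRUE), B = sample(codes, 15, TRUE))
  rownames(states) <- paste0("P", 1:15)
  tt <- .tt(states)
  ref <- apply(states, 2, function(v) table(factor(v, codes)))
  for (i in 1:200) {
    p <- permute_transitions(tt)
    expect_identical(apply(unclass(p), 2, function(v) table(factor(v, codes))), ref)
  }
})

test_that("a constant species is unchanged by permutation", {
  states <- cbind(A = rep("++", 6), B = c("--", "--", "-+", "+-", "++", "++"))
  rownames(states) <- paste0("P", 1:6)
  tt <- .tt(states)
  set.seed(1)
  p <- permute_transitions(tt)
  expect_identical(unname(p[, "A"]), rep("++", 6))
})

test_that("joint site-assignments are uniform over the enumeration", {
  # 4 sites, each species showing each state once: 24 x 24 = 576 equally
  # likely joint assignments, identifiable because states are distinct
  codes <- c("--", "++", "-+", "+-")
  states <- cbind(A = codes, B = codes[c(2, 3, 4, 1)])
  rownames(states) <- paste0("P", 1:4)
  tt <- .tt(states)
  set.seed(99)
  n <- 100000
  ids <- character(n)
  for (i in seq_len(n)) {
    p <- permute_transitions(tt)
    ids[i] <- paste(c(p[, 1], p[, 2]), collapse = "")
  }
  counts <- table(ids)
  expect_identical(length(counts), 576L)
  gof <- suppressWarnings(chisq.test(as.vector(counts), p = rep(1 / 576, 576)))
  expect_gt(gof$p.value, 0.01)
})

test_that("identical tables and configs reproduce identical test results", {
  ds <- make_scenario("strong_avoidance", seed = 2, n_sites = 25)
  tt <- encode_transitions(ds$truth, c(1, 2))
  r1 <- suppressMessages(cooc_test(tt, n_perm = 400, seed = 31))
  r2 <- suppressMessages(cooc_test(tt, n_perm = 400, seed = 31))
  expect_identical(r1[names(r1) != "config"], r2[names(r2) != "config"])
})

test_that("identical transition vectors give the analytic null and tail", {
  # both species: each state at exactly 2 of 8 sites, identically arranged.
  # The (A ++, B ++) cell has empirical 1; under permutation the overlap of
  # the two 2-site sets is hypergeometric(8, 2, 2): mean 0.5 -> null mean of
  # the proportion 0.25, and P(overlap = 2) = 1/28.
  codes <- c("--", "++", "-+", "+-")
  v <- rep(codes, each = 2)
  states <- cbind(A = v, B = v)
  rownames(states) <- paste0("P", 1:8)
  res <- cooc_test(.tt(states), n_perm = 20000, seed = 5)
  expect_equal(res$empirical$proportions["A:++", "B:++"], 1)
  p_exact <- 1 / 28
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_equal(res$null_mean["A:++", "B:++"], 0.25, tolerance = 3 * sqrt(0.25 * 0.75 / 2) / sqrt(20000) / 0.25)
  expect_lt(abs(res$p_upper["A:++", "B:++"] - p_exact), 3 * se + 2 / 20000)
})

test_that("Monte-Carlo p-values match exhaustive enumeration on a 4-site table", {
  states <- cbind(A = c("++", "++", "--", "+-"), B = c("++", "--", "--", "-+"))
  rownames(states) <- paste0("P", 1:4)
  exact <- exact_two_species_null(states)
  res <- cooc_test(.tt(states), n_perm = 20000, seed = 17, scope = "all_cells")
  B <- 20000
  for (r in rownames(exact$empirical)) {
    for (c in colnames(exact$empirical)) {
      if (is.na(exact$empirical[r, c]) || !res$tested[r, c]) next
      for (side in c("p_upper", "p_lower")) {
        pe <- exact[[side]][r, c]
        se <- sqrt(pe * (1 - pe) / B)
        expect_lt(abs(res[[side]][r, c] - pe), 3 * se + 2 / B)
      }
    }
  }
})

test_that("a degenerate null pins p-values at 1 with no direction", {
  states <- cbind(A = rep("++", 8), B = rep(c("--", "++"), 4))
  rownames(states) <- paste0("P", 1:8)
  res <- cooc_test(.tt(states), n_perm = 200, seed = 4)
  expect_equal(unname(res$p_upper["A:++", "B:--"]), 1)
  expect_equal(unname(res$p_lower["A:++", "B:--"]), 1)
  expect_identical(unname(res$direction["A:++", "B:--"]), "none")
})

test_that("permutation p-values are valid (never anti-conservative) under a true null", {
  # independent species: rejection rate at alpha = 0.05 must not exceed the
  # nominal level beyond binomial noise
  set.seed(123)
  n_rep <- 150
  rej <- 0L; n_ok <- 0L
  for (i in seq_len(n_rep)) {
    codes <- c("--", "++", "-+", "+-")
    states <- cbind(A = sample(codes, 20, TRUE, prob = c(.4, .3, .2, .1)),
                    B = sample(codes, 20, TRUE, prob = c(.3, .4, .1, .2)))
    rownames(states) <- paste0("P", 1:20)
    res <- suppressMessages(cooc_test(.tt(states), n_perm = 300))
    p <- res$p_two_sided["A:++", "B:++"]
    if (is.na(p)) next
    n_ok <- n_ok + 1L
    rej <- rej + (p <= 0.05)
  }
  rate <- rej / n_ok
  expect_lte(rate, 0.05 + 2.576 * sqrt(0.05 * 0.95 / n_ok))
})

test_that("relabelling species permutes result cells accordingly", {
  set.seed(8)
  codes <- c("--", "++", "-+", "+-")
  states <- cbind(A = sample(codes, 12, TRUE), B = sample(codes, 12, TRUE))
  rownames(states) <- paste0("P", 1:12)
  res1 <- suppressMessages(cooc_test(.tt(states), n_perm = 300, seed = 6))
  relab <- states
  colnames(relab) <- c("X", "Y")
  res2 <- suppressMessages(cooc_test(.tt(relab), n_perm = 300, seed = 6))
  m1 <- res1$empirical$proportions
  m2 <- res2$empirical$proportions
  expect_equal(unname(m1), unname(m2))
  expect_equal(unname(res1$p_two_sided), unname(res2$p_two_sided))
  expect_identical(rownames(m2), sub("^B", "Y", sub("^A", "X", rownames(m1))))
})

test_that("one-sided configurations only flag their own direction", {
  ds <- make_scenario("strong_avoidance", seed = 12)
  tt <- encode_transitions(ds$truth, c(1, 2))
  lo <- suppressMessages(cooc_test(tt, n_perm = 300, seed = 1, tail = "one_sided_lower"))
  expect_true(all(lo$direction %in% c("none", "less_than_expected")))
  up <- suppressMessages(cooc_test(tt, n_perm = 300, seed = 1, tail = "one_sided_upper"))
  expect_true(all(up$direction %in% c("none", "more_than_expected")))
})

test_that("result tables round-trip through the TSV writer", {
  ds <- make_scenario("paper_like", seed = 4)
  det <- call_detections(ds$wells, ds$curve, months = 1:3)
  tt <- encode_transitions(det$matrix, c(2, 3))
  res <- suppressMessages(cooc_test(tt, n_perm = 200, seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cooc_results(res, path, provenance = c(seed = 2))
  back <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  expect_identical(nrow(back), nrow(as.data.frame(res)))
  expect_equal(back$empirical, as.data.frame(res)$empirical)
  expect_identical(back$direction, as.data.frame(res)$direction)
})
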