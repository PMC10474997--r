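.two_month_dm <- function(m1, m2, species = c("A", "B")) {
  # m1, m2: site x species 0/1 matrices for the two months
  arr <- array(NA_integer_, dim = c(length(species), nrow(m1), 2),
               dimnames = list(species, rownames(m1) %||% paste0("P", seq_len(nrow(m1))),
                               c("1", "2")))
  arr[, , 1] <- t(m1); arr[, , 2] <- t(m2)
  detection_matrix(arr)
}

test_that("state pairs map to the four transition codes", {
  m1 <- cbind(A = c(1L, 0L, 1L, 0L), B = c(1L, 1L, 0L, 0L))
  m2 <- cbind(A = c(0L, 1L, 1L, 0L), B = c(1L, 0L, 0L, 0L))
  tt <- encode_transitions(.two_month_dm(m1, m2), c(1, 2))
  expect_identical(unname(tt[, "A"]), c("+-", "-+", "++", "--"))
  expect_identical(unname(tt[, "B"]), c("++", "+-", "--", "--"))
})

test_that("a site missing in either month is dropped for all species", {
  m1 <- cbind(A = c(1L, 1L, 0L), B = c(0L, 1L, 1L))
  m2 <- cbind(A = c(1L, 0L, 0L), B = c(0L, 1L, 1L))
  dm <- .two_month_dm(m1, m2)
  dm[, 2, "2"] <- NA_integer_  # site 2 unsampled in month 2
  tt <- encode_transitions(dm, c(1, 2))
  expect_identical(nrow(tt), 2L)
  expect_false("P2" %in% rownames(tt))
})

test_that("non-consecutive or absent month pairs are usage errors", {
  m <- cbind(A = c(1L, 0L), B = c(0L, 1L))
  dm <- .two_month_dm(m, m)
  expect_error(encode_transitions(dm, c(1, 3)), "consecutive")
  expect_error(encode_transitions(dm, c(2, 3)), "not both present")
})

test_that("transition counts are conserved across the four states", {
  ds <- make_scenario("paper_like", seed = 3)
  for (t in 1:2) {
    tt <- encode_transitions(ds$truth, c(t, t + 1))
    tab <- table(factor(tt[, "A1"], levels = c("--", "++", "-+", "+-")))
    expect_identical(sum(tab), nrow(tt))
  }
})

test_that("the worked proportions hold: half-accompanied gives 0.5, always-accompanied gives 1", {
  # species A persists at 14 sites; B disappears at exactly 7 of them
  states <- cbind(A = rep("++", 14),
                  B = c(rep("+-", 7), rep("--", 7)))
  rownames(states) <- sprintf("P%02d", 1:14)
  cm <- cooccurrence_matrix(transition_table(states))
  expect_equal(cm$proportions["A:++", "B:+-"], 0.5, tolerance = 0)
  # every B disappearance happens where A persists
  expect_equal(cm$proportions["B:+-", "A:++"], 1, tolerance = 0)
})

test_that("rows for events that never occur are undefined, not zero", {
  states <- cbind(A = c("++", "--", "++"), B = c("+-", "--", "++"))
  rownames(states) <- paste0("P", 1:3)
  cm <- cooccurrence_matrix(transition_table(states))
  expect_true(all(is.na(cm$proportions["A:-+", ])))
  expect_identical(unname(cm$row_counts["A:-+"]), 0L)
})

test_that("the matrix equals exhaustive site-by-site tabulation on small tables", {
  set.seed(5)
  codes <- c("--", "++", "-+", "+-")
  for (i in 1:20) {
    n <- sample(2:6, 1)
    states <- cbind(A = sample(codes, n, TRUE), B = sample(codes, n, TRUE),
                    C = sample(codes, n, TRUE))
    rownames(states) <- paste0("P", seq_len(n))
    cm <- cooccurrence_matrix(transition_table(states))
    oracle <- brute_cooc(states)
    expect_equal(cm$proportions, oracle$proportions)
    expect_equal(unname(cm$joint_counts), unname(oracle$joint_counts))
  }
})

test_that("row-conditional proportions over one column species sum to 1", {
  set.seed(9)
  codes <- c("--", "++", "-+", "+-")
  states <- cbind(A = sample(codes, 30, TRUE), B = sample(codes, 30, TRUE))
  rownames(states) <- paste0("P", 1:30)
  cm <- cooccurrence_matrix(transition_table(states))
  for (r in rownames(cm$proportions)) {
    if (cm$row_counts[r] == 0) next
    for (sp in c("A", "B")) {
      expect_equal(sum(cm$proportions[r, paste(sp, codes, sep = ":")]), 1)
    }
  }
  # same-species diagonal is 1 wherever the row event occurred
  occ <- names(which(cm$row_counts > 0))
  expect_true(all(cm$proportions[cbind(occ, occ)] == 1))
})

test_that("relabelling sites leaves the matrix unchanged", {
  set.seed(13)
  codes <- c("--", "++", "-+", "+-")
  states <- cbind(A = sample(codes, 12, TRUE), B = sample(codes, 12, TRUE))
  rownames(states) <- paste0("P", 1:12)
  cm1 <- cooccurrence_matrix(transition_table(states))
  shuffled <- states[sample(12), , drop = FALSE]
  rownames(shuffled) <- paste0("Q", 1:12)
  cm2 <- cooccurrence_matrix(transition_table(shuffled))
  expect_equal(cm1$proportions, cm2$proportions)
})

test_that("site summaries pool months and respect guild definitions", {
  roles <- c(A1 = "prey", F1 = "predator")
  # P1: prey only (May); P2: prey May + fish July -> co-occurrence; P3: nothing
  a1 <- rbind(P1 = c(1L, 0L, 0L), P2 = c(1L, 0L, 0L), P3 = c(0L, 0L, 0L))
  f1 <- rbind(P1 = c(0L, 0L, 0L), P2 = c(0L, 0L, 1L), P3 = c(0L, 0L, 0L))
  dm <- dm_build(A1 = a1, F1 = f1, roles = roles)
  s <- summarize_sites(dm)
  expect_identical(s$prey_only, c(TRUE, FALSE, FALSE))
  expect_identical(s$cooccur, c(FALSE, TRUE, FALSE))
  expect_identical(s$any_target, c(TRUE, TRUE, FALSE))
  summ <- summarize_study(dm)
  expect_equal(summ$fraction_cooccur, 1 / 3)
  expect_equal(summ$fraction_prey_any, 2 / 3)
  expect_true(summ$fraction_prey_only <= summ$fraction_prey_any)
  expect_true(summ$fraction_cooccur <=
                min(summ$fraction_prey_any, summ$fraction_fish_any))
})
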