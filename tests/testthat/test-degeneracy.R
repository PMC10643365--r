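verdict <- function(mean, Pp) list(posterior_mean = mean, Pp = Pp)

test_that("group assignment keys on excitatory motor afferents", {
  # both excitatory (group-level style estimates)
  expect_equal(assign_group(verdict(0.31, 0.90), verdict(0.66, 0.95)), "A")
  # only pSTS->M1
  expect_equal(assign_group(verdict(0.2, 0.6), verdict(0.5, 0.9)), "B")
  # only pOp->M1
  expect_equal(assign_group(verdict(0.3, 0.9), verdict(0.5, 0.6)), "C")
  # neither; definite inhibition still counts as D
  expect_equal(assign_group(verdict(-0.3, 0.99), verdict(-0.4, 0.99)), "D")
  # the threshold is strict: Pp exactly 0.75 does not qualify
  expect_equal(assign_group(verdict(0.3, 0.75), verdict(0.5, 0.75)), "D")
  # total over all sign/Pp combinations
  for (m1 in c(-0.2, 0, 0.2)) for (p1 in c(0.5, 0.9)) {
    expect_true(assign_group(verdict(m1, p1), verdict(-m1, p1)) %in%
                  c("A", "B", "C", "D"))
  }
})

test_that("neurological-model consistency requires group C with excitatory pSTS->pOp", {
  expect_true(neurological_consistent("C", verdict(0.3, 0.9)))
  expect_false(neurological_consistent("C", verdict(-0.25, 0.9)))
  expect_false(neurological_consistent("C", verdict(0.3, 0.6)))
  expect_false(neurological_consistent("A", verdict(0.3, 0.9)))
  expect_false(neurological_consistent("D", verdict(0.3, 0.9)))
})

test_that("membership entropy matches its closed-form values and bounds", {
  expect_equal(membership_entropy(c("A", "A", "A", "A")), 0)
  expect_equal(membership_entropy(c("A", "B", "C", "D")), log(4))
  expect_gt(membership_entropy(c("A", "B", "C", "D")), 1.3)
  expect_equal(membership_entropy(c("B", "B", "B", "C")), 0.5623,
               tolerance = 1e-4)
  # permutation invariance and bounds on random label sets
  set.seed(61)
  for (i in 1:20) {
    lab <- sample(c("A", "B", "C", "D"), 8, replace = TRUE)
    h <- membership_entropy(lab)
    expect_equal(h, membership_entropy(sample(lab)))
    expect_gte(h, 0)
    expect_lte(h, log(4) + 1e-12)
    expect_equal(h == 0, length(unique(lab)) == 1)
  }
  expect_error(membership_entropy(character(0)), "no labels")
})

test_that("cohort summaries agree with an independent brute-force recount", {
  set.seed(62)
  grid <- expand.grid(subject = 1:30, task = c("word", "pseudoword"),
                      configuration = c("c1", "c2", "c3", "c4"),
                      stringsAsFactors = FALSE)
  grid$label <- sample(c("A", "B", "C", "D"), nrow(grid), replace = TRUE,
                       prob = c(0.55, 0.2, 0.05, 0.2))
  grid$consistent <- grid$label == "C" & stats::runif(nrow(grid)) < 0.5
  rep_ <- summarise_cohort(tibble::as_tibble(grid))

  # fraction of subjects with >= 2 distinct groups, recounted by hand
  frac <- mean(vapply(unique(grid$subject), function(s) {
    length(unique(grid$label[grid$subject == s])) >= 2
  }, NA))
  expect_equal(rep_$summary$fraction_multi_group, frac)

  # per-subject-task entropy recounted by hand
  h_oracle <- vapply(seq_len(nrow(rep_$subject_entropy)), function(i) {
    s <- rep_$subject_entropy$subject[i]
    tk <- rep_$subject_entropy$task[i]
    membership_entropy(grid$label[grid$subject == s & grid$task == tk])
  }, 0)
  expect_equal(rep_$subject_entropy$entropy, h_oracle)

  # group counts total and per-cell recount
  expect_equal(sum(rep_$group_counts$n), nrow(grid))
  one <- rep_$group_counts[rep_$group_counts$task == "word" &
                             rep_$group_counts$configuration == "c2" &
                             rep_$group_counts$label == "A", ]
  expect_equal(one$n, sum(grid$label == "A" & grid$task == "word" &
                            grid$configuration == "c2"))
  expect_equal(rep_$summary$fraction_consistent, mean(grid$consistent))
})

test_that("an all-A cohort has zero entropy and no multi-group subjects", {
  grid <- expand.grid(subject = 1:5, task = "word",
                      configuration = c("c1", "c2"), stringsAsFactors = FALSE)
  grid$label <- "A"
  rep_ <- summarise_cohort(tibble::as_tibble(grid))
  expect_equal(rep_$mean_entropy$mean_entropy, 0)
  expect_equal(rep_$summary$fraction_multi_group, 0)
})

test_that("missing cells are reported, not imputed", {
  grid <- tibble::tibble(subject = c(1, 1), task = "word",
                         configuration = c("c1", "c2"),
                         label = c("A", NA))
  expect_error(summarise_cohort(grid), "missing")
  expect_error(summarise_cohort(grid[, -4]), "lacks columns")
})

test_that("task comparisons use rank-sum tests with Bonferroni correction", {
  counts <- function(A, B, C, D) {
    tibble::tibble(subject = seq_along(A), A = A, B = B, C = C, D = D)
  }
  set.seed(63)
  c1 <- counts(rpois(20, 2), rpois(20, 1), rpois(20, 0.3), rpois(20, 1))

  # identical distributions: adjusted p = 1.00
  res0 <- compare_group_distributions(c1, c1)
  expect_equal(res0$p_adjusted, rep(1, 4))

  # Bonferroni relation
  res1 <- compare_group_distributions(c1, counts(rpois(20, 2.3), rpois(20, 1),
                                                 rpois(20, 0.4), rpois(20, 1)))
  expect_equal(res1$p_adjusted, pmin(1, 4 * res1$p_value))

  # unequal subject sets are rejected
  c_bad <- c1; c_bad$subject <- c_bad$subject + 100
  expect_error(compare_group_distributions(c1, c_bad), "different subject")
})

test_that("a strong shift is detected, agreeing with a permutation oracle", {
  set.seed(64)
  a1 <- c(rep(2L, 10), rep(3L, 10))
  a2 <- c(rep(1L, 10), rep(2L, 10))
  t1 <- tibble::tibble(subject = 1:20, A = a1, B = 0L, C = 0L, D = 0L)
  t2 <- tibble::tibble(subject = 1:20, A = a2, B = 0L, C = 0L, D = 0L)
  res <- compare_group_distributions(t1, t2)
  pA <- res$p_value[res$group == "A"]
  expect_lt(res$p_adjusted[res$group == "A"], 0.05)

  # permutation oracle on the rank-sum statistic (1e5 draws)
  pooled <- c(a1, a2)
  r <- rank(pooled)
  obs <- sum(r[1:20])
  n_perm <- 1e5
  perm <- vapply(seq_len(n_perm), function(b) sum(r[sample(40, 20)]), 0)
  p_perm <- mean(abs(perm - mean(perm)) >= abs(obs - mean(perm)) - 1e-9)
  expect_lt(abs(pA - p_perm), 0.01)
})
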