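# Frozen expected values below were computed with a 30-digit arbitrary
# precision oracle (log2 evaluated via mpmath) on the worked single-position
# input p = (0.33, 0.33, 0.33, 0.01) against a uniform background.
fig_p <- c(A = 0.33, C = 0.33, G = 0.33, T = 0.01)
fig_rtilde <- c(A = 0.40053792958372874, C = 0.40053792958372874,
                G = 0.40053792958372874, T = -4.6438561897747247)

test_that("raw log ratios match the arbitrary-precision oracle", {
  s <- log_ratios(one_pos_probs(fig_p), "uniform")
  expect_equal(s$values[[1]], fig_rtilde, tolerance = 1e-14)
  expect_identical(s$mode, "raw")
  expect_identical(s$centering, "none")

  # identical distributions score zero everywhere
  p <- rand_simplex(5)
  s0 <- log_ratios(one_pos_probs(p), background(p))
  expect_true(all(abs(s0$values[[1]]) < 1e-12))

  expect_error(log_ratios(one_pos_probs(c(A = 1, C = 0, G = 0, T = 0)), "uniform"),
               regexp = "stabilize", class = "edl_domain_error")
})

test_that("median centering implements all three tie rules", {
  tie <- score_matrix(list(`1` = c(A = 0, B = 0, C = 1, D = 1)))
  expect_identical(median_center(tie, "conventional")$values[[1]],
                   c(A = -0.5, B = -0.5, C = 0.5, D = 0.5))
  expect_identical(median_center(tie, "smallest")$values[[1]],
                   c(A = 0, B = 0, C = 1, D = 1))
  expect_identical(median_center(tie, "largest")$values[[1]],
                   c(A = -1, B = -1, C = 0, D = 0))
  # a single symbol always centers to zero
  expect_identical(median_center(score_matrix(list(`1` = c(X = 5))), "largest")$values[[1]],
                   c(X = 0))
  # odd alphabets: all rules coincide at the middle order statistic
  v <- c(A = -2, B = 1, C = 7)
  for (rule in c("smallest", "conventional", "largest"))
    expect_identical(median_center(score_matrix(list(`1` = v)), rule)$values[[1]],
                     v - 1)
})

test_that("edlogo scores center the log ratios and report stack heights", {
  s <- edlogo_scores(one_pos_probs(fig_p), "uniform", rule = "conventional")
  expect_equal(s$values[[1]],
               c(A = 0, C = 0, G = 0, T = -5.0443941193584534),
               tolerance = 1e-14)
  expect_identical(s$mode, "edlogo")

  p <- rand_simplex(4)
  expect_true(all(abs(edlogo_scores(one_pos_probs(p), background(p))$values[[1]]) < 1e-12))

  tie <- score_matrix(list(`1` = c(A = 0, B = 0, C = 1, D = 1)))
  for (rule in c("smallest", "conventional", "largest"))
    expect_equal(stack_height(median_center(tie, rule), "1"), 2)
  expect_equal(stack_height(score_matrix(list(`1` = c(A = 0, B = 0))), "1"), 0)
  expect_error(stack_height(tie, "99"), class = "edl_lookup_error")
})

test_that("standard logo heights are frequencies scaled by information content", {
  s <- standard_logo_scores(one_pos_probs(c(A = 1, C = 0, G = 0, T = 0)))
  expect_equal(s$values[[1]], c(A = 2, C = 0, G = 0, T = 0))

  u <- standard_logo_scores(one_pos_probs(c(A = .25, C = .25, G = .25, T = .25)))
  expect_true(all(abs(u$values[[1]]) < 1e-12))

  # frozen from the arbitrary-precision entropy oracle
  s2 <- standard_logo_scores(one_pos_probs(fig_p))
  expect_equal(sum(s2$values[[1]]), 0.35009398839014421, tolerance = 1e-14)
  expect_equal(unname(s2$values[[1]]),
               c(0.11553101616874759, 0.11553101616874759,
                 0.11553101616874759, 0.0035009398839014421),
               tolerance = 1e-13)

  expect_error(standard_logo_scores(one_pos_probs(fig_p), n_ref = 1),
               class = "edl_validation_error")

  # stack height equals information content for random inputs
  set.seed(3)
  for (i in 1:20) {
    p <- rand_simplex(sample(2:9, 1))
    s <- standard_logo_scores(one_pos_probs(p))
    ic <- log2(length(p)) + sum(p * log2(p))
    expect_true(all(s$values[[1]] >= 0))
    expect_equal(stack_height(s, "1"), ic, tolerance = 1e-12)
  }
})

test_that("weighted-KL heights are p-weighted log ratios with signed depletion", {
  s <- wkl_scores(one_pos_probs(fig_p), "uniform")
  expect_equal(unname(s$values[[1]]),
               c(0.13217751676263048, 0.13217751676263048,
                 0.13217751676263048, -0.046438561897747247),
               tolerance = 1e-14)
  p <- rand_simplex(6)
  expect_true(all(abs(wkl_scores(one_pos_probs(p), background(p))$values[[1]]) < 1e-12))
  s1 <- wkl_scores(one_pos_probs(c(A = 1, C = 0, G = 0, T = 0)), "uniform")
  expect_equal(s1$values[[1]], c(A = 2, C = 0, G = 0, T = 0))
})

test_that("height differences are log-odds ratios, whatever the centering", {
  s <- edlogo_scores(one_pos_probs(fig_p), "uniform", rule = "conventional")
  expect_equal(log_odds(s, "1", "A", "T"), 5.0443941193584534, tolerance = 1e-14)
  expect_identical(log_odds(s, "1", "C", "C"), 0)
  expect_error(log_odds(s, "1", "A", "Z"), class = "edl_lookup_error")

  set.seed(5)
  for (i in 1:30) {
    n <- sample(2:8, 1)
    p <- rand_simplex(n)
    q <- rand_simplex(n, names(p))
    for (rule in c("smallest", "conventional", "largest")) {
      s <- edlogo_scores(one_pos_probs(p), background(q), rule)
      a <- sample(names(p), 1); b <- sample(names(p), 1)
      expect_equal(log_odds(s, "1", a, b),
                   log2((p[[a]] / p[[b]]) / (q[[a]] / q[[b]])),
                   tolerance = 1e-12)
    }
  }
})

test_that("the returned centering constant minimizes total stack height", {
  set.seed(7)
  for (n in 2:9) {
    for (i in 1:40) {
      v <- stats::setNames(rnorm(n, sd = 2), paste0("S", seq_len(n)))
      g <- min_stack_by_grid(v)
      for (rule in c("smallest", "conventional", "largest")) {
        r <- median_center(score_matrix(list(`1` = v)), rule)$values[[1]]
        expect_lte(sum(abs(r)), g$min + 1e-9)
      }
      if (n %% 2 == 0) {
        s <- sort(v)
        lo <- s[n / 2]; hi <- s[n / 2 + 1]
        inside <- seq(lo, hi, length.out = 7)
        f <- vapply(inside, function(c) sum(abs(v - c)), numeric(1))
        expect_true(all(abs(f - g$min) < 1e-9))
      }
    }
  }
})

test_that("conventional centering has the mirror property; smallest does not", {
  set.seed(9)
  for (i in 1:100) {
    n <- sample(2:8, 1)
    p <- rand_simplex(n)
    q <- rand_simplex(n, names(p))
    a <- edlogo_scores(one_pos_probs(p), background(q), "conventional")$values[[1]]
    b <- edlogo_scores(one_pos_probs(q), background(p), "conventional")$values[[1]]
    expect_true(max(abs(a + b)) < 1e-12)
  }
  # documented counterexample: an even alphabet with distinct central values
  p <- c(A = 0.2, C = 0.2, G = 0.3, T = 0.3)
  q <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  a <- edlogo_scores(one_pos_probs(p), background(q), "smallest")$values[[1]]
  b <- edlogo_scores(one_pos_probs(q), background(p), "smallest")$values[[1]]
  expect_gt(max(abs(a + b)), 0.1)
})

test_that("centered scores are invariant to constant shifts of the raw scores", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(1:9, 1)
    v <- stats::setNames(rnorm(n), paste0("S", seq_len(n)))
    k <- rnorm(1, sd = 10)
    for (rule in c("smallest", "conventional", "largest")) {
      r1 <- median_center(score_matrix(list(`1` = v)), rule)$values[[1]]
      r2 <- median_center(score_matrix(list(`1` = v + k)), rule)$values[[1]]
      expect_equal(r1, r2, tolerance = 1e-12)
    }
  }
})

test_that("median adjustment applies to externally supplied score matrices", {
  pssm <- score_matrix(matrix(c(1.2, -0.3, 0.4, 2.5,
                                0.1, 0.1, -1.0, 0.6),
                              nrow = 4,
                              dimnames = list(c("A", "C", "G", "T"), c("1", "2"))))
  adj <- median_center(pssm, "conventional")
  for (j in 1:2) {
    v <- adj$values[[j]]
    expect_equal(stats::median(v), 0, tolerance = 1e-12)
  }
  expect_identical(adj$centering, "conventional")
})
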