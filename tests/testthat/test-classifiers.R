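toy_2d <- function() {
  tibble::tibble(
    x1 = c(1, 2, 7, 8), x2 = c(1, 2, 7, 8),
    label = c("neg", "neg", "pos", "pos")
  )
}

test_that("Gaussian NB: symmetric toy gives 50/50 at the midpoint", {
  d <- tibble::tibble(x = c(-1.2, -1, -0.8, 0.8, 1, 1.2),
                      label = rep(c("a", "b"), each = 3))
  m <- fit_gaussian_nb(d)
  p <- predict(m, tibble::tibble(x = 0))
  expect_equal(p$a, 0.5, tolerance = 1e-9)
  expect_equal(p$b, 0.5, tolerance = 1e-9)
})

test_that("Gaussian NB posteriors match a manual Bayes computation", {
  d <- tibble::tibble(x = c(0, 2, 10, 12), label = c("a", "a", "b", "b"))
  m <- fit_gaussian_nb(d)
  q <- 4
  # hand Bayes: equal priors, class a ~ N(1, 2), class b ~ N(11, 2)
  la <- dnorm(q, 1, sqrt(2)); lb <- dnorm(q, 11, sqrt(2))
  p <- predict(m, tibble::tibble(x = q))
  expect_equal(p$a, la / (la + lb), tolerance = 1e-12)
  expect_equal(predict(m, tibble::tibble(x = q), type = "class"), "a")
})

test_that("probability rows sum to one for every classifier", {
  set.seed(17)
  d <- tibble::tibble(x1 = rnorm(60), x2 = rnorm(60),
                      label = rep(c("a", "b"), 30))
  new <- tibble::tibble(x1 = rnorm(25), x2 = rnorm(25))
  fits <- list(fit_gaussian_nb(d), fit_multinomial_nb(d),
               fit_decision_table(d), fit_logistic(d),
               fit_smo(d))
  for (m in fits) {
    p <- as.matrix(predict(m, new, type = "prob"))
    expect_true(all(p >= 0))
    expect_equal(unname(rowSums(p)), rep(1, nrow(new)), tolerance = 1e-9)
  }
})

test_that("Gaussian NB agrees with an independent reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(23)
  n <- 500
  d <- tibble::tibble(
    x1 = rnorm(n) + rep(c(0, 1.5), length.out = n),
    x2 = rnorm(n) - rep(c(0, 1), length.out = n),
    x3 = rnorm(n),
    label = rep(c("a", "b"), length.out = n)
  )
  ours <- predict(fit_gaussian_nb(d), d, type = "class")
  ref <- as.character(predict(
    e1071::naiveBayes(label ~ x1 + x2 + x3, data = as.data.frame(d)),
    as.data.frame(d)))
  expect_gte(mean(ours == ref), 0.99)
})

test_that("multinomial NB: large smoothing pulls posteriors to the priors", {
  set.seed(5)
  d <- tibble::tibble(x = c(rnorm(30, 0), rnorm(10, 3)),
                      label = rep(c("a", "b"), c(30, 10)))
  m <- fit_multinomial_nb(d, alpha = 1e8)
  p <- predict(m, tibble::tibble(x = 2.5))
  expect_equal(p$a, 0.75, tolerance = 1e-4)
  expect_equal(p$b, 0.25, tolerance = 1e-4)
})

test_that("multinomial NB matches a hand two-bin count ratio", {
  # feature splits cleanly into two bins; class a: 3 low 1 high, b: 1 low 3 high
  d <- tibble::tibble(x = c(0, 0, 0, 1, 0, 1, 1, 1),
                      label = rep(c("a", "b"), each = 4))
  m <- fit_multinomial_nb(d, n_bins = 2, alpha = 1)
  p <- predict(m, tibble::tibble(x = 0))
  # smoothed likelihoods: P(low|a) = 4/6, P(low|b) = 2/6, equal priors
  expect_equal(p$a, (4 / 6) / (4 / 6 + 2 / 6), tolerance = 1e-12)
})

test_that("multinomial NB survives unseen bins and constant features", {
  d <- tibble::tibble(x = c(1, 1.1, 1.2, 5, 5.1, 5.2), const = 1,
                      label = rep(c("a", "b"), each = 3))
  m <- fit_multinomial_nb(d, n_bins = 4)
  p <- predict(m, tibble::tibble(x = 100, const = 1))
  expect_true(all(is.finite(as.matrix(p))))
  expect_equal(sum(as.matrix(p)), 1, tolerance = 1e-9)
})

test_that("decision table finds the single predictive feature among noise", {
  set.seed(29)
  n <- 120
  signal <- rep(c(0, 1), each = n / 2)
  d <- tibble::tibble(
    signal = signal,
    noise1 = runif(n), noise2 = runif(n),
    label = ifelse(signal == 1, "pos", "neg")
  )
  m <- fit_decision_table(d)
  expect_equal(m$selected, "signal")
  expect_equal(mean(predict(m, d) == d$label), 1.0)
})

test_that("decision table falls back to the global majority on unseen keys", {
  d <- tibble::tibble(x = c(rep(0, 6), rep(10, 4)),
                      label = c(rep("neg", 6), rep("pos", 4)))
  m <- fit_decision_table(d, n_bins = 2)
  # a key far outside the training bins clamps to an edge bin; an empty
  # selection model must return the majority class
  if (length(m$selected) == 0) {
    expect_equal(unique(predict(m, tibble::tibble(x = c(-5, 99)))), "neg")
  } else {
    expect_equal(predict(m, tibble::tibble(x = 0)), "neg")
    expect_equal(predict(m, tibble::tibble(x = 10)), "pos")
  }
  # memorization of exact training keys
  expect_equal(predict(m, d), d$label)
})

test_that("logistic regression stays finite on separable data and matches Eq. closed form", {
  d <- toy_2d()
  m <- fit_logistic(d, ridge = 1e-2)
  expect_true(all(is.finite(m$coef)))
  expect_equal(predict(m, d, type = "class"), d$label)
  # zero-coefficient model: probability = 1/(1 + e^{-b0}) everywhere
  m0 <- m; m0$coef <- c(0.7, 0, 0)
  p <- predict(m0, d)
  expect_equal(p$pos, rep(plogis(0.7), 4))
})

test_that("logistic regression agrees with glm on a well-conditioned problem", {
  set.seed(37)
  n <- 400
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  eta <- -0.4 + 1.2 * d$x1 - 0.8 * d$x2
  d$label <- ifelse(runif(n) < plogis(eta), "pos", "neg")
  m <- fit_logistic(d, ridge = 0)
  expect_true(m$converged)
  ref <- glm(I(label == "pos") ~ x1 + x2, binomial(), data = d)
  expect_equal(unname(m$coef), unname(coef(ref)), tolerance = 1e-5)
  ours <- predict(m, d, type = "class")
  refc <- ifelse(fitted(ref) >= 0.5, "pos", "neg")
  expect_gte(mean(ours == refc), 0.99)
})

test_that("logistic coefficient signs recover the generator's effect directions", {
  co <- preprocess_cohort(small_cohort(n_patients = 80, records = 30,
                                       missing_rate = 0))
  m <- fit_logistic(co)
  est <- tidy(m)
  coef_of <- function(nm) est$estimate[est$term == nm]
  expect_gt(coef_of("heart_rate"), 0)
  expect_gt(coef_of("body_temp_f"), 0)
  expect_lt(coef_of("spo2"), 0)
})

test_that("SMO satisfies KKT feasibility on a separable toy", {
  d <- toy_2d()
  m <- fit_smo(d, C = 1)
  expect_equal(predict(m, d), d$label)
  k <- smo_kkt(m, d)
  expect_true(k$box_ok)
  expect_lt(abs(k$sum_alpha_y), 1e-6)
  expect_equal(k$n_violations, 0)
  # repeated fits are identical (deterministic sweep)
  m2 <- fit_smo(d, C = 1)
  expect_identical(m$alpha, m2$alpha)
  expect_identical(m$b, m2$b)
})

test_that("SMO with a linear kernel cannot fit XOR but an RBF kernel can", {
  xor <- tibble::tibble(x1 = c(0, 0, 1, 1), x2 = c(0, 1, 0, 1),
                        label = c("neg", "pos", "pos", "neg"))
  lin <- fit_smo(xor, C = 10)
  expect_lt(mean(predict(lin, xor) == xor$label), 1.0)
  rbf <- fit_smo(xor, C = 100, kernel = "rbf", gamma = 2)
  expect_equal(mean(predict(rbf, xor) == xor$label), 1.0)
})

test_that("SMO box limit: C -> 0 collapses the multipliers", {
  d <- toy_2d()
  m <- fit_smo(d, C = 1e-9)
  expect_true(all(m$alpha <= 1e-9 + 1e-15))
  expect_lt(diff(range(decision_value(m, d))), 1e-6)
})

test_that("single-class training data is rejected everywhere", {
  d <- tibble::tibble(x = rnorm(5), label = "a")
  expect_error(fit_gaussian_nb(d), "two classes")
  expect_error(fit_multinomial_nb(d), "two classes")
  expect_error(fit_logistic(d), "two classes")
  expect_error(fit_smo(d), "two classes")
})

test_that("models round-trip through JSON with identical predictions", {
  set.seed(41)
  d <- tibble::tibble(x1 = rnorm(40), x2 = rnorm(40),
                      label = rep(c("a", "b"), 20))
  new <- tibble::tibble(x1 = rnorm(10), x2 = rnorm(10))
  for (fit in list(fit_gaussian_nb, fit_logistic, fit_smo)) {
    m <- fit(d)
    path <- withr::local_tempfile(fileext = ".json")
    save_model(m, path)
    m2 <- load_model(path)
    expect_equal(predict(m2, new, type = "prob"),
                 predict(m, new, type = "prob"), tolerance = 1e-12)
  }
})
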