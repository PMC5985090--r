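test_that("logistic probability implements the sigmoid of B'F", {
  m0 <- logistic_model(rep(0, 15), "thumb", "index")
  expect_identical(logistic_probability(m0, rnorm(14)), 0.5)

  msat <- logistic_model(c(10, rep(0, 14)), "thumb", "index")
  expect_gt(logistic_probability(msat, rnorm(14)), 0.9999)

  set.seed(9)
  for (rep in 1:20) {
    B <- rnorm(15)
    f <- rnorm(14, sd = 2)
    m <- logistic_model(B, "a", "b")
    expect_equal(logistic_probability(m, f), oracle_sigmoid(B, f),
                 tolerance = 1e-12)
    # complement symmetry
    mneg <- logistic_model(-B, "a", "b")
    expect_equal(logistic_probability(m, f) + logistic_probability(mneg, f), 1,
                 tolerance = 1e-12)
  }
})

test_that("logistic probability stays finite under extreme activations", {
  m <- logistic_model(c(800, rep(0, 14)), "a", "b")
  expect_identical(logistic_probability(m, rep(0, 14)), 1)
  m2 <- logistic_model(c(-800, rep(0, 14)), "a", "b")
  expect_identical(logistic_probability(m2, rep(0, 14)), 0)
  expect_error(logistic_probability(m, c(NA, rnorm(13))), "non-finite")
})

test_that("the decision rule assigns class 1 only above 0.5", {
  expect_identical(decide(0.51), 1L)
  expect_identical(decide(0.49), 2L)
  expect_identical(decide(0.5), 2L)  # tie goes to class 2
  expect_error(decide(1.2), "\\[0, 1\\]")
})

test_that("decide composed with the sigmoid matches exhaustive evaluation", {
  set.seed(19)
  for (rep in 1:50) {
    B <- rnorm(15); f <- rnorm(14)
    m <- logistic_model(B, "a", "b")
    p <- oracle_sigmoid(B, f)
    expect_identical(decide(logistic_probability(m, f)),
                     if (p > 0.5) 1L else 2L)
  }
})

test_that("the two-stage network branches as the hierarchy dictates", {
  # intercept-only networks force each branch deterministically
  net1_fist <- logistic_model(c(-5, rep(0, 14)), "thumb+index", "fist")
  net1_move <- logistic_model(c(5, rep(0, 14)), "thumb+index", "fist")
  net2_thumb <- logistic_model(c(5, rep(0, 14)), "thumb", "index")
  net2_index <- logistic_model(c(-5, rep(0, 14)), "thumb", "index")
  f <- rnorm(14)

  p <- classify(two_stage_model(net1_fist, net2_thumb), f)
  expect_identical(p$label, "fist")
  expect_true(is.na(p$p2))  # network II never consulted

  p <- classify(two_stage_model(net1_move, net2_thumb), f)
  expect_identical(p$label, "thumb")
  expect_false(is.na(p$p2))

  p <- classify(two_stage_model(net1_move, net2_index), f)
  expect_identical(p$label, "index")
})

test_that("model construction enforces the stage contract", {
  a <- logistic_model(rnorm(15), "thumb+index", "fist")
  b <- logistic_model(rnorm(15), "thumb", "index")
  expect_error(two_stage_model(b, b), "fist as class 2")
  expect_error(two_stage_model(a, a), "thumb from index")
  expect_error(logistic_model(rnorm(14), "a", "b"), "15")
  expect_error(logistic_model(rnorm(15), "a", "a"), "distinct")
})

test_that("training on mirror-symmetric data yields a zero intercept", {
  set.seed(29)
  X1 <- matrix(rnorm(50 * 14), 50)
  X <- rbind(X1, -X1)
  labels <- rep(c("thumb", "index"), each = 50)
  m <- train_logistic(X, labels, ridge = 1e-6)
  expect_lt(abs(m$B[1]), 1e-6)
})

test_that("a separable toy problem is fit to 100% training accuracy", {
  set.seed(39)
  n <- 40
  X <- matrix(0, n, 14)
  X[, 3] <- c(rnorm(n / 2, 2, 0.2), rnorm(n / 2, -2, 0.2))  # F3 carries the class
  labels <- rep(c("thumb", "index"), each = n / 2)
  m <- train_logistic(X, labels, ridge = 1)
  pred <- apply(X, 1, function(f) {
    if (decide(logistic_probability(m, f)) == 1L) m$class1_label else m$class2_label
  })
  expect_identical(unname(pred), labels)
})

test_that("the fitted likelihood improves on the null model", {
  set.seed(49)
  X <- matrix(rnorm(80 * 14), 80)
  labels <- ifelse(X[, 3] + rnorm(80) > 0, "thumb", "index")
  ridge <- 1e-4
  m <- train_logistic(X, labels, ridge = ridge)
  pen_ll <- function(B) {
    z <- drop(cbind(1, X) %*% B)
    y <- as.numeric(labels == m$class1_label)
    sum(y * z - log1p(exp(z))) - ridge * sum(B[-1]^2) / 2
  }
  expect_gte(attr(m, "log_likelihood"), pen_ll(rep(0, 15)))
  expect_equal(attr(m, "log_likelihood"), pen_ll(m$B), tolerance = 1e-8)
  expect_true(attr(m, "converged"))
})

test_that("IRLS at vanishing ridge matches the glm maximum likelihood fit", {
  set.seed(59)
  X <- matrix(rnorm(300 * 14), 300)
  eta <- 0.4 + X %*% c(0.8, -0.5, 0.3, rep(0, 11))
  y <- rbinom(300, 1, 1 / (1 + exp(-eta)))
  labels <- ifelse(y == 1, "thumb", "index")
  m <- train_logistic(X, labels, ridge = 1e-10, class1 = "thumb")
  ref <- stats::glm.fit(cbind(1, X), y, family = stats::binomial())
  expect_equal(unname(m$B), unname(ref$coefficients), tolerance = 1e-6)
})

test_that("coefficients of a known logistic model are recovered", {
  set.seed(69)
  n <- 2000
  X <- matrix(rnorm(n * 14), n)
  B_true <- c(0.3, round(runif(14, -1, 1), 2))
  p <- 1 / (1 + exp(-drop(cbind(1, X) %*% B_true)))
  labels <- ifelse(rbinom(n, 1, p) == 1, "thumb", "index")
  m <- train_logistic(X, labels, ridge = 1e-10, class1 = "thumb")
  rmse <- sqrt(mean((m$B - B_true)^2))
  expect_lt(rmse, 0.15)
})

test_that("degenerate training inputs are rejected or flagged", {
  X <- matrix(rnorm(20 * 14), 20)
  expect_error(train_logistic(X, rep("thumb", 20)), "two classes")
  expect_error(train_logistic(X, c("thumb", rep("index", 19))),
               "2 examples per class")
  expect_error(train_logistic(X, rep(c("thumb", "index"), 10), ridge = -1))
})

test_that("two-stage training follows the relabel-and-subset scheme", {
  set.seed(79)
  n <- 60
  X <- matrix(rnorm(3 * n * 14, sd = 0.3), 3 * n)
  X[1:n, 3] <- X[1:n, 3] + 4                    # thumb: F3 high
  X[(n + 1):(2 * n), 4] <- X[(n + 1):(2 * n), 4] + 4  # index: FC5 high
  X[(2 * n + 1):(3 * n), 3:4] <- X[(2 * n + 1):(3 * n), 3:4] + 4  # fist: both
  labels <- rep(c("thumb", "index", "fist"), each = n)

  expect_error(train_two_stage(X[1:(2 * n), ], labels[1:(2 * n)]),
               "must be present")

  model <- train_two_stage(X, labels, ridge = 1e-4)
  expect_identical(model$network1$class2_label, "fist")
  expect_setequal(c(model$network2$class1_label, model$network2$class2_label),
                  c("thumb", "index"))

  # network II depends only on the thumb/index subset: perturbing every
  # fist row leaves its coefficients untouched
  X2 <- X
  X2[labels == "fist", ] <- X2[labels == "fist", ] + rnorm(sum(labels == "fist") * 14)
  model2 <- train_two_stage(X2, labels, ridge = 1e-4)
  expect_equal(model2$network2$B, model$network2$B, tolerance = 1e-9)

  # well-separated classes classify perfectly
  preds <- classify_all(model, X)
  expect_identical(as.character(preds), labels)
})

test_that("predictions are invariant to compensated feature rescaling", {
  set.seed(89)
  X <- matrix(abs(rnorm(30 * 14)), 30)
  net1 <- logistic_model(rnorm(15), "thumb+index", "fist")
  net2 <- logistic_model(rnorm(15), "thumb", "index")
  model <- two_stage_model(net1, net2)
  c_scale <- 37.5
  rescale <- function(m) logistic_model(c(m$B[1], m$B[-1] / c_scale),
                                        m$class1_label, m$class2_label)
  model_s <- two_stage_model(rescale(net1), rescale(net2))
  p1 <- classify_all(model, X)
  p2 <- classify_all(model_s, X * c_scale)
  expect_identical(as.character(p1), as.character(p2))
})

test_that("stratified splitting is reproducible and respects the 75/25 ratio", {
  labels <- rep(c("thumb", "index", "fist"), times = c(40, 40, 40))
  s1 <- split_train_test(labels, seed = 5)
  s2 <- split_train_test(labels, seed = 5)
  expect_identical(s1, s2)
  expect_identical(length(s1$train), 90L)
  expect_identical(sort(c(s1$train, s1$test)), seq_along(labels))
  for (cls in unique(labels)) {
    expect_identical(sum(labels[s1$train] == cls), 30L)
  }
  s3 <- split_train_test(labels, seed = 6)
  expect_false(identical(s1$train, s3$train))
})

test_that("two-stage models round-trip through JSON", {
  net1 <- logistic_model(rnorm(15), "thumb+index", "fist")
  net2 <- logistic_model(rnorm(15), "thumb", "index")
  model <- two_stage_model(net1, net2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(model, path)
  back <- read_model_json(path)
  expect_equal(back$network1$B, model$network1$B, tolerance = 1e-12)
  expect_equal(back$network2$B, model$network2$B, tolerance = 1e-12)
  expect_identical(back$network1$class1_label, "thumb+index")
  f <- rnorm(14)
  expect_identical(classify(back, f)$label, classify(model, f)$label)
})
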