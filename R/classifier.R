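#' Binary logistic model over band-power features
#'
#' A weight vector B of 15 coefficients — intercept plus one weight per
#' channel feature — together with the two class labels it separates. The
#' probability of `class1` is the sigmoid of \eqn{B^T F} with F augmented by
#' a leading 1 for the intercept.
#'
#' @param B numeric vector of 15 finite coefficients (intercept first).
#' @param class1_label,class2_label distinct class names.
#' @return A `logistic_model` object.
#' @export
logistic_model <- function(B, class1_label, class2_label) {
  B <- as.numeric(B)
  if (length(B) != length(emotiv_channels) + 1L || !all(is.finite(B))) {
    stop("B must hold ", length(emotiv_channels) + 1L,
         " finite coefficients (intercept + one per channel)", call. = FALSE)
  }
  if (identical(class1_label, class2_label)) {
    stop("class labels must be distinct", call. = FALSE)
  }
  names(B) <- c("(Intercept)", emotiv_channels)
  structure(list(B = B, class1_label = class1_label, class2_label = class2_label),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> %s (class 1) vs %s (class 2); |B| = %d\n",
              x$class1_label, x$class2_label, length(x$B)))
  invisible(x)
}

#' Class-1 probability of a logistic model
#'
#' Evaluates \eqn{P(G = 1) = \exp(B^T F) / (\exp(B^T F) + 1)} with the
#' feature vector augmented by a leading 1 (intercept). Computed in the
#' numerically stable branch form, so it is exact to the working precision
#' for \eqn{|B^T F|} far beyond 700.
#'
#' @param model a [logistic_model].
#' @param f numeric feature vector of 14 band powers.
#' @return Probability of class 1 in (0, 1).
#' @export
logistic_probability <- function(model, f) {
  stopifnot(inherits(model, "logistic_model"))
  f <- as.numeric(f)
  if (length(f) != length(emotiv_channels)) {
    stop("feature vector must have ", length(emotiv_channels), " values",
         call. = FALSE)
  }
  if (!all(is.finite(f))) stop("non-finite features", call. = FALSE)
  z <- unname(model$B[1L]) + sum(model$B[-1L] * f)
  if (z >= 0) 1 / (1 + exp(-z)) else exp(z) / (1 + exp(z))
}

#' Decision rule on a class-1 probability
#'
#' Class 1 if the probability exceeds 0.5, otherwise class 2. A probability
#' of exactly 0.5 goes to class 2 (a measure-zero tie, resolved toward the
#' second branch).
#'
#' @param p probability in \[0, 1\].
#' @return Integer class index, `1L` or `2L`.
#' @export
decide <- function(p) {
  if (!is.finite(p) || p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
  if (p > 0.5) 1L else 2L
}

#' Two-stage classifier network
#'
#' The hierarchical decoder: network I separates the merged
#' \{thumb, index\} class from fist; network II, consulted only when
#' network I rejects fist, separates thumb from index.
#'
#' @param network1 [logistic_model] with `class2_label = "fist"`.
#' @param network2 [logistic_model] over `"thumb"` (class 1) and `"index"`
#'   (class 2).
#' @return A `two_stage_model` object.
#' @export
two_stage_model <- function(network1, network2) {
  stopifnot(inherits(network1, "logistic_model"),
            inherits(network2, "logistic_model"))
  if (!identical(network1$class2_label, "fist")) {
    stop("network I must have fist as class 2", call. = FALSE)
  }
  if (!setequal(c(network2$class1_label, network2$class2_label),
                c("thumb", "index"))) {
    stop("network II must separate thumb from index", call. = FALSE)
  }
  structure(list(network1 = network1, network2 = network2),
            class = "two_stage_model")
}

#' @export
print.two_stage_model <- function(x, ...) {
  cat("<two_stage_model>\n  network I :", x$network1$class1_label, "vs",
      x$network1$class2_label, "\n  network II:", x$network2$class1_label,
      "vs", x$network2$class2_label, "\n")
  invisible(x)
}

#' Classify a feature vector with the two-stage network
#'
#' Network I decides fist vs non-fist; when it chooses the merged class,
#' network II decides thumb vs index.
#'
#' @param model a [two_stage_model].
#' @param f numeric feature vector of 14 band powers.
#' @return List with `label` (movement class), `p1` (network-I class-1
#'   probability) and `p2` (network-II probability, `NA` when network I
#'   chose fist).
#' @export
classify <- function(model, f) {
  stopifnot(inherits(model, "two_stage_model"))
  p1 <- logistic_probability(model$network1, f)
  if (decide(p1) == 2L) {
    return(list(label = model$network1$class2_label, p1 = p1, p2 = NA_real_))
  }
  p2 <- logistic_probability(model$network2, f)
  label <- if (decide(p2) == 1L) model$network2$class1_label else model$network2$class2_label
  list(label = label, p1 = p1, p2 = p2)
}

#' @rdname classify
#' @param features feature table (from [feature_table()]) or 14-column
#'   numeric matrix, one row per chunk.
#' @return `classify_all()`: character vector of predicted labels, with the
#'   stage probabilities attached as a `"probabilities"` attribute.
#' @export
classify_all <- function(model, features) {
  X <- if (is.data.frame(features)) feature_matrix(features) else as.matrix(features)
  preds <- apply(X, 1L, function(row) classify(model, row))
  labels <- vapply(preds, `[[`, "", "label")
  attr(labels, "probabilities") <- cbind(
    p1 = vapply(preds, `[[`, 0, "p1"),
    p2 = vapply(preds, `[[`, 0, "p2"))
  labels
}

#' Fit a binary logistic model by penalized IRLS
#'
#' Maximizes the ridge-penalized binomial log-likelihood
#' \eqn{\ell(B) - (\lambda/2) \sum_{j \ge 1} B_j^2} (intercept unpenalized)
#' by iteratively reweighted least squares with step halving, iterating
#' until the gradient max-norm falls below `tol` (default 1e-8) or 100
#' iterations. The fit is deterministic for fixed input. The small default
#' ridge keeps the Newton system well conditioned on separable data without
#' materially biasing the weights.
#'
#' @param features 14-column numeric matrix or feature table, one row per
#'   training chunk.
#' @param labels vector with exactly the two values `class1` and `class2`.
#' @param ridge L2 penalty \eqn{\lambda} (default 1e-8).
#' @param class1 label coded as class 1; default the first of the canonical
#'   movement order present, otherwise the first unique label.
#' @param tol gradient max-norm convergence tolerance.
#' @param max_iter iteration cap; hitting it flags the model via the
#'   `converged` attribute and a warning, never silently.
#' @return A [logistic_model] with attributes `converged`, `iterations`,
#'   and `log_likelihood` (penalized, at the optimum).
#' @export
train_logistic <- function(features, labels, ridge = 1e-8, class1 = NULL,
                           tol = 1e-8, max_iter = 100L) {
  X <- if (is.data.frame(features)) feature_matrix(features) else as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels), ridge >= 0)
  ulab <- unique(labels)
  if (length(ulab) != 2L) {
    stop("need exactly two classes in labels, got ", length(ulab), call. = FALSE)
  }
  if (is.null(class1)) {
    ord <- c(movement_classes, setdiff(ulab, movement_classes))
    class1 <- ord[ord %in% ulab][1L]
  }
  class2 <- setdiff(ulab, class1)
  if (any(table(labels) < 2L)) {
    stop("need at least 2 examples per class", call. = FALSE)
  }
  if (!all(is.finite(X))) stop("non-finite features", call. = FALSE)

  y <- as.numeric(labels == class1)
  Xa <- cbind(1, X)  # leading-1 augmentation for the intercept
  p_ <- ncol(Xa)
  pen <- c(0, rep(ridge, p_ - 1L))  # intercept unpenalized

  loglik <- function(B) {
    z <- drop(Xa %*% B)
    # y*z - log(1+e^z), stable form
    sum(y * z - ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))) -
      sum(pen * B^2) / 2
  }
  B <- numeric(p_)
  ll <- loglik(B)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    z <- drop(Xa %*% B)
    p <- 1 / (1 + exp(-pmin(pmax(z, -700), 700)))
    grad <- drop(crossprod(Xa, y - p)) - pen * B
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    W <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Xa * W, Xa) + diag(pen, p_)
    step <- solve(H, grad)
    # step halving guards the Newton step on ill-conditioned systems
    alpha <- 1
    repeat {
      Bnew <- B + alpha * step
      llnew <- loglik(Bnew)
      if (llnew >= ll - 1e-12 || alpha < 2^-30) break
      alpha <- alpha / 2
    }
    B <- Bnew
    ll <- llnew
  }
  if (!converged) {
    # final gradient check (max_iter may land exactly on the optimum)
    z <- drop(Xa %*% B)
    p <- 1 / (1 + exp(-pmin(pmax(z, -700), 700)))
    converged <- max(abs(drop(crossprod(Xa, y - p)) - pen * B)) < tol
    if (!converged) {
      warning("IRLS did not reach gradient tolerance ", tol, " in ", max_iter,
              " iterations (model flagged via attr(., 'converged'))")
    }
  }
  model <- logistic_model(B, class1, class2)
  attr(model, "converged") <- converged
  attr(model, "iterations") <- iter
  attr(model, "log_likelihood") <- ll
  model
}

#' Train the two-stage network on three-class data
#'
#' Network I is trained on all rows with labels relabeled to the merged
#' \{thumb, index\} class (class 1) versus fist (class 2); network II is
#' trained on the thumb/index subset only (thumb = class 1). All three
#' movement classes must be present.
#'
#' @inheritParams train_logistic
#' @param labels three-class movement labels, one per row.
#' @return A [two_stage_model].
#' @export
train_two_stage <- function(features, labels, ridge = 1e-8) {
  X <- if (is.data.frame(features)) feature_matrix(features) else as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  if (!all(movement_classes %in% labels)) {
    stop("all three classes (", paste(movement_classes, collapse = ", "),
         ") must be present", call. = FALSE)
  }
  lab1 <- ifelse(labels == "fist", "fist", "thumb+index")
  net1 <- train_logistic(X, lab1, ridge = ridge, class1 = "thumb+index")
  keep <- labels != "fist"
  net2 <- train_logistic(X[keep, , drop = FALSE], labels[keep],
                         ridge = ridge, class1 = "thumb")
  two_stage_model(net1, net2)
}

#' Stratified train/test split of chunk indices
#'
#' Splits row indices class by class, `train_frac` (default 75%) to
#' training, the rest to test, using a fixed seed so the split is
#' reproducible. Per-class training counts are rounded to the nearest
#' integer.
#'
#' @param labels class label per row.
#' @param train_frac fraction assigned to training (default 0.75).
#' @param seed RNG seed for the within-class shuffle.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, train_frac = 0.75, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  labels <- as.character(labels)
  with_local_seed(seed, function() {
    train <- integer(0)
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      n_tr <- max(1L, min(length(idx) - 1L, round(train_frac * length(idx))))
      train <- c(train, sample(idx)[seq_len(n_tr)])
    }
    list(train = sort(train), test = setdiff(seq_along(labels), train))
  })
}

#' Two-stage model JSON interchange
#'
#' Serializes a fitted network as
#' `{"network1": {"class1": ..., "class2": ..., "B": [15 numbers]}, "network2": {...}}`.
#'
#' @param model a [two_stage_model].
#' @param path JSON file path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` the reconstructed [two_stage_model].
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "two_stage_model"))
  ser <- function(m) list(class1 = m$class1_label, class2 = m$class2_label,
                          B = unname(m$B))
  jsonlite::write_json(list(network1 = ser(model$network1),
                            network2 = ser(model$network2)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  de <- function(d) logistic_model(d$B, d$class1, d$class2)
  two_stage_model(de(doc$network1), de(doc$network2))
}
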