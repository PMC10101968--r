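# Two-stage hierarchical decision-maker. Stage A separates monocyte-like
# cells from tumor cells, stage B resolves the tumor type; stage-A errors
# propagate into stage-B outputs by construction. Shallow ReLU networks
# carry the 3D-feature pipeline, logistic regression + linear
# discriminant the 2D baseline.

# ---- shallow neural network (44 -> hidden ReLU -> 1 sigmoid) ----------

nn_forward <- function(X, w) {
  H <- pmax(X %*% w$W1 + matrix(w$b1, nrow(X), length(w$b1), byrow = TRUE), 0)
  s <- as.numeric(H %*% w$W2 + w$b2)
  list(H = H, p = stats::plogis(s))
}

nn_train <- function(X, y, hidden, seed, epochs = 500L, patience = 20L,
                     val_frac = 0.1, lr = 0.01) {
  n <- nrow(X); d <- ncol(X)
  with_seed(seed, {
    W1 <- matrix(rnorm(d * hidden, sd = sqrt(2 / d)), d, hidden)
    b1 <- numeric(hidden)
    W2 <- matrix(rnorm(hidden, sd = sqrt(2 / hidden)), hidden, 1)
    b2 <- 0
    vi <- sample(n, max(1L, round(val_frac * n)))
    w <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    Xt <- X[-vi, , drop = FALSE]; yt <- y[-vi]
    Xv <- X[vi, , drop = FALSE];  yv <- y[vi]
    m <- lapply(w, function(a) a * 0); v <- lapply(w, function(a) a * 0)
    b1c <- 0.9; b2c <- 0.999; epsi <- 1e-8
    best <- Inf; best_w <- w; stall <- 0L
    nt <- nrow(Xt)
    for (ep in seq_len(epochs)) {
      fw <- nn_forward(Xt, w)
      err <- fw$p - yt                     # d(loss)/d(logit), cross-entropy
      gW2 <- crossprod(fw$H, err) / nt
      gb2 <- mean(err)
      dH <- (err %*% t(w$W2)) * (fw$H > 0)
      gW1 <- crossprod(Xt, dH) / nt
      gb1 <- colMeans(dH)
      g <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      for (k in names(w)) {
        m[[k]] <- b1c * m[[k]] + (1 - b1c) * g[[k]]
        v[[k]] <- b2c * v[[k]] + (1 - b2c) * g[[k]]^2
        mh <- m[[k]] / (1 - b1c^ep)
        vh <- v[[k]] / (1 - b2c^ep)
        w[[k]] <- w[[k]] - lr * mh / (sqrt(vh) + epsi)
      }
      pv <- nn_forward(Xv, w)$p
      pv <- pmin(pmax(pv, 1e-12), 1 - 1e-12)
      loss <- -mean(yv * log(pv) + (1 - yv) * log(1 - pv))
      if (loss < best - 1e-6) {
        best <- loss; best_w <- w; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
    best_w
  })
}

# ---- stage models ------------------------------------------------------

#' Fit one binary stage classifier
#'
#' Features are z-scored with parameters frozen at fit time. Kinds:
#' \code{"shallow_nn"} (width-44 input, ReLU hidden layer, sigmoid
#' output, cross-entropy loss, Adam, early stopping on a held-out 10\%
#' of the training data), \code{"logistic"} (binomial GLM) and
#' \code{"lda"} (linear discriminant). Deterministic given \code{seed}.
#'
#' @param features Numeric matrix (rows = cells, columns = the 44
#'   features).
#' @param labels Class labels, exactly two distinct values.
#' @param kind One of \code{"shallow_nn"}, \code{"logistic"},
#'   \code{"lda"}.
#' @param hidden_width Hidden nodes for the shallow network.
#' @param seed Training seed.
#' @param positive_class Label treated as the positive class (score 1);
#'   defaults to the first distinct label.
#' @return An object of class \code{stage_model}.
#' @export
fit_stage <- function(features, labels, kind = c("shallow_nn", "logistic", "lda"),
                      hidden_width = 100L, seed = 1L, positive_class = NULL) {
  kind <- match.arg(kind)
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(features) != length(labels)) stop("features/labels size mismatch")
  bad <- which(!apply(features, 2, function(c) all(is.finite(c))))
  if (length(bad))
    stop("non-finite feature column(s): ",
         paste(colnames(features)[bad] %||% bad, collapse = ", "))
  cls <- unique(labels)
  if (length(cls) != 2)
    stop("need exactly two classes, got: ", paste(cls, collapse = ", "))
  if (is.null(positive_class)) positive_class <- cls[1]
  if (!positive_class %in% cls) stop("positive_class not present in labels")
  negative_class <- setdiff(cls, positive_class)
  y <- as.numeric(labels == positive_class)

  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(features, 2, ctr), 2, scl, "/")

  fit <- switch(kind,
    shallow_nn = nn_train(Xs, y, hidden_width, seed),
    logistic = {
      cf <- with_seed(seed, suppressWarnings(
        stats::glm.fit(cbind(1, Xs), y,
                       family = stats::binomial())$coefficients))
      cf[!is.finite(cf)] <- 0
      cf
    },
    lda = {
      # LDA cannot handle features that are constant within both groups
      # (possible on very small training sets); drop and remember them
      wsd <- vapply(seq_len(ncol(Xs)), function(cc) {
        max(stats::sd(Xs[y == 1, cc]), stats::sd(Xs[y == 0, cc]))
      }, 0)
      keep <- which(is.finite(wsd) & wsd > 1e-8)
      if (length(keep) < 1) stop("no informative features for LDA")
      obj <- with_seed(seed, suppressWarnings(
        MASS::lda(Xs[, keep, drop = FALSE], grouping = factor(y))))
      list(obj = obj, keep = keep)
    }
  )
  structure(list(kind = kind, fit = fit, center = ctr, scale = scl,
                 hidden_width = if (kind == "shallow_nn") hidden_width else NA,
                 positive_class = positive_class,
                 negative_class = negative_class,
                 n_features = ncol(features), n_train = nrow(features),
                 seed = seed),
            class = "stage_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.stage_model <- function(x, ...) {
  cat("<stage_model> ", x$kind,
      if (x$kind == "shallow_nn") paste0(" (hidden ", x$hidden_width, ")"),
      ": ", x$positive_class, " (+) vs ", x$negative_class,
      " (-), ", x$n_features, " features\n", sep = "")
  invisible(x)
}

#' Predict with a stage classifier
#'
#' @param model A \code{stage_model}.
#' @param features Numeric matrix with the training width.
#' @return List with \code{scores} in [0, 1] (probability of the
#'   positive class) and \code{labels}; a score of exactly 0.5 maps to
#'   the positive class.
#' @export
predict_stage <- function(model, features) {
  stopifnot(inherits(model, "stage_model"))
  features <- as.matrix(features)
  if (ncol(features) != model$n_features)
    stop("feature width ", ncol(features), " != training width ",
         model$n_features)
  Xs <- sweep(sweep(features, 2, model$center), 2, model$scale, "/")
  scores <- switch(model$kind,
    shallow_nn = nn_forward(Xs, model$fit)$p,
    logistic = as.numeric(stats::plogis(cbind(1, Xs) %*% model$fit)),
    lda = as.numeric(stats::predict(model$fit$obj,
                                    Xs[, model$fit$keep,
                                       drop = FALSE])$posterior[, "1"])
  )
  labels <- ifelse(scores >= 0.5, model$positive_class, model$negative_class)
  list(scores = scores, labels = labels)
}

# ---- hierarchical model ------------------------------------------------

#' Default hierarchical classifier configuration
#'
#' 3D flavor: shallow networks with 100 (stage A) and 10 (stage B)
#' hidden nodes. 2D flavor: logistic regression (A) + linear
#' discriminant (B).
#'
#' @param flavor \code{"3D"} or \code{"2D"}.
#' @return List with \code{stage_A} and \code{stage_B} settings.
#' @export
hierarchical_config <- function(flavor = c("3D", "2D")) {
  flavor <- match.arg(flavor)
  if (flavor == "3D") {
    list(stage_A = list(kind = "shallow_nn", hidden_width = 100L),
         stage_B = list(kind = "shallow_nn", hidden_width = 10L))
  } else {
    list(stage_A = list(kind = "logistic", hidden_width = NA),
         stage_B = list(kind = "lda", hidden_width = NA))
  }
}

#' Fit the hierarchical two-stage classifier
#'
#' Stage A is trained on MC vs tumor (NB and OC pooled), stage B on NB
#' vs OC only. At prediction time, items stage A labels MC exit as MC;
#' the rest are routed to stage B — so a true MC can only end up NB/OC
#' through a stage-A error, reproducing the error-propagation structure
#' of the two chained decisions.
#'
#' @param train_features Numeric matrix of 44-feature rows.
#' @param train_labels Labels in \{MC, NB, OC\}; all three must be
#'   present.
#' @param config Stage settings, see \code{\link{hierarchical_config}}.
#' @param seed Training seed (both stages derive from it).
#' @return An object of class \code{hier_model}.
#' @export
fit_hierarchical <- function(train_features, train_labels,
                             config = hierarchical_config("3D"), seed = 1L) {
  train_features <- as.matrix(train_features)
  train_labels <- as.character(train_labels)
  missing_cls <- setdiff(c("MC", "NB", "OC"), unique(train_labels))
  if (length(missing_cls))
    stop("missing class(es): ", paste(missing_cls, collapse = ", "))
  lab_A <- ifelse(train_labels == "MC", "MC", "tumor")
  stage_A <- fit_stage(train_features, lab_A, config$stage_A$kind,
                       config$stage_A$hidden_width %||% 100L,
                       seed = derive_seed(seed, 11L),
                       positive_class = "MC")
  sel_B <- train_labels %in% c("NB", "OC")
  stage_B <- fit_stage(train_features[sel_B, , drop = FALSE],
                       train_labels[sel_B], config$stage_B$kind,
                       config$stage_B$hidden_width %||% 10L,
                       seed = derive_seed(seed, 13L),
                       positive_class = "NB")
  structure(list(stage_A = stage_A, stage_B = stage_B,
                 classes = c("MC", "NB", "OC"), config = config,
                 seed = seed),
            class = "hier_model")
}

#' @export
print.hier_model <- function(x, ...) {
  cat("<hier_model> stage A: ", x$stage_A$kind, " (MC vs tumor); stage B: ",
      x$stage_B$kind, " (NB vs OC)\n", sep = "")
  invisible(x)
}

#' @export
summary.hier_model <- function(object, ...) {
  cat("Hierarchical two-stage classifier\n")
  print(object$stage_A)
  print(object$stage_B)
  cat("Training seed:", object$seed, "\n")
  invisible(object)
}

#' Predict three-class labels with the hierarchical classifier
#'
#' @param object A \code{hier_model}.
#' @param newdata Numeric matrix of 44-feature rows.
#' @param ... Unused.
#' @return Character vector of labels in \{MC, NB, OC\}.
#' @export
predict.hier_model <- function(object, newdata, ...) {
  pa <- predict_stage(object$stage_A, newdata)
  out <- pa$labels
  tum <- which(out != "MC")
  if (length(tum)) {
    pb <- predict_stage(object$stage_B,
                        as.matrix(newdata)[tum, , drop = FALSE])
    out[tum] <- pb$labels
  }
  out
}
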