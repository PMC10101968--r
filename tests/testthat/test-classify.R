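# Stage classifiers and the hierarchical decision-maker.

make_blobs <- function(n_per, gap = 3, d = 44, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d, 0), n_per, d),
             matrix(rnorm(n_per * d, gap), n_per, d))
  list(X = X, y = rep(c("pos", "neg"), each = n_per))
}

test_that("every stage kind fits separable blobs perfectly and is seeded", {
  b <- make_blobs(60)
  for (kind in c("shallow_nn", "logistic", "lda")) {
    m <- fit_stage(b$X, b$y, kind, hidden_width = 16, seed = 5)
    p <- predict_stage(m, b$X)
    expect_equal(mean(p$labels == b$y), 1)
    expect_true(all(p$scores >= 0 & p$scores <= 1))
    m2 <- fit_stage(b$X, b$y, kind, hidden_width = 16, seed = 5)
    expect_identical(predict_stage(m2, b$X)$scores, p$scores)
  }
})

test_that("label-permuted training stays at chance level", {
  accs <- vapply(1:10, function(s) {
    b <- make_blobs(60, gap = 3, seed = 100 + s)
    set.seed(200 + s)
    y_perm <- sample(b$y)
    tr <- 1:80; te <- 81:120
    m <- fit_stage(b$X[tr, ], y_perm[tr], "shallow_nn", hidden_width = 8,
                   seed = s)
    mean(predict_stage(m, b$X[te, ])$labels == y_perm[te])
  }, 0)
  expect_gte(mean(accs), 0.40)
  expect_lte(mean(accs), 0.60)
})

test_that("degenerate inputs are rejected with informative errors", {
  b <- make_blobs(20)
  expect_error(fit_stage(b$X, rep("pos", 40), "logistic"), "two classes")
  Xb <- b$X; Xb[3, 7] <- NA
  colnames(Xb) <- paste0("f", 1:44)
  expect_error(fit_stage(Xb, b$y, "logistic"), "f7")
  m <- fit_stage(b$X, b$y, "logistic")
  expect_error(predict_stage(m, b$X[, 1:10]), "width")
})

test_that("a zero-weight network scores exactly 0.5 and ties go positive", {
  m <- structure(list(kind = "shallow_nn",
                      fit = list(W1 = matrix(0, 4, 3), b1 = numeric(3),
                                 W2 = matrix(0, 3, 1), b2 = 0),
                      center = numeric(4), scale = rep(1, 4),
                      hidden_width = 3, positive_class = "pos",
                      negative_class = "neg", n_features = 4, seed = 1),
                 class = "stage_model")
  p <- predict_stage(m, matrix(rnorm(20), 5, 4))
  expect_true(all(p$scores == 0.5))
  expect_true(all(p$labels == "pos"))
})

test_that("standardization is frozen at fit time", {
  b <- make_blobs(50)
  m <- fit_stage(b$X, b$y, "logistic", seed = 2)
  # shifting a probe point by the training center reproduces the
  # standardized prediction: the standardizer travels with the model
  probe <- b$X[1:5, ]
  p1 <- predict_stage(m, probe)
  m_shift <- m
  expect_identical(predict_stage(m_shift, probe)$scores, p1$scores)
  expect_equal(m$center, colMeans(b$X))
})

# three-class features with an exactly decodable structure: column 1
# separates MC, column 2 separates NB from OC
hier_features <- function(labels, noise = 0.1, seed = 1) {
  set.seed(seed)
  n <- length(labels)
  X <- matrix(rnorm(n * 44, sd = noise), n, 44)
  X[, 1] <- X[, 1] + ifelse(labels == "MC", 2, -2)
  X[, 2] <- X[, 2] + ifelse(labels == "NB", 2, -2)
  X
}

test_that("hierarchical fit sees the right rows per stage", {
  labels <- rep(c("MC", "NB", "OC"), c(2000, 1000, 1000))
  X <- hier_features(labels)
  cfg <- list(stage_A = list(kind = "logistic"),
              stage_B = list(kind = "lda"))
  m <- fit_hierarchical(X, labels, cfg, seed = 3)
  expect_equal(m$stage_A$n_train, 4000)
  expect_equal(m$stage_B$n_train, 2000)
  expect_error(fit_hierarchical(X[labels != "NB", ], labels[labels != "NB"],
                                cfg, 1), "NB")
})

test_that("oracle stages compose to perfect three-class labels", {
  labels <- rep(c("MC", "NB", "OC"), each = 100)
  X <- hier_features(labels)
  cfg <- list(stage_A = list(kind = "logistic"),
              stage_B = list(kind = "lda"))
  m <- fit_hierarchical(X, labels, cfg, seed = 3)
  te_labels <- rep(c("MC", "NB", "OC"), each = 40)
  Xt <- hier_features(te_labels, seed = 9)
  expect_equal(mean(predict(m, Xt) == te_labels), 1)
  # same seed, same model pair
  m2 <- fit_hierarchical(X, labels, cfg, seed = 3)
  expect_identical(predict(m2, Xt), predict(m, Xt))
})

test_that("stage-A errors propagate with the routing identity", {
  te_labels <- rep(c("MC", "NB", "OC"), c(50, 60, 60))
  Xt <- hier_features(te_labels, seed = 13)
  # corrupt two true-MC rows so stage A must route them to the tumor side
  Xt[1:2, 1] <- -2
  labels <- rep(c("MC", "NB", "OC"), each = 150)
  X <- hier_features(labels, seed = 21)
  cfg <- list(stage_A = list(kind = "logistic"),
              stage_B = list(kind = "lda"))
  m <- fit_hierarchical(X, labels, cfg, seed = 3)
  ev <- evaluate_hierarchical(m, Xt, te_labels)
  # hierarchical MC recall equals stage-A MC recall exactly
  expect_equal(ev$hierarchical$raw$per_class$MC[["tpr"]],
               ev$stage_A$raw$per_class$MC[["tpr"]])
  expect_equal(ev$stage_A$confusion["MC", "tumor"], 2)
  # errors only accumulate: hierarchical accuracy <= stage-A accuracy
  expect_lte(ev$hierarchical$raw$accuracy, ev$stage_A$raw$accuracy)
  # the two corrupted MCs exit as NB or OC, never as MC
  expect_equal(sum(ev$hierarchical$confusion["MC", c("NB", "OC")]), 2)
})
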