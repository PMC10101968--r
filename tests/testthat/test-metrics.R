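# Confusion matrices and the printed-table metric panel.

test_that("confusion_matrix counts, orders and rejects correctly", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "a", "b"), c("a", "b"))
  expect_equal(unclass(cm), matrix(c(2L, 0L, 0L, 1L), 2,
                                   dimnames = list(true = c("a", "b"),
                                                   predicted = c("a", "b"))))
  sw <- confusion_matrix(c("a", "b"), c("b", "a"), c("a", "b"))
  expect_equal(diag(sw), c(a = 0L, b = 0L))
  expect_error(confusion_matrix("a", "c", c("a", "b")), "unknown label")
})

test_that("the 229-cell three-class fixture has the printed row sums", {
  truth <- rep(c("MC", "NB", "OC"), c(47, 122, 60))
  pred <- c(rep("MC", 45), rep("NB", 2),                # MC row
            rep("MC", 4), rep("NB", 114), rep("OC", 4), # NB row
            rep("NB", 1), rep("OC", 59))                # OC row
  cm <- confusion_matrix(truth, pred, c("MC", "NB", "OC"))
  expect_equal(rowSums(cm), c(MC = 47, NB = 122, OC = 60))
  expect_equal(diag(cm), c(MC = 45, NB = 114, OC = 59))
})

test_that("binary panel reproduces the stage-A printed values", {
  cm <- cm_from_recalls(c(95.7, 97.8), c(47, 182), c("MC", "tumor"))
  expect_equal(unclass(cm),
               matrix(c(45L, 4L, 2L, 178L), 2,
                      dimnames = list(true = c("MC", "tumor"),
                                      predicted = c("MC", "tumor"))))
  rep <- binary_metrics(cm)
  expect_equal(rep$rounded$accuracy, 97.4)
  mc <- rep$rounded$per_class$MC
  expect_equal(mc[["ppv"]], 91.8)
  expect_equal(mc[["f1"]], 93.8)
  expect_equal(mc[["mcc"]], 92.1)
  expect_equal(mc[["balanced_accuracy"]], 96.8)
  expect_equal(mc[["fowlkes_mallows"]], 93.8)
  tu <- rep$rounded$per_class$tumor
  expect_equal(tu[["tpr"]], 97.8)
  expect_equal(tu[["ppv"]], 98.9)
})

test_that("binary panel reproduces the stage-B printed values", {
  cm <- cm_from_recalls(c(96.7, 98.3), c(122, 60), c("NB", "OC"))
  expect_equal(unclass(cm),
               matrix(c(118L, 1L, 4L, 59L), 2,
                      dimnames = list(true = c("NB", "OC"),
                                      predicted = c("NB", "OC"))))
  rep <- binary_metrics(cm)
  expect_equal(rep$rounded$accuracy, 97.3)
  nb <- rep$rounded$per_class$NB
  expect_equal(nb[["ppv"]], 99.2)
  expect_equal(nb[["f1"]], 97.9)
  expect_equal(nb[["mcc"]], 93.9)
})

test_that("a perfect binary classifier scores 100 on every statistic", {
  cm <- confusion_matrix(rep(c("p", "n"), each = 10),
                         rep(c("p", "n"), each = 10), c("p", "n"))
  rep <- binary_metrics(cm)
  expect_equal(rep$rounded$accuracy, 100)
  expect_true(all(unlist(rep$rounded$per_class) == 100))
})

test_that("three-class panel matches the hierarchical printed values", {
  cm <- matrix(c(45L, 4L, 0L,
                 2L, 114L, 1L,
                 0L, 4L, 59L), 3,
               dimnames = list(true = c("MC", "NB", "OC"),
                               predicted = c("MC", "NB", "OC")))
  class(cm) <- c("confusion_matrix", "matrix")
  rep <- multiclass_metrics(cm)
  expect_equal(rep$rounded$accuracy, 95.2)
  expect_equal(rep$rounded$per_class$MC[["tpr"]], 95.7)
  expect_equal(rep$rounded$per_class$NB[["tpr"]], 93.4)
  expect_equal(rep$rounded$per_class$OC[["tpr"]], 98.3)
  expect_equal(rep$rounded$per_class$NB[["ppv"]], 97.4)
  expect_equal(rep$rounded$per_class$OC[["ppv"]], 93.7)
  expect_equal(rep$rounded$per_class$MC[["ppv"]], 91.8)
})

test_that("overall accuracy depends only on the diagonal", {
  base <- c(30, 95, 49)
  sizes <- c(47, 122, 60)
  for (rep_i in 1:3) {
    cm <- matrix(0L, 3, 3, dimnames = list(true = c("MC", "NB", "OC"),
                                           predicted = c("MC", "NB", "OC")))
    diag(cm) <- base
    set.seed(rep_i)
    for (r in 1:3) {
      rest <- sizes[r] - base[r]
      split <- sample(0:rest, 1)
      others <- setdiff(1:3, r)
      cm[r, others[1]] <- cm[r, others[1]] + split
      cm[r, others[2]] <- cm[r, others[2]] + rest - split
    }
    class(cm) <- c("confusion_matrix", "matrix")
    expect_equal(multiclass_metrics(cm)$rounded$accuracy, 76.0)
  }
})

test_that("panel agrees with a brute-force four-cell oracle", {
  set.seed(42)
  for (i in 1:1000) {
    cells <- sample(0:80, 4, replace = TRUE)
    if (cells[1] + cells[2] == 0 || cells[3] + cells[4] == 0) next
    cm <- matrix(as.integer(cells), 2,
                 dimnames = list(true = c("p", "n"), predicted = c("p", "n")))
    # row-major reading: tp, fn / fp, tn
    tp <- cells[1]; fn <- cells[3]; fp <- cells[2]; tn <- cells[4]
    class(cm) <- c("confusion_matrix", "matrix")
    got <- binary_metrics(cm)
    want <- binary_panel_brute(tp, fn, fp, tn)
    expect_equal(got$raw$accuracy, want[["acc"]], tolerance = 1e-12)
    p <- got$raw$per_class$p
    for (pair in list(c("tpr", "tpr"), c("tnr", "tnr"), c("ppv", "ppv"),
                      c("npv", "npv"), c("balanced_accuracy", "ba"),
                      c("f1", "f1"), c("mcc", "mcc"),
                      c("fowlkes_mallows", "fm"))) {
      if (is.finite(want[[pair[2]]]))
        expect_equal(p[[pair[1]]], want[[pair[2]]], tolerance = 1e-12)
    }
    # binary symmetry: class-2 panel is class-1 with TPR<->TNR, PPV<->NPV
    n <- got$raw$per_class$n
    expect_equal(n[["tpr"]], p[["tnr"]])
    expect_equal(n[["ppv"]], p[["npv"]])
  }
})

test_that("percentages round half-up to one decimal", {
  # 90/96 = 93.75 must print as 93.8, not 93.7
  cm <- matrix(c(45L, 4L, 2L, 178L), 2,
               dimnames = list(true = c("a", "b"), predicted = c("a", "b")))
  class(cm) <- c("confusion_matrix", "matrix")
  expect_equal(binary_metrics(cm)$rounded$per_class$a[["f1"]], 93.8)
})

test_that("cm_from_recalls handles edges and rejects bad input", {
  expect_equal(diag(cm_from_recalls(c(100, 100), c(10, 20))), c(pos = 10, neg = 20))
  expect_error(cm_from_recalls(c(101, 50), c(10, 10)), "\\[0, 100\\]")
  expect_error(cm_from_recalls(c(50, 50, 50), c(10, 10, 10)), "binary")
})

test_that("degenerate denominators are reported as NA, not zero", {
  cm <- matrix(c(0L, 0L, 5L, 5L), 2,
               dimnames = list(true = c("p", "n"), predicted = c("p", "n")))
  class(cm) <- c("confusion_matrix", "matrix")
  rep <- binary_metrics(cm)
  expect_true(is.na(rep$raw$per_class$p[["ppv"]]))
})
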