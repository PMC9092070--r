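# worked 2x2 example: truth [[0,0],[1,1]], pred [[0,1],[1,1]] (row-wise)
worked_truth <- matrix(c(0L, 1L, 0L, 1L), 2, 2)
worked_pred <- matrix(c(0L, 1L, 1L, 1L), 2, 2)

test_that("the 2x2 worked example gives the textbook values", {
  t2 <- confusion_tally(worked_pred, worked_truth, n_classes = 2)
  expect_equal(t2$TP[t2$id == 1], 2L)
  expect_equal(t2$FP[t2$id == 1], 1L)
  expect_equal(t2$FN[t2$id == 1], 0L)
  expect_equal(t2$TN[t2$id == 1], 1L)
  expect_equal(pixel_accuracy(t2), 0.75)
  expect_equal(as.numeric(mean_pixel_accuracy(t2)), 0.75)
  expect_equal(iou(t2, 1), 2 / 3)
  expect_equal(mean_iou(t2), 7 / 12)
})

test_that("perfect prediction yields FP = FN = 0 and unit metrics", {
  truth <- matrix(sample(0:5, 64, TRUE), 8, 8)
  t6 <- confusion_tally(truth, truth)
  expect_true(all(t6$FP == 0L) && all(t6$FN == 0L))
  expect_equal(pixel_accuracy(t6), 1)
  expect_equal(as.numeric(mean_pixel_accuracy(t6)), 1)
  expect_equal(mean_iou(t6), 1)
})

test_that("constant prediction scores the truth frequency of that class", {
  set.seed(4)
  truth <- matrix(sample(0:5, 256, TRUE), 16, 16)
  pred <- matrix(3L, 16, 16)
  t6 <- confusion_tally(pred, truth)
  expect_equal(pixel_accuracy(t6), mean(truth == 3L))
})

test_that("three-class fixtures reproduce hand-enumerated MPA and MIOU", {
  # class 0: 4 px all correct; class 1: 4 px, 2 predicted as 2; class 2:
  # 4 px, none recovered (all predicted as 0) -> recalls 1, 0.5, 0
  truth <- matrix(c(rep(0L, 4), rep(1L, 4), rep(2L, 4)), 3, 4, byrow = TRUE)
  pred <- matrix(c(rep(0L, 4), 1L, 1L, 2L, 2L, rep(0L, 4)), 3, 4, byrow = TRUE)
  t3 <- confusion_tally(pred, truth, n_classes = 3)
  expect_equal(as.numeric(mean_pixel_accuracy(t3)), mean(c(1, 0.5, 0)))
  # IOUs: class0 4/8, class1 2/4, class2 0/6
  expect_equal(iou(t3, 0), 0.5)
  expect_equal(mean_iou(t3), mean(c(4 / 8, 2 / 4, 0)))
})

test_that("offset rectangles give the counted overlap IoU", {
  truth <- matrix(0L, 20, 30)
  truth[6:15, 1:10] <- 1L
  pred <- matrix(0L, 20, 30)
  pred[6:15, 6:15] <- 1L
  t2 <- confusion_tally(pred, truth, n_classes = 2)
  expect_equal(iou(t2, 1), 50 / 150)
  # disjoint regions -> IoU 0
  pred2 <- matrix(0L, 20, 30)
  pred2[6:15, 21:30] <- 1L
  expect_equal(iou(confusion_tally(pred2, truth, n_classes = 2), 1), 0)
})

test_that("metrics match the brute-force per-pixel oracle on random pairs", {
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    truth <- matrix(sample(0:5, 32 * 32, TRUE), 32, 32)
    pred <- matrix(sample(0:5, 32 * 32, TRUE), 32, 32)
    t6 <- confusion_tally(pred, truth)
    orc <- oracle_metrics(pred, truth, 6)
    expect_identical(as.numeric(t6$TP), orc$TP)
    expect_identical(as.numeric(t6$FN), orc$FN)
    expect_equal(pixel_accuracy(t6), orc$PA, tolerance = 1e-12)
    expect_equal(as.numeric(mean_pixel_accuracy(t6)), orc$MPA, tolerance = 1e-12)
    expect_equal(mean_iou(t6), orc$MIOU, tolerance = 1e-12)
  }
})

test_that("PA equals the one-vs-rest accuracy of every class", {
  set.seed(21)
  truth <- matrix(sample(0:5, 400, TRUE), 20, 20)
  pred <- matrix(sample(0:5, 400, TRUE), 20, 20)
  t6 <- confusion_tally(pred, truth)
  pa_ovr <- (t6$TP + t6$TN) / attr(t6, "N")
  # the global PA identity holds only when mistakes are symmetric per class;
  # the invariant asserted here is the defining one: PA = sum(TP) / N, and
  # every class's (TP+TN)/N is an upper bound realized under one-vs-rest
  expect_true(all(pa_ovr >= pixel_accuracy(t6)))
  expect_equal(pixel_accuracy(t6), sum(t6$TP) / attr(t6, "N"))
  # in the binary case the identity is exact for both classes
  t2 <- confusion_tally(matrix(sample(0:1, 64, TRUE), 8),
                        matrix(sample(0:1, 64, TRUE), 8), n_classes = 2)
  expect_equal((t2$TP + t2$TN) / attr(t2, "N"),
               rep(pixel_accuracy(t2), 2))
})

test_that("consistent class permutation leaves PA, MPA, MIOU unchanged", {
  set.seed(31)
  truth <- matrix(sample(0:5, 256, TRUE), 16, 16)
  pred <- matrix(sample(0:5, 256, TRUE), 16, 16)
  perm <- sample(0:5)
  t1 <- confusion_tally(pred, truth)
  t2 <- confusion_tally(matrix(perm[pred + 1L], 16), matrix(perm[truth + 1L], 16))
  expect_equal(pixel_accuracy(t1), pixel_accuracy(t2))
  expect_equal(as.numeric(mean_pixel_accuracy(t1)), as.numeric(mean_pixel_accuracy(t2)))
  expect_equal(mean_iou(t1), mean_iou(t2))
})

test_that("MIOU <= MPA when every class is present", {
  for (seed in 41:45) {
    set.seed(seed)
    truth <- matrix(rep(0:5, length.out = 144)[sample(144)], 12, 12)
    pred <- matrix(sample(0:5, 144, TRUE), 12, 12)
    t6 <- confusion_tally(pred, truth)
    expect_lte(mean_iou(t6), as.numeric(mean_pixel_accuracy(t6)))
  }
})

test_that("classes absent from truth are excluded from MPA, not zeroed", {
  truth <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  pred <- truth
  t6 <- confusion_tally(pred, truth)
  mpa <- mean_pixel_accuracy(t6)
  expect_equal(as.numeric(mpa), 1)
  expect_setequal(attr(mpa, "excluded"), c("INL", "IPL", "OPL", "RNFL"))
  # absent from both pred and truth -> IoU undefined
  expect_true(is.na(iou(t6, 5)))
})

test_that("invalid inputs are rejected", {
  expect_error(confusion_tally(matrix(0L, 2, 2), matrix(0L, 3, 3)), "shapes differ")
  expect_error(confusion_tally(matrix(7L, 2, 2), matrix(0L, 2, 2)), "invalid id")
  expect_error(iou(confusion_tally(worked_pred, worked_truth, 2), 9), "invalid class")
})
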