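test_that("confusion counts match hand enumeration", {
  gt <- matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 0), 3, 3)
  pred <- gt
  pred[1, 1] <- 0  # one miss
  cc <- confusion(pred, gt)
  expect_equal(cc, c(tp = 2, fp = 0, tn = 6, fn = 1))
  expect_equal(unname(confusion(gt, gt)[c("fp", "fn")]), c(0, 0))
  inv <- confusion(1 - gt, gt)
  expect_equal(unname(inv[c("tp", "tn")]), c(0, 0))
  # region restriction
  region <- matrix(0, 3, 3); region[1, ] <- 1
  expect_equal(sum(confusion(pred, gt, region)), 3)
  expect_error(confusion(pred, matrix(0, 2, 2)), "dims")
  expect_error(confusion(pred * 2, gt), "binary")
})

test_that("Se/Sp/Acc follow their formulas and swap under label flip", {
  expect_equal(se_sp_acc(c(tp = 1, fp = 1, tn = 1, fn = 1)),
               c(Se = 0.5, Sp = 0.5, Acc = 0.5))
  expect_equal(se_sp_acc(c(tp = 5, fp = 0, tn = 15, fn = 0)),
               c(Se = 1, Sp = 1, Acc = 1))
  cc <- c(tp = 7, fp = 2, tn = 30, fn = 3)
  m <- se_sp_acc(cc)
  sw <- se_sp_acc(c(tp = unname(cc["tn"]), fp = unname(cc["fn"]),
                    tn = unname(cc["tp"]), fn = unname(cc["fp"])))
  expect_equal(unname(sw["Se"]), unname(m["Sp"]))
  expect_equal(unname(sw["Sp"]), unname(m["Se"]))
  expect_equal(unname(sw["Acc"]), unname(m["Acc"]))
  # accuracy is the prevalence-weighted mean of Se and Sp
  prev <- (cc["tp"] + cc["fn"]) / sum(cc)
  expect_equal(unname(m["Acc"]),
               unname(prev * m["Se"] + (1 - prev) * m["Sp"]))
  expect_true(is.na(se_sp_acc(c(tp = 0, fp = 0, tn = 3, fn = 0))["Se"]))
})

test_that("whole-frame vessel arithmetic at 447x447 reproduces", {
  mask <- matrix(0L, 447, 447)
  mask[seq_len(19551)] <- 1L
  cc <- confusion(mask, mask)
  expect_equal(sum(cc), 199809)
  expect_equal(unname(cc["tp"]), 19551)
  expect_equal(unname(cc["tn"]), 180258)
  expect_equal(unname(se_sp_acc(cc)["Acc"]), 1)
})

test_that("AUC equals brute-force Mann-Whitney concordance on toys", {
  # perfectly separating scores
  gt <- matrix(c(1, 1, 1, 0, 0, 0), 2, 3)
  p <- matrix(c(0.9, 0.8, 0.7, 0.2, 0.1, 0.3), 2, 3)
  expect_equal(roc_auc(p, gt), 1)
  # constant scores carry no information
  expect_equal(roc_auc(matrix(0.4, 2, 3), gt), 0.5)
  # one inversion, checked against exhaustive pair counting
  p2 <- matrix(c(0.9, 0.2, 0.7, 0.8, 0.1, 0.3), 2, 3)
  expect_equal(roc_auc(p2, gt), mw_auc(as.vector(p2), as.vector(gt)))
  # random toys with ties
  for (s in 1:5) {
    withr::with_seed(s, {
      gt3 <- matrix(rbinom(9, 1, 0.5), 3, 3)
      p3 <- matrix(sample(seq(0, 1, 0.25), 9, replace = TRUE), 3, 3)
    })
    if (length(unique(as.vector(gt3))) < 2) next
    expect_equal(roc_auc(p3, gt3), mw_auc(as.vector(p3), as.vector(gt3)),
                 label = paste("seed", s))
  }
  expect_error(roc_auc(matrix(0.5, 2, 2), matrix(1, 2, 2)), "single class")
})

test_that("overlay colours are lossless with respect to the counts", {
  withr::with_seed(31, {
    img <- array(runif(16 * 16 * 3), c(16, 16, 3))
    gt <- matrix(rbinom(256, 1, 0.3), 16, 16)
    pred <- matrix(rbinom(256, 1, 0.3), 16, 16)
  })
  sty <- overlay_style()
  ov <- render_overlay(img, pred, gt, sty)
  is_col <- function(col) ov[, , 1] == col[1] & ov[, , 2] == col[2] &
    ov[, , 3] == col[3]
  cc <- confusion(pred, gt)
  expect_equal(sum(is_col(sty$tp)), unname(cc["tp"]))
  expect_equal(sum(is_col(sty$fp)), unname(cc["fp"]))
  expect_equal(sum(is_col(sty$fn)), unname(cc["fn"]))
  # perfect prediction leaves only tp colour among overlay colours
  ov2 <- render_overlay(img, gt, gt, sty)
  expect_equal(sum(is_col2 <- ov2[, , 3] == 1 & ov2[, , 1] == 0), sum(gt))
  # all-zero prediction paints misses only
  ov3 <- render_overlay(img, gt * 0L, gt, sty)
  expect_equal(sum(ov3[, , 1] == 0 & ov3[, , 2] == 0 & ov3[, , 3] == 0),
               sum(gt))
  expect_error(overlay_style(tp_color = c(0, 1, 0)), "distinct")
})

test_that("2x2 overlay enumerates to exact pixel colours", {
  img <- array(1, c(2, 2, 3))  # gray = 0.6 everywhere after dimming
  gt <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  pred <- matrix(c(1L, 0L, 1L, 0L), 2, 2)
  ov <- render_overlay(img, pred, gt)
  expect_equal(ov[1, 1, ], c(0, 0, 1))      # tp: blue
  expect_equal(ov[2, 1, ], c(0, 0, 0))      # fn: black
  expect_equal(ov[1, 2, ], c(0, 1, 0))      # fp: green
  expect_equal(ov[2, 2, ], rep(0.6, 3))     # tn: dimmed gray
})

test_that("dataset evaluation pools counts consistently", {
  model <- vn_init(plan_vessnet(c(32, 32, 3), 2, base_filters = 2), seed = 9)
  pairs <- generate_dataset(2, synth_params(image_size = 32, seed = 7,
                                            width_range = c(1, 2)))
  rep1 <- evaluate_dataset(model, pairs[1])
  rep2 <- evaluate_dataset(model, c(pairs[1], pairs[1]))
  # duplicating an image leaves the aggregate unchanged
  pooled1 <- rep1[rep1$id == "pooled", c("Se", "Sp", "Acc", "AUC")]
  pooled2 <- rep2[rep2$id == "pooled", c("Se", "Sp", "Acc", "AUC")]
  expect_equal(unname(unlist(pooled1)), unname(unlist(pooled2)))
  rep <- evaluate_dataset(model, pairs)
  expect_equal(nrow(rep), 3L)  # 2 images + pooled row
  # pooled accuracy is the count-weighted mean of per-image accuracies
  per <- rep[rep$id != "pooled", ]
  wts <- rowSums(per[, c("tp", "fp", "tn", "fn")])
  expect_equal(rep$Acc[rep$id == "pooled"],
               sum(per$Acc * wts) / sum(wts))
  # TSV export round-trips
  f <- withr::local_tempfile(fileext = ".tsv")
  evaluate_dataset(model, pairs, out = f)
  expect_equal(nrow(utils::read.delim(f)), 3L)
  expect_error(evaluate_dataset(model, list()), "empty")
})
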