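test_that("confusion matrices cross-tabulate exactly", {
  tr <- rep(TISSUE_CLASSES, c(4, 3, 3))
  cm <- confusion_matrix(tr, tr)
  expect_equal(unname(diag(as.matrix(cm))), c(4L, 3L, 3L))
  expect_equal(sum(cm) - sum(diag(as.matrix(cm))), 0L)

  cm2 <- confusion_matrix(c("cancer", "cancer"), c("cancer", "glands"))
  expect_equal(cm2["cancer", "cancer"], 1L, ignore_attr = TRUE)
  expect_equal(cm2["cancer", "glands"], 1L, ignore_attr = TRUE)
  expect_equal(attr(cm2, "n_pixels"), 2L)

  expect_error(confusion_matrix(c("cancer", "glands"), "cancer"),
               "length")

  # trace/n equals independently computed accuracy on a synthetic run
  set.seed(8)
  truth <- sample(TISSUE_CLASSES, 500, TRUE)
  pred <- ifelse(runif(500) < 0.8, truth, sample(TISSUE_CLASSES, 500, TRUE))
  cm3 <- confusion_matrix(truth, pred)
  expect_equal(sum(diag(as.matrix(cm3))) / attr(cm3, "n_pixels"),
               mean(truth == pred))
})

test_that("agreement reports reproduce every printed training-table cell", {
  rep_tr <- agreement_report(load_reference_confusion("training"))
  disp <- agreement_display(rep_tr)
  expect_equal(disp$agreement, c(96.4, 99.3, 79.9, 98.1))
  expect_equal(disp$se, c(0.19, 0.05, 1.08, 0.06))
  expect_equal(disp$n, c(9870, 34014, 1389, 45273))
})

test_that("agreement reports reproduce every printed validation-table cell", {
  rep_va <- agreement_report(load_reference_confusion("validation"))
  disp <- agreement_display(rep_va)
  expect_equal(disp$agreement, c(95.4, 99.8, 83.8, 98.6))
  expect_equal(disp$se, c(0.25, 0.03, 1.47, 0.07))
})

test_that("degenerate agreement inputs behave", {
  id <- desilasso:::as_confusion_matrix(diag(100, 3))
  rownames(id) <- colnames(id) <- TISSUE_CLASSES
  disp <- agreement_display(agreement_report(id))
  expect_equal(disp$agreement, rep(100, 4))
  expect_equal(disp$se, rep(0, 4))
  empty_row <- desilasso:::as_confusion_matrix(
    matrix(c(5, 0, 0, 0, 0, 0, 0, 0, 0), 3, byrow = TRUE,
           dimnames = list(TISSUE_CLASSES, TISSUE_CLASSES)))
  expect_warning(rep2 <- agreement_report(empty_row), "zero pixels")
  expect_equal(nrow(rep2$per_class), 1)
  expect_error(agreement_report(desilasso:::as_confusion_matrix(matrix(0, 3, 3))),
               "empty")
})

test_that("merging glands and stroma into normal reproduces the two-class tables", {
  tr <- merge_classes(load_reference_confusion("training"))
  expect_equal(unname(tr["normal", ]), c(238L, 35165L), ignore_attr = TRUE)
  expect_equal(unname(tr["cancer", ]), c(9514L, 356L), ignore_attr = TRUE)
  expect_equal(attr(tr, "n_pixels"), 45273L)
  # merged overall: 44679/45273 = 98.7 after display rounding (the
  # two-class reading of the training table)
  expect_equal(round(agreement_report(tr)$overall$agreement, 1), 98.7)

  va <- merge_classes(load_reference_confusion("validation"))
  expect_equal(va["normal", "cancer"], 26L, ignore_attr = TRUE)
  expect_equal(round(agreement_report(va)$overall$agreement, 1), 98.9)

  # cancer-row diagonal and pixel totals survive any merge
  all_one <- merge_classes(load_reference_confusion("training"),
                           c(cancer = "t", glands = "t", stroma = "t"))
  expect_equal(as.integer(all_one), attr(all_one, "n_pixels"))
  expect_equal(agreement_report(all_one)$overall$agreement, 100)
})

test_that("majority rule uses a strict 50% boundary", {
  mk <- function(n_cancer, n_total) {
    factor(rep(c("cancer", "glands"), c(n_cancer, n_total - n_cancer)),
           levels = TISSUE_CLASSES)
  }
  expect_equal(majority_rule_verdict(mk(60, 100), "a")$verdict, "cancer")
  expect_equal(majority_rule_verdict(mk(50, 100), "b")$verdict, "normal")
  expect_equal(majority_rule_verdict(mk(51, 100), "c")$verdict, "cancer")
  v <- majority_rule_verdict(mk(12, 100), "d")
  expect_equal(v$verdict, "normal")
  expect_equal(v$fraction_cancer, 0.12)
})

test_that("composition agreement compares predicted and pathology percentages", {
  lab <- matrix("glands", 10, 10)
  rmap <- matrix(1L, 10, 10)
  mask <- annotation_mask(lab, regions = data.frame(
    region_id = 1L, f_cancer = 0.15, f_glands = 0.85, f_stroma = 0),
    region_map = rmap)
  # prediction with 12% cancer pixels: within default 10-point tolerance
  pred <- structure(list(class = factor(
    rep(c("cancer", "glands"), c(12, 88)), levels = TISSUE_CLASSES)),
    class = "pixel_prediction")
  cc <- composition_agreement(pred, mask)
  expect_true(cc$pass)
  expect_equal(cc$abs_difference, 3)
  # 20% truth vs 81% predicted: fails
  mask2 <- annotation_mask(lab, regions = data.frame(
    region_id = 1L, f_cancer = 0.2, f_glands = 0, f_stroma = 0.8),
    region_map = rmap)
  pred2 <- structure(list(class = factor(
    rep(c("cancer", "stroma"), c(81, 19)), levels = TISSUE_CLASSES)),
    class = "pixel_prediction")
  cc2 <- composition_agreement(pred2, mask2)
  expect_false(cc2$pass)
  # exact match passes with zero difference
  pred3 <- structure(list(class = factor(
    rep(c("cancer", "stroma"), c(20, 80)), levels = TISSUE_CLASSES)),
    class = "pixel_prediction")
  expect_equal(composition_agreement(pred3, mask2)$abs_difference, 0)
})

test_that("margin reports flag by threshold and roll up to the case", {
  mr <- margin_report(c(neck = 0, uncinate = 0.12))
  expect_identical(mr$flagged, c(FALSE, TRUE))
  expect_true(attr(mr, "case_positive"))
  mr2 <- margin_report(c(neck = 0.005), threshold_pct = 1)
  expect_false(attr(mr2, "case_positive"))
  # saturation: a 100% threshold can never flag
  mr3 <- margin_report(c(a = 1, b = 0.5), threshold_pct = 100)
  expect_false(any(mr3$flagged))
  # verdict-list input
  v <- list(majority_rule_verdict(
    factor(rep("glands", 10), levels = TISSUE_CLASSES), "neck"))
  expect_false(attr(margin_report(v), "case_positive"))
})
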