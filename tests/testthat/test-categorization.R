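# Fixture: Gaussian clusters in the LF-HF plane with controllable layout.
make_clusters <- function(centers, n = 30, sd = 1, seed = 1,
                          subject = NULL) {
  set.seed(seed)
  df <- purrr::imap_dfr(centers, function(ctr, lbl) {
    tibble::tibble(label = lbl,
                   LFiA_ms = rnorm(n, ctr[1], sd),
                   HFiA_ms = rnorm(n, ctr[2], sd))
  })
  if (!is.null(subject)) df$subject_id <- subject
  df
}

test_that("baseline standardization centers each subject's baseline at the origin", {
  d1 <- make_clusters(list(rest = c(30, 40), task = c(50, 20)), seed = 2,
                      subject = "S1")
  d2 <- make_clusters(list(rest = c(45, 55), task = c(60, 30)), seed = 3,
                      subject = "S2")
  d <- dplyr::bind_rows(d1, d2)
  s <- standardize_by_baseline(d, "rest")
  for (subj in c("S1", "S2")) {
    base <- s[s$subject_id == subj & s$label == "rest", ]
    expect_equal(median(base$LFiA_ms), 0)
    expect_equal(median(base$HFiA_ms), 0)
  }
  # subjects are centered independently: task offsets differ from pooled
  expect_false(isTRUE(all.equal(
    median(s$LFiA_ms[s$label == "task" & s$subject_id == "S1"]),
    median(s$LFiA_ms[s$label == "task" & s$subject_id == "S2"]))))

  # constant features collapse to zero
  cst <- tibble::tibble(label = rep(c("rest", "go"), each = 4),
                        LFiA_ms = 7, HFiA_ms = 9)
  z <- standardize_by_baseline(cst, "rest")
  expect_true(all(z$LFiA_ms == 0) && all(z$HFiA_ms == 0))

  # idempotence
  expect_equal(standardize_by_baseline(s, "rest"), s)
  expect_error(standardize_by_baseline(d, "nope"), "not present")
})

test_that("well-separated clusters are categorized perfectly in 2D", {
  d <- make_clusters(list(rest = c(30, 40), stress = c(60, 10)), seed = 4)
  m <- fit_categorizer_2d(d)
  expect_equal(categorization_accuracy(m), 100)
  expect_identical(as.character(predict(m, d)), d$label)
})

test_that("three-cluster fits carve contiguous regions containing their centroids", {
  centers <- list(rest = c(20, 45), mental = c(55, 15), exercise = c(18, 12))
  d <- make_clusters(centers, sd = 2, seed = 5)
  m <- fit_categorizer_2d(d)
  for (lbl in names(centers)) {
    nd <- tibble::tibble(LFiA_ms = centers[[lbl]][1],
                         HFiA_ms = centers[[lbl]][2])
    expect_equal(as.character(predict(m, nd)), lbl)
  }
  dm <- decision_map(m, resolution = 60)
  expect_setequal(unique(as.character(dm$label)), names(centers))
})

test_that("refitting on identical data reproduces identical predictions", {
  d <- make_clusters(list(a = c(30, 40), b = c(50, 20)), sd = 4, seed = 6)
  m1 <- fit_categorizer_2d(d)
  m2 <- fit_categorizer_2d(d)
  expect_identical(predict(m1, d), predict(m2, d))
})

test_that("1D fits use only their feature and lose on jointly-separable data", {
  # separable along LFiA alone: 1D matches 2D at 100%
  d <- make_clusters(list(a = c(20, 30), b = c(60, 30)), sd = 2, seed = 7)
  expect_equal(categorization_accuracy(fit_categorizer_1d(d, "LFiA_ms")), 100)
  expect_equal(categorization_accuracy(fit_categorizer_2d(d)), 100)

  # XOR-like layout: no single axis separates, the plane does
  xor <- dplyr::bind_rows(
    make_clusters(list(a = c(20, 20)), n = 20, sd = 1.5, seed = 8),
    make_clusters(list(a = c(60, 60)), n = 20, sd = 1.5, seed = 9),
    make_clusters(list(b = c(20, 60)), n = 20, sd = 1.5, seed = 10),
    make_clusters(list(b = c(60, 20)), n = 20, sd = 1.5, seed = 11))
  ca2 <- categorization_accuracy(fit_categorizer_2d(xor))
  ca_lf <- categorization_accuracy(fit_categorizer_1d(xor, "LFiA_ms"))
  ca_hf <- categorization_accuracy(fit_categorizer_1d(xor, "HFiA_ms"))
  expect_gt(ca2, max(ca_lf, ca_hf))
  expect_gt(ca2, 90)
  expect_lt(max(ca_lf, ca_hf), 75)
})

test_that("1D predictions ignore the other feature entirely", {
  d <- make_clusters(list(a = c(20, 30), b = c(60, 30)), sd = 2, seed = 12)
  m <- fit_categorizer_1d(d, "LFiA_ms")
  shifted <- d
  shifted$HFiA_ms <- d$HFiA_ms + 1e4
  expect_identical(predict(m, d), predict(m, shifted))
})

test_that("accuracy is chance-level for permuted labels and 50% for one-sided predictions", {
  set.seed(13)
  d <- make_clusters(list(a = c(30, 40), b = c(45, 25), c = c(20, 15)),
                     n = 60, sd = 3, seed = 13)
  d$label <- sample(d$label)
  ca <- categorization_accuracy(fit_categorizer_2d(d))
  expect_gt(ca, 20)
  expect_lt(ca, 50)

  # balanced binary data far inside one region: half the rows are right
  m <- fit_categorizer_2d(make_clusters(list(a = c(0, 0), b = c(100, 100)),
                                        seed = 14))
  probe <- tibble::tibble(label = rep(c("a", "b"), each = 10),
                          LFiA_ms = rnorm(20, 0, 1),
                          HFiA_ms = rnorm(20, 0, 1))
  expect_equal(categorization_accuracy(m, probe), 50)
  expect_error(categorization_accuracy(m, probe[0, ]), "no rows")
})

test_that("cross-validated accuracy is reported and plausible for separable data", {
  d <- make_clusters(list(a = c(30, 40), b = c(60, 10)), n = 40, sd = 2,
                     seed = 15)
  m <- fit_categorizer_2d(d)
  ca_cv <- categorization_accuracy(m, mode = "cv", folds = 5, seed = 1)
  expect_gte(ca_cv, 95)
})

test_that("degenerate fits are rejected", {
  one <- make_clusters(list(a = c(30, 40)), seed = 16)
  expect_error(fit_categorizer_2d(one), "2 classes")
  tiny <- make_clusters(list(a = c(30, 40), b = c(50, 20)), n = 2, seed = 17)
  expect_error(fit_categorizer_2d(tiny), "3 rows")
})

test_that("rank-sum comparisons are exact for small untied samples", {
  expect_equal(wilcoxon_scenarios(c(1, 2, 3), c(1, 2, 3)), 1)
  p <- wilcoxon_scenarios(1:5, 6:10)
  expect_equal(p, 2 / 252)
  expect_equal(p, ranksum_enum_p(1:5, 6:10))

  a <- c(3.5)
  b <- c(1, 2, 3, 4, 5)
  p1 <- wilcoxon_scenarios(a, b)
  expect_equal(p1, ranksum_enum_p(a, b))
  expect_gt(p1, 0.05)

  set.seed(18)
  for (i in 1:10) {
    a <- rnorm(sample(2:6, 1))
    b <- rnorm(sample(2:6, 1))
    expect_equal(wilcoxon_scenarios(a, b), ranksum_enum_p(a, b))
  }
  expect_error(wilcoxon_scenarios(numeric(0), 1:3), "non-empty")
})

test_that("decision maps cover the plane consistently with point predictions", {
  d <- make_clusters(list(a = c(30, 40), b = c(60, 10)), seed = 19)
  m <- fit_categorizer_2d(d)
  dm <- decision_map(m, resolution = 80)
  expect_equal(nrow(dm), 80 * 80)
  expect_setequal(unique(as.character(dm$label)), c("a", "b"))

  # each training point's nearest cell carries its predicted label
  pred <- as.character(predict(m, d))
  for (i in seq_len(10)) {
    j <- which.min((dm$x - d$LFiA_ms[i])^2 + (dm$y - d$HFiA_ms[i])^2)
    expect_equal(as.character(dm$label[j]), pred[i])
  }
  # doubling the resolution does not move training-point predictions
  dm2 <- decision_map(m, resolution = 160)
  for (i in seq_len(10)) {
    j <- which.min((dm2$x - d$LFiA_ms[i])^2 + (dm2$y - d$HFiA_ms[i])^2)
    expect_equal(as.character(dm2$label[j]), pred[i])
  }
  expect_error(decision_map(m, resolution = 0), "positive")
})

test_that("tidy and glance summarise categorizers", {
  d <- make_clusters(list(a = c(30, 40), b = c(60, 10)), seed = 20)
  m <- fit_categorizer_2d(d)
  td <- tidy(m)
  expect_true(all(c("truth", "prediction", "n", "correct") %in% names(td)))
  expect_equal(sum(td$n), nrow(d))
  gl <- glance(m)
  expect_equal(gl$n_classes, 2)
  expect_equal(gl$accuracy_pct, 100)
})
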