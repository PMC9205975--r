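test_that("gold-standard files parse exactly, with line-numbered errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("G1\tG2\t1", "G2\tG3\t0", "G1\tG3\t1", "G3\tG1\t0",
               "G3\tG2\t1"), path)
  gold <- read_gold_standard(path)
  expect_identical(nrow(gold), 5L)
  expect_identical(gold$label, c(1L, 0L, 1L, 0L, 1L))
  expect_identical(gold$regulator[1], "G1")

  writeLines("G1\tG2\t1", path)
  one <- read_gold_standard(path)
  expect_identical(one$label, 1L)

  writeLines(c("G1\tG2\t1", "G2\tG3"), path)
  expect_error(read_gold_standard(path), "line 2")
  writeLines("G1\tG2\t7", path)
  expect_error(read_gold_standard(path), "label")
})

test_that("an empty file plus a 3-gene universe yields 6 negative pairs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), path)
  gold <- read_gold_standard(path, universe = c("A", "B", "C"))
  expect_identical(nrow(gold), 6L)
  expect_true(all(gold$label == 0L))
  expect_false(any(gold$regulator == gold$target))
})

test_that("perfect rankings and all-tied scores give textbook areas", {
  gold <- tibble::tibble(
    regulator = c("A", "A", "B", "B", "C", "C"),
    target = c("B", "C", "A", "C", "A", "B"),
    label = c(1L, 1L, 0L, 0L, 0L, 0L)
  )
  perfect <- tibble::tibble(source = gold$regulator, target = gold$target,
                            te = c(0.9, 0.8, 0.2, 0.1, 0.3, 0.05))
  bm <- benchmark_network(perfect, gold)
  expect_equal(bm$auroc, 1.0)
  expect_equal(bm$auprc, 1.0)

  tied <- dplyr::mutate(perfect, te = 0.4)
  expect_equal(benchmark_network(tied, gold)$auroc, 0.5)
})

test_that("sweep AUROC equals the pairwise rank statistic", {
  gold <- tibble::tibble(
    regulator = c("A", "A", "B", "B", "C", "C"),
    target = c("B", "C", "A", "C", "A", "B"),
    label = c(1L, 0L, 0L, 1L, 0L, 0L)
  )
  scores <- tibble::tibble(source = gold$regulator, target = gold$target,
                           te = c(0.7, 0.6, 0.1, 0.3, 0.5, 0.2))
  bm <- benchmark_network(scores, gold)
  expect_equal(bm$auroc, rank_auroc(scores$te, gold$label), tolerance = 1e-12)

  # property: random scores with ties, many instances
  set.seed(17)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) == 0 || sum(labels) == n) next
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    genes <- sprintf("g%02d", 1:(n + 1))
    g <- tibble::tibble(regulator = genes[1:n], target = genes[n + 1],
                        label = labels)
    s <- tibble::tibble(source = g$regulator, target = g$target, te = sc)
    expect_equal(benchmark_network(s, g)$auroc, rank_auroc(sc, labels),
                 tolerance = 1e-12)
  }
})

test_that("sweep AUROC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  n <- 60
  labels <- rbinom(n, 1, 0.4)
  labels[1:2] <- c(0L, 1L)
  sc <- round(runif(n), 2)
  genes <- sprintf("g%02d", 1:(n + 1))
  g <- tibble::tibble(regulator = genes[1:n], target = genes[n + 1],
                      label = labels)
  s <- tibble::tibble(source = g$regulator, target = g$target, te = sc)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(benchmark_network(s, g)$auroc, ref, tolerance = 1e-12)
})

test_that("inverting scores reflects AUROC about one half", {
  set.seed(29)
  n <- 30
  labels <- c(1L, 0L, rbinom(n - 2, 1, 0.5))
  sc <- runif(n) # continuous, no ties
  genes <- sprintf("g%02d", 1:(n + 1))
  g <- tibble::tibble(regulator = genes[1:n], target = genes[n + 1],
                      label = labels)
  s <- tibble::tibble(source = g$regulator, target = g$target, te = sc)
  s_inv <- dplyr::mutate(s, te = -te)
  expect_equal(benchmark_network(s, g)$auroc,
               1 - benchmark_network(s_inv, g)$auroc, tolerance = 1e-12)
})

test_that("AUPRC of random scores concentrates near prevalence", {
  genes <- sprintf("g%02d", 1:10)
  gold <- tidyr::expand_grid(regulator = genes, target = genes) |>
    dplyr::filter(regulator != target)
  set.seed(31)
  gold$label <- as.integer(seq_len(nrow(gold)) %in% sample(nrow(gold), 27))
  prevalence <- mean(gold$label)
  auprcs <- vapply(1:200, function(i) {
    s <- tibble::tibble(source = gold$regulator, target = gold$target,
                        te = runif(nrow(gold)))
    benchmark_network(s, gold)$auprc
  }, numeric(1))
  expect_lt(abs(mean(auprcs) - prevalence), 0.05)
})

test_that("degenerate gold standards and unknown pairs raise errors", {
  gold <- tibble::tibble(regulator = c("A", "B"), target = c("B", "A"),
                         label = c(1L, 1L))
  s <- tibble::tibble(source = c("A", "B"), target = c("B", "A"),
                      te = c(0.5, 0.2))
  expect_error(benchmark_network(s, gold), "positive")
  s2 <- dplyr::add_row(s, source = "A", target = "Z", te = 0.1)
  gold2 <- dplyr::mutate(gold, label = c(1L, 0L))
  expect_error(benchmark_network(s2, gold2), "without a gold label")
})

test_that("unscored gold pairs are ranked last with a coverage warning", {
  gold <- tibble::tibble(regulator = c("A", "B", "C"),
                         target = c("B", "C", "A"),
                         label = c(1L, 0L, 0L))
  s <- tibble::tibble(source = "A", target = "B", te = 0.9)
  expect_warning(bm <- benchmark_network(s, gold), "not scored")
  expect_equal(bm$auroc, 1.0)
})

test_that("confusion metrics follow the PPV and sensitivity formulas", {
  # TP=3, FP=1, FN=2 -> PPV 0.75, Se 0.6
  gold <- tibble::tibble(
    regulator = sprintf("r%d", 1:7), target = sprintf("t%d", 1:7),
    label = c(1L, 1L, 1L, 0L, 1L, 1L, 0L)
  )
  s <- tibble::tibble(source = gold$regulator, target = gold$target,
                      te = c(0.9, 0.8, 0.7, 0.6, 0.1, 0.2, 0.05))
  cm <- confusion_at_threshold(s, gold, threshold = 0.5)
  expect_identical(c(cm$tp, cm$fp, cm$fn, cm$tn), c(3L, 1L, 2L, 1L))
  expect_equal(cm$ppv, 0.75)
  expect_equal(cm$sensitivity, 0.6)

  expect_warning(hi <- confusion_at_threshold(s, gold, threshold = 2),
                 "PPV undefined")
  expect_identical(c(hi$tp, hi$fp), c(0L, 0L))
  expect_true(is.na(hi$ppv))
})

test_that("benchmark objects expose tidy, glance, and autoplot", {
  gold <- tibble::tibble(
    regulator = c("A", "A", "B", "B", "C", "C"),
    target = c("B", "C", "A", "C", "A", "B"),
    label = c(1L, 1L, 0L, 0L, 0L, 0L)
  )
  s <- tibble::tibble(source = gold$regulator, target = gold$target,
                      te = seq(0.9, 0.4, length.out = 6))
  bm <- benchmark_network(s, gold)
  expect_s3_class(tidy(bm), "tbl_df")
  expect_true(all(c("threshold", "tpr", "fpr", "precision", "recall") %in%
                    names(tidy(bm))))
  g <- glance(bm)
  expect_identical(nrow(g), 1L)
  expect_identical(g$n_pos, 2L)
  expect_s3_class(autoplot(bm), "ggplot")
})
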