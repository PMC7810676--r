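test_that("the split design yields 669 training and 450 test events", {
  labels <- rep(paste0("sp", 1:9), each = 500)
  sp <- split_spec("sp3", seed = 7L)
  idx <- build_split(labels, sp)
  expect_length(idx$train, 669L)
  expect_length(idx$test, 450L)
  expect_identical(sum(labels[idx$train] == "sp3"), 333L)
  expect_true(all(table(labels[idx$train][labels[idx$train] != "sp3"]) == 42L))
  expect_true(all(table(labels[idx$test]) == 50L))
  # strict mode: train and test disjoint
  expect_length(intersect(idx$train, idx$test), 0L)
  # deterministic in the seed
  expect_identical(build_split(labels, sp), idx)
  expect_false(identical(build_split(labels, split_spec("sp3", seed = 8L)),
                         idx))
})

test_that("small pools error in strict mode but pass in lenient mode", {
  labels <- rep(paste0("sp", 1:9), each = 370)   # < 333 + 50
  expect_error(build_split(labels, split_spec("sp1", seed = 1L)),
               "too small")
  expect_warning(idx <- build_split(labels,
                                    split_spec("sp1", seed = 1L,
                                               strict = FALSE)),
                 "overlap")
  expect_length(idx$train, 669L)
  expect_length(idx$test, 450L)
  expect_error(build_split(labels, split_spec("absent", seed = 1L)),
               "not present")
})

test_that("accuracy is the fraction of correct labels", {
  expect_identical(classification_accuracy(c("a", "b"), c("a", "b")), 1)
  expect_identical(classification_accuracy(c("a", "b"), c("b", "a")), 0)
  # TP = 40, TN = 35, FP = 15, FN = 10 -> 75 / 100
  predicted <- c(rep("target", 40), rep("other", 35),
                 rep("target", 15), rep("other", 10))
  truth <- c(rep("target", 40), rep("other", 35),
             rep("other", 15), rep("target", 10))
  expect_identical(classification_accuracy(predicted, truth), 0.75)
  expect_error(classification_accuracy("a", c("a", "b")), "equal length")
})

test_that("pairwise accuracy restricts to the species pair", {
  truth_species <- rep(c("t", "u", "v"), each = 50)
  # all-'target' predictions: 50 TP + 50 FP -> 0.5 on any pair
  predicted <- rep("target", 150)
  expect_identical(pairwise_accuracy(predicted, truth_species, "t", "u"),
                   0.5)
  # definitional equality with accuracy() on the 100-event subset
  withr::with_seed(5, predicted <- sample(c("target", "other"), 150,
                                          replace = TRUE))
  sel <- truth_species %in% c("t", "v")
  expect_identical(
    pairwise_accuracy(predicted, truth_species, "t", "v"),
    classification_accuracy(predicted[sel],
                            ifelse(truth_species[sel] == "t", "target",
                                   "other")))
  expect_error(pairwise_accuracy(predicted, truth_species, "t", "zz"),
               "no test events")
})

test_that("bootstrap intervals follow the linear-interpolation convention", {
  expect_equal(bootstrap_interval(1:100),
               c(low = 5.95, high = 95.05))
  expect_identical(unname(diff(bootstrap_interval(rep(0.8, 10)))), 0)
  withr::with_seed(9, {
    for (i in 1:10) {
      v <- runif(sample(5:200, 1))
      bi <- bootstrap_interval(v)
      expect_lte(bi[["low"]], median(v))
      expect_gte(bi[["high"]], median(v))
    }
  })
  expect_error(bootstrap_interval(0.5), "at least 2")
})

# a hand-built evaluation with known pairwise means
toy_evaluation <- function(acc) {
  # acc: named list target -> named numeric of other-species means
  pair_rows <- list(); fold_rows <- list()
  for (target in names(acc)) for (m in c("m1", "m2")) {
    for (fold in 1:2) {
      fold_rows[[length(fold_rows) + 1L]] <-
        data.frame(target = target, method = m, fold = fold,
                   accuracy = mean(acc[[target]]))
      for (other in names(acc[[target]])) {
        shift <- if (m == "m2") 0.01 else 0
        pair_rows[[length(pair_rows) + 1L]] <-
          data.frame(target = target, method = m, fold = fold,
                     other = other,
                     accuracy = acc[[target]][[other]] + shift)
      }
    }
  }
  structure(list(folds = do.call(rbind, fold_rows),
                 pairwise = do.call(rbind, pair_rows),
                 n_train_sessions = length(fold_rows),
                 n_pairwise_sessions = length(pair_rows),
                 methods = c("m1", "m2"), targets = names(acc),
                 n_folds = 2L, seed = 1L),
            class = "wb_evaluation")
}

test_that("hardest-other selects the minimum mean with lexical ties", {
  ev <- toy_evaluation(list(t1 = c(b = 0.9, c = 0.7, d = 0.8),
                            t2 = c(a = 0.6, c = 0.6, d = 0.95)))
  s <- summary(ev)
  expect_identical(hardest_other(s, "t1", "m1"), "c")
  # two-way tie at 0.6 -> lexicographically first
  expect_identical(hardest_other(s, "t2", "m1"), "a")
  # removing the hardest species leaves the second-lowest
  ev2 <- ev
  ev2$pairwise <- ev2$pairwise[!(ev2$pairwise$target == "t1" &
                                   ev2$pairwise$other == "c"), ]
  expect_identical(hardest_other(summary(ev2), "t1", "m1"), "d")
  expect_error(hardest_other(s, "t9", "m1"), "no such")
})

test_that("method comparisons count wins over the pair grid", {
  ev <- toy_evaluation(list(t1 = c(b = 0.9, c = 0.7, d = 0.8),
                            t2 = c(a = 0.6, c = 0.6, d = 0.95)))
  s <- summary(ev)
  self <- compare_methods(s, "m1", "m1")
  expect_identical(self$a_wins + self$b_wins, 0L)
  expect_identical(self$ties, self$n_pairs)
  # m2 constructed to beat m1 on every pair
  cmp <- compare_methods(s, "m2", "m1")
  expect_identical(cmp$a_wins, cmp$n_pairs)
  expect_identical(cmp$a_wins + cmp$b_wins + cmp$ties, cmp$n_pairs)
  expect_error(compare_methods(s, "m1", "nope"), "same")
})

test_that("summary statistics recompute exactly from the raw folds", {
  ev <- grid_folds2()
  s <- summary(ev)
  # spot-check each (target, method) cell against direct recomputation
  for (i in sample(nrow(s$overall), 5)) {
    row <- s$overall[i, ]
    v <- ev$folds$accuracy[ev$folds$target == row$target &
                             ev$folds$method == row$method]
    expect_identical(row$mean, mean(v))
    expect_identical(row$median, median(v))
  }
  row <- s$pairwise[17, ]
  v <- ev$pairwise$accuracy[ev$pairwise$target == row$target &
                              ev$pairwise$method == row$method &
                              ev$pairwise$other == row$other]
  expect_identical(row$mean, mean(v))
  bi <- bootstrap_interval(v)
  expect_identical(row$low, bi[["low"]])
  expect_identical(row$high, bi[["high"]])
})

test_that("the experiment loop counts sessions by the grid formula", {
  ds <- fixture("separable_pair", flyer_pair(120, 550, sd = 8, n = 80L,
                                             seed = 41L))
  dm <- fixture("separable_design", design_matrices(ds))
  ev <- run_experiment(design = dm, methods = c("wbf", "features"),
                       n_folds = 3L, seed = 1L,
                       split = split_spec("x", 30L, 30L, 15L))
  # 2 targets x 2 methods x 3 folds
  expect_identical(ev$n_train_sessions, 12L)
  # x 1 other species each
  expect_identical(ev$n_pairwise_sessions, 12L)
  expect_identical(nrow(ev$folds), 12L)
  expect_true(all(ev$folds$accuracy >= 0 & ev$folds$accuracy <= 1))

  # one fold replayed by hand: the stored overall accuracy equals a
  # brute-force event-by-event confusion count
  fold_seed <- wingbeatr:::derive_seed(1L, "species_a", "wbf", 2L)
  idx <- build_split(dm$labels, split_spec("species_a", 30L, 30L, 15L,
                                           seed = fold_seed))
  clf <- fit_classifier("wbf", dm$wbf[idx$train, , drop = FALSE],
                        dm$labels[idx$train] == "species_a",
                        seed = wingbeatr:::derive_seed(fold_seed, "fit"))
  pred <- predict(clf, dm$wbf[idx$test, , drop = FALSE])
  truth <- ifelse(dm$labels[idx$test] == "species_a", "target", "other")
  tp <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == "target" && truth[i] == "target") tp <- tp + 1L
    if (pred[i] == "other" && truth[i] == "other") tn <- tn + 1L
  }
  stored <- ev$folds$accuracy[ev$folds$target == "species_a" &
                                ev$folds$method == "wbf" &
                                ev$folds$fold == 2L]
  expect_identical(stored, (tp + tn) / length(pred))
})
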