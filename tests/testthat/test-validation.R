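# Stratified review sampling, confusion matrices, the 12-metric suite,
# threshold calibration, lost-information accounting, FN imputation.

test_that("stratified allocation is proportional with largest-remainder totals", {
  ids <- c(sprintf("a%03d", 1:100), sprintf("b%02d", 1:50))
  strata <- rep(c("A", "B"), c(100, 50))
  s <- stratified_sample(ids, strata, 0.1, seed = 5)
  expect_length(s, 15)
  expect_equal(sum(grepl("^a", s)), 10)
  expect_equal(sum(grepl("^b", s)), 5)
  expect_false(anyDuplicated(s) > 0)          # without replacement
  # fraction 1 returns everything
  expect_setequal(stratified_sample(ids, strata, 1, seed = 1), ids)
})

test_that("per-stratum allocations stay within one of exact shares; same seed reproduces", {
  set.seed(2)
  sizes <- sample(5:200, 10)
  strata <- rep(LETTERS[1:10], sizes)
  ids <- sprintf("%s%04d", strata, seq_along(strata))
  s1 <- stratified_sample(ids, strata, 0.13, seed = 99)
  s2 <- stratified_sample(ids, strata, 0.13, seed = 99)
  expect_identical(as.character(s1), as.character(s2))
  expect_length(s1, round(0.13 * length(ids)))
  got <- table(factor(substr(s1, 1, 1), levels = LETTERS[1:10]))
  expect_true(all(abs(got - 0.13 * sizes) <= 1))
  s3 <- stratified_sample(ids, strata, 0.13, seed = 100)
  expect_false(identical(as.character(s1), as.character(s3)))
})

test_that("confusion matrix enumerates the four cells at a threshold", {
  truth <- stats::setNames(c(TRUE, TRUE, FALSE, FALSE), paste0("v", 1:4))
  conf <- stats::setNames(c(0.9, 0.5, 0.9, 0.1), paste0("v", 1:4))
  cm <- confusion_matrix(truth, conf, threshold = 0.8)
  expect_equal(cm[cm$stratum == "all", c("tp", "fn", "fp", "tn")],
               data.frame(tp = 1, fn = 1, fp = 1, tn = 1),
               ignore_attr = TRUE)
  # all-negative truth at threshold 1: everything is a true negative
  tn_only <- confusion_matrix(stats::setNames(rep(FALSE, 4), paste0("v", 1:4)),
                              conf, threshold = 1)
  expect_equal(tn_only$tn, 4)
  expect_equal(tn_only$n, 4)
})

test_that("confusion matrix equals a brute-force four-way scan on synthetic videos", {
  cfg <- scenario_config(frames_per_video = 3)
  sim <- simulate_video_index(2500, 2500, cfg, seed = 17)
  cm <- confusion_matrix(sim$truth, sim$index, threshold = 0.8)
  conf <- sim$index$animal[match(names(sim$truth), sim$index$media_id)]
  sel <- conf > 0.8
  expect_equal(cm$tp, sum(sim$truth & sel))
  expect_equal(cm$tn, sum(!sim$truth & !sel))
  expect_equal(cm$fp, sum(!sim$truth & sel))
  expect_equal(cm$fn, sum(sim$truth & !sel))
  expect_equal(cm$n, 5000)
})

test_that("metric suite matches the independent formula transcription to 1e-12", {
  set.seed(123)
  for (i in 1:200) {
    cells <- as.list(rpois(4, lambda = sample(c(1, 5, 50, 500), 4,
                                              replace = TRUE)))
    names(cells) <- c("tp", "tn", "fp", "fn")
    if (sum(unlist(cells)) == 0) cells$tp <- 1L
    cm <- as.data.frame(cells)
    got <- compute_metrics(cm)
    want <- oracle_metrics(cells$tp, cells$tn, cells$fp, cells$fn)
    for (m in names(want)) {
      expect_equal(got[[m]], want[[m]], tolerance = 1e-12, info = m)
    }
    # identity constraints where both sides are defined
    for (pair in list(c("TPR", "FNR"), c("TNR", "FPR"), c("PPV", "FDR"),
                      c("NPV", "FOR"), c("ACC", "ERR"))) {
      a <- got[[pair[1]]]; b <- got[[pair[2]]]
      if (!is.na(a) && !is.na(b)) expect_equal(a + b, 1, tolerance = 1e-12)
    }
    if (!is.na(got$MCC)) expect_true(got$MCC >= -1 - 1e-12 && got$MCC <= 1 + 1e-12)
  }
})

test_that("degenerate confusion matrices yield explicit undefined metrics", {
  perfect <- compute_metrics(data.frame(tp = 1, tn = 1, fp = 0, fn = 0))
  expect_equal(perfect$ACC, 1); expect_equal(perfect$F1, 1)
  expect_equal(perfect$MCC, 1); expect_equal(perfect$ERR, 0)
  nopos <- compute_metrics(data.frame(tp = 0, tn = 10, fp = 0, fn = 0))
  expect_true(is.na(nopos$TPR))
  expect_true(is.na(nopos$MCC))
  expect_true(is.na(nopos$PPV))
  expect_equal(nopos$ACC, 1)
  expect_error(compute_metrics(data.frame(tp = 0, tn = 0, fp = 0, fn = 0)),
               "empty")
})

test_that("threshold curves are monotone and hit the boundary cases", {
  cfg <- scenario_config(frames_per_video = 3)
  sim <- simulate_video_index(800, 800, cfg, seed = 31)
  curve <- threshold_curves(sim$truth, sim$index)
  expect_equal(nrow(curve), 101)
  expect_true(all(diff(curve$fn_rate) >= 0))   # FN rate non-decreasing in tau
  expect_true(all(diff(curve$fp_rate) <= 0))   # FP rate non-increasing
  # tau = 0: only truth-positive videos with zero confidence can be FN
  expect_equal(curve$fn_rate[curve$threshold == 0],
               sum(sim$truth & sim$index$animal == 0) / 1600)
  expect_equal(curve$fp_rate[curve$threshold == 1], 0)
})

test_that("empirical FN rate tracks the analytic law within 3 binomial SE", {
  cfg <- scenario_config(frames_per_video = 3,
                         animal_pool = data.frame(species = "Turdus merula",
                                                  visit_rate = 1,
                                                  detectability = 0.9))
  n <- 4000
  sim <- simulate_video_index(n, 0, cfg, seed = 63)
  curve <- threshold_curves(sim$truth, sim$index)
  for (tau in c(0.25, 0.5, 0.8)) {
    p <- expected_fn_rate(cfg, tau)
    se <- sqrt(p * (1 - p) / n)
    emp <- curve$fn_rate[abs(curve$threshold - tau) < 1e-9]
    expect_lt(abs(emp - p), 3 * se + 1e-12)
  }
})

test_that("optimal threshold minimizes fp+fn with ties to the lowest grid value", {
  curve <- structure(data.frame(stratum = "all", threshold = c(0.2, 0.5, 0.8),
                                success_rate = 1,
                                fp_rate = c(0.4, 0.1, 0.0),
                                fn_rate = c(0.0, 0.1, 0.4), n = 100),
                     class = c("threshold_curve", "data.frame"))
  expect_equal(select_optimal_threshold(curve), 0.5)
  flat <- curve; flat$fp_rate <- 0; flat$fn_rate <- 0
  expect_equal(select_optimal_threshold(flat), 0.2)
  # exhaustive grid-scan oracle on a random curve
  set.seed(77)
  rc <- structure(data.frame(stratum = "all", threshold = seq(0, 1, 0.01),
                             success_rate = 1, fp_rate = runif(101),
                             fn_rate = runif(101), n = 50),
                  class = c("threshold_curve", "data.frame"))
  obj <- rc$fp_rate + rc$fn_rate
  expect_equal(select_optimal_threshold(rc),
               rc$threshold[which(obj == min(obj))[1]])
  # FN-weighted objective shifts the choice toward lower thresholds
  expect_lte(select_optimal_threshold(curve, fn_cost = 5), 0.5)
})

test_that("lost-information report recovers planted losses exactly", {
  set.seed(6)
  full <- data.frame(
    plant_species = rep(c("P1", "P2"), c(40, 30)),
    animal_species = c(sample(c("A", "B", "C"), 40, replace = TRUE),
                       sample(c("A", "D"), 30, replace = TRUE)))
  drop <- c(sample(which(full$plant_species == "P1"), 5),
            sample(which(full$plant_species == "P2" & full$animal_species == "D"),
                   sum(full$plant_species == "P2" & full$animal_species == "D")))
  cv <- full[-drop, ]
  rep_ <- lost_information_report(full, cv)
  p1 <- rep_[rep_$stratum == "P1", ]
  expect_equal(p1$n_events, 40)
  expect_equal(p1$events_lost, 5)
  expect_equal(p1$pct_lost, 100 * 5 / 40)
  p2 <- rep_[rep_$stratum == "P2", ]
  expect_equal(p2$unique_interactions_lost, "D")  # all D events dropped
  comm <- attr(rep_, "community_unique_lost")
  expect_equal(comm, data.frame(plant = "P2", animal = "D"),
               ignore_attr = TRUE)
  # identity comparison: no losses anywhere
  zero <- lost_information_report(full, full)
  expect_true(all(zero$events_lost == 0))
  expect_true(all(zero$pct_lost == 0))
  expect_true(all(zero$unique_interactions_lost == ""))
  # cv containing a pair absent from full is a consistency error
  bad <- rbind(cv, data.frame(plant_species = "P1", animal_species = "Z"))
  expect_error(lost_information_report(full, bad), "absent from the full")
})

test_that("FN imputation is a flagged, unscaled union of disjoint record sets", {
  cv <- data.frame(media_id = sprintf("c%04d", 1:200), x = 1)
  fn <- data.frame(media_id = sprintf("f%04d", 1:37), x = 2)
  out <- impute_false_negatives(cv, fn)
  expect_equal(nrow(out), 237)
  expect_equal(sum(out$provenance == "imputed"), 37)
  expect_error(impute_false_negatives(cv, cv[1, ]), "overlap")
  # empty FN set is the identity (plus the provenance flag)
  id <- impute_false_negatives(cv, fn[0, ])
  expect_equal(nrow(id), 200)
  expect_true(all(id$provenance == "cv"))
})
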