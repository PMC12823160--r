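# Quantifying information loss from computer-vision false negatives:
# stratified review samples, confusion matrices, standard binary
# performance metrics (incl. MCC), threshold-calibration curves,
# lost-information accounting, and FN imputation.

#' Stratified proportional sample of media for human review
#'
#' Draws a without-replacement sample whose size in each stratum (typically
#' the focal plant species) is proportional to the stratum's share of
#' videos. Per-stratum allocations start at `floor(fraction * n_stratum)`
#' and a largest-remainder correction tops them up so the total equals
#' `round(fraction * N)`.
#'
#' @param ids Character vector of media ids.
#' @param strata Stratum label per id (same length).
#' @param fraction Sampling fraction in `(0, 1]` (the study used 0.10).
#' @param seed Integer seed; the same seed reproduces the sample exactly.
#' @return Character vector of sampled ids. Strata smaller than their
#'   allocation contribute all their ids and are listed in the
#'   `short_strata` attribute.
#' @export
stratified_sample <- function(ids, strata, fraction, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1, length(ids) == length(strata))
  strata <- as.character(strata)
  n_by <- table(strata)
  target_total <- round(fraction * length(ids))
  base <- floor(fraction * n_by)
  rem <- fraction * n_by - base
  deficit <- target_total - sum(base)
  alloc <- as.integer(base)
  names(alloc) <- names(n_by)
  if (deficit > 0) {
    # largest remainders first; deterministic tie-break on stratum name
    ord <- order(-rem, names(n_by))
    top <- ord[seq_len(min(deficit, length(ord)))]
    alloc[top] <- alloc[top] + 1L
  } else if (deficit < 0) {
    ord <- order(rem, names(n_by))
    cut <- ord[seq_len(min(-deficit, length(ord)))]
    alloc[cut] <- pmax(alloc[cut] - 1L, 0L)
  }
  short <- character()
  out <- with_seed(seed, {
    unlist(lapply(names(alloc), function(s) {
      pool <- ids[strata == s]
      k <- alloc[[s]]
      if (k >= length(pool)) {
        if (k > length(pool)) short <<- c(short, s)
        pool
      } else {
        pool[sample.int(length(pool), k)]
      }
    }), use.names = FALSE)
  })
  structure(out, short_strata = short)
}

#' Confusion matrix for blank-vs-animal video classification
#'
#' Compares detector decisions at a threshold (video selected when its
#' maximum animal confidence is strictly greater than the threshold, see
#' [partition_videos()]) against human-reviewed truth.
#'
#' @param truth Named logical vector: `TRUE` when the video truly contains
#'   an animal, names are media ids.
#' @param index A `video_confidence_index` covering those ids (or a named
#'   numeric vector of video-level confidences).
#' @param threshold Confidence threshold (default 0.8).
#' @param strata Optional named character vector (or vector aligned with
#'   `truth`) giving each video's stratum; per-stratum rows are added
#'   before the combined `"all"` row.
#' @param category Detector category (default `"animal"`).
#' @return Data frame of class `confusion_matrix`: `stratum`, `threshold`,
#'   `tp`, `tn`, `fp`, `fn`, `n`.
#' @export
confusion_matrix <- function(truth, index, threshold = 0.8, strata = NULL,
                             category = "animal") {
  conf <- .video_confidences(index, names(truth), category)
  if (anyNA(conf))
    stop("confidence missing for media id(s): ",
         paste(utils::head(names(truth)[is.na(conf)], 5), collapse = ", "))
  sel <- conf > threshold
  cell <- function(keep) {
    data.frame(tp = sum(truth[keep] & sel[keep]),
               tn = sum(!truth[keep] & !sel[keep]),
               fp = sum(!truth[keep] & sel[keep]),
               fn = sum(truth[keep] & !sel[keep]))
  }
  rows <- list()
  if (!is.null(strata)) {
    strata <- as.character(strata)
    for (s in sort(unique(strata))) {
      r <- cell(strata == s)
      rows[[length(rows) + 1L]] <- cbind(stratum = s, threshold = threshold, r)
    }
  }
  rows[[length(rows) + 1L]] <-
    cbind(stratum = "all", threshold = threshold, cell(rep(TRUE, length(truth))))
  out <- do.call(rbind, rows)
  out$n <- out$tp + out$tn + out$fp + out$fn
  structure(out, class = c("confusion_matrix", "data.frame"))
}

#' @noRd
.video_confidences <- function(index, ids, category = "animal") {
  if (inherits(index, "video_confidence_index") || is.data.frame(index)) {
    conf <- index[[category]][match(ids, index$media_id)]
  } else {
    conf <- unname(index[ids])
  }
  names(conf) <- ids
  conf
}

#' The standard binary-classification metric suite
#'
#' Computes the twelve common rates and performance metrics from a
#' confusion matrix: TPR (sensitivity/recall), TNR (specificity), FPR, FNR,
#' PPV (precision), NPV, FDR, FOR, ACC, ERR, F1 and MCC (Matthews
#' correlation coefficient, the metric of choice under class imbalance).
#' A metric whose denominator is zero is explicitly undefined (`NA`), never
#' silently 0.
#'
#' @param cm A `confusion_matrix` data frame (any data frame with `tp`,
#'   `tn`, `fp`, `fn` columns works).
#' @return The input with the twelve metric columns appended.
#' @export
compute_metrics <- function(cm) {
  tp <- as.numeric(cm$tp); tn <- as.numeric(cm$tn)
  fp <- as.numeric(cm$fp); fn <- as.numeric(cm$fn)
  if (any(tp + tn + fp + fn <= 0)) stop("empty confusion matrix (n = 0)")
  div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  cm$TPR <- div(tp, tp + fn)
  cm$TNR <- div(tn, fp + tn)
  cm$FPR <- div(fp, fp + tn)
  cm$FNR <- div(fn, fn + tp)
  cm$PPV <- div(tp, tp + fp)
  cm$NPV <- div(tn, tn + fn)
  cm$FDR <- div(fp, fp + tp)
  cm$FOR <- div(fn, fn + tn)
  cm$ACC <- div(tp + tn, tp + tn + fp + fn)
  cm$ERR <- div(fp + fn, tp + tn + fp + fn)
  cm$F1  <- div(2 * tp, 2 * tp + fp + fn)
  mcc_den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  cm$MCC <- ifelse(mcc_den > 0, (tp * tn - fp * fn) / mcc_den, NA_real_)
  cm
}

#' False-positive / false-negative calibration curves over thresholds
#'
#' For every threshold on a grid, computes the success rate
#' `(TP + TN) / n` and the FP and FN rates as proportions of all evaluated
#' videos (`FP / n`, `FN / n` -- the convention used when reporting
#' confusion cells as proportions of the review sample). Plotting these
#' cumulative curves per focal plant species is how species-specific
#' confidence thresholds are calibrated.
#'
#' @inheritParams confusion_matrix
#' @param grid Ascending threshold grid (default `seq(0, 1, 0.01)`).
#' @return Data frame of class `threshold_curve`: `stratum`, `threshold`,
#'   `success_rate`, `fp_rate`, `fn_rate`, `n`.
#' @export
threshold_curves <- function(truth, index, grid = seq(0, 1, by = 0.01),
                             strata = NULL, category = "animal") {
  stopifnot(!is.unsorted(grid), all(grid >= 0), all(grid <= 1))
  rows <- lapply(grid, function(tau) {
    cm <- confusion_matrix(truth, index, threshold = tau, strata = strata,
                           category = category)
    data.frame(stratum = cm$stratum, threshold = tau,
               success_rate = (cm$tp + cm$tn) / cm$n,
               fp_rate = cm$fp / cm$n,
               fn_rate = cm$fn / cm$n,
               n = cm$n)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$stratum, out$threshold), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("threshold_curve", "data.frame"))
}

#' Select the optimal confidence threshold from a calibration curve
#'
#' Minimizes `fp_rate + fn_cost * fn_rate` over the grid; ties are broken
#' toward the lowest threshold, favoring recall (the protocol is
#' FN-averse: a missed interaction is worse than an extra video to review).
#'
#' @param curve A `threshold_curve` (single stratum, or the result is
#'   computed per stratum).
#' @param fn_cost Relative cost of a false negative (default 1 =
#'   unweighted FPR + FNR).
#' @return Named numeric vector of optimal thresholds, one per stratum
#'   (a bare scalar when the curve has a single stratum).
#' @export
select_optimal_threshold <- function(curve, fn_cost = 1) {
  stopifnot(nrow(curve) > 0)
  pick <- function(cv) {
    cv <- cv[order(cv$threshold), , drop = FALSE]
    obj <- cv$fp_rate + fn_cost * cv$fn_rate
    cv$threshold[which.min(obj)]  # which.min takes the first (lowest) tie
  }
  res <- vapply(split(curve, curve$stratum), pick, numeric(1))
  if (length(res) == 1) unname(res) else res
}

#' Lost-information accounting for detector false negatives
#'
#' Compares the interaction events recovered when false negatives are
#' included (`events_full`) against the CV-only events (`events_cv`), per
#' plant stratum: events lost, percentage lost, animal species with at
#' least one lost event, and pairwise interactions present only in the
#' full data (unique interactions lost). The `community_unique_lost`
#' attribute lists plant-animal pairs absent from the entire CV network.
#'
#' @param events_full,events_cv Data frames with one row per event and
#'   columns `animal_species` plus the stratum column `by`.
#' @param by Stratum column (default `"plant_species"`).
#' @return Data frame of class `lost_info_report`: `stratum`, `n_events`,
#'   `n_species`, `events_lost`, `pct_lost`, `species_lost`,
#'   `unique_interactions_lost` (`;`-joined animal names).
#' @export
lost_information_report <- function(events_full, events_cv,
                                    by = "plant_species") {
  stopifnot(by %in% names(events_full), by %in% names(events_cv),
            "animal_species" %in% names(events_full),
            "animal_species" %in% names(events_cv))
  pair <- function(e) paste(e[[by]], e$animal_species, sep = "\r")
  extra <- setdiff(unique(pair(events_cv)), unique(pair(events_full)))
  if (length(extra) > 0)
    stop("CV events contain pair(s) absent from the full data: ",
         paste(gsub("\r", " x ", extra), collapse = ", "))
  strata <- sort(unique(events_full[[by]]))
  animals <- sort(unique(c(events_full$animal_species,
                           events_cv$animal_species)))
  count <- function(e) table(factor(e[[by]], levels = strata),
                             factor(e$animal_species, levels = animals))
  Wf <- count(events_full); Wc <- count(events_cv)
  lost <- Wf - Wc
  out <- data.frame(
    stratum = strata,
    n_events = as.integer(rowSums(Wf)),
    n_species = as.integer(rowSums(Wf > 0)),
    events_lost = as.integer(rowSums(lost)),
    pct_lost = 100 * rowSums(lost) / rowSums(Wf),
    species_lost = as.integer(rowSums(lost > 0)),
    unique_interactions_lost = vapply(seq_along(strata), function(i) {
      paste(animals[Wf[i, ] > 0 & Wc[i, ] == 0], collapse = ";")
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  comm <- which(Wf > 0 & Wc == 0, arr.ind = TRUE)
  structure(out, class = c("lost_info_report", "data.frame"),
            community_unique_lost = data.frame(
              plant = strata[comm[, 1]], animal = animals[comm[, 2]],
              row.names = NULL, stringsAsFactors = FALSE))
}

#' Render lost-information percentages at one decimal
#'
#' @param report A `lost_info_report`.
#' @return The report with `pct_lost` formatted as in published tables
#'   (e.g. `"10.0"`).
#' @export
format_lost_info <- function(report) {
  report$pct_lost <- sprintf("%.1f", report$pct_lost)
  report
}

#' Impute human-reviewed false negatives into the CV record set
#'
#' The reviewed false negatives from the stratified validation sample are
#' added back to the CV-selected records as a direct union -- no scaling or
#' extrapolation -- with their provenance flagged.
#'
#' @param cv_records,reviewed_fn_records Observation-style data frames with
#'   a `media_id` column; the two sets must be disjoint by `media_id`.
#' @return Combined data frame with a `provenance` column (`"cv"` /
#'   `"imputed"`).
#' @export
impute_false_negatives <- function(cv_records, reviewed_fn_records) {
  overlap <- intersect(cv_records$media_id, reviewed_fn_records$media_id)
  if (length(overlap) > 0)
    stop("reviewed FN records overlap CV records by media_id: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  cols <- union(names(cv_records), names(reviewed_fn_records))
  pad <- function(df) {
    for (cl in setdiff(cols, names(df))) df[[cl]] <- NA
    df[, cols, drop = FALSE]
  }
  cv <- pad(cv_records)
  cv$provenance <- rep("cv", nrow(cv))
  fn <- pad(reviewed_fn_records)
  fn$provenance <- rep("imputed", nrow(fn))
  out <- rbind(cv, fn)
  rownames(out) <- NULL
  out
}
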