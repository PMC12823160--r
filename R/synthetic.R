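# Synthetic camera-trap studies with known ground truth: deployments,
# Poisson animal visits emitting cascades of short trigger videos, wind
# false triggers, and Beta-distributed frame-level detector confidences.
# Every pipeline stage is testable against the generator's bookkeeping.

#' Configuration of a synthetic camera-trap study
#'
#' Defaults emulate a frugivory survey with motion-triggered cameras in
#' video mode: 10 s videos with a 1 s re-trigger gap, wind-dominated false
#' triggers (roughly 80% of videos empty), visits arriving as homogeneous
#' Poisson processes per deployment and animal species with exponential
#' visit durations, and frame-level detector confidences drawn from
#' Beta(8, 2) on frames where the animal is visible and Beta(2, 8) on empty
#' frames. Per-species detectability `d` is the probability that an
#' occupied video's frame actually shows the animal to the detector (it
#' subsumes occlusion by vegetation and mimetic plumage as a single miss
#' probability).
#'
#' @param n_plant_species Number of focal plant species.
#' @param individuals_per_species Monitored plant individuals per species
#'   (one deployment each).
#' @param animal_pool Data frame with columns `species`, `visit_rate`
#'   (visits per deployment per day) and `detectability` in `(0, 1]`.
#' @param visit_duration_s Mean visit duration in seconds (exponential).
#' @param video_length_s,trigger_gap_s Video length and re-trigger delay;
#'   a visit emits consecutive videos every `video_length_s +
#'   trigger_gap_s` seconds.
#' @param wind_trigger_rate False (empty) triggers per deployment per day.
#' @param study_days Deployment span in days.
#' @param revision_interval_days Field-revision interval; sentinel first
#'   and last recordings are generated for each revision.
#' @param occupied_conf,empty_conf Length-2 Beta shape vectors for frame
#'   confidences on occupied and empty frames.
#' @param frames_per_video Frames extracted per video.
#' @param behavior_mix Named probability vector over [ct_behaviors()].
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_plant_species = 3,
                            individuals_per_species = 2,
                            animal_pool = data.frame(
                              species = c("Turdus merula", "Erithacus rubecula",
                                          "Sylvia atricapilla",
                                          "Sturnus unicolor", "Pica pica"),
                              visit_rate = c(2, 1, 0.5, 0.25, 0.1),
                              detectability = c(0.9, 0.8, 0.65, 0.75, 0.6)),
                            visit_duration_s = 45,
                            video_length_s = 10,
                            trigger_gap_s = 1,
                            wind_trigger_rate = 40,
                            study_days = 14,
                            revision_interval_days = 7,
                            occupied_conf = c(8, 2),
                            empty_conf = c(2, 8),
                            frames_per_video = 3,
                            behavior_mix = c(feeding = 0.25,
                                             probably_feeding = 0.2,
                                             searching_food = 0.25,
                                             perching = 0.15,
                                             passing = 0.15)) {
  stopifnot(n_plant_species >= 1, individuals_per_species >= 1,
            nrow(animal_pool) >= 1,
            all(animal_pool$visit_rate >= 0),
            all(animal_pool$detectability > 0),
            all(animal_pool$detectability <= 1),
            visit_duration_s > 0, video_length_s > 0, trigger_gap_s >= 0,
            wind_trigger_rate >= 0, study_days > 0,
            revision_interval_days > 0,
            all(occupied_conf > 0), all(empty_conf > 0),
            frames_per_video >= 1,
            all(names(behavior_mix) %in% ct_behaviors()),
            abs(sum(behavior_mix) - 1) < 1e-8)
  structure(as.list(environment()), class = "scenario_config")
}

#' @noRd
.study_origin <- as.POSIXct("2021-09-01 00:00:00", tz = "UTC")

#' Generate a complete synthetic study
#'
#' Simulates deployments, animal visits, trigger-cascade videos, wind false
#' triggers and sentinel revision recordings; draws per-frame detector
#' confidences conditioned on true video content; and returns
#' schema-valid project tables, the ground truth, and a MegaDetector-format
#' detection document, all reproducible under `seed`.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @return List with elements `tables` (a [camtrap_tables()] whose
#'   observations are the human truth labels for animal videos), `truth`
#'   (data frame: `media_id`, `contains_animal`, `animal_species`,
#'   `event_id`, `behavior`), `detections` (parsed detection document) and
#'   `manifest` (a `frame_manifest`).
#' @export
generate_scenario <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(seed, .generate_scenario_impl(config))
}

.generate_scenario_impl <- function(cfg) {
  plants <- sprintf("Plantus species%d", seq_len(cfg$n_plant_species))
  dep <- expand.grid(sp = seq_len(cfg$n_plant_species),
                     ind = seq_len(cfg$individuals_per_species),
                     KEEP.OUT.ATTRS = FALSE)
  deployments <- data.frame(
    deployment_id = sprintf("DEP%02d%02d", dep$sp, dep$ind),
    location_id = sprintf("LOC%02d%02d", dep$sp, dep$ind),
    plant_species = plants[dep$sp],
    plant_individual_id = sprintf("%s-%02d", gsub(" ", "_", plants[dep$sp]),
                                  dep$ind),
    camera_id = sprintf("CAM%03d", seq_len(nrow(dep))),
    camera_model = "Browning Dark Ops",
    start_ts = .study_origin,
    end_ts = .study_origin + cfg$study_days * 86400,
    setup_notes = "",
    stringsAsFactors = FALSE)

  video_step <- cfg$video_length_s + cfg$trigger_gap_s
  rev_edges <- unique(c(seq(0, cfg$study_days, by = cfg$revision_interval_days),
                        cfg$study_days))

  vids <- list()   # per-video rows: deployment, time_s, species, visit, revision
  nvisit <- 0L
  for (d in seq_len(nrow(deployments))) {
    did <- deployments$deployment_id[d]
    # animal visits: homogeneous Poisson arrivals, exponential durations
    for (a in seq_len(nrow(cfg$animal_pool))) {
      lam <- cfg$animal_pool$visit_rate[a]
      if (lam <= 0) next
      nv <- stats::rpois(1, lam * cfg$study_days)
      if (nv == 0) next
      starts <- sort(stats::runif(nv, 0, cfg$study_days * 86400))
      durs <- stats::rexp(nv, rate = 1 / cfg$visit_duration_s)
      for (v in seq_len(nv)) {
        nvisit <- nvisit + 1L
        offs <- seq(0, durs[v], by = video_step)  # >= 1 video per visit
        vids[[length(vids) + 1L]] <- data.frame(
          deployment_id = did, time_s = starts[v] + offs,
          species = cfg$animal_pool$species[a],
          event_id = sprintf("VISIT%05d", nvisit),
          revision = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
    # wind false triggers
    nw <- stats::rpois(1, cfg$wind_trigger_rate * cfg$study_days)
    if (nw > 0) {
      vids[[length(vids) + 1L]] <- data.frame(
        deployment_id = did,
        time_s = sort(stats::runif(nw, 0, cfg$study_days * 86400)),
        species = NA_character_, event_id = NA_character_,
        revision = NA_integer_,
        stringsAsFactors = FALSE)
    }
    # sentinel recordings bracketing every revision: the crew triggers the
    # camera when opening and when closing each revision interval
    nrev <- length(rev_edges) - 1L
    vids[[length(vids) + 1L]] <- data.frame(
      deployment_id = did,
      time_s = c(rev_edges[-length(rev_edges)], rev_edges[-1]) * 86400,
      species = NA_character_, event_id = NA_character_,
      revision = rep(seq_len(nrev), 2L),
      stringsAsFactors = FALSE)
  }
  allv <- do.call(rbind, vids)
  allv <- allv[order(allv$deployment_id, allv$time_s), , drop = FALSE]
  allv$media_id <- sprintf("V%06d", seq_len(nrow(allv)))
  rev_idx <- ifelse(!is.na(allv$revision), allv$revision,
                    pmin(findInterval(allv$time_s / 86400, rev_edges,
                                      rightmost.closed = TRUE),
                         length(rev_edges) - 1L))

  media <- data.frame(
    media_id = allv$media_id,
    deployment_id = allv$deployment_id,
    relative_path = file.path(allv$deployment_id,
                              paste0(allv$media_id, ".MP4")),
    timestamp = .study_origin + round(allv$time_s),
    duration_s = cfg$video_length_s,
    revision_id = sprintf("%s-R%02d", allv$deployment_id, rev_idx),
    timestamp_issue = FALSE,
    stringsAsFactors = FALSE)

  occupied <- !is.na(allv$species)
  # behavior drawn per visit: all videos of one visit share the behavior
  behavior <- rep(NA_character_, nrow(allv))
  visits <- unique(allv$event_id[occupied])
  if (length(visits) > 0) {
    per_visit <- sample(names(cfg$behavior_mix), length(visits),
                        replace = TRUE, prob = cfg$behavior_mix)
    behavior[occupied] <- per_visit[match(allv$event_id[occupied], visits)]
  }
  truth <- data.frame(media_id = allv$media_id,
                      contains_animal = occupied,
                      animal_species = allv$species,
                      event_id = allv$event_id,
                      behavior = behavior,
                      stringsAsFactors = FALSE)

  observations <- if (any(occupied)) {
    data.frame(
      observation_id = sprintf("OBS%06d", seq_len(sum(occupied))),
      media_id = allv$media_id[occupied],
      observation_type = "animal",
      scientific_name = allv$species[occupied],
      count = 1L,
      behavior = behavior[occupied],
      classification_method = "human",
      classified_by = "synthetic-truth",
      detector_confidence = NA_real_,
      stringsAsFactors = FALSE)
  } else {
    data.frame(observation_id = character(), media_id = character(),
               observation_type = character(), scientific_name = character(),
               count = integer(), behavior = character(),
               classification_method = character(), classified_by = character(),
               detector_confidence = numeric(), stringsAsFactors = FALSE)
  }

  det <- cfg$animal_pool$detectability[match(allv$species,
                                             cfg$animal_pool$species)]
  frames <- .draw_frame_confidences(occupied, det, cfg)
  detections <- .frames_to_doc(media, frames, cfg)

  frame_paths <- unlist(lapply(seq_len(nrow(media)), function(i)
    sprintf("%s/%s_%03d.jpg", media$deployment_id[i], media$media_id[i],
            seq_len(cfg$frames_per_video) - 1L)), use.names = FALSE)
  manifest <- build_frame_manifest(frame_paths)

  list(tables = camtrap_tables(deployments, media, observations),
       truth = truth, detections = detections, manifest = manifest)
}

# Per-frame confidences: an occupied video's frame shows the animal with
# probability d (then Beta(occupied_conf)), otherwise it looks empty
# (Beta(empty_conf)); empty videos' frames are always Beta(empty_conf).
#' @noRd
.draw_frame_confidences <- function(occupied, detectability, cfg) {
  k <- cfg$frames_per_video
  n <- length(occupied)
  d <- ifelse(occupied, detectability, 0)
  vis <- matrix(stats::runif(n * k) < rep(d, k), nrow = n)
  conf <- matrix(0, nrow = n, ncol = k)
  nv <- sum(vis)
  conf[vis] <- stats::rbeta(nv, cfg$occupied_conf[1], cfg$occupied_conf[2])
  conf[!vis] <- stats::rbeta(n * k - nv, cfg$empty_conf[1], cfg$empty_conf[2])
  round(conf, 6)
}

#' @noRd
.frames_to_doc <- function(media, conf, cfg) {
  k <- ncol(conf)
  images <- vector("list", nrow(media) * k)
  for (i in seq_len(nrow(media))) {
    for (j in seq_len(k)) {
      images[[(i - 1L) * k + j]] <- list(
        file = sprintf("%s/%s_%03d.jpg", media$deployment_id[i],
                       media$media_id[i], j - 1L),
        detections = list(list(category = "1", conf = conf[i, j],
                               bbox = list(0.1, 0.1, 0.5, 0.5))))
    }
  }
  list(images = images,
       detection_categories = list(`1` = "animal", `2` = "person",
                                   `3` = "vehicle"))
}

#' Simulate a video confidence index with fixed class sizes
#'
#' Calibration experiments need exact numbers of occupied and empty videos
#' rather than Poisson-random ones; this draws `n_occupied + n_empty`
#' videos' frame confidences under `config`'s Beta laws and detectability
#' (first species of the pool) and aggregates them by maximum, exactly as
#' the detection pipeline would.
#'
#' @param n_occupied,n_empty Video counts per class.
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @return List with `index` (a `video_confidence_index`), `truth` (named
#'   logical) and `strata` (all `"all"`).
#' @export
simulate_video_index <- function(n_occupied, n_empty, config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"),
            n_occupied >= 0, n_empty >= 0, n_occupied + n_empty > 0)
  with_seed(seed, {
    occupied <- rep(c(TRUE, FALSE), c(n_occupied, n_empty))
    d <- config$animal_pool$detectability[1]
    conf <- .draw_frame_confidences(occupied, rep(d, length(occupied)), config)
    mx <- apply(conf, 1, max)
    ids <- sprintf("V%06d", seq_along(occupied))
    index <- structure(
      data.frame(media_id = ids, n_frames = config$frames_per_video,
                 animal = mx, person = 0, vehicle = 0,
                 stringsAsFactors = FALSE),
      class = c("video_confidence_index", "data.frame"))
    truth <- stats::setNames(occupied, ids)
    list(index = index, truth = truth)
  })
}

#' Analytic false-negative rate of the synthetic detector
#'
#' Closed-form probability that an occupied video's maximum frame
#' confidence does not exceed the threshold: with `k` frames per video,
#' per-frame detectability `d` and Beta CDFs `F1` (occupied) and `F0`
#' (empty), `P(max <= tau) = (d * F1(tau) + (1 - d) * F0(tau))^k`, averaged
#' over the species pool weighted by visit rate.
#'
#' @param config A [scenario_config()].
#' @param threshold Threshold(s) in `[0, 1]` (vectorized).
#' @return False-negative probability per threshold.
#' @export
expected_fn_rate <- function(config, threshold) {
  stopifnot(inherits(config, "scenario_config"),
            all(threshold >= 0), all(threshold <= 1))
  k <- config$frames_per_video
  F1 <- stats::pbeta(threshold, config$occupied_conf[1],
                     config$occupied_conf[2])
  F0 <- stats::pbeta(threshold, config$empty_conf[1], config$empty_conf[2])
  w <- config$animal_pool$visit_rate
  if (sum(w) <= 0) w <- rep(1, length(w))
  w <- w / sum(w)
  sapply(seq_along(threshold), function(i) {
    sum(w * (config$animal_pool$detectability * F1[i] +
               (1 - config$animal_pool$detectability) * F0[i])^k)
  })
}

#' @rdname expected_fn_rate
#' @details `expected_fp_rate()` is the companion closed form for empty
#'   videos: `P(max > tau) = 1 - F0(tau)^k`.
#' @export
expected_fp_rate <- function(config, threshold) {
  stopifnot(inherits(config, "scenario_config"),
            all(threshold >= 0), all(threshold <= 1))
  F0 <- stats::pbeta(threshold, config$empty_conf[1], config$empty_conf[2])
  1 - F0^config$frames_per_video
}
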