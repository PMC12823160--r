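# Shared fixture builders. Everything is generated in code; no binary files.

fixture_tables <- function() {
  deployments <- data.frame(
    deployment_id = c("D1", "D2"),
    location_id = c("L1", "L2"),
    plant_species = c("Arbutus unedo", "Pistacia lentiscus"),
    plant_individual_id = c("AU-01", "PL-01"),
    camera_id = c("C1", "C2"),
    camera_model = "Browning Dark Ops",
    start_ts = "2021-09-01T00:00:00",
    end_ts = "2021-09-15T00:00:00",
    setup_notes = "",
    stringsAsFactors = FALSE)
  media <- data.frame(
    media_id = paste0("V", 1:5),
    deployment_id = c("D1", "D1", "D1", "D2", "D2"),
    relative_path = paste0("D/", paste0("V", 1:5), ".MP4"),
    timestamp = c("2021-09-01T10:00:00", "2021-09-01T10:00:11",
                  "2021-09-01T10:30:00", "2021-09-02T09:00:00",
                  "2021-09-02T09:00:11"),
    duration_s = 10,
    revision_id = c("D1-R01", "D1-R01", "D1-R01", "D2-R01", "D2-R01"),
    timestamp_issue = "false",
    stringsAsFactors = FALSE)
  observations <- data.frame(
    observation_id = paste0("O", 1:3),
    media_id = c("V1", "V2", "V4"),
    observation_type = "animal",
    scientific_name = c("Turdus merula", "Turdus merula", "Pica pica"),
    count = 1L,
    behavior = c("feeding", "feeding", "passing"),
    classification_method = "human",
    classified_by = "expert1",
    detector_confidence = c(0.95, 0.9, 0.85),
    stringsAsFactors = FALSE)
  list(deployments = deployments, media = media, observations = observations)
}

# randomized but schema-valid tables for round-trip property tests;
# confidences kept at <= 6 decimals so text round-trips are exact
random_tables <- function(n_dep = 3, n_media = 20, n_obs = 10, seed = 1) {
  set.seed(seed)
  species <- c("Arbutus unedo", "Pyrus bourgaeana", "Olea europæa")
  deployments <- data.frame(
    deployment_id = sprintf("D%02d", seq_len(n_dep)),
    location_id = sprintf("L%02d", seq_len(n_dep)),
    plant_species = sample(species, n_dep, replace = TRUE),
    plant_individual_id = sprintf("IND%02d", seq_len(n_dep)),
    camera_id = sprintf("C%02d", seq_len(n_dep)),
    camera_model = "Bushnell Trophy",
    start_ts = "2021-09-01T00:00:00",
    end_ts = "2021-09-30T00:00:00",
    setup_notes = "notas de campo, acentuación",
    stringsAsFactors = FALSE)
  t0 <- as.POSIXct("2021-09-01 00:00:00", tz = "UTC")
  media <- data.frame(
    media_id = sprintf("V%03d", seq_len(n_media)),
    deployment_id = sample(deployments$deployment_id, n_media, replace = TRUE),
    relative_path = sprintf("d/V%03d.MP4", seq_len(n_media)),
    timestamp = format(t0 + sort(sample.int(29 * 86400, n_media)),
                       "%Y-%m-%dT%H:%M:%S"),
    duration_s = 10,
    revision_id = "R01",
    timestamp_issue = "false",
    stringsAsFactors = FALSE)
  observations <- data.frame(
    observation_id = sprintf("O%03d", seq_len(n_obs)),
    media_id = sample(media$media_id, n_obs, replace = TRUE),
    observation_type = rep("animal", n_obs),
    scientific_name = sample(c("Turdus merula", "Curruça undata"),
                             n_obs, replace = TRUE),
    count = sample(1:4, n_obs, replace = TRUE),
    behavior = sample(ct_behaviors(), n_obs, replace = TRUE),
    classification_method = rep("human", n_obs),
    classified_by = rep("expert", n_obs),
    detector_confidence = round(runif(n_obs), 6),
    stringsAsFactors = FALSE)
  camtrap_tables(deployments, media, observations)
}

# small MegaDetector-format document with known ground truth
fixture_detection_doc <- function() {
  list(
    images = list(
      list(file = "D1/V1_000.jpg",
           detections = list(
             list(category = "1", conf = 0.91, bbox = list(0.1, 0.1, 0.2, 0.2)),
             list(category = "2", conf = 0.30, bbox = list(0.5, 0.5, 0.1, 0.1)))),
      list(file = "D1/V1_001.jpg", detections = list()),
      list(file = "D1/V2_000.jpg",
           detections = list(list(category = "1", conf = 0.45,
                                  bbox = list(0, 0, 1, 1))))),
    detection_categories = list(`1` = "animal", `2` = "person",
                                `3` = "vehicle"))
}

random_detection_doc <- function(n_videos = 5, frames_per_video = 4,
                                 p_det = 0.5, seed = 1) {
  set.seed(seed)
  images <- list()
  for (v in seq_len(n_videos)) {
    for (f in seq_len(frames_per_video)) {
      dets <- list()
      if (runif(1) < p_det) {
        for (k in seq_len(sample(1:2, 1))) {
          dets[[k]] <- list(category = sample(c("1", "2", "3"), 1),
                            conf = round(runif(1), 6),
                            bbox = list(0.1, 0.1, 0.2, 0.2))
        }
      }
      images[[length(images) + 1L]] <-
        list(file = sprintf("D/V%02d_%03d.jpg", v, f - 1L), detections = dets)
    }
  }
  list(images = images,
       detection_categories = list(`1` = "animal", `2` = "person",
                                   `3` = "vehicle"))
}

random_network <- function(nr, nc, max_w = 9, seed = 1,
                           plants = sprintf("P%d", seq_len(nr)),
                           animals = sprintf("A%d", seq_len(nc))) {
  set.seed(seed)
  bipartite_network(matrix(sample(0:max_w, nr * nc, replace = TRUE),
                           nr, nc, dimnames = list(plants, animals)))
}

# record sets for collapsing tests
records_df <- function(times_s, species = "Turdus merula", dep = "D1",
                       behavior = "feeding", count = 1L,
                       t0 = as.POSIXct("2021-09-01 00:00:00", tz = "UTC")) {
  data.frame(media_id = sprintf("V%04d", seq_along(times_s)),
             deployment_id = dep,
             animal_species = species,
             timestamp = t0 + times_s,
             behavior = behavior,
             count = count,
             stringsAsFactors = FALSE)
}

# independent brute-force event collapser (gap rule), used as oracle
oracle_collapse_count <- function(records, window_s = 300) {
  key <- paste(records$deployment_id, records$animal_species, sep = "\r")
  sum(vapply(split(records$timestamp, key), function(ts) {
    ts <- sort(ts)
    if (length(ts) == 0) return(0L)
    1L + sum(as.numeric(diff(ts), units = "secs") > window_s)
  }, integer(1)))
}
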