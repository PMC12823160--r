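# Behavior filtering, event collapsing, sampling effort, interaction and
# PIE matrices.

test_that("interaction filter keeps the feeding hierarchy only", {
  obs <- data.frame(
    observation_id = paste0("O", 1:3), media_id = paste0("V", 1:3),
    observation_type = "animal", scientific_name = "Turdus merula",
    count = 1L, behavior = c("feeding", "passing", "searching_food"),
    classification_method = "human", classified_by = "e",
    detector_confidence = NA_real_, stringsAsFactors = FALSE)
  expect_equal(nrow(filter_interaction_records(obs)), 2)
  expect_equal(nrow(filter_interaction_records(obs, include = ct_behaviors())), 3)
})

test_that("filter equals an independent predicate scan on random observations", {
  set.seed(4)
  n <- 100
  obs <- data.frame(
    observation_id = sprintf("O%03d", 1:n),
    media_id = sprintf("V%03d", 1:n),
    observation_type = sample(c("animal", "blank", "human"), n, replace = TRUE),
    scientific_name = sample(c("Turdus merula", "unidentified", ""), n,
                             replace = TRUE),
    count = 1L,
    behavior = sample(ct_behaviors(), n, replace = TRUE),
    classification_method = "human", classified_by = "e",
    detector_confidence = NA_real_, stringsAsFactors = FALSE)
  inc <- ct_interaction_behaviors()
  manual <- sum(mapply(function(ty, sp, be)
    ty == "animal" && be %in% inc && nzchar(sp) && sp != "unidentified",
    obs$observation_type, obs$scientific_name, obs$behavior))
  expect_equal(nrow(filter_interaction_records(obs)), manual)
})

test_that("gap rule splits events exactly at the window", {
  rec <- records_df(c(0, 10, 30, 360))
  ev <- collapse_events(rec, window_s = 300)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$n_videos, c(3L, 1L))
  expect_equal(as.numeric(ev$end_ts[1] - ev$start_ts[1], units = "secs"), 30)
  expect_equal(ev$start_ts[2], rec$timestamp[4])
  # boundary tie: gap exactly equal to the window merges
  ev2 <- collapse_events(records_df(c(0, 300)), window_s = 300)
  expect_equal(nrow(ev2), 1)
})

test_that("different species or deployments never merge", {
  rec <- rbind(records_df(c(0, 20, 40), species = "Turdus merula"),
               records_df(c(10, 30), species = "Pica pica"))
  ev <- collapse_events(rec)
  expect_equal(nrow(ev), 2)
  expect_equal(sort(ev$n_videos), c(2L, 3L))
  rec2 <- rbind(records_df(c(0, 20)), records_df(c(10, 30), dep = "D2"))
  expect_equal(nrow(collapse_events(rec2)), 2)
})

test_that("fixed-interval mode bins from the group's first record", {
  rec <- records_df(c(0, 100, 250, 320, 650))
  ev <- collapse_events(rec, window_s = 300, mode = "fixed")
  # bins [0,300), [300,600), [600,900) -> 3, 1, 1 videos
  expect_equal(nrow(ev), 3)
  expect_equal(ev$n_videos, c(3L, 1L, 1L))
})

test_that("collapsing conserves videos, is idempotent, and matches the oracle", {
  set.seed(21)
  for (rep in 1:5) {
    rec <- do.call(rbind, lapply(1:4, function(g) {
      records_df(sort(runif(250, 0, 5 * 86400)),
                 species = sample(c("A sp", "B sp"), 1),
                 dep = sample(c("D1", "D2"), 1))
    }))
    rec$media_id <- sprintf("V%05d", seq_len(nrow(rec)))
    ev <- collapse_events(rec, window_s = 300)
    expect_equal(sum(ev$n_videos), nrow(rec))                 # conservation
    expect_equal(nrow(ev), oracle_collapse_count(rec, 300))   # oracle
    # idempotence: collapsing the events (as one record per event) keeps
    # the same boundaries
    ev_rec <- data.frame(media_id = ev$event_id,
                         deployment_id = ev$deployment_id,
                         animal_species = ev$animal_species,
                         timestamp = ev$start_ts,
                         behavior = "feeding", count = 1L)
    ev2 <- collapse_events(ev_rec, window_s = 300)
    expect_equal(nrow(ev2), nrow(ev))
    expect_equal(sort(ev2$start_ts), sort(ev$start_ts))
  }
})

test_that("event count is non-increasing in the window", {
  set.seed(8)
  rec <- records_df(sort(runif(300, 0, 86400)))
  counts <- vapply(c(30, 60, 300, 900, 3600), function(w)
    nrow(collapse_events(rec, window_s = w)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("records with missing timestamps are excluded and reported", {
  rec <- records_df(c(0, 10))
  rec$timestamp[2] <- NA
  ev <- collapse_events(rec)
  expect_equal(nrow(ev), 1)
  expect_equal(attr(ev, "excluded"), "V0002")
})

test_that("effort is (last - first)/86400 in decimal days", {
  media <- data.frame(
    media_id = c("V1", "V2", "V3"),
    deployment_id = "D1",
    timestamp = ct_parse_timestamp(c("2021-01-01T00:00:00",
                                     "2021-01-05T06:00:00",
                                     "2021-01-08T12:00:00")),
    revision_id = "R1", timestamp_issue = FALSE, stringsAsFactors = FALSE)
  eff <- compute_effort(media)
  expect_equal(eff$effort_days, 7.5)
  expect_equal(eff$n_videos, 3)
})

test_that("single-video revisions yield undefined effort, reported and excluded", {
  media <- data.frame(
    media_id = c("V1", "V2", "V3"),
    deployment_id = "D1",
    timestamp = ct_parse_timestamp(c("2021-01-01T00:00:00",
                                     "2021-01-02T00:00:00",
                                     "2021-01-09T00:00:00")),
    revision_id = c("R1", "R1", "R2"), timestamp_issue = FALSE,
    stringsAsFactors = FALSE)
  eff <- compute_effort(media)
  expect_equal(eff$effort_days[eff$revision_id == "R1"], 1)
  expect_true(is.na(eff$effort_days[eff$revision_id == "R2"]))
  expect_equal(attr(eff, "undefined")$revision_id, "R2")
  expect_equal(sum(eff$effort_days, na.rm = TRUE), 1)
})

test_that("synthetic study effort sums to the configured deployment spans", {
  cfg <- scenario_config(n_plant_species = 1, individuals_per_species = 2,
                         study_days = 10, revision_interval_days = 5)
  sc <- generate_scenario(cfg, seed = 3)
  eff <- compute_effort(sc$tables$media)
  per_dep <- tapply(eff$effort_days, eff$deployment_id, sum, na.rm = TRUE)
  expect_equal(as.numeric(per_dep), rep(10, 2), tolerance = 1e-6)
})

test_that("interaction matrix counts events and conserves totals across levels", {
  dep <- fixture_tables()$deployments
  ev <- data.frame(
    event_id = sprintf("E%d", 1:4),
    deployment_id = c("D1", "D1", "D1", "D1"),
    animal_species = c("Turdus merula", "Turdus merula", "Turdus merula",
                       "Pica pica"),
    stringsAsFactors = FALSE)
  class(ev) <- c("interaction_events", "data.frame")
  net <- interaction_matrix(ev, dep)
  expect_equal(unname(net$weights["Arbutus unedo", ]), c(1, 3))
  expect_equal(sum(net$weights), nrow(ev))
  neti <- interaction_matrix(ev, dep, level = "individual")
  expect_equal(colSums(neti$weights), colSums(net$weights), ignore_attr = TRUE)
})

test_that("matrix total equals event count on random event sets", {
  set.seed(14)
  dep <- fixture_tables()$deployments
  ev <- data.frame(
    event_id = sprintf("E%d", 1:50),
    deployment_id = sample(dep$deployment_id, 50, replace = TRUE),
    animal_species = sample(c("A", "B", "C"), 50, replace = TRUE))
  net <- interaction_matrix(ev, dep)
  expect_equal(sum(net$weights), 50)
})

test_that("PIE normalizations behave as probabilities", {
  net <- bipartite_network(matrix(c(3, 1), 1, 2,
                                  dimnames = list("Arbutus unedo",
                                                  c("T merula", "P pica"))))
  expect_equal(unname(as.vector(pie_matrix(net))), c(0.75, 0.25))
  # diet weight 1 for all = unweighted
  pw <- pie_matrix(net, diet_weight = c(`T merula` = 1, `P pica` = 1))
  expect_equal(unclass(pw), unclass(pie_matrix(net)), ignore_attr = TRUE)
  expect_error(pie_matrix(net, diet_weight = c(`T merula` = 1.2)), "\\[0, 1\\]")
  # global mode sums to 1; row mode rows sum to 1 (zero rows stay zero)
  m <- random_network(4, 5, seed = 2)
  m$weights[2, ] <- 0
  expect_equal(sum(pie_matrix(m, "global")), 1)
  rs <- rowSums(pie_matrix(m, "row"))
  expect_equal(unname(rs), c(1, 0, 1, 1))
})

test_that("plant labels attach to events by deployment", {
  dep <- fixture_tables()$deployments
  ev <- data.frame(event_id = "E1", deployment_id = "D2",
                   animal_species = "Pica pica")
  out <- add_plant_labels(ev, dep)
  expect_equal(out$plant_species, "Pistacia lentiscus")
  expect_equal(out$plant_individual_id, "PL-01")
  expect_error(add_plant_labels(data.frame(deployment_id = "D9"), dep),
               "missing from deployment table")
})
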