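# Three-table data standard for camera-trap interaction surveys:
# deployments (one camera aimed at one focal plant for a period),
# media (the triggered videos), observations (what a reviewer -- human or
# machine -- saw in each video).

#' Controlled vocabulary of feeding-related behaviors
#'
#' Reviewed videos are tagged with one behavior per observation. The first
#' three levels form the feeding hierarchy used to score frugivory
#' interactions: `"feeding"` (fruit ingestion visible), `"probably_feeding"`
#' (fruit handled, ingestion not visible) and `"searching_food"` (active
#' fruit-foraging posture or movement). The remaining levels describe
#' animal presence that does not evidence a frugivory interaction.
#'
#' @return Character vector of the eight recognized behavior labels.
#' @export
ct_behaviors <- function() {
  c("feeding", "probably_feeding", "searching_food",
    "perching", "walking", "passing", "other", "unknown")
}

#' Behaviors counted as frugivory interactions by default
#'
#' @return Character vector: `feeding`, `probably_feeding`, `searching_food`.
#' @seealso [filter_interaction_records()]
#' @export
ct_interaction_behaviors <- function() {
  c("feeding", "probably_feeding", "searching_food")
}

#' @noRd
ct_observation_types <- function() {
  c("animal", "blank", "human", "vehicle", "unknown")
}

# Timestamps are stored as ISO-8601 local camera time. All cameras in a
# project share one clock convention; no timezone arithmetic is performed,
# so the fixed "UTC" tag is only an internal anchor.
#' Parse camera timestamps
#'
#' Accepts `YYYY-MM-DDTHH:MM:SS` and `YYYY-MM-DD HH:MM:SS`; anything else
#' (including empty strings) parses to `NA`, which callers flag as a
#' timestamp issue rather than dropping the row.
#'
#' @param x Character vector.
#' @return `POSIXct` vector (second resolution).
#' @export
ct_parse_timestamp <- function(x) {
  x <- as.character(x)
  x <- gsub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  # reject partially-matched garbage such as "2021-01-01 99:99:99"
  out
}

#' @rdname ct_parse_timestamp
#' @param t `POSIXct` vector.
#' @export
ct_format_timestamp <- function(t) {
  ifelse(is.na(t), "", format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
}

.dep_cols <- c("deployment_id", "location_id", "plant_species",
               "plant_individual_id", "camera_id", "camera_model",
               "start_ts", "end_ts", "setup_notes")
.med_cols <- c("media_id", "deployment_id", "relative_path", "timestamp",
               "duration_s", "revision_id", "timestamp_issue")
.obs_cols <- c("observation_id", "media_id", "observation_type",
               "scientific_name", "count", "behavior",
               "classification_method", "classified_by",
               "detector_confidence")

# CamTrap-DP style column aliases accepted on read
.col_aliases <- c(
  deploymentID = "deployment_id", locationID = "location_id",
  mediaID = "media_id", observationID = "observation_id",
  filePath = "relative_path", scientificName = "scientific_name",
  observationType = "observation_type", cameraID = "camera_id",
  cameraModel = "camera_model", classificationMethod = "classification_method",
  classifiedBy = "classified_by", timestampIssue = "timestamp_issue",
  deploymentStart = "start_ts", deploymentEnd = "end_ts"
)

.rename_aliases <- function(df) {
  hit <- names(df) %in% names(.col_aliases)
  names(df)[hit] <- unname(.col_aliases[names(df)[hit]])
  df
}

.ensure_cols <- function(df, cols, table) {
  for (cl in setdiff(cols, names(df))) df[[cl]] <- NA
  df[, cols, drop = FALSE]
}

#' Assemble a validated project-table set
#'
#' Bundles the three related tables, coerces column types, parses
#' timestamps (unparseable media timestamps set `timestamp_issue = TRUE`
#' and are retained) and runs referential-integrity checks. Violations are
#' collected in the `integrity` element -- never silently dropped; the
#' caller decides what to do with orphan rows.
#'
#' @param deployments,media,observations Data frames following the
#'   documented column schema (CamTrap-DP style aliases such as
#'   `deploymentID`, `mediaID` are accepted).
#' @return An object of class `camtrap_tables`: a list with elements
#'   `deployments`, `media`, `observations` and `integrity` (a data frame
#'   with columns `table`, `id`, `issue`; zero rows when clean).
#' @export
camtrap_tables <- function(deployments, media, observations) {
  deployments <- .ensure_cols(.rename_aliases(as.data.frame(deployments)),
                              .dep_cols, "deployments")
  media <- .ensure_cols(.rename_aliases(as.data.frame(media)),
                        .med_cols, "media")
  observations <- .ensure_cols(.rename_aliases(as.data.frame(observations)),
                               .obs_cols, "observations")

  for (cl in c("start_ts", "end_ts")) {
    if (!inherits(deployments[[cl]], "POSIXct"))
      deployments[[cl]] <- ct_parse_timestamp(deployments[[cl]])
  }
  if (!inherits(media$timestamp, "POSIXct")) {
    raw <- as.character(media$timestamp)
    media$timestamp <- ct_parse_timestamp(raw)
    bad <- is.na(media$timestamp) & !is.na(raw) & nzchar(raw)
    media$timestamp_issue <- isTRUE_vec(media$timestamp_issue) | bad
  } else {
    media$timestamp_issue <- isTRUE_vec(media$timestamp_issue)
  }
  media$duration_s <- as.numeric(media$duration_s)
  media$duration_s[is.na(media$duration_s)] <- 10
  observations$count <- suppressWarnings(as.integer(observations$count))
  observations$detector_confidence <-
    suppressWarnings(as.numeric(observations$detector_confidence))

  out <- structure(
    list(deployments = deployments, media = media,
         observations = observations),
    class = "camtrap_tables")
  out$integrity <- validate_tables(out)
  out
}

#' @noRd
isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  x <- tolower(as.character(x))
  !is.na(x) & x %in% c("true", "t", "1", "yes")
}

#' Referential-integrity and invariant checks for project tables
#'
#' @param x A `camtrap_tables` object.
#' @return Data frame (`table`, `id`, `issue`); zero rows when clean.
#' @export
validate_tables <- function(x) {
  issues <- list()
  add <- function(table, id, issue) {
    issues[[length(issues) + 1L]] <<-
      data.frame(table = table, id = as.character(id), issue = issue)
  }
  dep <- x$deployments; med <- x$media; obs <- x$observations

  d <- dep$deployment_id[duplicated(dep$deployment_id)]
  for (id in unique(d)) add("deployments", id, "duplicate deployment_id")
  bad <- !is.na(dep$start_ts) & !is.na(dep$end_ts) & dep$start_ts > dep$end_ts
  for (id in dep$deployment_id[bad]) add("deployments", id, "start_ts after end_ts")

  d <- med$media_id[duplicated(med$media_id)]
  for (id in unique(d)) add("media", id, "duplicate media_id")
  orphan <- !is.na(med$deployment_id) &
    !(med$deployment_id %in% dep$deployment_id)
  for (id in med$media_id[orphan]) add("media", id, "unknown deployment_id")
  bad <- !is.na(med$duration_s) & med$duration_s <= 0
  for (id in med$media_id[bad]) add("media", id, "non-positive duration_s")

  orphan <- !is.na(obs$media_id) & !(obs$media_id %in% med$media_id)
  for (id in obs$observation_id[orphan]) add("observations", id, "unknown media_id")
  bad <- !is.na(obs$observation_type) &
    !(obs$observation_type %in% ct_observation_types())
  for (id in obs$observation_id[bad]) add("observations", id, "unknown observation_type")
  is_animal <- !is.na(obs$observation_type) & obs$observation_type == "animal"
  noname <- is_animal &
    (is.na(obs$scientific_name) | !nzchar(trimws(as.character(obs$scientific_name))))
  for (id in obs$observation_id[noname])
    add("observations", id, "animal observation without scientific_name")
  badn <- is_animal & !is.na(obs$count) & obs$count < 1L
  for (id in obs$observation_id[badn]) add("observations", id, "animal count < 1")

  if (length(issues) == 0)
    return(data.frame(table = character(), id = character(),
                      issue = character()))
  do.call(rbind, issues)
}

#' Read the three project tables from CSV
#'
#' @param deployments,media,observations Paths to `deployment.csv`,
#'   `video.csv` and `observation.csv` (header row mandatory; comma
#'   separated, UTF-8).
#' @return A `camtrap_tables` object; see [camtrap_tables()].
#' @export
read_tables <- function(deployments, media, observations) {
  for (p in c(deployments, media, observations)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  rd <- function(p) utils::read.csv(p, colClasses = "character",
                                    fileEncoding = "UTF-8", check.names = FALSE)
  camtrap_tables(rd(deployments), rd(media), rd(observations))
}

#' Write project tables to a directory
#'
#' Writes `deployment.csv`, `video.csv` and `observation.csv`. Re-reading
#' the files with [read_tables()] reproduces the tables field-for-field.
#'
#' @param tables A `camtrap_tables` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "camtrap_tables"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)

  dep <- tables$deployments
  dep$start_ts <- ct_format_timestamp(dep$start_ts)
  dep$end_ts <- ct_format_timestamp(dep$end_ts)
  med <- tables$media
  med$timestamp <- ct_format_timestamp(med$timestamp)
  med$timestamp_issue <- ifelse(isTRUE_vec(med$timestamp_issue), "true", "false")
  obs <- tables$observations

  paths <- file.path(dir, c("deployment.csv", "video.csv", "observation.csv"))
  wr <- function(df, p) utils::write.csv(df, p, row.names = FALSE, na = "",
                                         fileEncoding = "UTF-8")
  wr(dep, paths[1]); wr(med, paths[2]); wr(obs, paths[3])
  invisible(paths)
}

#' Consensus species identification from multiple expert reviews
#'
#' When the first reviewer cannot confidently identify a species, several
#' additional experts review the video independently; the identification is
#' accepted when at least `min_agree` of them agree, otherwise the
#' observation is classified `"unidentified"` and excluded from interaction
#' analyses downstream.
#'
#' @param labels Character vector of species labels, one per annotator (or
#'   a data frame with a `scientific_name` column).
#' @param min_agree Minimum number of agreeing annotators (default 3).
#' @return A single label, or `"unidentified"` when no label reaches
#'   `min_agree` votes.
#' @export
resolve_species_consensus <- function(labels, min_agree = 3L) {
  if (is.data.frame(labels)) labels <- labels$scientific_name
  labels <- as.character(labels)
  labels <- labels[!is.na(labels) & nzchar(labels)]
  if (length(labels) == 0) stop("at least one annotation required")
  tab <- table(labels)
  win <- names(tab)[tab >= min_agree]
  if (length(win) > 1)
    stop("ambiguous consensus: ", paste(win, collapse = ", "))
  if (length(win) == 1) win else "unidentified"
}

#' @export
print.camtrap_tables <- function(x, ...) {
  cat("camtrap_tables:",
      nrow(x$deployments), "deployments,",
      nrow(x$media), "media,",
      nrow(x$observations), "observations;",
      nrow(x$integrity), "integrity issue(s)\n")
  invisible(x)
}

# Run code with a local, restorable RNG state so package functions taking a
# `seed` argument never perturb the caller's stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
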