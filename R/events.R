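# From reviewed videos to independent interaction events, sampling effort,
# and interaction / PIE matrices.

#' Keep only observations that evidence a frugivory interaction
#'
#' Retains animal observations whose behavior falls in the feeding
#' hierarchy (`include`) and whose species identification is resolved;
#' records of animals merely passing by, perching without foraging, etc.,
#' and `"unidentified"` consensus labels are discarded as negative records.
#'
#' @param observations Observation data frame (typically
#'   `tables$observations`, already joined to media if timestamps are
#'   needed downstream).
#' @param include Behaviors counted as interactions; default
#'   [ct_interaction_behaviors()].
#' @return The filtered observation data frame.
#' @export
filter_interaction_records <- function(observations,
                                       include = ct_interaction_behaviors()) {
  keep <- !is.na(observations$observation_type) &
    observations$observation_type == "animal" &
    !is.na(observations$behavior) & observations$behavior %in% include &
    !is.na(observations$scientific_name) &
    nzchar(observations$scientific_name) &
    observations$scientific_name != "unidentified"
  observations[keep, , drop = FALSE]
}

#' Join observations to their media timestamps and deployment
#'
#' Convenience step before [collapse_events()]: attaches `timestamp` and
#' `deployment_id` from the media table and renames `scientific_name` to
#' `animal_species`.
#'
#' @param observations Observation data frame.
#' @param media Media data frame.
#' @return Data frame with one row per observation and columns
#'   `media_id`, `deployment_id`, `animal_species`, `timestamp`,
#'   `behavior`, `count`.
#' @export
join_observation_media <- function(observations, media) {
  i <- match(observations$media_id, media$media_id)
  data.frame(media_id = observations$media_id,
             deployment_id = media$deployment_id[i],
             animal_species = observations$scientific_name,
             timestamp = media$timestamp[i],
             behavior = observations$behavior,
             count = observations$count,
             stringsAsFactors = FALSE)
}

#' Collapse consecutive videos into independent interaction events
#'
#' Consecutive short videos of the same animal species at the same
#' deployment are temporally autocorrelated: one frugivore visit usually
#' triggers several 10 s recordings. Records within each key group are
#' merged into one event using a 5 min (300 s) rule, in one of two modes:
#'
#' * `"chain"` (default): consecutive records, sorted by time, are merged
#'   while the start-to-start gap to the previous record is at most
#'   `window_s`; a gap strictly greater than `window_s` opens a new event.
#' * `"fixed"`: records are binned into fixed `window_s` intervals anchored
#'   at the group's first record.
#'
#' @param records Data frame from [join_observation_media()] (columns
#'   `media_id`, `timestamp`, `behavior`, `count`, and the `keys` columns).
#' @param window_s Independence window in seconds (default 300).
#' @param mode `"chain"` or `"fixed"`.
#' @param keys Grouping columns; records differing in any key are never
#'   merged. Default `(deployment_id, animal_species)`.
#' @return Data frame of class `interaction_events`: `event_id`,
#'   the key columns, `start_ts`, `end_ts`, `n_videos`, `behaviors`
#'   (`;`-joined multiset) and `max_count`. Records with missing
#'   timestamps are excluded and listed in the `excluded` attribute.
#' @export
collapse_events <- function(records, window_s = 300,
                            mode = c("chain", "fixed"),
                            keys = c("deployment_id", "animal_species")) {
  mode <- match.arg(mode)
  stopifnot(window_s > 0, all(keys %in% names(records)))
  excl <- records$media_id[is.na(records$timestamp)]
  rec <- records[!is.na(records$timestamp), , drop = FALSE]
  if (nrow(rec) == 0) {
    out <- data.frame(event_id = character(), start_ts = as.POSIXct(character()),
                      end_ts = as.POSIXct(character()), n_videos = integer(),
                      behaviors = character(), max_count = integer())
    for (k in rev(keys)) out <- cbind(stats::setNames(
      data.frame(x = character()), k), out)
    return(structure(out, class = c("interaction_events", "data.frame"),
                     excluded = excl, window_s = window_s, mode = mode))
  }
  grp <- interaction(rec[keys], drop = TRUE, sep = "\r")
  pieces <- lapply(split(rec, grp), function(g) {
    g <- g[order(g$timestamp), , drop = FALSE]
    gap <- c(Inf, as.numeric(diff(g$timestamp), units = "secs"))
    ev <- if (mode == "chain") {
      cumsum(gap > window_s)
    } else {
      off <- as.numeric(g$timestamp - g$timestamp[1], units = "secs")
      floor(off / window_s) + 1L
    }
    res <- lapply(split(seq_len(nrow(g)), ev), function(idx) {
      s <- g[idx, , drop = FALSE]
      cnt <- suppressWarnings(as.integer(s$count))
      row <- s[1, keys, drop = FALSE]
      row$start_ts <- min(s$timestamp)
      row$end_ts <- max(s$timestamp)
      row$n_videos <- length(idx)
      row$behaviors <- paste(sort(as.character(s$behavior)), collapse = ";")
      row$max_count <- if (all(is.na(cnt))) NA_integer_ else
        max(cnt, na.rm = TRUE)
      row
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out[[keys[1]]], out$start_ts), , drop = FALSE]
  rownames(out) <- NULL
  out <- cbind(event_id = sprintf("E%05d", seq_len(nrow(out))), out)
  structure(out, class = c("interaction_events", "data.frame"),
            excluded = excl, window_s = window_s, mode = mode)
}

#' Sampling effort per deployment revision
#'
#' Field crews record a trigger file at the beginning and end of every
#' deployment revision, so the span between the first and last media
#' timestamp of a revision measures its sampling effort. Effort is
#' expressed in decimal trap-days and can be summed over revisions,
#' deployments, plant individuals and plant species.
#'
#' @param media Media data frame (`deployment_id`, `revision_id`,
#'   `timestamp`, `timestamp_issue`).
#' @return Data frame (`deployment_id`, `revision_id`, `effort_days`,
#'   `n_videos`). Revisions with fewer than two parseable timestamps get
#'   `effort_days = NA` and are listed in the `undefined` attribute;
#'   exclude them from sums.
#' @export
compute_effort <- function(media) {
  ok <- !is.na(media$timestamp) & !isTRUE_vec(media$timestamp_issue)
  key <- paste(media$deployment_id, media$revision_id, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_len(nrow(media)), key), function(idx) {
    m <- media[idx, , drop = FALSE]
    ts <- m$timestamp[ok[idx]]
    data.frame(deployment_id = m$deployment_id[1],
               revision_id = m$revision_id[1],
               effort_days = if (length(ts) >= 2)
                 as.numeric(difftime(max(ts), min(ts), units = "days"))
               else NA_real_,
               n_videos = nrow(m),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out <- out[order(out$deployment_id, out$revision_id), , drop = FALSE]
  structure(out,
            undefined = out[is.na(out$effort_days),
                            c("deployment_id", "revision_id")])
}

#' Aggregate effort to plant individuals or species
#'
#' @param effort Output of [compute_effort()].
#' @param deployments Deployment table.
#' @param level `"individual"` or `"species"`.
#' @return Data frame with the plant unit and summed `effort_days`
#'   (undefined revisions excluded).
#' @export
aggregate_effort <- function(effort, deployments,
                             level = c("species", "individual")) {
  level <- match.arg(level)
  col <- if (level == "species") "plant_species" else "plant_individual_id"
  i <- match(effort$deployment_id, deployments$deployment_id)
  unit <- deployments[[col]][i]
  keep <- !is.na(effort$effort_days)
  agg <- tapply(effort$effort_days[keep], unit[keep], sum)
  data.frame(unit = names(agg), effort_days = as.numeric(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Attach plant labels to events
#'
#' Adds `plant_species` and `plant_individual_id` from the deployment table
#' to an event data frame, as needed by [lost_information_report()].
#'
#' @param events `interaction_events` (or any data frame with a
#'   `deployment_id` column).
#' @param deployments Deployment table.
#' @return The events with the two plant columns appended.
#' @export
add_plant_labels <- function(events, deployments) {
  i <- match(events$deployment_id, deployments$deployment_id)
  if (anyNA(i)) stop("event deployment(s) missing from deployment table: ",
                     paste(unique(events$deployment_id[is.na(i)]),
                           collapse = ", "))
  events$plant_species <- deployments$plant_species[i]
  events$plant_individual_id <- deployments$plant_individual_id[i]
  events
}

#' Build the weighted plant x animal interaction matrix
#'
#' Each cell counts interaction events between a plant unit (species for
#' community-level analyses, plant individual for individual-based ones)
#' and an animal species.
#'
#' @param events `interaction_events` from [collapse_events()].
#' @param deployments Deployment table used to attribute each event's
#'   deployment to its plant species / individual.
#' @param level `"species"` (default) or `"individual"`.
#' @return A [bipartite_network()] with integer event counts.
#' @export
interaction_matrix <- function(events, deployments,
                               level = c("species", "individual")) {
  level <- match.arg(level)
  if (nrow(events) == 0) stop("no events to tabulate")
  col <- if (level == "species") "plant_species" else "plant_individual_id"
  i <- match(events$deployment_id, deployments$deployment_id)
  if (anyNA(i)) stop("event deployment(s) missing from deployment table: ",
                     paste(unique(events$deployment_id[is.na(i)]), collapse = ", "))
  plant <- deployments[[col]][i]
  w <- table(factor(plant), factor(events$animal_species))
  bipartite_network(unclass(as.matrix(w)))
}

#' Probability of interspecific encounter (PIE) matrix
#'
#' Converts event counts into interaction probabilities. Row normalization
#' (default) is the phytocentric reading: `PIE[i, j]` is the probability
#' that plant unit `i` interacts with animal species `j`, i.e. each
#' nonzero plant row sums to 1. Global normalization divides by the grand
#' total instead. Foraging-based records can optionally be down-weighted by
#' the proportion of fruit in each animal's diet before normalizing.
#'
#' @param net A [bipartite_network()] of event counts.
#' @param normalization `"row"` (default) or `"global"`.
#' @param diet_weight Optional named numeric vector in `[0, 1]`, one entry
#'   per animal species (missing species default to 1).
#' @return Matrix of class `pie_matrix` with attributes `normalization`
#'   and `diet_weight`.
#' @export
pie_matrix <- function(net, normalization = c("row", "global"),
                       diet_weight = NULL) {
  normalization <- match.arg(normalization)
  w <- unclass(net$weights)
  if (!is.null(diet_weight)) {
    if (any(diet_weight < 0 | diet_weight > 1))
      stop("diet_weight values must lie in [0, 1]")
    dw <- rep(1, ncol(w))
    names(dw) <- colnames(w)
    hit <- intersect(names(diet_weight), colnames(w))
    dw[hit] <- diet_weight[hit]
    w <- sweep(w, 2, dw, `*`)
  }
  p <- if (normalization == "row") {
    rs <- rowSums(w)
    out <- w / ifelse(rs == 0, 1, rs)  # zero rows stay zero
    out
  } else {
    tot <- sum(w)
    if (tot == 0) w else w / tot
  }
  structure(p, class = c("pie_matrix", class(p)),
            normalization = normalization, diet_weight = diet_weight)
}

#' Write events, effort or matrices to CSV
#'
#' @param x An `interaction_events`, effort, or matrix-like object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_events <- function(x, path) {
  df <- as.data.frame(x)
  for (cl in c("start_ts", "end_ts"))
    if (cl %in% names(df)) df[[cl]] <- ct_format_timestamp(df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
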