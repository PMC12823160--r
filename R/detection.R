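# Frame-level object-detector output -> video-level classification.
#
# The object detector (MegaDetector v4/v5 output dialect) runs on individual
# frames extracted from each video; the video-level score is the maximum
# confidence over its frames, and videos are partitioned into
# selected-for-review vs blank at a confidence threshold.

.md_default_categories <- c("1" = "animal", "2" = "person", "3" = "vehicle")

#' Map frame files to their parent videos
#'
#' Frames are extracted into a directory tree mirroring the video tree and
#' named `<videoStem>_<frameIndex>.<ext>` (the default convention; supply
#' another capturing regular expression via `pattern`). The video stem is
#' the `media_id`.
#'
#' @param frame_paths Character vector of frame file paths.
#' @param pattern Regular expression applied to the file name without
#'   extension; the first capture group is the media id.
#' @param video_stems Optional character vector of known
#'   directory-qualified video stems (`dir/stem`); duplicates within one
#'   directory are reported as collisions.
#' @return Data frame (`frame_path`, `media_id`, `dir`) of class
#'   `frame_manifest`, with attribute `unmatched` listing paths that do not
#'   follow the convention (reported, never dropped silently).
#' @export
build_frame_manifest <- function(frame_paths,
                                 pattern = "^(.+)_(\\d+)$",
                                 video_stems = NULL) {
  if (!is.null(video_stems)) {
    dup <- unique(video_stems[duplicated(video_stems)])
    if (length(dup) > 0)
      stop("ambiguous video stems (same stem twice in one directory): ",
           paste(dup, collapse = ", "))
  }
  base <- basename(frame_paths)
  noext <- sub("\\.[A-Za-z0-9]+$", "", base)
  ok <- grepl(pattern, noext)
  stem <- sub(pattern, "\\1", noext[ok])
  man <- data.frame(frame_path = frame_paths[ok],
                    media_id = stem,
                    dir = dirname(frame_paths[ok]),
                    stringsAsFactors = FALSE)
  structure(man, class = c("frame_manifest", "data.frame"),
            unmatched = frame_paths[!ok])
}

#' @noRd
.as_detection_doc <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("detection file not found: ", x, call. = FALSE)
    x <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  }
  if (is.null(x$images)) stop("malformed detection document: no 'images' array")
  if (is.null(x$detection_categories))
    x$detection_categories <- as.list(.md_default_categories)
  x
}

#' Parse a MegaDetector-format detection document
#'
#' @param x A path to a detection `.json` file, or an already-parsed
#'   document (list with `images` and `detection_categories`).
#' @return Data frame of class `frame_detections` with one row per
#'   detection entry: `frame_path`, `category`, `confidence`, `bbox_x`,
#'   `bbox_y`, `bbox_w`, `bbox_h`. Frames whose `detections` array is empty
#'   contribute no rows. Unknown category codes are an error.
#' @export
parse_detections <- function(x) {
  doc <- .as_detection_doc(x)
  cats <- unlist(doc$detection_categories)
  rows <- vector("list", length(doc$images))
  for (i in seq_along(doc$images)) {
    img <- doc$images[[i]]
    if (is.null(img$file))
      stop("malformed detection document: images[[", i, "]] has no 'file'")
    dets <- img$detections
    if (is.null(dets) || length(dets) == 0) next
    code <- vapply(dets, function(d) as.character(d$category), character(1))
    unknown <- setdiff(unique(code), names(cats))
    if (length(unknown) > 0)
      stop("unknown category code(s) ", paste(unknown, collapse = ", "),
           " in image ", img$file)
    conf <- vapply(dets, function(d) as.numeric(d$conf), numeric(1))
    bb <- t(vapply(dets, function(d) {
      if (is.null(d$bbox)) rep(NA_real_, 4) else as.numeric(unlist(d$bbox))
    }, numeric(4)))
    rows[[i]] <- data.frame(frame_path = img$file,
                            category = unname(cats[code]),
                            confidence = conf,
                            bbox_x = bb[, 1], bbox_y = bb[, 2],
                            bbox_w = bb[, 3], bbox_h = bb[, 4],
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) == 0) {
    data.frame(frame_path = character(), category = character(),
               confidence = numeric(), bbox_x = numeric(), bbox_y = numeric(),
               bbox_w = numeric(), bbox_h = numeric())
  } else do.call(rbind, rows)
  if (any(out$confidence < 0 | out$confidence > 1))
    stop("confidence outside [0, 1] in detection document")
  class(out) <- c("frame_detections", "data.frame")
  attr(out, "frames_processed") <-
    vapply(doc$images, function(img) img$file, character(1))
  out
}

#' Combine several detection batches into one document
#'
#' Detector runs are typically batched (by season, camera or upload); this
#' concatenates their `images` arrays after checking the category maps
#' agree and no frame was processed twice.
#'
#' @param docs List of detection documents (paths or parsed lists).
#' @return A single combined document (list).
#' @export
merge_detection_batches <- function(docs) {
  docs <- lapply(docs, .as_detection_doc)
  ref <- docs[[1]]$detection_categories
  for (d in docs[-1]) {
    if (!identical(unlist(d$detection_categories)[order(names(unlist(d$detection_categories)))],
                   unlist(ref)[order(names(unlist(ref)))]))
      stop("conflicting detection_categories across batches")
  }
  images <- do.call(c, lapply(docs, `[[`, "images"))
  files <- vapply(images, `[[`, character(1), "file")
  dup <- unique(files[duplicated(files)])
  if (length(dup) > 0)
    stop("duplicate frame path(s) across batches: ",
         paste(utils::head(dup, 5), collapse = ", "))
  list(images = images, detection_categories = ref)
}

#' Aggregate frame-level detections to video-level confidences
#'
#' The video-level output keeps, for every video and category, the highest
#' confidence over that video's frames. Videos whose frames carry no
#' detections score 0; videos absent from the manifest are "not processed"
#' and do not appear at all (never counted as blank).
#'
#' @param detections A `frame_detections` data frame from
#'   [parse_detections()].
#' @param manifest A `frame_manifest` from [build_frame_manifest()].
#' @param permissive If `FALSE` (default) a detection on a frame not in the
#'   manifest is an error; if `TRUE` such detections are dropped and listed
#'   in the `orphan_frames` attribute.
#' @return Data frame of class `video_confidence_index`: `media_id`,
#'   `n_frames`, and one max-confidence column per category (`animal`,
#'   `person`, `vehicle`).
#' @export
aggregate_to_video <- function(detections, manifest, permissive = FALSE) {
  stopifnot(inherits(manifest, "data.frame"))
  lut <- manifest$media_id
  names(lut) <- manifest$frame_path
  miss <- setdiff(unique(detections$frame_path), manifest$frame_path)
  if (length(miss) > 0 && !permissive)
    stop("detections on frame(s) missing from manifest: ",
         paste(utils::head(miss, 5), collapse = ", "))
  det <- detections[detections$frame_path %in% manifest$frame_path, ,
                    drop = FALSE]
  det$media_id <- unname(lut[det$frame_path])

  media <- sort(unique(manifest$media_id))
  nfr <- table(factor(manifest$media_id, levels = media))
  out <- data.frame(media_id = media, n_frames = as.integer(nfr),
                    stringsAsFactors = FALSE)
  for (cat in c("animal", "person", "vehicle")) {
    v <- rep(0, length(media))
    sub <- det[det$category == cat, , drop = FALSE]
    if (nrow(sub) > 0) {
      mx <- tapply(sub$confidence, factor(sub$media_id, levels = media), max)
      v[!is.na(mx)] <- mx[!is.na(mx)]
    }
    out[[cat]] <- v
  }
  structure(out, class = c("video_confidence_index", "data.frame"),
            orphan_frames = miss)
}

#' Partition videos into selected and blank at a confidence threshold
#'
#' A video is selected for human review when its maximum detector
#' confidence for `category` is strictly greater than `threshold`
#' ("no detections above this threshold" means blank); ties at exactly the
#' threshold fall to blank. The partition is exhaustive and disjoint.
#'
#' @param index A `video_confidence_index`.
#' @param threshold Confidence threshold in `[0, 1]`; default 0.8, a
#'   conservative value for MegaDetector v4.
#' @param category Detector category used for the decision (default
#'   `"animal"`; person/vehicle detections are carried through the index
#'   but not used for interaction pipelines).
#' @return List with character vectors `selected` and `blank`.
#' @export
partition_videos <- function(index, threshold = 0.8, category = "animal") {
  stopifnot(threshold >= 0, threshold <= 1,
            category %in% c("animal", "person", "vehicle"))
  sel <- index[[category]] > threshold
  list(selected = index$media_id[sel], blank = index$media_id[!sel])
}

#' Extract frames from videos with an external tool (optional adapter)
#'
#' Thin adapter around an external `ffmpeg` binary that mirrors the video
#' directory tree and names frames `<videoStem>_<index>.jpg` so that
#' [build_frame_manifest()] recovers the mapping. The core pipeline never
#' requires this: detector output is consumed from JSON.
#'
#' @param video_dir Directory tree containing video files.
#' @param out_dir Output directory for the frame tree.
#' @param fps Frames sampled per second of video (default 1).
#' @param tool Path to the ffmpeg binary; defaults to
#'   `getOption("camtrapnet.ffmpeg")`, falling back to `ffmpeg` on the
#'   `PATH`.
#' @param extensions Video file extensions to process; other files are
#'   skipped with a warning.
#' @return Invisibly, the paths of extracted frames.
#' @export
extract_frames <- function(video_dir, out_dir, fps = 1,
                           tool = getOption("camtrapnet.ffmpeg",
                                            Sys.which("ffmpeg")),
                           extensions = c("mp4", "avi", "mov")) {
  if (is.null(tool) || !nzchar(tool) || !file.exists(tool))
    stop("frame extraction requires an external ffmpeg binary; ",
         "set options(camtrapnet.ffmpeg = \"/path/to/ffmpeg\")",
         call. = FALSE)
  files <- list.files(video_dir, recursive = TRUE, full.names = FALSE)
  isvid <- tolower(tools::file_ext(files)) %in% extensions
  if (any(!isvid))
    warning("skipping non-video file(s): ",
            paste(utils::head(files[!isvid], 5), collapse = ", "))
  out <- character()
  for (f in files[isvid]) {
    stem <- tools::file_path_sans_ext(basename(f))
    dest <- file.path(out_dir, dirname(f))
    dir.create(dest, recursive = TRUE, showWarnings = FALSE)
    status <- system2(tool,
                      c("-loglevel", "error", "-i",
                        shQuote(file.path(video_dir, f)),
                        "-vf", paste0("fps=", fps),
                        shQuote(file.path(dest, paste0(stem, "_%03d.jpg")))))
    if (status != 0) stop("ffmpeg failed on ", f)
    out <- c(out, list.files(dest, pattern = paste0("^", stem, "_"),
                             full.names = TRUE))
  }
  invisible(out)
}
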