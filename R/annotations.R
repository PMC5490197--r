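# Stage and event annotation handling: NSRR-style XML event exports and a
# plain two-column CSV dialect (epoch_index,stage) used for fixtures.

.aasm_stages <- c("W", "N1", "N2", "N3", "R")

.stage_alias <- c(
  "W" = "W", "WAKE" = "W", "0" = "W",
  "N1" = "N1", "NREM1" = "N1", "S1" = "N1", "1" = "N1",
  "N2" = "N2", "NREM2" = "N2", "S2" = "N2", "2" = "N2",
  "N3" = "N3", "NREM3" = "N3", "S3" = "N3", "3" = "N3",
  "N4" = "N4", "NREM4" = "N4", "S4" = "N4", "4" = "N4",
  "R" = "R", "REM" = "R", "5" = "R",
  "?" = "?", "UNSCORED" = "?", "9" = "?"
)

#' Construct an annotation set
#'
#' Bundles per-30-s-epoch sleep stages with timed events (arousal, movement,
#' artifact). Stage labels are normalized to `{W, N1, N2, N3, N4, R, ?}`;
#' unknown labels become `"?"`.
#'
#' @param stages Character vector, one label per 30-s epoch.
#' @param events A data frame with columns `class` (one of `arousal`,
#'   `movement`, `artifact`), `start` (s) and `duration` (s), or `NULL`.
#' @return An `annotation_set`: a list with `stages`, `events` (tibble) and
#'   `epoch_length` (30).
#' @export
annotation_set <- function(stages, events = NULL) {
  stages <- toupper(trimws(as.character(stages)))
  norm <- unname(.stage_alias[stages])
  norm[is.na(norm)] <- "?"
  if (is.null(events)) {
    events <- tibble(class = character(), start = numeric(), duration = numeric())
  } else {
    events <- as_tibble(events)
    stopifnot(all(c("class", "start", "duration") %in% names(events)))
    if (any(events$duration < 0, na.rm = TRUE)) stop("event durations must be non-negative")
  }
  structure(list(stages = norm, events = events, epoch_length = 30),
            class = "annotation_set")
}

#' Collapse R&K stage four into N3
#'
#' Studies scored with the older R&K vocabulary distinguish NREM3 and NREM4;
#' for consistency both are analysed as a single N3 stage. The original N4
#' positions are retained in a sidecar so the deep slow-wave sub-analysis can
#' still find them.
#'
#' @param annot An [annotation_set()].
#' @return The annotation set with stages in `{W, N1, N2, N3, R, ?}` and an
#'   added integer `n4_sidecar` (1 where the original label was N4).
#' @export
collapse_stages <- function(annot) {
  stopifnot(inherits(annot, "annotation_set"))
  annot$n4_sidecar <- as.integer(annot$stages == "N4")
  annot$stages[annot$stages == "N4"] <- "N3"
  annot$stages[!(annot$stages %in% .aasm_stages)] <- "?"
  annot
}

#' Read fixture stage annotations from CSV
#'
#' Reads the two-column `epoch_index,stage` dialect (0-based epoch index),
#' with an optional `class,start,duration` events CSV alongside.
#'
#' @param path Stage CSV path.
#' @param events_path Optional events CSV path.
#' @return An [annotation_set()].
#' @export
read_stage_csv <- function(path, events_path = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("epoch_index", "stage") %in% names(d)))
  d <- d[order(d$epoch_index), ]
  ev <- if (!is.null(events_path)) read.csv(events_path, stringsAsFactors = FALSE)
  annotation_set(d$stage, ev)
}

#' Read NSRR-style XML annotations
#'
#' Parses the profusion-style XML export: `<SleepStages>` holds one integer
#' per 30-s epoch (0 wake, 1-4 NREM, 5 REM) and `<ScoredEvents>` holds timed
#' events. Event names containing "arousal", "movement" or "artifact" are
#' mapped to the corresponding class; other events are dropped.
#'
#' @param path XML file path.
#' @return An [annotation_set()].
#' @export
read_nsrr_xml <- function(path) {
  doc <- xml2::read_xml(path)
  stages <- xml2::xml_text(xml2::xml_find_all(doc, ".//SleepStages/SleepStage"))
  evn <- xml2::xml_find_all(doc, ".//ScoredEvents/ScoredEvent")
  get1 <- function(node, tag) xml2::xml_text(xml2::xml_find_first(node, tag))
  ev <- purrr::map_dfr(evn, function(nd) {
    nm <- tolower(paste(get1(nd, "EventType"), get1(nd, "EventConcept"), get1(nd, "Name")))
    cls <- if (grepl("arousal", nm)) "arousal"
      else if (grepl("movement|limb", nm)) "movement"
      else if (grepl("artifact|artefact", nm)) "artifact"
      else NA_character_
    tibble(class = cls,
           start = as.numeric(get1(nd, "Start")),
           duration = as.numeric(get1(nd, "Duration")))
  })
  ev <- ev[!is.na(ev$class), , drop = FALSE]
  annotation_set(stages, ev)
}

#' Write fixture stage annotations to CSV
#' @param annot An [annotation_set()].
#' @param path Stage CSV path.
#' @param events_path Optional events CSV path (written only if events exist).
#' @return `path`, invisibly.
#' @export
write_stage_csv <- function(annot, path, events_path = NULL) {
  write.csv(data.frame(epoch_index = seq_along(annot$stages) - 1L,
                       stage = annot$stages),
            path, row.names = FALSE, quote = FALSE)
  if (!is.null(events_path) && nrow(annot$events)) {
    write.csv(annot$events, events_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
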