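# Time frames and staging schedules ------------------------------------------

#' Define a time frame of developmental landmarks
#'
#' A frame is an ordered set of interior landmarks (percent of normalized
#' developmental time, strictly between 0 and 100) plus, by default, the
#' 0% and 100% boundary landmarks.  The 0% boundary is fecundation; the
#' 100% boundary is the event chosen to close the normalization span
#' (onset of pectoral fin rays for the bundled data).
#'
#' @param interior numeric vector of interior landmarks in (0, 100).
#' @param include_bounds add the 0% and 100% landmarks (default `TRUE`);
#'   every analysis of the bundled data behaves as if they were present.
#' @return an object of class `time_frame`.
#' @export
time_frame <- function(interior, include_bounds = TRUE) {
  interior <- as.numeric(interior)
  if (!length(interior)) .stop("ontochron_frame_error", "empty time frame")
  if (any(is.na(interior)) || any(interior <= 0) || any(interior >= 100)) {
    .stop("ontochron_frame_error",
          "interior landmarks must lie strictly between 0 and 100")
  }
  if (any(diff(interior) <= 0)) {
    if (anyDuplicated(interior)) {
      .stop("ontochron_frame_error", "duplicated landmark")
    }
    interior <- sort(interior)
  }
  structure(list(interior = interior, include_bounds = include_bounds),
            class = "time_frame")
}

#' @export
print.time_frame <- function(x, ...) {
  cat(sprintf("time frame: %s%s\n", paste(x$interior, collapse = "-"),
              if (x$include_bounds) " (+ 0% and 100% bounds)" else ""))
  invisible(x)
}

#' @export
format.time_frame <- function(x, ...) paste(x$interior, collapse = "-")

#' Landmarks of a frame
#' @param frame a `time_frame`.
#' @return numeric vector of all landmarks, bounds included when the frame
#'   carries them.
#' @export
frame_landmarks <- function(frame) {
  if (frame$include_bounds) c(0, frame$interior, 100) else frame$interior
}

#' Construct a staging schedule
#'
#' Raw per-species input before normalization: the onset time of each
#' character in degree-Celsius-days (temperature multiplied by days, the
#' thermal time that makes developmental rates comparable across rearing
#' temperatures), plus the thermal times of the 0% boundary (fecundation)
#' and of the 100% boundary event.
#'
#' @param species species name (tokens joined by underscores).
#' @param onsets numeric vector of onset times in degree-days, one per
#'   character, `NA` for unknown; names are kept as character names.
#' @param t0 degree-days at fecundation.
#' @param t100 degree-days at the 100% boundary event; must exceed `t0`.
#' @return an object of class `staging_schedule`.
#' @export
staging_schedule <- function(species, onsets, t0, t100) {
  if (t100 <= t0) {
    .stop("ontochron_span_error",
          "degenerate normalization span: t100 (%g) <= t0 (%g)", t100, t0)
  }
  if (any(onsets < t0, na.rm = TRUE)) {
    .stop("ontochron_span_error", "onset before fecundation in %s", species)
  }
  structure(list(species = species, onsets = as.numeric(onsets),
                 names = names(onsets), t0 = t0, t100 = t100),
            class = "staging_schedule")
}

#' @export
print.staging_schedule <- function(x, ...) {
  cat(sprintf("staging schedule: %s, %d characters, span %g-%g degree-days\n",
              x$species, length(x$onsets), x$t0, x$t100))
  invisible(x)
}

#' Normalize a staging schedule to percent-of-development
#'
#' Linear map of degree-day onsets onto the 0-100 scale spanned by
#' fecundation and the 100% boundary event:
#' `100 * (onset - t0) / (t100 - t0)`.  Unknown onsets stay unknown;
#' events later than the boundary event map beyond 100.
#'
#' @param s a `staging_schedule`.
#' @return numeric vector of onset percentages (`NA` = unknown).
#' @export
normalize_schedule <- function(s) {
  stopifnot(inherits(s, "staging_schedule"))
  100 * (s$onsets - s$t0) / (s$t100 - s$t0)
}

#' Read staging schedules from a CSV table
#'
#' Long-format table with columns `species`, `character_index`,
#' `onset_degdays`; the per-species normalization span is supplied in
#' `boundaries` (columns `species`, `t0`, `t100`).
#'
#' @param file path to the staging CSV.
#' @param boundaries data frame with columns `species`, `t0`, `t100`.
#' @return list of `staging_schedule`, one per species.
#' @export
read_staging <- function(file, boundaries) {
  df <- read.csv(file)
  need <- c("species", "character_index", "onset_degdays")
  if (!all(need %in% names(df))) {
    .stop("ontochron_parse_error", "staging CSV must have columns %s",
          paste(need, collapse = ", "))
  }
  K <- max(df$character_index)
  lapply(split(df, df$species), function(d) {
    b <- boundaries[match(d$species[1], boundaries$species), ]
    if (is.na(b$t0)) {
      .stop("ontochron_parse_error", "no boundaries for species %s", d$species[1])
    }
    on <- rep(NA_real_, K)
    on[d$character_index] <- d$onset_degdays
    staging_schedule(d$species[1], on, b$t0, b$t100)
  })
}

#' Build an OTU matrix from staging schedules
#'
#' One OTU per (species, landmark) pair of the frame.  A character is
#' present at an interior landmark when its normalized onset is at or
#' before the landmark (closed boundary, so an event "at 25%" is visible
#' at the 25% landmark), absent when later, unknown when its onset is
#' unknown.  The 0% row is all-absent by definition (fecundation precedes
#' every onset) and the 100% bound row codes every known-onset character
#' present, matching how completed developmental repertoires are coded in
#' published matrices even for events that fall after the boundary event.
#'
#' @param schedules list of `staging_schedule` sharing one character set.
#' @param frame a `time_frame`.
#' @param characters optional character definitions.
#' @return an `onto_matrix` with `length(schedules) * length(landmarks)` rows.
#' @export
build_matrix_from_schedules <- function(schedules, frame, characters = NULL) {
  stopifnot(inherits(frame, "time_frame"))
  K <- unique(vapply(schedules, function(s) length(s$onsets), 0L))
  if (length(K) != 1) {
    .stop("ontochron_dimension_error", "schedules differ in character count")
  }
  lms <- frame_landmarks(frame)
  if (!length(lms)) .stop("ontochron_frame_error", "empty frame")
  rows <- list()
  for (s in schedules) {
    pct <- normalize_schedule(s)
    for (lm in lms) {
      st <- if (lm == 0) {
        rep(0L, K)
      } else if (lm == 100) {
        ifelse(is.na(pct), NA_integer_, 1L)
      } else {
        ifelse(is.na(pct), NA_integer_, as.integer(pct <= lm))
      }
      rows[[paste0(s$species, "_", lm, "%")]] <- st
    }
  }
  states <- do.call(rbind, rows)
  character_matrix(states, characters = characters)
}

#' Restrict a matrix to the OTUs of a time frame
#'
#' Row subset preserving the input row order: for each species the
#' landmarks of the frame (bounds included when the frame carries them).
#'
#' @param m an `onto_matrix`.
#' @param frame a `time_frame`.
#' @return an `onto_matrix` with `n_species * n_landmarks` rows.
#' @export
select_frame <- function(m, frame) {
  stopifnot(inherits(m, "onto_matrix"), inherits(frame, "time_frame"))
  lms <- frame_landmarks(frame)
  species <- unique(m$species)
  want <- expand.grid(species = species, landmark = lms,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  have <- paste(m$species, m$landmark)
  missing <- !(paste(want$species, want$landmark) %in% have)
  if (any(missing)) {
    .stop("ontochron_lookup_error", "no OTU for: %s",
          paste(sprintf("%s at %g%%", want$species[missing],
                        want$landmark[missing]), collapse = ", "))
  }
  subset_otus(m, m$landmark %in% lms)
}

#' The synchronic expectation tree
#'
#' The hierarchy expected when every species shares the same relative
#' timing of character onsets: a pectinate backbone ordered by landmark,
#' where the node for each landmark carries the OTUs of all species at
#' that landmark (a polytomy when there are more than two species) plus
#' the node of the next landmark.  The deepest node holds the 100% OTUs
#' and the root holds the 0% OTUs.  Observed topologies are compared
#' against this expectation to read off heterochronies.
#'
#' @param species character vector of species names.
#' @param frame a `time_frame`.
#' @return an `ape::phylo` tree with OTU-labelled tips.
#' @export
synchronic_tree <- function(species, frame) {
  if (!length(species)) .stop("ontochron_frame_error", "empty species list")
  lms <- frame_landmarks(frame)
  if (!length(lms)) .stop("ontochron_frame_error", "empty frame")
  tips <- function(lm) paste0(species, "_", lm, "%")
  wrap <- function(x) if (grepl(",", x, fixed = TRUE)) paste0("(", x, ")") else x
  # innermost clade first; singleton clades collapse into their parent
  nwk <- paste(tips(lms[length(lms)]), collapse = ",")
  if (length(lms) > 1) {
    for (lm in rev(lms[-length(lms)])) {
      nwk <- paste(c(tips(lm), wrap(nwk)), collapse = ",")
    }
  }
  tr <- ape::read.tree(text = paste0("(", nwk, ");"))
  tr
}
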