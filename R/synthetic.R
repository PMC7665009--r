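# Synthetic developmental schedules --------------------------------------------
#
# Generates multi-species staging schedules with known structure: in
# synchronic mode every species shares one set of normalized onset
# percentages (the null the detector must stay silent on), and named
# heterochronic shifts move chosen onsets of chosen species by a known
# number of percent points (the signal it must recover).  Absolute
# thermal spans differ between species so the degree-day normalization
# is exercised, but relative timing is what matters.

#' Configuration for schedule simulation
#'
#' @param n_species number of species (default 4, the study design the
#'   bundled data follow).
#' @param n_characters number of characters (default 53).
#' @param onsets `"uniform"` (onset percentages drawn uniformly on
#'   (0, 100) and shared across species) or a numeric vector of onset
#'   percentages supplied directly.
#' @param heterochronies list of shift specifications, each a list with
#'   `species` (index or name), `characters` (indices) and `shift`
#'   (percent points; positive = delayed = late, negative = advanced).
#' @param missing_rate probability in `[0, 1)` that a species/character
#'   onset is masked as unknown.
#' @param seed integer seed.
#' @return a list of class `sim_config`.
#' @export
simulation_config <- function(n_species = 4, n_characters = 53,
                              onsets = "uniform", heterochronies = list(),
                              missing_rate = 0, seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1) {
    .stop("ontochron_config_error", "missing_rate must be in [0, 1)")
  }
  if (is.numeric(onsets) && length(onsets) != n_characters) {
    .stop("ontochron_config_error", "supplied onsets must have length n_characters")
  }
  for (h in heterochronies) {
    if (!all(c("species", "characters", "shift") %in% names(h))) {
      .stop("ontochron_config_error",
            "each heterochrony needs species, characters, shift")
    }
  }
  structure(list(n_species = n_species, n_characters = n_characters,
                 onsets = onsets, heterochronies = heterochronies,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate staging schedules with known heterochronies
#'
#' In synchronic mode all species carry identical normalized onsets;
#' configured heterochronies are then applied as additive shifts in
#' percent points to the named species and characters.  Shifted onsets
#' must stay within (0, 200); events pushed past 100% remain absent at
#' every interior landmark but present at the 100% bound row (see
#' [build_matrix_from_schedules()]).  Output is reproducible for a fixed
#' seed.
#'
#' @param cfg a [simulation_config()].
#' @return list of `staging_schedule`, one per species (`Sim_sp1`, ...).
#' @export
simulate_schedules <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    base <- if (is.numeric(cfg$onsets)) cfg$onsets else
      sort(runif(cfg$n_characters, 0.5, 99.5))
    species <- paste0("Sim_sp", seq_len(cfg$n_species))
    pct <- matrix(rep(base, cfg$n_species), nrow = cfg$n_species, byrow = TRUE)
    for (h in cfg$heterochronies) {
      si <- if (is.character(h$species)) match(h$species, species) else h$species
      if (is.na(si) || si < 1 || si > cfg$n_species) {
        .stop("ontochron_config_error", "unknown species in heterochrony")
      }
      shifted <- pct[si, h$characters] + h$shift
      if (any(shifted <= 0 | shifted >= 200)) {
        .stop("ontochron_config_error",
              "shift pushes onset outside (0, 200)")
      }
      pct[si, h$characters] <- shifted
    }
    spans <- runif(cfg$n_species, 300, 600)   # degree-day span to the 100% event
    lapply(seq_len(cfg$n_species), function(i) {
      on <- pct[i, ] / 100 * spans[i]
      if (cfg$missing_rate > 0) {
        on[runif(cfg$n_characters) < cfg$missing_rate] <- NA
      }
      staging_schedule(species[i], on, t0 = 0, t100 = spans[i])
    })
  })
}

#' Precision and recall of heterochrony recovery
#'
#' Simulates schedules from `cfg`, builds the frame matrix, runs the full
#' detection pipeline and scores the reported events against the injected
#' shifts.  An injected shift counts as recovered when some reported
#' event matches its species and direction, shares at least one shifted
#' character, and sits at a landmark straddled by the shift (original
#' onset on one side, shifted onset on the other).  A reported event is a
#' true positive under the same matching.  With nothing injected and
#' nothing reported both rates are 1 by convention.
#'
#' @param cfg a [simulation_config()].
#' @param frame a `time_frame`.
#' @param options [search_options()] passed to the pipeline.
#' @return list with `precision`, `recall`, `n_injected`, `n_reported`,
#'   and the `events` table.
#' @export
recovery_experiment <- function(cfg, frame, options = search_options(seed = cfg$seed)) {
  schedules <- simulate_schedules(cfg)
  m <- build_matrix_from_schedules(schedules, frame)
  rep1 <- run_pipeline(m, frame, options)$reports[[1]]
  ev <- rep1$events
  species <- paste0("Sim_sp", seq_len(cfg$n_species))
  base <- if (is.numeric(cfg$onsets)) cfg$onsets else {
    # re-derive the base draw deterministically
    .with_seed(cfg$seed, sort(runif(cfg$n_characters, 0.5, 99.5)))
  }
  matches_injection <- function(h, e) {
    sp <- if (is.character(h$species)) h$species else species[h$species]
    dir <- if (h$shift > 0) "late" else "advanced"
    if (e$species != sp || e$direction != dir) return(FALSE)
    p0 <- base[h$characters]; p1 <- p0 + h$shift
    lo <- pmin(p0, p1); hi <- pmax(p0, p1)
    straddled <- h$characters[lo <= e$landmark & e$landmark < hi]
    length(intersect(e$characters[[1]], straddled)) > 0
  }
  n_inj <- length(cfg$heterochronies)
  n_rep <- nrow(ev)
  if (n_inj == 0 && n_rep == 0) {
    return(list(precision = 1, recall = 1, n_injected = 0, n_reported = 0,
                events = ev))
  }
  ev_rows <- lapply(seq_len(n_rep), function(i)
    list(species = ev$species[i], direction = ev$direction[i],
         landmark = ev$landmark[i], characters = ev$characters[i]))
  recovered <- vapply(cfg$heterochronies, function(h) {
    any(vapply(ev_rows, function(e) matches_injection(h, e), TRUE))
  }, TRUE)
  true_pos <- vapply(ev_rows, function(e) {
    any(vapply(cfg$heterochronies, function(h) matches_injection(h, e), TRUE))
  }, TRUE)
  list(precision = if (n_rep) mean(true_pos) else 1,
       recall = if (n_inj) mean(recovered) else 1,
       n_injected = n_inj, n_reported = n_rep, events = ev)
}
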