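# Heterochrony detection -------------------------------------------------------
#
# Two detection tiers.  Set-based screens read the matrix directly: a
# species is late at a landmark when it still lacks characters every (or
# most) other species already shows there, advanced when it alone already
# has them.  Tree-based diagnostics read the same signal off the
# parsimony result: the ACCTRAN placement of a character gain on a node
# whose descendants include every other species' landmark OTU but not the
# focal one.

.focal_row <- function(m, species, landmark) {
  i <- which(m$species == species & m$landmark == landmark)
  if (!length(i)) {
    .stop("ontochron_lookup_error", "no OTU for %s at %g%%", species, landmark)
  }
  i
}

.peer_rows <- function(m, species, landmark) {
  j <- which(m$species != species & m$landmark == landmark)
  if (!length(j)) {
    .stop("ontochron_input_error",
          "%s is the only species at %g%%; heterochrony is relative", species, landmark)
  }
  j
}

#' Characters a species is late in gaining at a landmark
#'
#' Strict mode: characters definitely absent in the focal OTU and
#' definitely present in every other species at that landmark.  Majority
#' mode: present in more than half of the other species with definite
#' states.  Unknown states never count for either side; a species with an
#' unknown state abstains.
#'
#' @param m an `onto_matrix`.
#' @param species focal species.
#' @param landmark landmark percentage present in `m`.
#' @param mode `"strict"` (default) or `"majority"`.
#' @return sorted integer vector of character indices (possibly empty).
#' @export
late_set <- function(m, species, landmark, mode = c("strict", "majority")) {
  mode <- match.arg(mode)
  i <- .focal_row(m, species, landmark)
  j <- .peer_rows(m, species, landmark)
  focal <- m$states[i, ]
  peers <- m$states[j, , drop = FALSE]
  absent_focal <- !is.na(focal) & focal == 0L
  hit <- if (mode == "strict") {
    apply(peers, 2, function(col) all(!is.na(col)) && all(col == 1L))
  } else {
    apply(peers, 2, function(col) {
      d <- col[!is.na(col)]
      length(d) > 0 && sum(d == 1L) > length(d) / 2
    })
  }
  sort(which(absent_focal & hit))
}

#' Characters a species has gained in advance at a landmark
#'
#' Mirror image of [late_set()]: characters definitely present in the
#' focal OTU and definitely absent in every other species (strict), or in
#' more than half of the other species with definite states (majority).
#'
#' @inheritParams late_set
#' @return sorted integer vector of character indices.
#' @export
advanced_set <- function(m, species, landmark, mode = c("strict", "majority")) {
  mode <- match.arg(mode)
  i <- .focal_row(m, species, landmark)
  j <- .peer_rows(m, species, landmark)
  focal <- m$states[i, ]
  peers <- m$states[j, , drop = FALSE]
  present_focal <- !is.na(focal) & focal == 1L
  hit <- if (mode == "strict") {
    apply(peers, 2, function(col) all(!is.na(col)) && all(col == 0L))
  } else {
    apply(peers, 2, function(col) {
      d <- col[!is.na(col)]
      length(d) > 0 && sum(d == 0L) > length(d) / 2
    })
  }
  sort(which(present_focal & hit))
}

# assemble an event data frame (characters as a list column)
.events_df <- function(rows) {
  if (!length(rows)) {
    return(data.frame(species = character(), landmark = numeric(),
                      direction = character(), mode = character(),
                      characters = I(list())))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$landmark, df$species, df$direction, df$mode), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.event_row <- function(species, landmark, direction, mode, characters) {
  data.frame(species = species, landmark = landmark, direction = direction,
             mode = mode, characters = I(list(sort(unname(characters)))))
}

# set-based events over all (species, interior landmark) pairs
.set_events <- function(m, frame) {
  lms <- frame$interior
  rows <- list()
  for (mode in c("strict", "majority")) {
    for (lm in lms) {
      for (sp in unique(m$species)) {
        if (!any(m$species == sp & m$landmark == lm)) next
        ls <- late_set(m, sp, lm, mode)
        if (length(ls)) rows[[length(rows) + 1L]] <- .event_row(sp, lm, "late", mode, ls)
        as_ <- advanced_set(m, sp, lm, mode)
        if (length(as_)) rows[[length(rows) + 1L]] <- .event_row(sp, lm, "advanced", mode, as_)
      }
    }
  }
  rows
}

#' Tree-based heterochrony diagnostics
#'
#' Reads heterochronies off the ACCTRAN character placements of a most
#' parsimonious tree.  For a focal OTU `(s, l)` a character `c` is
#' diagnostic of lateness when its gain maps to a node whose descendants
#' include every other species' `l`-OTU but not `(s, l)`; it is
#' diagnostic of advance when the gain node contains `(s, l)` but no
#' other species' OTU at a landmark at or before `l`.
#'
#' @param consensus rooted tree over the frame's OTUs (typically the
#'   strict consensus; used to check the leaf set).
#' @param changes an `onto_changes` map from [acctran_changes()] computed
#'   on a most parsimonious tree over the same leaves.
#' @param frame the `time_frame` analyzed.
#' @return data frame of events (`species`, `landmark`, `direction`,
#'   `mode = "tree"`, `characters` list column).
#' @export
tree_diagnostics <- function(consensus, changes, frame) {
  stopifnot(inherits(changes, "onto_changes"))
  tree <- changes$tree
  if (!setequal(consensus$tip.label, tree$tip.label)) {
    .stop("ontochron_label_error",
          "change map tree and consensus differ in leaf set")
  }
  parsed <- parse_otu_labels(tree$tip.label)
  species <- unique(parsed$species)
  clades <- .node_clades(tree)
  gains <- changes$changes[changes$changes$direction == "gain", , drop = FALSE]
  lms <- frame$interior
  acc <- list()  # key: species|landmark|direction -> character indices
  push <- function(sp, lm, dir, ch) {
    key <- paste(sp, lm, dir, sep = "|")
    acc[[key]] <<- c(acc[[key]], ch)
  }
  for (g in seq_len(nrow(gains))) {
    clade <- clades[[gains$child[g]]]
    cl <- parse_otu_labels(clade)
    for (lm in lms) {
      at_lm <- unique(cl$species[cl$landmark == lm])
      for (sp in species) {
        others <- setdiff(species, sp)
        if (!length(others)) next
        if (!(sp %in% at_lm) && all(others %in% at_lm)) {
          push(sp, lm, "late", gains$character[g])
        }
        early_others <- unique(cl$species[cl$landmark <= lm & cl$species != sp])
        if ((sp %in% at_lm) && !length(early_others)) {
          push(sp, lm, "advanced", gains$character[g])
        }
      }
    }
  }
  rows <- lapply(names(acc), function(key) {
    p <- strsplit(key, "|", fixed = TRUE)[[1]]
    .event_row(p[1], as.numeric(p[2]), p[3], "tree", unique(acc[[key]]))
  })
  .events_df(rows)
}

#' Run the full heterochrony pipeline over one or more time frames
#'
#' For each frame: restrict the matrix, search for all most parsimonious
#' trees (exact branch-and-bound up to `exact_max_taxa` distinct rows,
#' parsimony ratchet beyond), compute ensemble indices, take the strict
#' consensus, map changes under ACCTRAN, and collect set-based and
#' tree-based heterochrony events.  Tree-based events are kept when they
#' are supported by every most parsimonious tree of the result.
#'
#' @param m an `onto_matrix` containing all frames' OTUs.
#' @param frames a `time_frame` or list of them.
#' @param options a [search_options()] list.
#' @return an object of class `onto_report_set`: list of per-frame
#'   reports, each with `frame`, `search`, `consensus`, `changes`, and
#'   `events`.
#' @export
run_pipeline <- function(m, frames, options = search_options()) {
  if (inherits(frames, "time_frame")) frames <- list(frames)
  reports <- lapply(frames, function(frame) {
    tryCatch(.run_one_frame(m, frame, options),
             error = function(e) {
               .stop("ontochron_pipeline_error", "frame %s: %s",
                     format(frame), conditionMessage(e))
             })
  })
  structure(list(reports = reports), class = "onto_report_set")
}

.run_one_frame <- function(m, frame, options) {
  mf <- select_frame(m, frame)
  dp_n <- nrow(.distinct_patterns(mf)$patterns)
  use_exact <- switch(options$mode,
                      exact = TRUE, heuristic = FALSE,
                      auto = dp_n <= options$exact_max_taxa)
  res <- if (use_exact) branch_and_bound_search(mf, options)
         else heuristic_search(mf, options)
  cons <- strict_consensus(res$trees)
  ch_list <- lapply(res$trees, acctran_changes, m = mf)
  # events supported on every MP tree
  per_tree <- lapply(ch_list, function(ch) tree_diagnostics(cons, ch, frame))
  tree_events <- .intersect_events(per_tree)
  events <- .events_df(c(.set_events(mf, frame),
                         .df_to_rows(tree_events)))
  structure(list(frame = frame, matrix = mf, search = res,
                 consensus = cons, changes = ch_list[[1]],
                 events = events),
            class = "onto_report")
}

.df_to_rows <- function(df) {
  lapply(seq_len(nrow(df)), function(i) df[i, , drop = FALSE])
}

# intersect event tables: keep (species, landmark, direction) present in
# every table, with the intersection of diagnostic characters
.intersect_events <- function(tables) {
  if (!length(tables)) return(.events_df(list()))
  keyed <- lapply(tables, function(df) {
    setNames(df$characters, paste(df$species, df$landmark, df$direction, sep = "|"))
  })
  keys <- Reduce(intersect, lapply(keyed, names))
  rows <- lapply(keys, function(k) {
    chars <- Reduce(intersect, lapply(keyed, `[[`, k))
    if (!length(chars)) return(NULL)
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    .event_row(p[1], as.numeric(p[2]), p[3], "tree", chars)
  })
  .events_df(Filter(Negate(is.null), rows))
}

#' @export
print.onto_report <- function(x, ...) {
  cat(sprintf("frame %s: length %d, %d MP tree(s), CI %.2f, RI %.2f\n",
              format(x$frame), x$search$best_length, length(x$search$trees),
              x$search$fit$reported_ci, x$search$fit$reported_ri))
  ev <- x$events
  if (!nrow(ev)) {
    cat("  no heterochrony events\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(ev))) {
    cat(sprintf("  %s %s at %g%% [%s]: characters %s\n",
                ev$species[i], ev$direction[i], ev$landmark[i], ev$mode[i],
                paste(ev$characters[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.onto_report_set <- function(x, ...) {
  for (r in x$reports) print(r)
  invisible(x)
}

#' Serialize a report set to JSON
#'
#' @param reports an `onto_report_set` from [run_pipeline()].
#' @param file optional output path.
#' @return JSON string (invisibly when `file` is given).
#' @export
report_json <- function(reports, file = NULL) {
  payload <- lapply(reports$reports, function(r) {
    list(frame = r$frame$interior,
         best_length = r$search$best_length,
         n_trees = length(r$search$trees),
         ci = r$search$fit$reported_ci,
         ri = r$search$fit$reported_ri,
         ci_full = r$search$fit$ci,
         ri_full = r$search$fit$ri,
         consensus = to_newick(r$consensus),
         events = lapply(seq_len(nrow(r$events)), function(i) {
           list(species = r$events$species[i],
                landmark = r$events$landmark[i],
                direction = r$events$direction[i],
                mode = r$events$mode[i],
                characters = r$events$characters[[i]])
         }))
  })
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
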