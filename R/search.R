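# Maximum-parsimony tree search ------------------------------------------------
#
# Searches run over the distinct row patterns of the matrix plus a
# hypothetical all-absent ancestor; identical rows (notably the all-zero
# 0% outgroup rows) are merged for the search and re-expanded afterwards.
# Every returned tree is rooted at the ancestor: the root node stands for
# the all-absent state and the 0% OTUs hang from it.

#' Search options
#'
#' @param mode `"auto"` picks exact search up to `exact_max_taxa` distinct
#'   row patterns and the heuristic beyond; `"exact"` and `"heuristic"`
#'   force one.
#' @param collapse zero-length-branch collapse rule applied to the
#'   returned trees: `"max-zero"` (default; collapse branches whose
#'   maximum length over all optimal reconstructions is zero),
#'   `"min-zero"` (minimum length zero), or `"none"`.
#' @param max_trees cap on the number of retained condensed trees; when
#'   exceeded the result carries `capped = TRUE`.
#' @param seed integer seed driving the heuristic's random cycles.
#' @param exact_max_taxa largest number of distinct patterns handled by
#'   branch-and-bound under `mode = "auto"`.
#' @param ratchet_iter minimum number of ratchet iterations (and a fifth
#'   of the maximum) for the heuristic.
#' @param ratchet_k stop the ratchet after this many rounds without
#'   improvement.
#' @return a list of class `search_options`.
#' @export
search_options <- function(mode = c("auto", "exact", "heuristic"),
                           collapse = c("max-zero", "min-zero", "none"),
                           max_trees = 1000L, seed = 1L,
                           exact_max_taxa = 20L,
                           ratchet_iter = 50L, ratchet_k = 20L) {
  mode <- match.arg(mode)
  collapse <- match.arg(collapse)
  if (max_trees < 1) .stop("ontochron_option_error", "max_trees must be >= 1")
  structure(list(mode = mode, collapse = collapse,
                 max_trees = as.integer(max_trees), seed = as.integer(seed),
                 exact_max_taxa = as.integer(exact_max_taxa),
                 ratchet_iter = as.integer(ratchet_iter),
                 ratchet_k = as.integer(ratchet_k)),
            class = "search_options")
}

# group identical rows; the all-absent ancestor joins (or founds) the
# all-zero group
.distinct_patterns <- function(m) {
  s <- m$states
  if (.anc_label %in% rownames(s)) {
    .stop("ontochron_label_error", "label %s is reserved", .anc_label)
  }
  key <- apply(s, 1, function(r) paste(ifelse(is.na(r), "?", r), collapse = ""))
  anc_key <- paste(rep("0", ncol(s)), collapse = "")
  groups <- split(rownames(s), key)
  if (is.null(groups[[anc_key]])) groups[[anc_key]] <- character()
  groups[[anc_key]] <- c(.anc_label, groups[[anc_key]])
  pat <- do.call(rbind, lapply(names(groups), function(k) {
    z <- strsplit(k, "")[[1]]
    suppressWarnings(as.integer(ifelse(z == "?", NA, z)))
  }))
  rownames(pat) <- vapply(groups, `[`, "", 1)
  list(patterns = pat, groups = groups, anc_key = anc_key,
       anc_rep = groups[[anc_key]][1])
}

.as_phyDat <- function(pat) {
  ch <- matrix(ifelse(is.na(pat), "?", as.character(pat)),
               nrow = nrow(pat), dimnames = dimnames(pat))
  phangorn::phyDat(ch, type = "USER", levels = c("0", "1"), ambiguity = "?")
}

# --- small phylo surgery (edge-matrix level) ---------------------------------

# drop a tip that is a direct child of the root, keeping the root node
# even if it becomes a singleton (the root stands for the ancestor)
.remove_root_tip <- function(tree, tip) {
  nt <- length(tree$tip.label)
  ti <- match(tip, tree$tip.label)
  e <- tree$edge
  if (!any(e[, 1] == nt + 1L & e[, 2] == ti)) {
    .stop("ontochron_tree_error", "%s is not a child of the root", tip)
  }
  e <- e[e[, 2] != ti, , drop = FALSE]
  adj <- function(x) ifelse(x <= nt, x - (x > ti), x - 1L)
  structure(list(edge = cbind(adj(e[, 1]), adj(e[, 2])),
                 tip.label = tree$tip.label[-ti], Nnode = tree$Nnode),
            class = "phylo")
}

# attach extra tips as children of the root
.add_root_children <- function(tree, tips) {
  for (tp in tips) {
    nt <- length(tree$tip.label)
    e <- tree$edge
    e[e > nt] <- e[e > nt] + 1L      # renumber internals for the new tip
    e <- rbind(e, c(nt + 2L, nt + 1L))
    tree <- structure(list(edge = e, tip.label = c(tree$tip.label, tp),
                           Nnode = tree$Nnode),
                      class = "phylo")
  }
  tree
}

# replace tip `rep` by an internal node carrying the whole identical-row group
.expand_group <- function(tree, rep, members) {
  extra <- setdiff(members, rep)
  if (!length(extra)) return(tree)
  nt <- length(tree$tip.label)
  ti <- match(rep, tree$tip.label)
  k <- length(extra)
  e <- tree$edge
  e[e > nt] <- e[e > nt] + k
  newnode <- nt + k + tree$Nnode + 1L
  e[e[, 2] == ti, 2] <- newnode
  e <- rbind(e, c(newnode, ti), cbind(newnode, nt + seq_len(k)))
  structure(list(edge = e, tip.label = c(tree$tip.label, extra),
                 Nnode = tree$Nnode + 1L),
            class = "phylo")
}

# canonical string of a rooted tree (children sorted recursively)
.canonical_key <- function(tree) {
  nt <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(v) {
    if (v <= nt) return(tree$tip.label[v])
    sub <- sort(vapply(kids[[as.character(v)]], rec, ""))
    paste0("(", paste(sub, collapse = ","), ")")
  }
  rec(nt + 1L)
}

# collapse the given edges (each child node merges into its parent)
.collapse_edges <- function(tree, idx) {
  if (!length(idx)) return(tree)
  e <- tree$edge
  nt <- length(tree$tip.label)
  tot <- nt + tree$Nnode
  parent <- rep(NA_integer_, tot)
  parent[e[, 2]] <- e[, 1]
  gone <- e[idx, 2]
  target <- seq_len(tot)
  resolve <- function(x) { while (x %in% gone) x <- parent[x]; x }
  keep <- setdiff(seq_len(nrow(e)), idx)
  e2 <- cbind(vapply(e[keep, 1], resolve, 1L), e[keep, 2])
  nodes <- sort(unique(e2[, 1]))
  newnum <- integer(tot)
  newnum[seq_len(nt)] <- seq_len(nt)
  newnum[nodes] <- nt + seq_along(nodes)
  e3 <- cbind(newnum[e2[, 1]],
              ifelse(e2[, 2] <= nt, e2[, 2], newnum[e2[, 2]]))
  structure(list(edge = e3, tip.label = tree$tip.label,
                 Nnode = length(nodes)),
            class = "phylo")
}

# all rooted binary bracketings of a list of newick fragments
.bracketings <- function(xs) {
  k <- length(xs)
  if (k == 1) return(xs)
  if (k == 2) return(paste0("(", xs[1], ",", xs[2], ")"))
  out <- character()
  # partition into {first + subset, rest}; fixing the first element in the
  # left block enumerates each unordered bipartition once
  rest <- xs[-1]
  for (pick in 0:(2^(k - 1) - 1)) {
    sel <- as.logical(intToBits(pick))[seq_len(k - 1)]
    left <- c(xs[1], rest[sel])
    right <- rest[!sel]
    if (!length(right)) next
    out <- c(out, as.vector(outer(.bracketings(left), .bracketings(right),
                                  function(a, b) paste0("(", a, ",", b, ")"))))
  }
  out
}

# every binary resolution of a rooted, possibly multifurcating tree; the
# root keeps its two children (ancestor + rest) untouched when binary
.all_binary_resolutions <- function(tree, cap = 100000L) {
  nt <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  quote_lab <- function(x) {
    ifelse(grepl("[ %(),:;']", x), paste0("'", gsub("'", "''", x), "'"), x)
  }
  capped <- FALSE
  rec <- function(v) {
    if (v <= nt) return(quote_lab(tree$tip.label[v]))
    parts <- lapply(kids[[as.character(v)]], rec)
    combos <- Reduce(function(a, b) {
      as.vector(outer(a, b, paste, sep = "\r"))
    }, parts)
    out <- unlist(lapply(combos, function(cmb) {
      .bracketings(strsplit(cmb, "\r", fixed = TRUE)[[1]])
    }))
    if (length(out) > cap) {
      capped <<- TRUE
      out <- out[seq_len(cap)]
    }
    out
  }
  nwk <- rec(nt + 1L)
  trees <- lapply(paste0(nwk, ";"), function(t) ape::read.tree(text = t))
  for (i in seq_along(trees)) {
    trees[[i]]$tip.label <- sub("^'(.*)'$", "\\1",
                                gsub("''", "'", trees[[i]]$tip.label))
  }
  attr(trees, "capped") <- capped
  trees
}

# unrooted parsimony length of a pattern tree (root state free)
.pattern_score <- function(tree, pat) {
  idx <- match(tree$tip.label, rownames(pat))
  lay <- .tree_layout(tree)
  dp <- .down_pass(lay, pat[idx, , drop = FALSE])
  sum(pmin(dp$D0[lay$root, ], dp$D1[lay$root, ]))
}

# search engines may return partially collapsed trees in which several
# equally parsimonious binary resolutions are folded together; expand
# them back so condensation under any rule sees the full optimal set
.binary_mp_trees <- function(trees, pat) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  rooted <- lapply(trees, function(t) {
    ape::root.phylo(t, .anc_label, resolve.root = TRUE)
  })
  res <- unlist(lapply(rooted, .all_binary_resolutions), recursive = FALSE)
  sc <- vapply(res, .pattern_score, 0, pat = pat)
  res[sc == min(sc)]
}

# Close an optimal tree set under equal-score nearest-neighbor
# interchanges.  Branch-and-bound engines can return an incomplete set of
# tied trees when missing data makes placements ambiguous; walking the
# optimum's rearrangement island recovers the rest (validated against
# exhaustive enumeration in the test suite).
.mp_closure <- function(trees, pat) {
  if (!length(trees) || length(trees[[1]]$tip.label) < 4) return(trees)
  L <- min(vapply(trees, .pattern_score, 0, pat = pat))
  seen <- new.env(parent = emptyenv())
  queue <- list()
  keep <- list()
  push <- function(t) {
    key <- .canonical_key(ape::root.phylo(t, .anc_label, resolve.root = TRUE))
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      queue[[length(queue) + 1L]] <<- t
      keep[[length(keep) + 1L]] <<- t
    }
  }
  for (t in trees) push(ape::unroot(t))
  while (length(queue)) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    nbs <- phangorn::nni(t)
    if (inherits(nbs, "phylo")) nbs <- list(nbs)
    for (j in seq_along(nbs)) {
      if (.pattern_score(nbs[[j]], pat) == L) push(nbs[[j]])
    }
  }
  keep
}

# unrooted search tree over patterns -> rooted OTU tree (root = ancestor)
.expand_to_otus <- function(tree, dp) {
  tree <- ape::root.phylo(tree, .anc_label, resolve.root = TRUE)
  tree <- .remove_root_tip(tree, .anc_label)
  for (k in names(dp$groups)) {
    if (k == dp$anc_key) next
    mem <- dp$groups[[k]]
    if (length(mem) > 1) tree <- .expand_group(tree, mem[1], mem)
  }
  # real all-zero rows (the 0% outgroup OTUs) hang from the ancestor root
  .add_root_children(tree, setdiff(dp$groups[[dp$anc_key]], .anc_label))
}

#' Condense and deduplicate equally parsimonious trees
#'
#' Collapses internal branches with zero optimized length into polytomies
#' and removes duplicate topologies.  Under `"min-zero"` a branch is
#' collapsed when some optimal reconstruction assigns it zero changes;
#' under `"max-zero"` (the default elsewhere in the package) only when
#' every optimal reconstruction does.  Trees are scored rooted at the
#' all-absent ancestor.
#'
#' @param trees list (or `multiPhylo`) of rooted trees over the OTUs of `m`,
#'   all of equal length.
#' @param m an `onto_matrix`.
#' @param rule `"max-zero"`, `"min-zero"` or `"none"`.
#' @return a `multiPhylo` of condensed, duplicate-free trees, sorted by
#'   canonical form.
#' @export
condense_and_dedupe <- function(trees, m, rule = c("max-zero", "min-zero", "none")) {
  rule <- match.arg(rule)
  if (inherits(trees, "phylo")) trees <- list(trees)
  out <- list(); keys <- character()
  for (tr in trees) {
    ct <- tr
    if (rule != "none") {
      X <- .tip_states(tr, m)
      info <- .edge_zero_info(tr, X)
      collapsible <- if (rule == "min-zero") info$can_zero else info$must_zero
      internal <- tr$edge[, 2] > length(tr$tip.label)
      ct <- .collapse_edges(tr, which(collapsible & internal))
    }
    key <- .canonical_key(ct)
    if (!(key %in% keys)) {
      keys <- c(keys, key)
      out[[length(out) + 1L]] <- ct
    }
  }
  out <- out[order(keys)]
  class(out) <- "multiPhylo"
  out
}

# shared tail of both searches
.finalize_search <- function(binary, dp, m, opts, mode) {
  binary <- .binary_mp_trees(binary, dp$patterns)
  if (mode == "exact") binary <- .mp_closure(binary, dp$patterns)
  trees <- lapply(binary, .expand_to_otus, dp = dp)
  cond <- condense_and_dedupe(trees, m, opts$collapse)
  capped <- length(cond) > opts$max_trees
  if (capped) cond <- cond[seq_len(opts$max_trees)]
  class(cond) <- "multiPhylo"
  best <- fitch_length(cond[[1]], m, root_state = 0)
  fit <- ensemble_indices_matrix(m, best)
  structure(list(best_length = best, trees = cond, fit = fit,
                 n_binary = length(binary), n_distinct = nrow(dp$patterns),
                 capped = capped, mode = mode, collapse = opts$collapse),
            class = "onto_search")
}

#' @export
print.onto_search <- function(x, ...) {
  cat(sprintf("%s parsimony search: best length %d steps, %d condensed tree(s) [%s]\n",
              x$mode, x$best_length, length(x$trees), x$collapse))
  cat(sprintf("  %d distinct row patterns (ancestor included); CI %.2f RI %.2f (truncated)\n",
              x$n_distinct, x$fit$reported_ci, x$fit$reported_ri))
  if (x$capped) cat("  NOTE: tree list capped at max_trees\n")
  invisible(x)
}

#' Exact branch-and-bound search for all most parsimonious trees
#'
#' Finds every most parsimonious tree for the matrix by branch-and-bound
#' (an exact search), with characters unweighted and unordered.  Rooting
#' is fixed by a hypothetical all-absent ancestor, so the all-zero 0%
#' OTUs sit at the root.  Identical rows are merged during the search and
#' re-expanded before condensation; the returned trees are condensed
#' under the collapse rule and deduplicated.
#'
#' @param m an `onto_matrix` with at least 3 OTUs.
#' @param options a [search_options()] list.
#' @return an object of class `onto_search`: `best_length` (steps),
#'   `trees` (condensed `multiPhylo`), `fit` (ensemble indices), counts
#'   and flags.
#' @export
branch_and_bound_search <- function(m, options = search_options()) {
  if (nrow(m$states) < 3) .stop("ontochron_input_error", "need >= 3 OTUs")
  dp <- .distinct_patterns(m)
  n <- nrow(dp$patterns)
  binary <- if (n <= 3) {
    list(.star_tree(rownames(dp$patterns)))
  } else {
    pd <- .as_phyDat(dp$patterns)
    phangorn::bab(pd, trace = 0)
  }
  .finalize_search(binary, dp, m, options, "exact")
}

.star_tree <- function(labels) {
  ape::read.tree(text = paste0("(", paste(labels, collapse = ","), ");"))
}

#' Heuristic parsimony search
#'
#' Parsimony-ratchet search (random-addition starting trees plus
#' rearrangement cycles on reweighted data) over the distinct row
#' patterns; a scaling fallback for matrices too large for exact
#' enumeration.  The returned length is an upper bound on the optimum,
#' and the run is fully reproducible for a fixed seed.
#'
#' @inheritParams branch_and_bound_search
#' @return an `onto_search`; `trees` holds the distinct condensed best
#'   trees found (not guaranteed exhaustive).
#' @export
heuristic_search <- function(m, options = search_options()) {
  if (nrow(m$states) < 3) .stop("ontochron_input_error", "need >= 3 OTUs")
  dp <- .distinct_patterns(m)
  n <- nrow(dp$patterns)
  if (n <= 3) {
    return(.finalize_search(list(.star_tree(rownames(dp$patterns))),
                            dp, m, options, "heuristic"))
  }
  pd <- .as_phyDat(dp$patterns)
  binary <- .with_seed(options$seed, {
    tr <- phangorn::pratchet(pd, method = "fitch", trace = 0, all = TRUE,
                             minit = options$ratchet_iter,
                             maxit = 10L * options$ratchet_iter,
                             k = options$ratchet_k)
    if (inherits(tr, "phylo")) list(tr) else tr
  })
  .finalize_search(binary, dp, m, options, "heuristic")
}

# evaluate with a local RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Ensemble fit indices ---------------------------------------------------------

# internal: indices from a matrix and a tree length; the all-absent
# ancestor row enters the per-character step bounds, matching the rooted
# analyses the indices summarize
ensemble_indices_matrix <- function(m, S) {
  s <- rbind(m$states, 0L)
  mins <- apply(s, 2, char_min_steps)
  maxs <- apply(s, 2, char_max_steps)
  M <- sum(mins); G <- sum(maxs)
  if (M == 0) {
    .stop("ontochron_index_error",
          "indices undefined: no character varies (all-constant matrix)")
  }
  informative <- maxs >= 2
  Mi <- sum(mins[informative]); Gi <- sum(maxs[informative])
  Si <- S - sum(mins[!informative])   # uninformative characters change min times
  structure(list(M = M, G = G, S = as.integer(S),
                 ci = M / S,
                 ri = if (G > M) (G - S) / (G - M) else NA_real_,
                 reported_ci = trunc2(M / S),
                 reported_ri = if (G > M) trunc2((G - S) / (G - M)) else NA_real_,
                 ci_informative = if (Mi > 0) Mi / Si else NA_real_,
                 ri_informative = if (Gi > Mi) (Gi - Si) / (Gi - Mi) else NA_real_),
            class = "onto_fit")
}

#' @export
print.onto_fit <- function(x, ...) {
  cat(sprintf("fit: S=%d M=%d G=%d  CI=%.4f (reported %.2f)  RI=%.4f (reported %.2f)\n",
              x$S, x$M, x$G, x$ci, x$reported_ci, x$ri, x$reported_ri))
  cat(sprintf("  informative characters only: CI=%.4f RI=%.4f\n",
              x$ci_informative, x$ri_informative))
  invisible(x)
}

#' Ensemble consistency and retention indices
#'
#' `CI = M/S` and `RI = (G - S)/(G - M)`, where `S` is the tree length,
#' `M` the sum of per-character minimum steps and `G` the sum of
#' per-character maximum steps; the hypothetical all-absent ancestor row
#' is included in the step bounds, matching the rooted analyses.  A CI of
#' 1 means no homoplasy (fully cumulative organ rise); a high RI means
#' shared onsets are retained as groupings.  Reported values are
#' truncated, not rounded, to two decimals; full precision and
#' informative-characters-only variants are carried alongside.
#'
#' @param result an `onto_search`.
#' @param m the matrix the search was run on.
#' @return an object of class `onto_fit` with elements `M`, `G`, `S`,
#'   `ci`, `ri`, `reported_ci`, `reported_ri`, `ci_informative`,
#'   `ri_informative`.
#' @export
ensemble_indices <- function(result, m) {
  stopifnot(inherits(result, "onto_search"))
  ensemble_indices_matrix(m, result$best_length)
}
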