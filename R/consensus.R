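# Strict consensus and Newick interchange -------------------------------------

# clusters (rooted splits) of a tree as sorted comma-joined label strings;
# trivial clusters (single tips, full leaf set) included
.tree_clusters <- function(tree) {
  clades <- .node_clades(tree)
  unique(vapply(clades, function(x) paste(sort(x), collapse = ","), ""))
}

#' Strict consensus of equally parsimonious trees
#'
#' The rooted tree containing exactly the clusters (rooted clades)
#' present in every input tree; all conflicting or unrepeated groupings
#' collapse into polytomies.  All analyses here are rooted at the
#' all-absent ancestor, so clusters rather than unrooted bipartitions are
#' the unit of agreement.
#'
#' @param trees list or `multiPhylo` of rooted trees on one leaf set.
#' @return an `ape::phylo`, possibly multifurcating.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) .stop("ontochron_input_error", "no trees")
  leafset <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), leafset)) {
      .stop("ontochron_label_error", "trees differ in leaf set")
    }
  }
  shared <- Reduce(intersect, lapply(trees, .tree_clusters))
  .tree_from_clusters(trees[[1]]$tip.label, shared)
}

# build a rooted tree from a nested cluster set (labels comma-joined keys)
.tree_from_clusters <- function(tips, clusters) {
  sets <- strsplit(clusters, ",", fixed = TRUE)
  sets <- sets[order(-lengths(sets))]
  if (!length(sets) || length(sets[[1]]) != length(tips)) {
    sets <- c(list(tips), sets)
  }
  # drop duplicates and singletons; sets nest because they come from trees
  sets <- sets[!duplicated(vapply(sets, function(x) paste(sort(x), collapse = ","), ""))]
  big <- sets[lengths(sets) > 1]
  n_int <- length(big)
  nt <- length(tips)
  parent_of <- function(i) {
    # smallest strictly-containing cluster
    best <- 0L; bestlen <- Inf
    for (j in seq_len(n_int)) {
      if (j == i) next
      if (length(big[[j]]) > length(big[[i]]) && all(big[[i]] %in% big[[j]]) &&
          length(big[[j]]) < bestlen) {
        best <- j; bestlen <- length(big[[j]])
      }
    }
    best
  }
  edges <- matrix(0L, 0, 2)
  for (i in seq_len(n_int)) {
    p <- parent_of(i)
    if (p) edges <- rbind(edges, c(nt + p, nt + i))
  }
  for (t in seq_len(nt)) {
    best <- 0L; bestlen <- Inf
    for (j in seq_len(n_int)) {
      if (tips[t] %in% big[[j]] && length(big[[j]]) < bestlen) {
        best <- j; bestlen <- length(big[[j]])
      }
    }
    edges <- rbind(edges, c(nt + best, t))
  }
  # renumber internal nodes so the root (full set) is nt+1
  ord <- order(-lengths(big))
  newnum <- integer(n_int); newnum[ord] <- seq_len(n_int)
  e <- edges
  e[e > nt] <- nt + newnum[e[e > nt] - nt]
  structure(list(edge = e, tip.label = tips, Nnode = n_int),
            class = "phylo")
}

#' Newick interchange
#'
#' `to_newick` serializes a rooted tree (labels containing spaces or `%`
#' are single-quoted); `from_newick` parses one back.  Round-trips
#' preserve topology and labels.
#'
#' @param tree an `ape::phylo`.
#' @param text a Newick string.
#' @return `to_newick`: a string; `from_newick`: an `ape::phylo`.
#' @export
to_newick <- function(tree) {
  nt <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  quote_lab <- function(x) {
    if (grepl("[ %(),:;']", x)) paste0("'", gsub("'", "''", x), "'") else x
  }
  rec <- function(v) {
    if (v <= nt) return(quote_lab(tree$tip.label[v]))
    paste0("(", paste(vapply(kids[[as.character(v)]], rec, ""), collapse = ","), ")")
  }
  paste0(rec(nt + 1L), ";")
}

#' @rdname to_newick
#' @export
from_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) {
    # locate the first structural problem for the error message
    depth <- 0; pos <- nchar(text)
    for (i in seq_len(nchar(text))) {
      ch <- substr(text, i, i)
      if (ch == "(") depth <- depth + 1
      if (ch == ")") depth <- depth - 1
      if (depth < 0) { pos <- i; break }
    }
    .stop("ontochron_parse_error",
          "malformed Newick (unbalanced or illegal syntax near position %d)", pos)
  }
  unquote <- function(x) {
    q <- startsWith(x, "'") & endsWith(x, "'")
    x[q] <- gsub("''", "'", substr(x[q], 2, nchar(x[q]) - 1), fixed = TRUE)
    x
  }
  tr$tip.label <- unquote(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unquote(tr$node.label)
  tr
}
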