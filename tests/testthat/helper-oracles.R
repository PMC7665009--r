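# Independent oracles and small generators used across the suite.

# random 0/1/? matrix with parseable OTU labels, one row per distinct species
random_matrix <- function(n_otus, n_chars, miss = 0.1, all_zero_row = TRUE) {
  s <- matrix(rbinom(n_otus * n_chars, 1, 0.5), n_otus, n_chars)
  if (miss > 0) s[matrix(runif(n_otus * n_chars) < miss, n_otus, n_chars)] <- NA
  if (all_zero_row) s[1, ] <- 0L
  rownames(s) <- paste0("Sp", seq_len(n_otus), "_x_", seq_len(n_otus), "%")
  character_matrix(s)
}

# Fitch set-operation count on a rooted binary tree, one character at a
# time (independent of the package's vectorized Sankoff pass)
oracle_fitch <- function(tree, m) {
  X <- m$states[match(tree$tip.label, rownames(m$states)), , drop = FALSE]
  nt <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  score_one <- function(col) {
    count <- 0L
    rec <- function(v) {
      if (v <= nt) {
        x <- col[v]
        return(if (is.na(x)) c(TRUE, TRUE) else c(x == 0, x == 1))
      }
      sets <- lapply(kids[[as.character(v)]], rec)
      acc <- sets[[1]]
      for (s in sets[-1]) {
        inter <- acc & s
        if (any(inter)) acc <- inter else {
          acc <- acc | s
          count <<- count + 1L
        }
      }
      acc
    }
    rec(nt + 1L)
    count
  }
  sum(vapply(seq_len(ncol(X)), function(k) score_one(X[, k]), 0L))
}

# rooted clusters of a tree via ape, as sorted label strings (oracle route)
oracle_clusters <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  cl <- vapply(pp, function(i) paste(sort(labs[i]), collapse = ","), "")
  unique(c(cl, tree$tip.label))
}

# exhaustive search over every unrooted topology (ancestor taxon included),
# returning optimal length and the condensed/deduplicated rooted tree set
# through the same finishing steps the package search uses
oracle_exhaustive <- function(m, rule = "max-zero") {
  dp <- ontochron:::.distinct_patterns(m)
  pd <- ontochron:::.as_phyDat(dp$patterns)
  n <- nrow(dp$patterns)
  if (n <= 3) {
    # a single unrooted topology exists
    all_tr <- list(ape::read.tree(text = paste0(
      "(", paste(rownames(dp$patterns), collapse = ","), ");")))
  } else {
    all_tr <- phangorn::allTrees(n, rooted = FALSE, tip.label = rownames(dp$patterns))
  }
  sc <- if (inherits(all_tr, "multiPhylo")) phangorn::parsimony(all_tr, pd)
        else vapply(all_tr, function(t) phangorn::parsimony(t, pd), 0)
  best <- min(sc)
  opt <- all_tr[sc == best]
  expanded <- lapply(opt, ontochron:::.expand_to_otus, dp = dp)
  cond <- condense_and_dedupe(expanded, m, rule)
  list(best_length = best,
       keys = sort(vapply(cond, ontochron:::.canonical_key, "")))
}

fixture_md5 <- "ae44e6cddf8c9fcc88456d6fc5cbd2dd"
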