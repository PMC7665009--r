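# Parsimony scoring and ACCTRAN mapping ---------------------------------------
#
# Characters are binary with missing data; scoring is exact dynamic
# programming (unit-cost Sankoff) over rooted trees, which handles
# polytomies and reduces to Fitch counting on binary trees.  A large
# finite constant stands in for infeasible states so that sums stay
# finite.

.INF <- 1e9

# tip state matrix (0/1/NA) aligned to tree tip order
.tip_states <- function(tree, m) {
  lab <- tree$tip.label
  idx <- match(lab, rownames(m$states))
  if (anyNA(idx)) {
    .stop("ontochron_label_error", "tree tip(s) not in matrix: %s",
          paste(lab[is.na(idx)], collapse = ", "))
  }
  m$states[idx, , drop = FALSE]
}

# postorder child lists, cached layout for the passes
.tree_layout <- function(tree) {
  nt <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  list(ntip = nt, nnode = tree$Nnode, root = nt + 1L, po = po,
       kids = split(po[, 2], po[, 1]))
}

# D[[s+1]][v, k]: minimal changes in the subtree of v given v has state s
.down_pass <- function(lay, X) {
  nt <- lay$ntip; tot <- nt + lay$nnode; K <- ncol(X)
  D0 <- matrix(0, tot, K); D1 <- matrix(0, tot, K)
  tipX <- X[seq_len(nt), , drop = FALSE]
  D0[seq_len(nt), ][!is.na(tipX) & tipX == 1L] <- .INF
  D1[seq_len(nt), ][!is.na(tipX) & tipX == 0L] <- .INF
  po <- lay$po
  parents <- unique(po[, 1])
  for (u in parents) {
    s0 <- numeric(K); s1 <- numeric(K)
    for (v in lay$kids[[as.character(u)]]) {
      s0 <- s0 + pmin(D0[v, ], D1[v, ] + 1)
      s1 <- s1 + pmin(D1[v, ], D0[v, ] + 1)
    }
    D0[u, ] <- pmin(s0, .INF); D1[u, ] <- pmin(s1, .INF)
  }
  list(D0 = D0, D1 = D1)
}

#' Fitch parsimony length of a tree
#'
#' Number of character-state changes needed to explain the matrix on the
#' tree under unweighted, unordered (Fitch) parsimony, summed over
#' characters.  Unknown states are free to take either value; losses count
#' like gains, so organ loss appears as character reversal.  The root
#' state is unconstrained; on trees rooted at the all-absent ancestor the
#' optimum is the all-absent root state, so the value also equals the
#' rooted count.
#'
#' @param tree an `ape::phylo` whose tip labels are OTU labels of `m`
#'   (polytomies allowed).
#' @param m an `onto_matrix` covering exactly the tree's tips.
#' @param root_state `NA` (default) leaves the root state free; `0` fixes
#'   the root to the all-absent ancestor.
#' @return integer number of steps.
#' @export
fitch_length <- function(tree, m, root_state = NA) {
  X <- .tip_states(tree, m)
  if (length(tree$tip.label) != nrow(m$states)) {
    .stop("ontochron_label_error",
          "tree has %d tips but matrix has %d OTUs",
          length(tree$tip.label), nrow(m$states))
  }
  lay <- .tree_layout(tree)
  dp <- .down_pass(lay, X)
  len <- if (is.na(root_state)) {
    pmin(dp$D0[lay$root, ], dp$D1[lay$root, ])
  } else if (root_state == 0) dp$D0[lay$root, ] else dp$D1[lay$root, ]
  as.integer(sum(len))
}

#' Per-character step bounds
#'
#' `char_min_steps` is the minimum number of changes any tree needs for
#' the column (1 when both definite states occur, else 0);
#' `char_max_steps` is the maximum any tree can force (the column's steps
#' on a star tree), `min(#definite 0s, #definite 1s)`.  Unknown cells are
#' excluded from both counts.
#'
#' @param column vector of 0/1/`NA` states.
#' @return integer.
#' @export
char_min_steps <- function(column) {
  d <- column[!is.na(column)]
  as.integer(length(unique(d)) > 1)
}

#' @rdname char_min_steps
#' @export
char_max_steps <- function(column) {
  d <- column[!is.na(column)]
  as.integer(min(sum(d == 0), sum(d == 1)))
}

# Per-edge reconstruction freedom, root fixed to the all-absent state.
# For edge (u, v):
#   can_zero : some MP reconstruction puts 0 changes on the edge (all chars)
#   must_zero: every MP reconstruction puts 0 changes on it (all chars)
.edge_zero_info <- function(tree, X) {
  lay <- .tree_layout(tree)
  nt <- lay$ntip; tot <- nt + lay$nnode; K <- ncol(X)
  dp <- .down_pass(lay, X)
  D0 <- dp$D0; D1 <- dp$D1
  L <- D0[lay$root, ]                      # per-character optimum, root all-absent
  # E[v, s]: minimal changes outside the subtree of v, v in state s,
  # including the edge above v; A/B drop the edge term.
  E0 <- matrix(.INF, tot, K); E1 <- matrix(.INF, tot, K)
  E0[lay$root, ] <- 0
  pre <- lay$po[rev(seq_len(nrow(lay$po))), , drop = FALSE]
  A0 <- matrix(NA_real_, tot, K); A1 <- matrix(NA_real_, tot, K)
  sib0 <- list(); sib1 <- list()
  for (i in seq_len(nrow(pre))) {
    u <- pre[i, 1]; v <- pre[i, 2]
    key <- as.character(u)
    if (is.null(sib0[[key]])) {
      s0 <- numeric(K); s1 <- numeric(K)
      for (w in lay$kids[[key]]) {
        s0 <- s0 + pmin(D0[w, ], D1[w, ] + 1)
        s1 <- s1 + pmin(D1[w, ], D0[w, ] + 1)
      }
      sib0[[key]] <- s0; sib1[[key]] <- s1
    }
    A0[v, ] <- E0[u, ] + sib0[[key]] - pmin(D0[v, ], D1[v, ] + 1)
    A1[v, ] <- E1[u, ] + sib1[[key]] - pmin(D1[v, ], D0[v, ] + 1)
    E0[v, ] <- pmin(A0[v, ], A1[v, ] + 1)
    E1[v, ] <- pmin(A1[v, ], A0[v, ] + 1)
  }
  edge <- tree$edge
  can_zero <- logical(nrow(edge)); must_zero <- logical(nrow(edge))
  for (i in seq_len(nrow(edge))) {
    v <- edge[i, 2]
    same <- pmin(A0[v, ] + D0[v, ], A1[v, ] + D1[v, ])
    diff <- pmin(A0[v, ] + 1 + D1[v, ], A1[v, ] + 1 + D0[v, ])
    can_zero[i] <- all(same <= L)
    must_zero[i] <- all(diff > L)
  }
  list(can_zero = can_zero, must_zero = must_zero, per_char_len = L)
}

#' Map character changes onto a tree under ACCTRAN
#'
#' Assigns every node a state for every character so that the total
#' number of changes equals the Fitch length, resolving ambiguous
#' placements by accelerated transformation: a change is pushed as close
#' to the root as the optimum allows, so a disputed gain becomes an early
#' gain compensated by later reversals rather than parallel gains near
#' the tips.  The tree is rooted at the all-absent ancestor (root state
#' fixed to absence for every character).
#'
#' @param tree rooted `ape::phylo` over the OTUs of `m`.
#' @param m an `onto_matrix`.
#' @return an object of class `onto_changes`: list with `tree`, `states`
#'   (node x character matrix of reconstructed states) and `changes`, a
#'   data frame with one row per change (`edge`, `parent`, `child`,
#'   `character`, `direction` gain/loss).
#' @export
acctran_changes <- function(tree, m) {
  X <- .tip_states(tree, m)
  lay <- .tree_layout(tree)
  nt <- lay$ntip; tot <- nt + lay$nnode; K <- ncol(X)
  dp <- .down_pass(lay, X)
  D0 <- dp$D0; D1 <- dp$D1
  S <- matrix(NA_integer_, tot, K)
  S[lay$root, ] <- 0L
  pre <- lay$po[rev(seq_len(nrow(lay$po))), , drop = FALSE]
  for (i in seq_len(nrow(pre))) {
    u <- pre[i, 1]; v <- pre[i, 2]
    f <- S[u, ]
    # prefer the state that is strictly cheaper below v; on a tie keep the
    # parent state (forced); when the cheaper state conflicts with the
    # parent within one step, both placements are optimal and ACCTRAN
    # takes the change on this edge (the rootward option)
    s <- ifelse(D0[v, ] < D1[v, ], 0L, ifelse(D1[v, ] < D0[v, ], 1L, f))
    S[v, ] <- s
  }
  edge <- tree$edge
  rows <- list()
  for (i in seq_len(nrow(edge))) {
    u <- edge[i, 1]; v <- edge[i, 2]
    chg <- which(S[u, ] != S[v, ])
    if (length(chg)) {
      rows[[length(rows) + 1L]] <- data.frame(
        edge = i, parent = u, child = v, character = chg,
        direction = ifelse(S[v, chg] == 1L, "gain", "loss"))
    }
  }
  changes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(edge = integer(), parent = integer(), child = integer(),
               character = integer(), direction = character())
  structure(list(tree = tree, states = S, changes = changes),
            class = "onto_changes")
}

#' @export
print.onto_changes <- function(x, ...) {
  cat(sprintf("ACCTRAN change map: %d changes (%d gains, %d losses) on %d edges\n",
              nrow(x$changes), sum(x$changes$direction == "gain"),
              sum(x$changes$direction == "loss"),
              length(unique(x$changes$edge))))
  invisible(x)
}

# descendant tip labels below each node
.node_clades <- function(tree) {
  lay <- .tree_layout(tree)
  clades <- vector("list", lay$ntip + lay$nnode)
  for (i in seq_len(lay$ntip)) clades[[i]] <- tree$tip.label[i]
  for (i in seq_len(nrow(lay$po))) {
    u <- lay$po[i, 1]; v <- lay$po[i, 2]
    clades[[u]] <- c(clades[[u]], clades[[v]])
  }
  clades
}
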