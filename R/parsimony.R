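# Gain/loss parsimony for presence/absence characters on a rooted species
# tree. The character starts absent on the stem edge above the root, so
# every presence requires at least one gain (invasion) somewhere on the
# tree; losses model elimination of the element from a lineage.

tip_state_vector <- function(tree, tip_states) {
  tips <- tree$labels[tree$is_tip]
  if (is.logical(tip_states)) {
    tip_states <- stats::setNames(as.integer(tip_states), names(tip_states))
  }
  miss <- setdiff(tips, names(tip_states))
  if (length(miss) > 0L) {
    stop("no state for leaf: ", paste(miss, collapse = ", "))
  }
  st <- as.integer(tip_states[tips])
  if (anyNA(st) || !all(st %in% c(0L, 1L))) {
    stop("tip states must be 0/1 (or FALSE/TRUE)")
  }
  st
}

trans_cost <- function(from, to, gain_cost, loss_cost) {
  ifelse(from == to, 0, ifelse(to == 1L, gain_cost, loss_cost))
}

sankoff_table <- function(tree, tip_states, gain_cost, loss_cost) {
  st <- tip_state_vector(tree, tip_states)
  C <- matrix(Inf, nrow = tree$n_nodes, ncol = 2)  # cols: state 0, state 1
  for (v in tree$postorder) {
    if (tree$is_tip[v]) {
      C[v, st[v] + 1L] <- 0
    } else {
      for (s in 0:1) {
        tot <- 0
        for (ch in tree$children[[v]]) {
          tot <- tot + min(trans_cost(s, 0L, gain_cost, loss_cost) + C[ch, 1],
                           trans_cost(s, 1L, gain_cost, loss_cost) + C[ch, 2])
        }
        C[v, s + 1L] <- tot
      }
    }
  }
  total <- min(C[tree$root, 1],                      # stem stays absent
               gain_cost + C[tree$root, 2])          # gain on the stem edge
  list(C = C, total = total, states = st)
}

#' Minimum gain/loss cost of a presence/absence character
#'
#' Sankoff dynamic programming from the leaves to the root, with the
#' ancestral (stem) state fixed to absent; a gain on the stem edge itself
#' is allowed and costs `gain_cost`.
#'
#' @param tree a `rooted_tree` (see [read_newick()]).
#' @param tip_states named logical/0-1 vector over all leaf labels
#'   (`TRUE` = element present in that genome).
#' @param gain_cost,loss_cost event weights (defaults: unit costs, i.e.
#'   plain event counting).
#' @return minimal total event cost (numeric).
#' @examples
#' tr <- parse_newick("((A,B),C);")
#' sankoff_min_cost(tr, c(A = TRUE, B = TRUE, C = FALSE))  # 1
#' @export
sankoff_min_cost <- function(tree, tip_states, gain_cost = 1, loss_cost = 1) {
  sankoff_table(tree, tip_states, gain_cost, loss_cost)$total
}

#' Enumerate all minimum-cost gain/loss scenarios
#'
#' Backtracks through the Sankoff table to produce *every* internal-state
#' labeling achieving the minimum cost, converts each to its event set,
#' and deduplicates. A scenario is identified by its set of gain edges and
#' loss edges; edges are named by their child node (the edge above the
#' root is `"stem"`).
#'
#' @inheritParams sankoff_min_cost
#' @param max_scenarios safety cap on the enumeration.
#' @return list with `cost` and `scenarios`, a list of
#'   `gain_loss_scenario` objects (fields `gains`, `losses`, `cost`),
#'   sorted by number of gains then edge names.
#' @export
enumerate_scenarios <- function(tree, tip_states, gain_cost = 1,
                                loss_cost = 1, max_scenarios = 10000L) {
  tab <- sankoff_table(tree, tip_states, gain_cost, loss_cost)
  C <- tab$C
  labelings <- list()
  # recursive assignment: given node v must take state s, extend partial
  # labeling with all optimal child-state combinations
  assign_node <- function(v, s, lab) {
    lab[v] <- s
    if (tree$is_tip[v]) return(list(lab))
    out <- list(lab)
    for (ch in tree$children[[v]]) {
      best <- min(trans_cost(s, 0L, gain_cost, loss_cost) + C[ch, 1],
                  trans_cost(s, 1L, gain_cost, loss_cost) + C[ch, 2])
      opts <- c(0L, 1L)[vapply(0:1, function(t) {
        trans_cost(s, t, gain_cost, loss_cost) + C[ch, t + 1L] == best
      }, logical(1))]
      nxt <- list()
      for (partial in out) {
        for (t in opts) {
          nxt <- c(nxt, assign_node(ch, t, partial))
          if (length(nxt) > max_scenarios) {
            stop("more than ", max_scenarios, " optimal labelings")
          }
        }
      }
      out <- nxt
    }
    out
  }
  root_opts <- c(0L, 1L)[vapply(0:1, function(s) {
    trans_cost(0L, s, gain_cost, loss_cost) + C[tree$root, s + 1L] == tab$total
  }, logical(1))]
  for (s in root_opts) {
    labelings <- c(labelings,
                   assign_node(tree$root, s, rep(NA_integer_, tree$n_nodes)))
  }
  seen <- character(0)
  scens <- list()
  for (lab in labelings) {
    sc <- labeling_to_scenario(tree, lab, gain_cost, loss_cost)
    key <- paste(paste(sc$gains, collapse = ","),
                 paste(sc$losses, collapse = ","), sep = "|")
    if (!key %in% seen) {
      seen <- c(seen, key)
      scens[[length(scens) + 1L]] <- sc
    }
  }
  ord <- order(vapply(scens, function(s) length(s$gains), integer(1)),
               vapply(scens, function(s) paste(s$gains, collapse = ","),
                      character(1)),
               vapply(scens, function(s) paste(s$losses, collapse = ","),
                      character(1)))
  list(cost = tab$total, scenarios = scens[ord])
}

labeling_to_scenario <- function(tree, lab, gain_cost = 1, loss_cost = 1) {
  gains <- character(0); losses <- character(0)
  for (v in seq_len(tree$n_nodes)) {
    p <- tree$parent[v]
    ps <- if (is.na(p)) 0L else lab[p]
    if (ps == 0L && lab[v] == 1L) gains <- c(gains, edge_name(tree, v))
    if (ps == 1L && lab[v] == 0L) losses <- c(losses, edge_name(tree, v))
  }
  structure(list(gains = sort(gains), losses = sort(losses),
                 cost = gain_cost * length(gains) + loss_cost * length(losses)),
            class = "gain_loss_scenario")
}

#' @export
print.gain_loss_scenario <- function(x, ...) {
  cat("<scenario> cost ", x$cost, ": ",
      length(x$gains), " gain(s) [", paste(x$gains, collapse = ", "), "], ",
      length(x$losses), " loss(es) [", paste(x$losses, collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' Replay a scenario's events down the tree
#'
#' Starting from absent on the stem, applies the scenario's gain and loss
#' edges from the root down and returns the implied tip states. Used to
#' verify that every reported scenario reproduces the observations.
#'
#' @param tree a `rooted_tree`.
#' @param scenario a `gain_loss_scenario`.
#' @return named logical vector of tip states.
#' @export
replay_scenario <- function(tree, scenario) {
  state <- rep(NA, tree$n_nodes)
  apply_edge <- function(v, incoming) {
    nm <- edge_name(tree, v)
    s <- incoming
    if (nm %in% scenario$gains) s <- 1L
    if (nm %in% scenario$losses) s <- 0L
    state[v] <<- s
    for (ch in tree$children[[v]]) apply_edge(ch, s)
  }
  apply_edge(tree$root, 0L)
  out <- as.logical(state[tree$is_tip])
  names(out) <- tree$labels[tree$is_tip]
  out
}

#' Dollo (single-origin) scenario
#'
#' Places exactly one gain on the edge above the most recent common
#' ancestor of the present tips and the minimal set of losses explaining
#' the absent tips below it.
#'
#' @inheritParams sankoff_min_cost
#' @return a `gain_loss_scenario`.
#' @export
dollo_scenario <- function(tree, tip_states) {
  st <- tip_state_vector(tree, tip_states)
  present_tips <- which(tree$is_tip)[st == 1L]
  if (length(present_tips) == 0L) stop("dollo_scenario: no present tips")
  # subtree presence flags, bottom-up
  has_present <- rep(FALSE, tree$n_nodes)
  for (v in tree$postorder) {
    has_present[v] <- if (tree$is_tip[v]) st[v] == 1L else
      any(has_present[tree$children[[v]]])
  }
  # MRCA of present tips: deepest node whose subtree holds all of them
  n_present_below <- rep(0L, tree$n_nodes)
  for (v in tree$postorder) {
    n_present_below[v] <- if (tree$is_tip[v]) as.integer(st[v] == 1L) else
      sum(n_present_below[tree$children[[v]]])
  }
  mrca <- tree$root
  repeat {
    kids <- tree$children[[mrca]]
    nxt <- kids[n_present_below[kids] == length(present_tips)]
    if (length(nxt) == 1L && !tree$is_tip[nxt]) { mrca <- nxt; next }
    if (length(nxt) == 1L && tree$is_tip[nxt]) { mrca <- nxt }
    break
  }
  gains <- edge_name(tree, mrca)
  # losses: edges inside the MRCA subtree whose child subtree has no
  # present tip but whose parent (still "present") does
  losses <- character(0)
  collect <- function(v) {
    for (ch in tree$children[[v]]) {
      if (!has_present[ch]) {
        losses <<- c(losses, edge_name(tree, ch))
      } else {
        collect(ch)
      }
    }
  }
  collect(mrca)
  structure(list(gains = sort(gains), losses = sort(losses),
                 cost = 1 + length(losses)),
            class = "gain_loss_scenario")
}
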