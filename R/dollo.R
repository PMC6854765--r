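#' Dollo reconstruction of a single presence/absence character
#'
#' Under the Dollo model a gene-family member is gained exactly once and
#' may be lost independently any number of times. Given the leaf states of
#' one character, the most parsimonious single-gain scenario places the
#' gain on the branch subtending the most recent common ancestor of all
#' possessing leaves, and one loss on each maximal subtree below that node
#' that contains no possessing leaf.
#'
#' Characters present in every leaf are assigned the [PRE_ROOT] gain: their
#' origin predates the root of the sampled tree and is unobservable on it.
#' `"unknown"` leaf states are treated as absences when locating the gain
#' node, but a maximal empty subtree consisting entirely of unknown leaves
#' generates no loss event (absence of annotation is not evidence of
#' loss); the scenario records this policy in its `policy` field.
#'
#' @param tree A [rooted_tree].
#' @param presence Named vector over all leaf labels of `tree`, with
#'   values `"present"`, `"absent"` or `"unknown"` (logical vectors are
#'   accepted: `TRUE`/`FALSE`/`NA`).
#' @param character Name of the character (used in reports).
#' @return An object of class `gain_loss_scenario`: a list with elements
#'   `character`, `gain_node` (integer node id, [PRE_ROOT], or `NA` when
#'   no leaf possesses the character), `gain_branch` (branch id = child
#'   node id, [PRE_ROOT], or `NA`), `losses` (integer vector of branch
#'   ids) and `policy`.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' reconstruct_character(tr, c(A = TRUE, B = TRUE, C = FALSE, D = TRUE), "x")
#' @export
reconstruct_character <- function(tree, presence, character = "character") {
  stopifnot(inherits(tree, "rooted_tree"))
  presence <- normalize_states(presence)
  labs <- leaf_labels(tree)
  missing <- setdiff(labs, names(presence))
  if (length(missing)) {
    stop("presence state missing for leaf: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  st <- presence[labs]

  scenario <- function(gain_node, gain_branch, losses) {
    structure(list(character = character,
                   gain_node = gain_node, gain_branch = gain_branch,
                   losses = losses,
                   policy = "unknown=absent-for-gain, all-unknown-subtree=no-loss"),
              class = "gain_loss_scenario")
  }

  present_leaves <- labs[st == "present"]
  if (length(present_leaves) == 0L) {
    return(scenario(NA_integer_, NA_integer_, integer(0)))
  }
  g <- mrca_node(tree, present_leaves)
  gain_branch <- if (g == tree$root) PRE_ROOT else g

  # subtree tallies of present / known (non-unknown) leaves
  n <- n_nodes(tree)
  n_present <- integer(n)
  n_known <- integer(n)
  for (v in postorder_nodes(tree)) {
    if (is_leaf(tree, v)) {
      n_present[v] <- as.integer(st[v] == "present")
      n_known[v] <- as.integer(st[v] != "unknown")
    } else {
      kids <- tree$children[[v]]
      n_present[v] <- sum(n_present[kids])
      n_known[v] <- sum(n_known[kids])
    }
  }

  # losses: maximal empty subtrees strictly below the gain node
  losses <- integer(0)
  stack <- tree$children[[g]]
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (n_present[v] == 0L) {
      if (n_known[v] > 0L) losses <- c(losses, v)
      # all-unknown subtree: no loss recorded, nothing to descend into
    } else if (!is_leaf(tree, v)) {
      stack <- c(stack, tree$children[[v]])
    }
  }
  scenario(g, gain_branch, sort(losses))
}

normalize_states <- function(x) {
  if (is.logical(x)) {
    out <- ifelse(is.na(x), "unknown", ifelse(x, "present", "absent"))
    names(out) <- names(x)
    return(out)
  }
  if (!all(x %in% c("present", "absent", "unknown"))) {
    stop("states must be 'present', 'absent' or 'unknown'", call. = FALSE)
  }
  x
}

#' @export
print.gain_loss_scenario <- function(x, ...) {
  g <- if (is.na(x$gain_node)) "none" else if (x$gain_branch == PRE_ROOT)
    "PRE_ROOT" else paste0("branch above node ", x$gain_node)
  cat("gain_loss_scenario '", x$character, "': gain = ", g,
      ", losses = ", length(x$losses), "\n", sep = "")
  invisible(x)
}

#' Dollo reconstruction of every character of a phyletic matrix
#'
#' Runs [reconstruct_character()] for each column of `matrix` and
#' aggregates the events. The default gain count excludes characters whose
#' gain is [PRE_ROOT] (present in all taxa): their origin lies before the
#' root and is not an event on the tree.
#'
#' @param tree A [rooted_tree]; its leaf labels must equal the matrix taxa
#'   as sets.
#' @param matrix A [phyletic_matrix].
#' @return An object of class `event_report`: a list with elements
#'   `scenarios` (named list of `gain_loss_scenario`), `gain_count`
#'   (PRE_ROOT-excluded), `gain_count_total` (including PRE_ROOT origins),
#'   `loss_count`, and `events` (data frame with columns `character`,
#'   `event`, `branch` (child-node label), `node` (child-node id; 0 for
#'   PRE_ROOT) and `depth`).
#' @examples
#' fx <- apo_fixture()
#' rep <- reconstruct_all(fx$tree, fx$matrix)
#' rep$gain_count
#' @export
reconstruct_all <- function(tree, matrix) {
  stopifnot(inherits(tree, "rooted_tree"), inherits(matrix, "phyletic_matrix"))
  taxa <- matrix_taxa(matrix)
  labs <- leaf_labels(tree)
  if (!setequal(taxa, labs)) {
    stop("taxon sets differ; only in matrix: {",
         paste(setdiff(taxa, labs), collapse = ", "),
         "}, only in tree: {",
         paste(setdiff(labs, taxa), collapse = ", "), "}", call. = FALSE)
  }
  chars <- matrix_characters(matrix)
  scenarios <- lapply(chars, function(ch) {
    pres <- stats::setNames(unclass(matrix)[, ch], taxa)
    reconstruct_character(tree, pres, ch)
  })
  names(scenarios) <- chars

  rows <- list()
  for (sc in scenarios) {
    if (!is.na(sc$gain_branch)) {
      dep <- if (sc$gain_branch == PRE_ROOT) -1L else node_depth(tree, sc$gain_node)
      rows[[length(rows) + 1L]] <- data.frame(
        character = sc$character, event = "gain",
        branch = node_label(tree, sc$gain_branch),
        node = sc$gain_branch, depth = dep,
        stringsAsFactors = FALSE)
    }
    for (b in sc$losses) {
      rows[[length(rows) + 1L]] <- data.frame(
        character = sc$character, event = "loss",
        branch = node_label(tree, b), node = b,
        depth = node_depth(tree, b), stringsAsFactors = FALSE)
    }
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(character = character(0), event = character(0),
               branch = character(0), node = integer(0), depth = integer(0))

  gains_on_tree <- vapply(scenarios, function(s)
    !is.na(s$gain_branch) && s$gain_branch != PRE_ROOT, logical(1L))
  gains_any <- vapply(scenarios, function(s) !is.na(s$gain_branch), logical(1L))

  structure(
    list(scenarios = scenarios,
         gain_count = sum(gains_on_tree),
         gain_count_total = sum(gains_any),
         loss_count = sum(vapply(scenarios, function(s) length(s$losses), integer(1L))),
         events = events),
    class = "event_report"
  )
}

#' @export
print.event_report <- function(x, ...) {
  cat(sprintf("event_report: %d characters; %d gain events (%d origins incl. pre-root); %d loss events\n",
              length(x$scenarios), x$gain_count, x$gain_count_total,
              x$loss_count))
  invisible(x)
}

#' Events aggregated per branch
#'
#' @param report An `event_report` from [reconstruct_all()].
#' @return Data frame with one row per (branch, event kind): columns
#'   `branch`, `node`, `event`, `count`, `characters` (comma-separated).
#' @export
events_by_branch <- function(report) {
  stopifnot(inherits(report, "event_report"))
  ev <- report$events
  if (!nrow(ev)) {
    return(data.frame(branch = character(0), node = integer(0),
                      event = character(0), count = integer(0),
                      characters = character(0)))
  }
  key <- paste(ev$node, ev$event, sep = "\r")
  out <- do.call(rbind, lapply(split(ev, key), function(d) {
    data.frame(branch = d$branch[1L], node = d$node[1L], event = d$event[1L],
               count = nrow(d),
               characters = paste(sort(d$character), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$node, out$event), , drop = FALSE]
}

#' Emergence order of family members
#'
#' Groups characters by the node at which their gain is inferred and sorts
#' the groups by the depth of that node: characters older than the root
#' ([PRE_ROOT] gains) come first, then progressively younger origins.
#' Groups whose gain nodes share the same depth are merged and reported as
#' simultaneous (the tree does not order them). Characters absent from
#' every taxon have no origin and are omitted.
#'
#' @param tree A [rooted_tree].
#' @param matrix A [phyletic_matrix].
#' @return Data frame with one row per emergence rank: columns `rank`,
#'   `depth` (-1 for pre-root origins) and `members` (comma-separated,
#'   alphabetical).
#' @examples
#' fx <- apo_fixture()
#' emergence_order(fx$tree, fx$matrix)
#' @export
emergence_order <- function(tree, matrix) {
  report <- reconstruct_all(tree, matrix)
  sc <- Filter(function(s) !is.na(s$gain_branch), report$scenarios)
  if (!length(sc)) {
    return(data.frame(rank = integer(0), depth = integer(0),
                      members = character(0)))
  }
  depth <- vapply(sc, function(s) {
    if (s$gain_branch == PRE_ROOT) -1L else node_depth(tree, s$gain_node)
  }, integer(1L))
  groups <- split(vapply(sc, `[[`, character(1L), "character"), depth)
  depths <- as.integer(names(groups))
  ord <- order(depths)
  data.frame(
    rank = seq_along(ord),
    depth = depths[ord],
    members = vapply(groups[ord], function(g) paste(sort(g), collapse = ","),
                     character(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
}
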