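# Generic probability-tree engine: chance nodes with branch probabilities,
# terminal leaves carrying itemized costs and consequence flags, exact
# expected-cost roll-back, and a brute-force path-enumeration oracle.

#' Consequence flags recognized on terminal leaves
#' @export
CONSEQUENCE_FLAGS <- c("air_transfer", "ground_transfer", "ed_encounter", "tpa_given")

# branch-probability sums must close to 1 within this tolerance
PROB_SUM_TOL <- 1e-9

#' Create a chance node
#'
#' A chance node represents a point where a patient follows exactly one of
#' several mutually exclusive branches, each with a probability. Branch
#' probabilities at a node must sum to 1 (the branches are exhaustive).
#'
#' @param label Character identifier for the node.
#' @param branches A list of branches, each created by [branch()].
#' @return An object of class `chance_node`.
#' @seealso [terminal_leaf()], [branch()], [expected_cost()]
#' @export
#' @examples
#' tree <- chance_node("flip", list(
#'   branch("heads", 0.5, terminal_leaf("h", c(prize = 10))),
#'   branch("tails", 0.5, terminal_leaf("t", c(prize = 0)))
#' ))
#' expected_cost(tree)
chance_node <- function(label, branches) {
  stopifnot(is.character(label), length(label) == 1L, is.list(branches),
            length(branches) >= 1L)
  structure(list(label = label, branches = branches), class = "chance_node")
}

#' Create a branch of a chance node
#'
#' @param label Character identifier for the branch.
#' @param p Branch probability in \[0, 1\].
#' @param child The subtree reached along this branch: a `chance_node` or a
#'   `terminal_leaf`.
#' @return An object of class `tree_branch`.
#' @export
branch <- function(label, p, child) {
  stopifnot(is.character(label), length(label) == 1L, is.numeric(p),
            length(p) == 1L)
  if (!inherits(child, c("chance_node", "terminal_leaf"))) {
    stop("branch child must be a chance_node or terminal_leaf", call. = FALSE)
  }
  structure(list(label = label, p = as.numeric(p), child = child),
            class = "tree_branch")
}

#' Create a terminal leaf
#'
#' A leaf closes one care pathway; the costs of the patient reaching that
#' end-point are attached as named items, together with the consequence flags
#' realized on the path (secondary air/ground transfer, ED encounter, tPA).
#'
#' @param label Character identifier.
#' @param cost_items Named numeric vector of non-negative cost items (USD).
#'   An empty or unnamed zero-length vector denotes a costless end-point.
#' @param flags Character vector, subset of [CONSEQUENCE_FLAGS].
#' @return An object of class `terminal_leaf`.
#' @export
terminal_leaf <- function(label, cost_items = numeric(0), flags = character(0)) {
  stopifnot(is.character(label), length(label) == 1L, is.numeric(cost_items))
  bad <- setdiff(flags, CONSEQUENCE_FLAGS)
  if (length(bad)) {
    stop("unknown consequence flag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(label = label, cost_items = cost_items,
                 flags = unique(as.character(flags))),
            class = "terminal_leaf")
}

#' Validate a probability tree
#'
#' Walks the tree and reports every violation of its structural invariants:
#' branch probabilities at each chance node must sum to 1 (within 1e-9),
#' every probability must lie in \[0, 1\], and every leaf cost item must be
#' non-negative. Violations are reported, never thrown.
#'
#' @param tree A `chance_node` or `terminal_leaf`.
#' @return A character vector of violation messages; empty when the tree is
#'   valid.
#' @export
validate_tree <- function(tree) {
  violations <- character(0)
  walk <- function(node, path) {
    if (inherits(node, "terminal_leaf")) {
      neg <- node$cost_items < 0
      if (any(neg)) {
        violations <<- c(violations, sprintf(
          "negative cost item '%s' (%g) at leaf '%s'",
          names(node$cost_items)[neg], node$cost_items[neg], path))
      }
      return(invisible())
    }
    ps <- vapply(node$branches, function(b) b$p, numeric(1))
    out <- ps < 0 | ps > 1
    if (any(out)) {
      labs <- vapply(node$branches, function(b) b$label, character(1))
      violations <<- c(violations, sprintf(
        "probability %g out of [0,1] on branch '%s' of node '%s'",
        ps[out], labs[out], path))
    }
    if (abs(sum(ps) - 1) > PROB_SUM_TOL) {
      violations <<- c(violations, sprintf(
        "branch probabilities at node '%s' sum to %.12g, not 1", path, sum(ps)))
    }
    for (b in node$branches) walk(b$child, paste(path, b$label, sep = "/"))
    invisible()
  }
  walk(tree, tree$label)
  violations
}

stop_if_invalid <- function(tree) {
  v <- validate_tree(tree)
  if (length(v)) {
    stop("invalid tree:\n", paste("  -", v, collapse = "\n"), call. = FALSE)
  }
  invisible(tree)
}

#' Expected cost of a probability tree
#'
#' Exact probability-weighted roll-back: the expected cost of a leaf is the
#' sum of its cost items; the expected cost of a chance node is the
#' probability-weighted sum over its branches.
#'
#' @param tree A valid `chance_node` or `terminal_leaf`.
#' @param validate Check tree invariants first (default `TRUE`); the check is
#'   skipped in inner loops that evaluate a tree already validated once.
#' @return Expected cost in USD (a single number).
#' @export
expected_cost <- function(tree, validate = TRUE) {
  if (validate) stop_if_invalid(tree)
  ev <- function(node) {
    if (inherits(node, "terminal_leaf")) return(sum(node$cost_items))
    s <- 0
    for (b in node$branches) s <- s + b$p * ev(b$child)
    s
  }
  ev(tree)
}

#' Enumerate all root-to-leaf paths
#'
#' Brute-force oracle for [expected_cost()]: one row per leaf with the path
#' labels, the joint probability (product of branch probabilities along the
#' path), the total leaf cost, and the leaf's consequence flags. Over a valid
#' tree the joint probabilities sum to 1.
#'
#' @inheritParams expected_cost
#' @return A data.frame with columns `path` (labels joined by "/"),
#'   `probability`, `cost`, and one logical column per entry of
#'   [CONSEQUENCE_FLAGS].
#' @export
enumerate_paths <- function(tree, validate = TRUE) {
  if (validate) stop_if_invalid(tree)
  rows <- list()
  walk <- function(node, path, p) {
    if (inherits(node, "terminal_leaf")) {
      flags <- as.list(CONSEQUENCE_FLAGS %in% node$flags)
      names(flags) <- CONSEQUENCE_FLAGS
      rows[[length(rows) + 1L]] <<- c(
        list(path = paste(c(path, node$label), collapse = "/"),
             probability = p, cost = sum(node$cost_items)), flags)
      return(invisible())
    }
    for (b in node$branches) walk(b$child, c(path, b$label), p * b$p)
    invisible()
  }
  walk(tree, character(0), 1)
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Restate a cost in another price-index year
#'
#' Multiplies a cost by the ratio of two price-index values (for this model,
#' the Medicare component of the Consumer Price Index), restating it from the
#' year of `index_source` to the year of `index_target`.
#'
#' @param cost Cost (USD) expressed in the source year.
#' @param index_source Index value for the year the cost is quoted in; must be
#'   positive.
#' @param index_target Index value for the target base year; must be positive.
#' @return `cost * index_target / index_source`.
#' @export
#' @examples
#' adjust_cost_to_base_year(100, 100, 110) # 10% healthcare inflation -> 110
adjust_cost_to_base_year <- function(cost, index_source, index_target) {
  if (!is.numeric(index_source) || !is.numeric(index_target) ||
      any(index_source <= 0) || any(index_target <= 0)) {
    stop("price-index values must be positive numbers", call. = FALSE)
  }
  cost * index_target / index_source
}

# --- JSON serialization ------------------------------------------------------

node_to_list <- function(node) {
  if (inherits(node, "terminal_leaf")) {
    list(label = node$label,
         cost_items = as.list(node$cost_items),
         flags = as.list(node$flags))
  } else {
    list(label = node$label,
         branches = lapply(node$branches, function(b) {
           list(label = b$label, p = b$p, child = node_to_list(b$child))
         }))
  }
}

list_to_node <- function(x) {
  if (!is.null(x$branches)) {
    chance_node(x$label, lapply(x$branches, function(b) {
      branch(b$label, b$p, list_to_node(b$child))
    }))
  } else {
    items <- unlist(x$cost_items)
    if (is.null(items)) items <- numeric(0)
    terminal_leaf(x$label, items, unlist(x$flags))
  }
}

#' Serialize a tree to JSON / read it back
#'
#' Lossless round-trip of the tree structure: chance nodes as
#' `{"label", "branches": [{"label", "p", "child"}]}`, leaves as
#' `{"label", "cost_items": {name: amount}, "flags": [...]}`.
#'
#' @param tree A `chance_node` or `terminal_leaf`.
#' @param path File to write to / read from.
#' @return `write_tree` returns `path` invisibly; `read_tree` returns the tree.
#' @export
write_tree <- function(tree, path) {
  # 17 significant digits guarantee an exact double round-trip
  jsonlite::write_json(node_to_list(tree), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  list_to_node(jsonlite::read_json(path))
}

#' @export
print.chance_node <- function(x, ...) {
  show <- function(node, indent, p) {
    pad <- strrep("  ", indent)
    if (inherits(node, "terminal_leaf")) {
      cat(sprintf("%s[%s] cost=%.2f%s\n", pad, node$label,
                  sum(node$cost_items),
                  if (length(node$flags)) paste0(" {", paste(node$flags, collapse = ","), "}") else ""))
    } else {
      cat(sprintf("%s%s\n", pad, node$label))
      for (b in node$branches) {
        cat(sprintf("%s +- %s (p=%.4g)\n", pad, b$label, b$p))
        show(b$child, indent + 2L, b$p)
      }
    }
  }
  show(x, 0L, 1)
  invisible(x)
}
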