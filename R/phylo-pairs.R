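#' Parse a time-calibrated Newick phylogeny
#'
#' Reads a rooted, time-calibrated tree (branch lengths in years) whose
#' internal node labels, when present, carry clade support values.
#' Support is expected as a posterior probability in \[0, 1\]; labels in
#' \[0, 100\] (percent dialect) are rescaled to fractions with a warning.
#' Non-ultrametric trees are accepted with a warning, since divergence
#' times of cherries are then only approximate.
#'
#' @param newick path to a Newick file, or a Newick string.
#' @param tol relative tolerance for the ultrametricity check (fraction
#'   of tree depth).
#' @return An [ape::phylo] object with two extra components:
#'   `node.support` (numeric per internal node, `NA` where no label) and
#'   `depth` (maximum root-to-tip path length, years).
#' @export
parseTimeTree <- function(newick, tol = 1e-6) {
  txt <- if (is.character(newick) && length(newick) == 1L &&
             !grepl("[(;]", newick) && file.exists(newick))
    paste(readLines(newick, encoding = "UTF-8"), collapse = "") else newick
  tree <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tree))
    stop("Newick parse error: input could not be read as a tree")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; a time-calibrated tree is required")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  support <- rep(NA_real_, tree$Nnode)
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label
    lab[lab == ""] <- NA
    support <- suppressWarnings(as.numeric(lab))
    if (any(support > 1, na.rm = TRUE)) {
      if (all(support <= 100, na.rm = TRUE)) {
        warning("node support values look like percentages; rescaling to [0, 1]")
        support <- support / 100
      } else {
        warning("node labels outside [0, 100]; not interpretable as support")
        support[] <- NA_real_
      }
    }
  }
  depths <- ape::node.depth.edgelength(tree)
  depth <- max(depths[seq_len(ape::Ntip(tree))])
  tip_depths <- depths[seq_len(ape::Ntip(tree))]
  if (diff(range(tip_depths)) > tol * max(depth, .Machine$double.eps))
    warning(sprintf(
      "tree is not ultrametric (tip heights range %.6g to %.6g)",
      min(tip_depths), max(tip_depths)))
  tree$node.support <- support
  tree$depth <- depth
  tree
}

#' Extract sister pairs (cherries) from a phylogeny
#'
#' A cherry is an internal node whose children are exactly two tips; the
#' two languages share an immediate common ancestor not shared with any
#' other tip, so the resulting pairs are phylogenetically independent of
#' one another by construction.  `divergence_time` is the height of the
#' common ancestor above the tips (the tip branch length on an
#' ultrametric tree; the mean of the two tip branches otherwise) and
#' `pair_path_length` the sum of the two tip branches.
#'
#' @param tree a tree from [parseTimeTree()] (an [ape::phylo]).
#' @param polytomy_pairs if `TRUE`, tip children of a polytomy are also
#'   paired up greedily (first with second, third with fourth, ...).  Off
#'   by default: pairs should come from a fully resolved tree.
#' @return data.frame with one row per pair: `pair_id`, `language_a`,
#'   `language_b`, `divergence_time`, `pair_path_length`, `support`,
#'   `shared_nodes` (ancestral nodes from the pair's common ancestor up
#'   to and including the root).
#' @export
extractCherries <- function(tree, polytomy_pairs = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  support <- if (!is.null(tree$node.support)) tree$node.support
             else rep(NA_real_, tree$Nnode)
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  elen <- tree$edge.length
  rows <- list()
  addPair <- function(tips, lens, node) {
    a <- tree$tip.label[tips[1]]; b <- tree$tip.label[tips[2]]
    ord <- order(c(a, b))
    rows[[length(rows) + 1L]] <<- data.frame(
      pair_id = paste(sort(c(a, b)), collapse = "--"),
      language_a = c(a, b)[ord[1]], language_b = c(a, b)[ord[2]],
      divergence_time = mean(lens),
      pair_path_length = sum(lens),
      support = support[node - ntip],
      shared_nodes = .countAncestors(tree, node),
      stringsAsFactors = FALSE)
  }
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    kids <- child[parent == node]
    kid_lens <- elen[parent == node]
    tip_kids <- kids <= ntip
    if (length(kids) == 2L && all(tip_kids)) {
      addPair(kids, kid_lens, node)
    } else if (polytomy_pairs && length(kids) > 2L && sum(tip_kids) >= 2L) {
      tk <- kids[tip_kids]; tl <- kid_lens[tip_kids]
      for (i in seq_len(length(tk) %/% 2L))
        addPair(tk[c(2L * i - 1L, 2L * i)], tl[c(2L * i - 1L, 2L * i)], node)
    }
  }
  if (!length(rows))
    return(data.frame(pair_id = character(0), language_a = character(0),
                      language_b = character(0),
                      divergence_time = numeric(0),
                      pair_path_length = numeric(0), support = numeric(0),
                      shared_nodes = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# number of ancestral nodes from `node` (inclusive) up to the root
.countAncestors <- function(tree, node) {
  root <- ape::Ntip(tree) + 1L
  n <- 0L
  while (TRUE) {
    n <- n + 1L
    if (node == root) break
    node <- tree$edge[tree$edge[, 2] == node, 1]
  }
  n
}

#' Filter sister pairs on support, depth and an explicit reject list
#'
#' Retains pairs whose clade support meets the posterior-probability
#' threshold (default 0.80), whose divergence time is strictly below
#' `max_divergence` (pairs spanning the whole tree are not closely
#' related languages, merely opposite ends of the phylogeny), and whose
#' id is not on the reject list.  The reject list carries decisions that
#' cannot be automated, such as pairs whose classification disagrees
#' with a reference catalogue.
#'
#' @param pairs data.frame from [extractCherries()].
#' @param min_support minimum support (fraction).  Pairs without a
#'   support value are rejected when `min_support > 0`.
#' @param max_divergence strict upper bound on `divergence_time` (years).
#' @param reject character vector of `pair_id`s to drop.
#' @param quiet suppress the rejection messages.
#' @return The retained rows, with a `rejections` attribute: a
#'   data.frame of `pair_id`, `reason` for every dropped pair.
#' @export
filterPairs <- function(pairs, min_support = 0.80, max_divergence = Inf,
                        reject = character(0), quiet = FALSE) {
  reason <- rep(NA_character_, nrow(pairs))
  no_support <- is.na(pairs$support)
  fail_support <- (!no_support & pairs$support < min_support) |
    (no_support & min_support > 0)
  reason[fail_support] <- ifelse(no_support[fail_support],
                                 "no support value",
                                 sprintf("support %.3f < %.3f",
                                         pairs$support[fail_support],
                                         min_support))
  too_deep <- is.na(reason) & pairs$divergence_time >= max_divergence
  reason[too_deep] <- sprintf("divergence %.0f >= %.0f",
                              pairs$divergence_time[too_deep], max_divergence)
  listed <- is.na(reason) & pairs$pair_id %in% reject
  reason[listed] <- "on reject list"
  kept <- pairs[is.na(reason), , drop = FALSE]
  rejections <- data.frame(pair_id = pairs$pair_id[!is.na(reason)],
                           reason = reason[!is.na(reason)],
                           stringsAsFactors = FALSE)
  if (!quiet && nrow(rejections))
    message(paste0("rejected ", rejections$pair_id, ": ",
                   rejections$reason, collapse = "\n"))
  rownames(kept) <- NULL
  attr(kept, "rejections") <- rejections
  kept
}

#' Write a sister-pair table
#'
#' CSV output with one row per retained pair (id, the two languages,
#' shared nodes, divergence time and tip-path length).
#'
#' @param pairs data.frame from [extractCherries()]/[filterPairs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePairTable <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}
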