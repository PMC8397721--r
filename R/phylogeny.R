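#' Binary presence/absence matrix for one patient's samples
#'
#' Builds the variant x sample 0/1 matrix used for maximum-parsimony tree
#' reconstruction from SNVs and indels. A matched-normal column of all zeros
#' is appended as the outgroup; any variant observed in a sample labelled as
#' the normal is rejected as non-somatic.
#'
#' @param mutations Either a mutation \code{data.frame} for one patient
#'   (columns \code{sample}, \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}) or a named list of per-sample variant-key character
#'   vectors.
#' @param normal Name of the outgroup column (default "normal").
#' @return Integer matrix in \{0, 1\}; rownames are variant keys, colnames
#'   sample names with the normal last. No all-zero rows.
#' @export
build_matrix <- function(mutations, normal = "normal") {
  if (is.data.frame(mutations)) {
    keys <- paste(mutations$chrom, mutations$pos, mutations$ref, mutations$alt,
                  sep = ":")
    calls <- split(keys, mutations$sample)
  } else {
    calls <- mutations
  }
  if (normal %in% names(calls)) {
    germline <- calls[[normal]]
    calls[[normal]] <- NULL
    calls <- lapply(calls, setdiff, y = germline)
  }
  if (length(calls) < 1) stop("no tumor samples")
  variants <- sort(unique(unlist(calls)))
  mat <- vapply(calls, function(v) as.integer(variants %in% v),
                integer(length(variants)))
  if (length(variants) == 1) mat <- matrix(mat, nrow = 1, dimnames = list(variants, names(calls)))
  mat <- cbind(mat, 0L)
  colnames(mat)[ncol(mat)] <- normal
  rownames(mat) <- variants
  mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  mat
}

# ---- nested-tree machinery -------------------------------------------------
# A topology is stored rooted on the outgroup edge: the root has two
# children, the outgroup leaf and a nested binary tree over the tumor
# samples. Leaves are character scalars, internal nodes length-2 lists.

.nested_leaves <- function(t) {
  if (is.character(t)) t else unlist(lapply(t, .nested_leaves))
}

# all rooted binary trees over a leaf set, by stepwise insertion
.all_rooted_trees <- function(leaves) {
  trees <- list(leaves[1])
  for (leaf in leaves[-1]) {
    trees <- unlist(lapply(trees, .insert_everywhere, leaf = leaf),
                    recursive = FALSE)
  }
  trees
}

.insert_everywhere <- function(t, leaf) {
  out <- list(list(t, leaf))          # above the current (sub)tree root
  if (is.list(t)) {
    for (i in 1:2) {
      for (sub in .insert_everywhere(t[[i]], leaf)) {
        t2 <- t
        t2[[i]] <- sub
        out <- c(out, list(t2))
      }
    }
  }
  out
}

# Fitch bottom-up pass, vectorized over variants.
# State sets encoded as integers: 1 = {0}, 2 = {1}, 3 = {0,1}.
.fitch_up <- function(t, mat) {
  if (is.character(t)) {
    return(list(set = mat[, t] + 1L, score = 0L, node = t))
  }
  a <- .fitch_up(t[[1]], mat)
  b <- .fitch_up(t[[2]], mat)
  inter <- bitwAnd(a$set, b$set)
  set <- ifelse(inter > 0L, inter, bitwOr(a$set, b$set))
  list(set = set, score = a$score + b$score + sum(inter == 0L),
       children = list(a, b))
}

#' Fitch small-parsimony score of a topology
#'
#' Sums, over all variants, the minimum number of 0/1 state changes the
#' topology requires (Fitch algorithm), rooting on the outgroup edge.
#'
#' @param topology A tree from [infer_parsimony_tree()], a Newick string, or
#'   a nested-list topology over the tumor samples.
#' @param mat Binary matrix from [build_matrix()].
#' @param normal Outgroup column name.
#' @return Integer parsimony score.
#' @export
fitch_score <- function(topology, mat, normal = "normal") {
  nested <- .as_tumor_nested(topology, normal)
  leaves <- sort(.nested_leaves(nested))
  expected <- sort(setdiff(colnames(mat), normal))
  if (!identical(leaves, expected)) {
    stop("topology leaves do not match matrix samples")
  }
  if (nrow(mat) == 0) return(0L)
  up <- .fitch_up(nested, mat)
  norm_set <- rep(1L, nrow(mat))                 # outgroup is all-zero
  inter <- bitwAnd(up$set, norm_set)
  up$score + sum(inter == 0L)
}

# coerce the accepted topology forms to a nested tumor subtree
.as_tumor_nested <- function(topology, normal = "normal") {
  if (inherits(topology, "tumor_tree")) return(topology$nested)
  if (is.character(topology) && length(topology) == 1 &&
      grepl("[(;]", topology)) {
    return(read_newick(topology, normal = normal)$nested)
  }
  topology
}

#' Assign mutations to tree edges by Fitch traceback
#'
#' Performs a minimal Fitch reconstruction with the ancestral (outgroup)
#' state fixed at 0 and counts, per edge, the variants whose 0->1 (or back)
#' change falls on it. Edges are named by the sorted tumor samples below
#' them; the edge above all tumor samples is the trunk. Variants requiring
#' more than one change (homoplasy) are flagged.
#'
#' @param tree A \code{tumor_tree} from [infer_parsimony_tree()].
#' @param mat Binary matrix from [build_matrix()].
#' @return \code{data.frame} with \code{edge} and \code{count}; per-variant
#'   edge assignments in attribute \code{"assignments"}, homoplastic variant
#'   keys in attribute \code{"homoplasy"}.
#' @export
assign_edge_mutations <- function(tree, mat) {
  stopifnot(inherits(tree, "tumor_tree"))
  normal <- tree$normal
  nested <- tree$nested
  nv <- nrow(mat)
  if (nv == 0) {
    counts <- stats::setNames(rep(0L, length(tree$edge_labels)), tree$edge_labels)
    out <- data.frame(edge = names(counts), count = as.integer(counts),
                      stringsAsFactors = FALSE)
    attr(out, "assignments") <- list(); attr(out, "homoplasy") <- character(0)
    return(out)
  }
  up <- .fitch_up(nested, mat)
  change <- list()
  rec <- function(up_node, nested_node, parent_state) {
    parent_bit <- ifelse(parent_state == 0L, 1L, 2L)
    keep <- bitwAnd(up_node$set, parent_bit) > 0L
    state <- ifelse(keep, parent_state, 1L - parent_state)
    label <- paste(sort(.nested_leaves(nested_node)), collapse = "+")
    change[[label]] <<- !keep
    if (is.list(nested_node)) {
      for (i in 1:2) rec(up_node$children[[i]], nested_node[[i]], state)
    }
  }
  rec(up, nested, 0L)                     # root state = outgroup state = 0
  change[[normal]] <- rep(FALSE, nv)      # outgroup edge carries no changes
  counts <- vapply(change, sum, integer(1))
  n_changes <- Reduce(`+`, lapply(change, as.integer))
  homoplasy <- rownames(mat)[n_changes > 1]
  assignments <- lapply(change, function(ch) rownames(mat)[ch])
  out <- data.frame(edge = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "assignments") <- assignments
  attr(out, "homoplasy") <- homoplasy
  out
}

# canonical newick: children ordered by their label-only string
.nested_newick <- function(t, lengths = NULL, normal = NULL) {
  node_str <- function(n) {
    if (is.character(n)) {
      lab <- n
      str <- n
    } else {
      parts <- lapply(n, node_str)
      ord <- order(vapply(parts, `[[`, character(1), "plain"))
      parts <- parts[ord]
      lab <- paste(sort(.nested_leaves(n)), collapse = "+")
      str <- paste0("(", paste(vapply(parts, `[[`, character(1), "str"),
                               collapse = ","), ")")
    }
    if (!is.null(lengths)) {
      len <- if (lab %in% names(lengths)) lengths[[lab]] else 0
      str <- paste0(str, ":", len)
    }
    list(str = str, plain = if (is.character(n)) n else
      paste0("(", paste(sort(vapply(n, function(x)
        node_str_plain(x), character(1))), collapse = ","), ")"))
  }
  node_str_plain <- function(n) {
    if (is.character(n)) return(n)
    paste0("(", paste(sort(vapply(n, node_str_plain, character(1))),
                      collapse = ","), ")")
  }
  node_str(t)$str
}

.tree_newick <- function(nested, normal, lengths = NULL) {
  sub <- .nested_newick(nested, lengths)
  norm <- if (is.null(lengths)) normal else paste0(normal, ":0")
  paste0("(", sub, ",", norm, ");")
}

#' Infer the maximum-parsimony tree for one patient
#'
#' Exhaustively enumerates all unrooted topologies over the tumor samples
#' plus the all-zero normal outgroup, scores each with the Fitch algorithm
#' and returns the minimum-score tree. Ties are broken by the
#' lexicographically smallest canonical Newick string. Branch lengths are
#' the mutation counts assigned to each edge by [assign_edge_mutations()].
#'
#' @param mat Binary matrix from [build_matrix()].
#' @param normal Outgroup column name.
#' @param max_leaves Hard cap on total leaves for the exhaustive search
#'   (default 8); larger inputs raise an error.
#' @return Object of class \code{tumor_tree}: list with \code{nested} (the
#'   tumor subtree), \code{normal}, \code{score}, \code{edge_counts} (named
#'   by the sorted samples below each edge; the trunk is the edge naming all
#'   tumor samples), \code{newick}, \code{homoplasy}.
#' @export
infer_parsimony_tree <- function(mat, normal = "normal", max_leaves = 8) {
  if (!normal %in% colnames(mat)) stop("matrix lacks the outgroup column '", normal, "'")
  tumor <- setdiff(colnames(mat), normal)
  if (ncol(mat) > max_leaves) {
    stop("exhaustive search capped at ", max_leaves,
         " leaves; raise max_leaves explicitly for larger patients")
  }
  if (length(tumor) < 1) stop("need at least one tumor sample")
  topos <- .all_rooted_trees(sort(tumor))
  scores <- vapply(topos, function(t) fitch_score(t, mat, normal), integer(1))
  best <- which(scores == min(scores))
  if (length(best) > 1) {
    nwk <- vapply(topos[best], function(t) .tree_newick(t, normal), character(1))
    best <- best[order(nwk)[1]]
  }
  nested <- topos[[best]]
  tree <- structure(list(nested = nested, normal = normal,
                         score = min(scores)), class = "tumor_tree")
  ec <- assign_edge_mutations(tree, mat)
  counts <- stats::setNames(ec$count, ec$edge)
  tree$edge_counts <- counts
  tree$edge_labels <- ec$edge
  tree$homoplasy <- attr(ec, "homoplasy")
  tree$newick <- .tree_newick(nested, normal, lengths = as.list(counts))
  tree
}

#' @export
print.tumor_tree <- function(x, ...) {
  cat("tumor_tree (parsimony score ", x$score, "): ", x$newick, "\n", sep = "")
  invisible(x)
}

#' Write / read the Newick form of a tumor tree
#'
#' Branch lengths carry the per-edge mutation counts; the normal outgroup
#' leaf has length 0. [read_newick()] round-trips trees written by
#' [write_newick()].
#'
#' @param tree A \code{tumor_tree}.
#' @param path Optional file to write to; the string is returned invisibly.
#' @return The Newick string.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "tumor_tree"))
  if (!is.null(path)) writeLines(tree$newick, path)
  if (is.null(path)) tree$newick else invisible(tree$newick)
}

#' @rdname write_newick
#' @param text Newick string.
#' @param normal Outgroup leaf name.
#' @export
read_newick <- function(text, normal = "normal") {
  phy <- ape::read.tree(text = text)
  if (!normal %in% phy$tip.label) stop("tree lacks the outgroup leaf '", normal, "'")
  nested_len <- .phylo_to_nested(phy, normal)
  tree <- structure(list(nested = nested_len$nested, normal = normal,
                         score = NA_integer_), class = "tumor_tree")
  counts <- nested_len$lengths
  tree$edge_counts <- unlist(counts)
  tree$edge_labels <- names(tree$edge_counts)
  tree$newick <- .tree_newick(tree$nested, normal,
                              lengths = as.list(tree$edge_counts))
  tree
}

# convert an ape phylo (rooted or unrooted) into the outgroup-rooted nested
# representation, collapsing the degree-2 root ape introduces
.phylo_to_nested <- function(phy, normal) {
  phy <- ape::root(phy, outgroup = normal, resolve.root = TRUE)
  edge <- phy$edge
  ntip <- length(phy$tip.label)
  lens <- if (is.null(phy$edge.length)) rep(0, nrow(edge)) else phy$edge.length
  lengths <- list()
  descend <- function(node) {
    if (node <= ntip) return(phy$tip.label[node])
    kids <- edge[edge[, 1] == node, 2]
    subs <- lapply(kids, descend)
    if (length(subs) == 1) return(subs[[1]])
    # record lengths keyed by clade label
    for (i in seq_along(kids)) {
      lab <- paste(sort(.nested_leaves(subs[[i]])), collapse = "+")
      lengths[[lab]] <<- lens[which(edge[, 1] == node & edge[, 2] == kids[i])]
    }
    if (length(subs) == 2) return(subs)
    # polytomy at the root: peel off the normal leaf
    Reduce(function(a, b) list(a, b), subs)
  }
  root_node <- ntip + 1
  kids <- edge[edge[, 1] == root_node, 2]
  subs <- lapply(kids, descend)
  labs <- vapply(subs, function(s) paste(sort(.nested_leaves(s)), collapse = "+"),
                 character(1))
  for (i in seq_along(kids)) {
    lengths[[labs[i]]] <- lens[which(edge[, 1] == root_node & edge[, 2] == kids[i])]
  }
  norm_i <- which(labs == normal)
  if (length(norm_i) != 1) stop("could not root on the outgroup leaf")
  tumor_subs <- subs[-norm_i]
  nested <- if (length(tumor_subs) == 1) tumor_subs[[1]] else
    Reduce(function(a, b) list(a, b), tumor_subs)
  list(nested = nested, lengths = lengths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
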