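#' Build a rooted concept taxonomy
#'
#' A taxonomy is a rooted tree of concept nodes given as a child -> parent
#' edge list. Node depth is counted from the root with root depth = 1 (the
#' original Wu-Palmer counting convention; the similarity values depend on
#' it).
#'
#' @param edges data.frame (or 2-column matrix) with columns `child`,
#'   `parent`.
#' @return a `taxonomy`: list with `parent` (named character), `depth`
#'   (named integer) and `root`.
#' @export
taxonomy <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("child", "parent") %in% names(edges)))
    names(edges)[1:2] <- c("child", "parent")
  child <- as.character(edges$child)
  parent <- as.character(edges$parent)
  if (anyDuplicated(child)) stop("a node may only have one parent")
  nodes <- union(child, parent)
  roots <- setdiff(parent, child)
  if (length(roots) != 1L)
    stop("taxonomy must have exactly one root, found: ",
         paste(roots, collapse = ", "))
  pmap <- stats::setNames(parent, child)
  depth <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  depth[roots] <- 1L
  pending <- child
  while (length(pending)) {
    ready <- pending[!is.na(depth[pmap[pending]])]
    if (length(ready) == 0L) stop("taxonomy contains a cycle")
    depth[ready] <- depth[pmap[ready]] + 1L
    pending <- setdiff(pending, ready)
  }
  structure(list(parent = pmap, depth = depth, root = roots),
            class = "taxonomy")
}

#' Read a taxonomy from a plain-text edge list
#'
#' @param path TSV file with two columns, child and parent (header
#'   optional: a first line `child<TAB>parent` is recognised).
#' @return a `taxonomy`.
#' @export
read_taxonomy <- function(path) {
  first <- readLines(path, n = 1L)
  header <- identical(tolower(trimws(strsplit(first, "\t")[[1]][1])),
                      "child")
  edges <- utils::read.table(path, sep = "\t", header = header,
                             stringsAsFactors = FALSE,
                             col.names = c("child", "parent"))
  taxonomy(edges)
}

.ancestor_path <- function(tax, node) {
  if (!node %in% names(tax$depth)) stop("node not in taxonomy: ", node)
  path <- node
  while (node != tax$root) {
    node <- tax$parent[[node]]
    path <- c(path, node)
  }
  path
}

#' Wu-Palmer taxonomy similarity
#'
#' `2 * depth(LCS(a, b)) / (depth(a) + depth(b))` where LCS is the deepest
#' common ancestor (lowest common subsumer) and the root has depth 1. The
#' value lies in `(0, 1]`, equals 1 iff `a == b`, and is symmetric.
#'
#' @param tax a `taxonomy`.
#' @param a,b node ids.
#' @return similarity in `[0, 1]`.
#' @export
wu_palmer <- function(tax, a, b) {
  pa <- .ancestor_path(tax, a)
  pb <- .ancestor_path(tax, b)
  common <- intersect(pa, pb)
  lcs_depth <- max(tax$depth[common])
  2 * lcs_depth / (tax$depth[[a]] + tax$depth[[b]])
}

#' Pairwise Wu-Palmer similarity matrix
#'
#' @param tax a `taxonomy`.
#' @param items node ids (distinct); e.g. the 12 classifiers give a
#'   12 x 12 symmetric matrix with unit diagonal.
#' @return symmetric numeric matrix with `items` as dimnames.
#' @export
pairwise_matrix <- function(tax, items) {
  items <- as.character(items)
  if (length(items) < 2L) stop("need at least 2 items")
  if (anyDuplicated(items)) stop("duplicate item ids")
  n <- length(items)
  m <- diag(1, n)
  dimnames(m) <- list(items, items)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    m[i, j] <- m[j, i] <- wu_palmer(tax, items[i], items[j])
  }
  m
}

#' Pairwise absolute-difference matrix of a lexical property
#'
#' Similarity of visual complexity (stroke count) or log word frequency
#' between items is measured as the absolute difference for each pair.
#'
#' @param values named numeric vector (names = item ids).
#' @return symmetric matrix of `|v_i - v_j|`.
#' @export
abs_diff_matrix <- function(values) {
  m <- abs(outer(values, values, "-"))
  dimnames(m) <- list(names(values), names(values))
  m
}

#' Compare within-group pairwise values between two groups
#'
#' Collects the within-group upper-triangle values of a pairwise matrix
#' (Wu-Palmer similarities, or absolute property differences) for each of
#' two groups and compares the group means with a two-sample t test
#' (Welch by default). Pairwise values sharing an item are not independent;
#' the test is the conventional screening check, not an exact one.
#'
#' @param matrix symmetric pairwise matrix with item dimnames.
#' @param group_labels named character vector (names = item ids) with
#'   exactly two distinct labels; each group needs >= 2 items.
#' @param var_equal use the pooled-variance t test instead of Welch.
#' @return one-row data.frame: `group_a`, `group_b`, `mean_a`, `mean_b`,
#'   `statistic`, `df`, `p_value`.
#' @export
group_similarity_test <- function(matrix, group_labels, var_equal = FALSE) {
  groups <- sort(unique(group_labels))
  if (length(groups) != 2L) stop("need exactly two groups")
  vals <- lapply(groups, function(g) {
    ids <- names(group_labels)[group_labels == g]
    if (length(ids) < 2L) stop("group ", g, " has fewer than 2 items")
    sub <- matrix[ids, ids]
    sub[upper.tri(sub)]
  })
  tt <- stats::t.test(vals[[1]], vals[[2]], var.equal = var_equal)
  data.frame(group_a = groups[1], group_b = groups[2],
             mean_a = mean(vals[[1]]), mean_b = mean(vals[[2]]),
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, stringsAsFactors = FALSE)
}

#' Synthetic toy taxonomy over the experiment's concepts
#'
#' The concept hierarchy the original stimuli were scored against is not
#' redistributable, so the package ships a small synthetic stand-in with the
#' structural property the design relies on: classifier concepts of the two
#' animacy constraints sit at symmetric depths (so the classifier groups are
#' matched on mean within-group similarity), while animate noun concepts
#' share denser common ancestry than inanimate noun concepts (each inanimate
#' noun gets a private subtype level), making mean within-animate noun
#' similarity exceed the within-inanimate mean.
#'
#' @param lexicon a lexicon list from [synthetic_lexicon()]; its classifier
#'   and noun ids become taxonomy leaves.
#' @return list: `tax` (a `taxonomy`), `edges` (the child/parent
#'   data.frame).
#' @export
toy_taxonomy <- function(lexicon = synthetic_lexicon(seed = 1)) {
  cls <- lexicon$classifiers
  nouns <- lexicon$nouns
  e <- list(data.frame(child = c("animate", "inanimate"), parent = "entity"))
  add <- function(child, parent) {
    e[[length(e) + 1L]] <<- data.frame(child = child, parent = parent,
                                       stringsAsFactors = FALSE)
  }
  for (g in unique(cls$subgroup)) add(g, .subgroup_animacy[[g]])
  ## classifier concepts: children of their subgroup (depth 4 everywhere)
  add(cls$id, cls$subgroup)
  ## noun concepts: one category node per classifier (depth 4); animate
  ## nouns attach directly (depth 5), inanimate nouns through a private
  ## subtype node (depth 6)
  for (i in seq_len(nrow(cls))) {
    cat_node <- paste0("cat_", cls$id[i])
    add(cat_node, cls$subgroup[i])
    ids <- nouns$id[nouns$classifier_id == cls$id[i]]
    if (cls$animacy[i] == "animate") {
      add(ids, cat_node)
    } else {
      sub_nodes <- paste0("subtype_", ids)
      add(sub_nodes, cat_node)
      add(ids, sub_nodes)
    }
  }
  edges <- do.call(rbind, e)
  list(tax = taxonomy(edges), edges = edges)
}

#' Write a taxonomy edge list as TSV
#' @param edges child/parent data.frame (e.g. `toy_taxonomy()$edges`).
#' @param path file path.
#' @export
write_taxonomy_tsv <- function(edges, path) {
  utils::write.table(edges[, c("child", "parent")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
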