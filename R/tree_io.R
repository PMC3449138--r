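#' Read a Newick tree with optional foreground tags
#'
#' Parses a Newick file via \code{ape::read.tree} and extracts PAML-style
#' \code{#1} suffixes on leaf or internal-node labels as foreground-branch
#' flags for branch-site models. A tag on an internal node marks only that
#' node's subtending branch as foreground; multiple tagged branches are
#' allowed and all form one foreground set. Branches without lengths get a
#' default of 0.1 and the result is flagged
#' (\code{attr(, "default_branch_lengths")}).
#'
#' @param path Newick file; or use \code{text =} for a literal string.
#' @param text optional Newick string (overrides \code{path}).
#' @return An \code{ape::phylo} with an extra logical element
#'   \code{foreground} of length \code{nrow(edge)} (TRUE on tagged branches).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("Newick parse error in: ", substr(text, 1, 60), call. = FALSE)
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch length in tree", call. = FALSE)

  n_tip <- length(tr$tip.label)
  fg_nodes <- integer(0)
  tagged_tips <- grepl("#1$", tr$tip.label)
  if (any(tagged_tips)) {
    fg_nodes <- c(fg_nodes, which(tagged_tips))
    tr$tip.label <- sub("\\s*#1$", "", tr$tip.label)
  }
  if (!is.null(tr$node.label)) {
    tagged_nodes <- grepl("#1$", tr$node.label)
    if (any(tagged_nodes))
      fg_nodes <- c(fg_nodes, n_tip + which(tagged_nodes))
    tr$node.label <- sub("\\s*#1$", "", tr$node.label)
  }
  defaulted <- FALSE
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(0.1, nrow(tr$edge))
    defaulted <- TRUE
  } else if (anyNA(tr$edge.length)) {
    tr$edge.length[is.na(tr$edge.length)] <- 0.1
    defaulted <- TRUE
  }
  tr$foreground <- tr$edge[, 2] %in% fg_nodes
  attr(tr, "default_branch_lengths") <- defaulted
  tr
}

# check that tree leaves and alignment taxa coincide
check_taxa <- function(aln, tree) {
  a <- sort(aln$taxon_names); b <- sort(tree$tip.label)
  if (!identical(a, b))
    stop("taxon mismatch between alignment and tree: only in alignment {",
         paste(setdiff(a, b), collapse = ","), "}, only in tree {",
         paste(setdiff(b, a), collapse = ","), "}", call. = FALSE)
  invisible(TRUE)
}

# Postorder edge traversal encoded for the C++ pruning kernel.
# Nodes are renumbered 0-based: tips 0..n-1 (alignment row order),
# internals follow ape numbering shifted to match.
tree_encoding <- function(tree, aln) {
  check_taxa(aln, tree)
  n_tip <- length(tree$tip.label)
  tip_map <- match(tree$tip.label, aln$taxon_names) # ape tip i -> aln row
  reord <- ape::reorder.phylo(tree, "postorder")
  # map ape node ids to 0-based ids where tips use alignment row order
  node_id <- function(v) ifelse(v <= n_tip, tip_map[v] - 1L, v - 1L)
  fg <- tree$foreground %||% rep(FALSE, nrow(tree$edge))
  # reorder foreground flags to postorder edge order
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  fg <- fg[match(paste(reord$edge[, 1], reord$edge[, 2]), key)]
  parent0 <- as.integer(node_id(reord$edge[, 1]))
  root0 <- as.integer(n_tip) # ape root n_tip+1, 0-based
  list(parent = parent0,
       child = as.integer(node_id(reord$edge[, 2])),
       length = as.numeric(reord$edge.length),
       foreground = as.logical(fg),
       n_tip = n_tip,
       n_node = n_tip + tree$Nnode,
       root = root0,
       # For a bifurcating root only the SUM of the two root-adjacent branch
       # lengths is identifiable under a reversible model (pulley principle);
       # joint branch-length fits tie them to one total, split evenly.
       root_children = which(parent0 == root0))
}
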