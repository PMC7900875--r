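#' Screening configuration for gene-tree subgenome assignment
#'
#' @param maternal_taxa,paternal_taxa diploid taxon labels of the two
#'   parental groups.
#' @param bs_min minimum bootstrap support; clades with support strictly
#'   below it are excluded ("lower than 60" excluded, so 60 passes).
#' @return object of class \code{screen_config}.
#' @export
screen_config <- function(maternal_taxa = c("pr", "re"),
                          paternal_taxa = c("eq", "mi", "mo"),
                          bs_min = 60) {
  if (bs_min < 0 || bs_min > 100) .stopf("bs_min must lie in [0, 100]")
  structure(list(maternal_taxa = maternal_taxa, paternal_taxa = paternal_taxa,
                 bs_min = bs_min), class = "screen_config")
}

# Tip-label sets of every internal node, aligned with tree$node.label.
.node_tipsets <- function(tree) {
  pp <- ape::prop.part(tree)
  lapply(pp, function(idx) tree$tip.label[idx])
}

#' Monophyly and support of a taxon set on an unrooted tree
#'
#' A set is a clade of the unrooted tree when some edge bipartitions the
#' leaves into the set and its complement, i.e. when either the set or its
#' complement is a rooted clade of the stored tree. The bipartition's
#' support is read from the internal-node label (RAxML convention); when
#' both representations carry a label the non-missing one is used.
#'
#' @param tree an \pkg{ape} \code{phylo} object with bootstrap values as
#'   node labels.
#' @param taxa_set character vector of tip labels.
#' @return list with \code{is_monophyletic} and \code{support} (numeric or
#'   NA; NA for the trivial all-leaves set).
#' @export
clade_support <- function(tree, taxa_set) {
  tips <- tree$tip.label
  unknown <- setdiff(taxa_set, tips)
  if (length(unknown))
    .stopf("taxa not in tree: %s", paste(unknown, collapse = ", "))
  if (setequal(taxa_set, tips))
    return(list(is_monophyletic = TRUE, support = NA_real_))
  # pendant edges: a single tip, or everything but one tip, is trivially a
  # clade of the unrooted tree (no internal node carries its support)
  if (length(taxa_set) == 1 || length(taxa_set) == length(tips) - 1)
    return(list(is_monophyletic = TRUE, support = NA_real_))
  sets <- .node_tipsets(tree)
  labels <- tree$node.label
  if (is.null(labels)) labels <- rep(NA_character_, length(sets))
  comp <- setdiff(tips, taxa_set)
  sup_set <- sup_comp <- NA_real_
  found <- FALSE
  for (i in seq_along(sets)) {
    hit_set <- setequal(sets[[i]], taxa_set)
    hit_comp <- setequal(sets[[i]], comp)
    if (hit_set || hit_comp) {
      found <- TRUE
      s <- suppressWarnings(as.numeric(labels[i]))
      if (hit_set && !is.na(s)) sup_set <- s
      if (hit_comp && !is.na(s)) sup_comp <- s
    }
  }
  # the set's own node labels the bipartition; the complement's label is a
  # fallback for trees annotated on the other side of the edge
  list(is_monophyletic = found,
       support = if (!is.na(sup_set)) sup_set else sup_comp)
}

#' Assign a polyploid transcript to a subgenome from its gene tree
#'
#' The transcript is called M when the maternal taxa plus the transcript
#' form a supported clade and the paternal analogue does not (and
#' symmetrically for P); a supported-but-weak clade (bootstrap below
#' \code{bs_min}) excludes the tree. When both augmented sets are clades
#' the transcript sits on the backbone between the two parental groups and
#' is unresolved: an unrooted tree cannot side it.
#'
#' @param tree a \code{phylo} gene tree containing all diploid taxa and the
#'   transcript.
#' @param transcript_label tip label of the polyploid transcript.
#' @param cfg a [screen_config()].
#' @return one of \code{"M"}, \code{"P"}, \code{"excluded"},
#'   \code{"unresolved"}.
#' @export
assign_by_tree <- function(tree, transcript_label, cfg = screen_config()) {
  if (!transcript_label %in% tree$tip.label)
    .stopf("transcript '%s' is not a tip of the tree", transcript_label)
  m <- clade_support(tree, c(cfg$maternal_taxa, transcript_label))
  p <- clade_support(tree, c(cfg$paternal_taxa, transcript_label))
  if (m$is_monophyletic && p$is_monophyletic) return("unresolved")
  side <- if (m$is_monophyletic) m else if (p$is_monophyletic) p else NULL
  if (is.null(side)) return("unresolved")
  if (!is.na(side$support) && side$support < cfg$bs_min) return("excluded")
  if (m$is_monophyletic) "M" else "P"
}

#' Screen a table of newick gene trees
#'
#' @param newick character vector of newick strings, one tree per
#'   transcript.
#' @param transcript_labels tip label of the transcript in each tree.
#' @param cfg a [screen_config()].
#' @return data frame with \code{transcript}, \code{call}.
#' @export
screen_gene_trees <- function(newick, transcript_labels, cfg = screen_config()) {
  stopifnot(length(newick) == length(transcript_labels))
  calls <- vapply(seq_along(newick), function(i) {
    tree <- ape::read.tree(text = newick[i])
    assign_by_tree(tree, transcript_labels[i], cfg)
  }, "")
  data.frame(transcript = transcript_labels, call = calls,
             stringsAsFactors = FALSE)
}
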