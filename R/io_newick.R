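#' Write a phylogenetic tree in Newick format
#'
#' Serialises an `ape` `phylo` object with branch lengths printed to six
#' decimals and internal node labels (bootstrap support) when present.
#' Leaf labels containing Newick metacharacters are single-quoted; labels
#' containing newlines cannot be quoted and raise an error.
#'
#' @param tree `phylo` object.
#' @param path output file.
#' @return invisibly, the Newick string.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) stop("write_newick: duplicate leaf labels")
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt_label <- function(lab) {
    if (is.na(lab) || !nzchar(lab)) return("")
    if (grepl("[\n\r]", lab)) stop("write_newick: label contains newline: ", lab)
    if (grepl("[](),:;'\"\t []", lab))
      paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
    else lab
  }
  rec <- function(node, edge_idx) {
    if (node <= ntip) {
      s <- fmt_label(tree$tip.label[node])
    } else {
      kids <- children[[as.character(node)]]
      inner <- paste(vapply(kids, function(e) rec(tree$edge[e, 2L], e),
                            character(1)), collapse = ",")
      sup <- if (!is.null(tree$node.label)) fmt_label(tree$node.label[node - ntip]) else ""
      s <- paste0("(", inner, ")", sup)
    }
    if (!is.na(edge_idx) && !is.null(tree$edge.length))
      s <- paste0(s, ":", sprintf("%.6f", tree$edge.length[edge_idx]))
    s
  }
  str <- paste0(rec(ntip + 1L, NA_integer_), ";")
  writeLines(str, path)
  invisible(str)
}
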