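#' Write a ledger-annotated tree as phyloXML
#'
#' Emits one `<phylogeny rooted="true">` with nested `<clade>` elements
#' carrying the node name and, when a ledger is given, `<property>`
#' elements (`dom:present_count`, `dom:gained_count`, `dom:lost_count`,
#' and optionally `dom:gained` / `dom:lost` comma-joined domain lists).
#' The file is viewable with Archaeopteryx-class phyloXML viewers.
#'
#' @param tree a [rooted_tree()].
#' @param path output path.
#' @param ledger optional `event_ledger` from [reconstruct()].
#' @param domain_lists also attach the per-branch gained/lost domain
#'   lists (not only counts).
#' @return Invisibly, `path`.
#' @export
write_phyloxml <- function(tree, path, ledger = NULL,
                           domain_lists = FALSE) {
  doc <- xml2::xml_new_root(
    "phyloxml",
    xmlns = "http://www.phyloxml.org")
  phylo <- xml2::xml_add_child(doc, "phylogeny", rooted = "true")
  root_name <- tree$labels[tree$root]
  add_prop <- function(node, ref, value) {
    p <- xml2::xml_add_child(node, "property",
                             ref = ref, datatype = "xsd:string",
                             applies_to = "clade")
    xml2::xml_text(p) <- as.character(value)
  }
  build <- function(parent_xml, nd) {
    cl <- xml2::xml_add_child(parent_xml, "clade")
    nm <- xml2::xml_add_child(cl, "name")
    xml2::xml_text(nm) <- tree$labels[nd]
    if (!is.null(ledger)) {
      name <- tree$labels[nd]
      gained <- if (name == root_name) ledger$root_gains
                else ledger$gains[[name]]
      add_prop(cl, "dom:present_count", length(ledger$present[[name]]))
      add_prop(cl, "dom:gained_count", length(gained))
      add_prop(cl, "dom:lost_count", length(ledger$losses[[name]]))
      if (domain_lists) {
        add_prop(cl, "dom:gained", paste(gained, collapse = ","))
        add_prop(cl, "dom:lost",
                 paste(ledger$losses[[name]], collapse = ","))
      }
    }
    for (ch in tree$children[[nd]]) build(cl, ch)
  }
  build(phylo, tree$root)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a phyloXML file written by [write_phyloxml()]
#'
#' @param path phyloXML file path.
#' @return List with `tree` (a [rooted_tree()]) and `properties` (data
#'   frame: `node`, `ref`, `value`).
#' @export
read_phyloxml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  root_clade <- xml2::xml_find_first(doc, "./phylogeny/clade")
  if (inherits(root_clade, "xml_missing"))
    stop("no <phylogeny>/<clade> in ", path)
  props <- list()
  newick_of <- function(cl) {
    name <- xml2::xml_text(xml2::xml_find_first(cl, "./name"))
    for (p in xml2::xml_find_all(cl, "./property")) {
      props[[length(props) + 1L]] <<- data.frame(
        node = name, ref = xml2::xml_attr(p, "ref"),
        value = xml2::xml_text(p), stringsAsFactors = FALSE)
    }
    kids <- xml2::xml_find_all(cl, "./clade")
    if (length(kids) == 0L) return(name)
    paste0("(", paste(vapply(kids, newick_of, ""), collapse = ","),
           ")", name)
  }
  nw <- paste0(newick_of(root_clade), ";")
  list(tree = rooted_tree(nw),
       properties = if (length(props)) do.call(rbind, props)
                    else data.frame(node = character(0),
                                    ref = character(0),
                                    value = character(0)))
}
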