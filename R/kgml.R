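#' Classify KGML relation subtypes into an edge sign
#'
#' KEGG annotates relations with mechanism subtypes. Phosphorylation,
#' dephosphorylation, indirect effects, expression and compound-mediated
#' relations are read as activations unless an inhibitory label is also
#' present; ubiquitination, inhibition and repression are read as
#' inhibitions. A relation labeled both phosphorylation and inhibition is a
#' phosphorylation that inhibits the next node, i.e. an inhibition edge.
#'
#' @param subtypes Character vector of KGML subtype names (non-empty).
#' @return `"inhibition"` if any inhibitory label is present, otherwise
#'   `"activation"`. Unknown labels trigger a warning and count as
#'   activations.
#' @examples
#' classify_relation("expression")                      # activation
#' classify_relation("ubiquitination")                  # inhibition
#' classify_relation(c("phosphorylation", "inhibition")) # inhibition
#' @export
classify_relation <- function(subtypes) {
  subtypes <- tolower(as.character(subtypes))
  if (length(subtypes) == 0L)
    stop("classify_relation: empty subtype list")
  inhibitory <- c("inhibition", "repression", "ubiquitination")
  activating <- c("activation", "expression", "phosphorylation",
                  "dephosphorylation", "indirect", "indirect effect",
                  "compound", "hidden compound", "state change",
                  "binding/association", "glycosylation", "methylation")
  unknown <- setdiff(subtypes, c(inhibitory, activating))
  if (length(unknown))
    warning("unknown relation subtype(s) treated as activation: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  if (any(subtypes %in% inhibitory)) "inhibition" else "activation"
}

#' Parse a KGML pathway description into a pathway graph
#'
#' Reads a KEGG Markup Language (KGML, >= v0.7.0) document and builds the
#' signed directed graph used throughout the package. Gene entries with
#' several gene names become `alternatives` nodes; `group` entries and
#' endpoints of binding/association relations are merged into a single
#' `complex` node whose members must be simultaneously active; compound
#' entries are spliced out, the flanking gene nodes being connected by a
#' direct activation edge; `map` entries (links to other pathways) are
#' dropped with a warning, since each pathway is modeled independently.
#' Node ids are namespaced by the pathway id so multi-pathway runs cannot
#' collide.
#'
#' @param x Path to a KGML file, or a KGML document as a single string.
#' @return A [pathway_graph].
#' @seealso [read_pathway_json()] for the JSON fixture dialect.
#' @export
parse_kgml <- function(x) {
  doc <- tryCatch(xml2::read_xml(x), error = function(e)
    stop("malformed KGML document: ", conditionMessage(e), call. = FALSE))
  root <- xml2::xml_name(doc)
  if (root != "pathway")
    stop("malformed KGML: root element is <", root, ">, expected <pathway>")
  pid <- xml2::xml_attr(doc, "name")
  if (is.na(pid) || pid == "") pid <- "pathway"
  pid <- sub("^path:", "", pid)

  entries <- xml2::xml_find_all(doc, "./entry")
  ids <- xml2::xml_attr(entries, "id")
  types <- xml2::xml_attr(entries, "type")
  names_attr <- xml2::xml_attr(entries, "name")
  if (anyNA(ids))
    stop("malformed KGML: <entry> without id attribute")

  keep <- rep(TRUE, length(entries))
  if (any(types %in% c("map", "maplink"))) {
    warning("dropping ", sum(types %in% c("map", "maplink")),
            " map-link entr(y/ies) in pathway '", pid,
            "' (cross-pathway links are not modeled)", call. = FALSE)
    keep <- keep & !(types %in% c("map", "maplink"))
  }
  entry_type <- stats::setNames(types, ids)
  entry_genes <- stats::setNames(vector("list", length(ids)), ids)
  group_members <- list()
  for (i in seq_along(entries)) {
    if (!keep[i]) next
    id <- ids[i]
    if (types[i] == "group") {
      comp <- xml2::xml_attr(xml2::xml_find_all(entries[[i]], "./component"),
                             "id")
      if (length(comp) < 2L)
        stop("KGML group entry '", id, "' has fewer than two components")
      group_members[[id]] <- comp
    } else {
      genes <- strsplit(trimws(names_attr[i]), "\\s+")[[1]]
      genes <- genes[genes != "" & genes != "undefined"]
      entry_genes[[id]] <- genes
    }
  }

  # union-find over entry ids: groups and binding/association relations merge
  parent <- stats::setNames(ids[keep], ids[keep])
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[[rb]] <<- ra
    invisible(NULL)
  }
  known <- function(e) e %in% names(parent)
  for (gid in names(group_members)) {
    comp <- group_members[[gid]]
    miss <- comp[!vapply(comp, known, TRUE)]
    if (length(miss))
      stop("KGML group '", gid, "' references unknown entries: ",
           paste(miss, collapse = ", "))
    for (cid in comp) union2(gid, cid)
  }

  relations <- xml2::xml_find_all(doc, "./relation")
  rel <- vector("list", length(relations))
  for (i in seq_along(relations)) {
    e1 <- xml2::xml_attr(relations[[i]], "entry1")
    e2 <- xml2::xml_attr(relations[[i]], "entry2")
    if (is.na(e1) || is.na(e2))
      stop("malformed KGML: <relation> without entry1/entry2")
    if (!known(e1) || !known(e2)) {
      if ((!is.na(entry_type[e1]) && entry_type[e1] %in% c("map", "maplink")) ||
          (!is.na(entry_type[e2]) && entry_type[e2] %in% c("map", "maplink")))
        next  # relation to a dropped map link
      stop("KGML relation references unknown entry: ",
           if (!known(e1)) e1 else e2)
    }
    subtypes <- xml2::xml_attr(
      xml2::xml_find_all(relations[[i]], "./subtype"), "name")
    if (any(tolower(subtypes) %in% c("binding/association", "association"))) {
      union2(e1, e2)  # complex formation, not signal flow
      next
    }
    sign <- if (length(subtypes) == 0L) {
      warning("KGML relation ", e1, "->", e2,
              " has no subtype; treated as activation", call. = FALSE)
      "activation"
    } else classify_relation(subtypes)
    rel[[i]] <- data.frame(from = e1, to = e2, sign = sign,
                           stringsAsFactors = FALSE)
  }
  rel <- do.call(rbind, rel)

  # resolve merged representatives
  roots <- vapply(names(parent), find, "")
  clusters <- split(names(parent), roots)

  node_id_of <- character(0)   # entry id -> final node id
  nodes <- list()
  compound_nodes <- character(0)
  for (members in clusters) {
    genes <- unique(unlist(entry_genes[members], use.names = FALSE))
    mtypes <- entry_type[members]
    real <- members[mtypes != "group"]
    nid <- paste0(pid, ":", paste(sort(as.integer(real)), collapse = "_"))
    if (all(mtypes[mtypes != "group"] == "compound")) {
      compound_nodes <- c(compound_nodes, nid)
      node_id_of[members] <- nid
      next
    }
    if (length(genes) == 0L) {
      node_id_of[members] <- NA_character_
      next  # entries carrying no genes (e.g. undefined orthologs)
    }
    kind <- if (length(genes) == 1L) "single"
            else if (length(real) >= 2L) "complex"
            else "alternatives"
    nodes[[nid]] <- list(kind = kind, genes = genes)
    node_id_of[members] <- nid
  }
  # compound placeholders: keep ids so edges can be spliced through them
  for (nid in compound_nodes) nodes[[nid]] <- list(kind = "single",
                                                   genes = paste0("cpd@", nid))

  edges <- NULL
  if (!is.null(rel)) {
    rel$from <- node_id_of[rel$from]
    rel$to <- node_id_of[rel$to]
    rel <- rel[!is.na(rel$from) & !is.na(rel$to) & rel$from != rel$to, ,
               drop = FALSE]
    edges <- unique(rel)
  }
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        sign = character(), stringsAsFactors = FALSE)

  # splice compound intermediaries: a -> cpd -> b becomes a -> b (activation)
  for (cn in compound_nodes) {
    up <- edges$from[edges$to == cn]
    down <- edges$to[edges$from == cn]
    new <- expand.grid(from = up, to = down, stringsAsFactors = FALSE)
    new <- new[new$from != new$to, , drop = FALSE]
    if (nrow(new)) new$sign <- "activation"
    edges <- edges[edges$from != cn & edges$to != cn, , drop = FALSE]
    if (nrow(new)) edges <- unique(rbind(edges, new))
    nodes[[cn]] <- NULL
  }

  pathway_graph(pid, nodes, edges)
}
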