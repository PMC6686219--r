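# RDF/XML deserialization via xml2.  Covers the constructs OWL tools emit:
# typed node elements, rdf:about / rdf:ID / rdf:nodeID / rdf:resource,
# nested node elements, rdf:parseType="Resource" and "Collection", literal
# properties with rdf:datatype or xml:lang.

rdfxml_state <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  e$bnode <- 0L
  e$base <- ""
  e
}

rx_emit <- function(st, s, p, o, kind, lang = "", dt = "") {
  st$rows[[length(st$rows) + 1L]] <- list(s, p, o, kind, lang, dt)
}

rx_new_bnode <- function(st) {
  st$bnode <- st$bnode + 1L
  sprintf("_:x%d", st$bnode)
}

rx_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else v
}

rx_expand_name <- function(node) {
  # namespace-qualified element name -> absolute IRI
  ns <- xml2::xml_ns(xml2::xml_root(node))
  nm <- xml2::xml_name(node, ns = ns)
  colon <- regexpr(":", nm, fixed = TRUE)
  if (colon < 0L) return(nm)
  prefix <- substr(nm, 1L, colon - 1L)
  local <- substr(nm, colon + 1L, nchar(nm))
  uri <- ns[[prefix]]
  if (is.null(uri) || is.na(uri)) nm else paste0(uri, local)
}

rx_resolve <- function(st, ref) {
  if (grepl("^[A-Za-z][A-Za-z0-9+.-]*:", ref)) ref else paste0(st$base, ref)
}

# A node element: returns the subject term (IRI or blank label).
rx_parse_node <- function(st, node) {
  about  <- rx_attr(node, "rdf:about") %||% rx_attr(node, "about")
  id     <- rx_attr(node, "rdf:ID") %||% rx_attr(node, "ID")
  nodeid <- rx_attr(node, "rdf:nodeID") %||% rx_attr(node, "nodeID")
  subj <- if (!is.null(about)) {
    rx_resolve(st, about)
  } else if (!is.null(id)) {
    rx_resolve(st, paste0("#", id))
  } else if (!is.null(nodeid)) {
    paste0("_:", nodeid)
  } else {
    rx_new_bnode(st)
  }
  name <- rx_expand_name(node)
  if (name != paste0(RDF_NS, "Description")) {
    rx_emit(st, subj, IRI_RDF_TYPE, name, "iri")
  }
  for (child in xml2::xml_children(node)) {
    rx_parse_property(st, subj, child)
  }
  subj
}

rx_parse_property <- function(st, subj, prop) {
  pred <- rx_expand_name(prop)
  resource <- rx_attr(prop, "rdf:resource") %||% rx_attr(prop, "resource")
  nodeid <- rx_attr(prop, "rdf:nodeID") %||% rx_attr(prop, "nodeID")
  ptype <- rx_attr(prop, "rdf:parseType") %||% rx_attr(prop, "parseType")
  if (!is.null(resource)) {
    rx_emit(st, subj, pred, rx_resolve(st, resource), "iri")
    return(invisible())
  }
  if (!is.null(nodeid)) {
    rx_emit(st, subj, pred, paste0("_:", nodeid), "blank")
    return(invisible())
  }
  if (!is.null(ptype) && ptype == "Collection") {
    members <- vapply(xml2::xml_children(prop),
                      function(ch) rx_parse_node(st, ch), "")
    if (length(members) == 0L) {
      rx_emit(st, subj, pred, IRI_RDF_NIL, "iri")
      return(invisible())
    }
    cells <- vapply(members, function(m) rx_new_bnode(st), "")
    rx_emit(st, subj, pred, cells[[1L]], "blank")
    for (k in seq_along(members)) {
      kind <- if (startsWith(members[[k]], "_:")) "blank" else "iri"
      rx_emit(st, cells[[k]], IRI_RDF_FIRST, members[[k]], kind)
      if (k < length(members)) {
        rx_emit(st, cells[[k]], IRI_RDF_REST, cells[[k + 1L]], "blank")
      } else {
        rx_emit(st, cells[[k]], IRI_RDF_REST, IRI_RDF_NIL, "iri")
      }
    }
    return(invisible())
  }
  if (!is.null(ptype) && ptype == "Resource") {
    inner <- rx_new_bnode(st)
    rx_emit(st, subj, pred, inner, "blank")
    for (child in xml2::xml_children(prop)) {
      rx_parse_property(st, inner, child)
    }
    return(invisible())
  }
  kids <- xml2::xml_children(prop)
  if (length(kids) > 0L) {
    obj <- rx_parse_node(st, kids[[1L]])
    kind <- if (startsWith(obj, "_:")) "blank" else "iri"
    rx_emit(st, subj, pred, obj, kind)
    return(invisible())
  }
  dt <- rx_attr(prop, "rdf:datatype") %||% rx_attr(prop, "datatype") %||% ""
  lang <- rx_attr(prop, "xml:lang") %||% rx_attr(prop, "lang") %||% ""
  rx_emit(st, subj, pred, xml2::xml_text(prop), "literal", lang, dt)
  invisible()
}

read_rdfxml_doc <- function(doc) {
  st <- rdfxml_state()
  root <- xml2::xml_root(doc)
  base <- xml2::xml_attr(root, "xml:base")
  if (is.na(base)) base <- xml2::xml_attr(root, "base")
  if (!is.na(base) && !is.null(base)) st$base <- base
  for (node in xml2::xml_children(root)) {
    rx_parse_node(st, node)
  }
  make_triples(st$rows)
}
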