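# OntologyModel: parsed entities, typed axioms, label annotations, imports.
# Triples from either serialization are mapped onto the axiom representation
# in axioms.R; the inverse mapping serializes a model back to Turtle.

OWL_CHARACTERISTIC_TYPES <- c(
  "FunctionalProperty"        = "FunctionalObjectProperty",
  "InverseFunctionalProperty" = "InverseFunctionalObjectProperty",
  "TransitiveProperty"        = "TransitiveObjectProperty",
  "SymmetricProperty"         = "SymmetricObjectProperty",
  "AsymmetricProperty"        = "AsymmetricObjectProperty",
  "ReflexiveProperty"         = "ReflexiveObjectProperty",
  "IrreflexiveProperty"       = "IrreflexiveObjectProperty"
)

BUILTIN_ANNOTATION_PROPERTIES <- c(
  paste0(RDFS_NS, c("label", "comment", "seeAlso", "isDefinedBy")),
  paste0(OWL_NS, c("versionInfo", "deprecated", "backwardCompatibleWith",
                   "incompatibleWith", "priorVersion")),
  paste0(SKOS_NS, c("prefLabel", "altLabel", "definition", "note"))
)

# Structural predicates consumed while assembling expressions / n-ary nodes.
STRUCTURAL_PREDICATES <- c(
  paste0(OWL_NS, c("onProperty", "someValuesFrom", "allValuesFrom",
                   "hasValue", "minCardinality", "maxCardinality",
                   "cardinality", "minQualifiedCardinality",
                   "maxQualifiedCardinality", "qualifiedCardinality",
                   "onClass", "onDataRange", "intersectionOf", "unionOf",
                   "complementOf", "oneOf", "members", "distinctMembers",
                   "sourceIndividual", "assertionProperty",
                   "targetIndividual", "targetValue")),
  IRI_RDF_FIRST, IRI_RDF_REST
)

new_ontology_model <- function() {
  structure(list(
    ontology_iri = "",
    entities = list(
      classes = character(), individuals = character(),
      object_properties = character(), data_properties = character(),
      annotation_properties = character()
    ),
    datatypes = character(),
    axioms = list(),
    label_annotations = data.frame(
      iri = character(), property = character(), value = character(),
      lang = character(), stringsAsFactors = FALSE),
    imports = character(),
    undeclared_properties = character(),
    source = ""
  ), class = "ontology_model")
}

#' @export
print.ontology_model <- function(x, ...) {
  ax <- census_axioms(x)
  el <- census_elements(x)
  cat("<ontology_model> ", if (nzchar(x$ontology_iri)) x$ontology_iri
      else "(anonymous)", "\n", sep = "")
  cat(sprintf("  axioms: %d (%d logical, %d non-logical)\n",
              ax$n_total, ax$n_logical, ax$n_non_logical))
  cat(sprintf("  elements: %d classes, %d individuals, %d object / %d data properties\n",
              el$n_classes, el$n_individuals, el$n_object_properties,
              el$n_data_properties))
  if (length(x$imports)) {
    cat("  imports:", paste(x$imports, collapse = ", "), "\n")
  }
  invisible(x)
}

## ---- triples -> model ----------------------------------------------------

triples_to_model <- function(tr) {
  model <- new_ontology_model()

  objs_of <- function(s, p) {
    tr$object[tr$subject == s & tr$predicate == p]
  }
  rdf_list <- function(node) {
    out <- character()
    while (!identical(node, IRI_RDF_NIL)) {
      f <- objs_of(node, IRI_RDF_FIRST)
      if (length(f) == 0L) break
      out <- c(out, f[[1L]])
      r <- objs_of(node, IRI_RDF_REST)
      if (length(r) == 0L) break
      node <- r[[1L]]
    }
    out
  }

  is_type <- tr$predicate == IRI_RDF_TYPE & tr$obj_kind != "literal"
  typed <- function(type_iri) unique(tr$subject[is_type & tr$object == type_iri])

  onto_subjects <- typed(paste0(OWL_NS, "Ontology"))
  named_onto <- onto_subjects[!startsWith(onto_subjects, "_:")]
  if (length(named_onto)) model$ontology_iri <- named_onto[[1L]]
  model$imports <- unique(tr$object[tr$predicate == paste0(OWL_NS, "imports")])

  decl_kinds <- c(
    Class = paste0(OWL_NS, "Class"),
    NamedIndividual = paste0(OWL_NS, "NamedIndividual"),
    ObjectProperty = paste0(OWL_NS, "ObjectProperty"),
    DataProperty = paste0(OWL_NS, "DatatypeProperty"),
    AnnotationProperty = paste0(OWL_NS, "AnnotationProperty"),
    Datatype = paste0(RDFS_NS, "Datatype")
  )
  declared <- lapply(decl_kinds, function(t) {
    s <- typed(t)
    sort(s[!startsWith(s, "_:")])
  })
  model$entities$classes <- declared$Class
  model$entities$individuals <- declared$NamedIndividual
  model$entities$object_properties <- declared$ObjectProperty
  model$entities$data_properties <- declared$DataProperty
  model$entities$annotation_properties <- declared$AnnotationProperty
  model$datatypes <- declared$Datatype

  axioms <- list()
  add <- function(ax) axioms[[length(axioms) + 1L]] <<- ax

  for (kind in names(decl_kinds)) {
    for (iri in declared[[kind]]) {
      add(axiom("Declaration", entity_kind = kind, iri = iri))
    }
  }

  prop_kind <- function(p) {
    if (p %in% model$entities$object_properties) return("object")
    if (p %in% model$entities$data_properties) return("data")
    if (p %in% model$entities$annotation_properties) return("annotation")
    if (p %in% BUILTIN_ANNOTATION_PROPERTIES) return("annotation")
    "unknown"
  }

  parse_ce <- function(node, kind) {
    if (kind != "blank") return(node)
    get1 <- function(p) {
      v <- objs_of(node, p)
      if (length(v)) v[[1L]] else NULL
    }
    okind <- function(p) {
      k <- tr$obj_kind[tr$subject == node & tr$predicate == p]
      if (length(k)) k[[1L]] else ""
    }
    on_prop <- get1(paste0(OWL_NS, "onProperty"))
    if (!is.null(on_prop)) {
      some <- get1(paste0(OWL_NS, "someValuesFrom"))
      if (!is.null(some)) {
        # punned IRIs keep the class reading; datatype only when unambiguous
        is_datarange <- prop_kind(on_prop) == "data" ||
          startsWith(some, XSD_NS) ||
          (some %in% model$datatypes && !(some %in% model$entities$classes))
        if (is_datarange) {
          return(list(type = "DataSomeValuesFrom", property = on_prop,
                      range = some))
        }
        return(list(type = "ObjectSomeValuesFrom", property = on_prop,
                    filler = parse_ce(some,
                      okind(paste0(OWL_NS, "someValuesFrom")))))
      }
      all_v <- get1(paste0(OWL_NS, "allValuesFrom"))
      if (!is.null(all_v)) {
        return(list(type = "ObjectAllValuesFrom", property = on_prop,
                    filler = parse_ce(all_v,
                      okind(paste0(OWL_NS, "allValuesFrom")))))
      }
      has_v <- get1(paste0(OWL_NS, "hasValue"))
      if (!is.null(has_v)) {
        return(list(type = "ObjectHasValue", property = on_prop,
                    individual = has_v))
      }
      card_preds <- c(
        ObjectMinCardinality = "minCardinality",
        ObjectMinCardinality = "minQualifiedCardinality",
        ObjectMaxCardinality = "maxCardinality",
        ObjectMaxCardinality = "maxQualifiedCardinality",
        ObjectExactCardinality = "cardinality",
        ObjectExactCardinality = "qualifiedCardinality"
      )
      for (k in seq_along(card_preds)) {
        n <- get1(paste0(OWL_NS, card_preds[[k]]))
        if (!is.null(n)) {
          filler <- get1(paste0(OWL_NS, "onClass"))
          out <- list(type = names(card_preds)[[k]],
                      n = as.integer(n), property = on_prop)
          if (!is.null(filler)) {
            out$filler <- parse_ce(filler, okind(paste0(OWL_NS, "onClass")))
          }
          return(out)
        }
      }
    }
    int_of <- get1(paste0(OWL_NS, "intersectionOf"))
    if (!is.null(int_of)) {
      mem <- rdf_list(int_of)
      return(list(type = "ObjectIntersectionOf", operands = lapply(
        mem, function(m) parse_ce(m, if (startsWith(m, "_:")) "blank" else "iri"))))
    }
    un_of <- get1(paste0(OWL_NS, "unionOf"))
    if (!is.null(un_of)) {
      mem <- rdf_list(un_of)
      return(list(type = "ObjectUnionOf", operands = lapply(
        mem, function(m) parse_ce(m, if (startsWith(m, "_:")) "blank" else "iri"))))
    }
    comp <- get1(paste0(OWL_NS, "complementOf"))
    if (!is.null(comp)) {
      return(list(type = "ObjectComplementOf", operand = parse_ce(
        comp, if (startsWith(comp, "_:")) "blank" else "iri")))
    }
    one <- get1(paste0(OWL_NS, "oneOf"))
    if (!is.null(one)) {
      return(list(type = "ObjectOneOf", individuals = as.list(rdf_list(one))))
    }
    abort_ontoqc(sprintf("unrecognized class expression at node %s", node),
                 "ontoqc_format_error")
  }

  # property characteristics via rdf:type
  for (short in names(OWL_CHARACTERISTIC_TYPES)) {
    for (p in typed(paste0(OWL_NS, short))) {
      if (startsWith(p, "_:")) next
      ax_type <- OWL_CHARACTERISTIC_TYPES[[short]]
      if (short == "FunctionalProperty" && prop_kind(p) == "data") {
        ax_type <- "FunctionalDataProperty"
      }
      add(axiom(ax_type, property = p))
    }
  }

  # n-ary helper nodes
  for (node in typed(paste0(OWL_NS, "AllDisjointClasses"))) {
    mem <- rdf_list(objs_of(node, paste0(OWL_NS, "members"))[[1L]])
    add(axiom("DisjointClasses", classes = lapply(
      mem, function(m) parse_ce(m, if (startsWith(m, "_:")) "blank" else "iri"))))
  }
  for (node in typed(paste0(OWL_NS, "AllDifferent"))) {
    lst <- c(objs_of(node, paste0(OWL_NS, "distinctMembers")),
             objs_of(node, paste0(OWL_NS, "members")))
    if (length(lst)) {
      add(axiom("DifferentIndividuals", individuals = as.list(rdf_list(lst[[1L]]))))
    }
  }
  for (node in typed(paste0(OWL_NS, "NegativePropertyAssertion"))) {
    src <- objs_of(node, paste0(OWL_NS, "sourceIndividual"))
    prp <- objs_of(node, paste0(OWL_NS, "assertionProperty"))
    tgt_i <- objs_of(node, paste0(OWL_NS, "targetIndividual"))
    tgt_v_rows <- tr[tr$subject == node &
                       tr$predicate == paste0(OWL_NS, "targetValue"), ]
    if (length(src) && length(prp)) {
      if (length(tgt_i)) {
        add(axiom("NegativeObjectPropertyAssertion", property = prp[[1L]],
                  subject = src[[1L]], object = tgt_i[[1L]]))
      } else if (nrow(tgt_v_rows)) {
        add(axiom("NegativeDataPropertyAssertion", property = prp[[1L]],
                  subject = src[[1L]],
                  value = owl_literal(tgt_v_rows$object[[1L]],
                                      tgt_v_rows$lang[[1L]],
                                      tgt_v_rows$datatype[[1L]])))
      }
    }
  }

  reserved_obj <- function(o) {
    any(vapply(RESERVED_NS, function(ns) startsWith(o, ns), TRUE))
  }
  extra_individuals <- character()
  undeclared <- character()

  for (i in seq_len(nrow(tr))) {
    s <- tr$subject[[i]]; p <- tr$predicate[[i]]; o <- tr$object[[i]]
    kind <- tr$obj_kind[[i]]
    s_kind <- if (startsWith(s, "_:")) "blank" else "iri"
    if (p %in% STRUCTURAL_PREDICATES) next
    if (p == IRI_RDF_TYPE) {
      if (kind == "literal") next
      if (reserved_obj(o)) next                # declarations, vocab typing
      if (s_kind == "blank" &&
          length(objs_of(s, paste0(OWL_NS, "onProperty")))) next
      add(axiom("ClassAssertion", ce = parse_ce(o, kind), individual = s))
      extra_individuals <- c(extra_individuals, s)
      next
    }
    if (p == paste0(OWL_NS, "imports") || p == paste0(OWL_NS, "versionIRI")) next
    if (s == model$ontology_iri && p %in% BUILTIN_ANNOTATION_PROPERTIES) {
      add(axiom("AnnotationAssertion", property = p, subject = s,
                value = if (kind == "literal")
                  owl_literal(o, tr$lang[[i]], tr$datatype[[i]]) else o))
      next
    }
    if (p == paste0(RDFS_NS, "subClassOf")) {
      add(axiom("SubClassOf", sub = parse_ce(s, s_kind),
                sup = parse_ce(o, kind)))
      next
    }
    if (p == paste0(OWL_NS, "equivalentClass")) {
      if (s %in% model$datatypes) {
        add(axiom("DatatypeDefinition", datatype = s, datarange = o))
      } else {
        add(axiom("EquivalentClasses",
                  classes = list(parse_ce(s, s_kind), parse_ce(o, kind))))
      }
      next
    }
    if (p == paste0(OWL_NS, "disjointWith")) {
      add(axiom("DisjointClasses",
                classes = list(parse_ce(s, s_kind), parse_ce(o, kind))))
      next
    }
    if (p == paste0(OWL_NS, "disjointUnionOf")) {
      add(axiom("DisjointUnion", class = s, disjuncts = lapply(
        rdf_list(o), function(m)
          parse_ce(m, if (startsWith(m, "_:")) "blank" else "iri"))))
      next
    }
    if (p == paste0(RDFS_NS, "subPropertyOf")) {
      k <- prop_kind(s)
      add(switch(k,
        data = axiom("SubDataPropertyOf", sub = s, sup = o),
        annotation = axiom("SubAnnotationPropertyOf", sub = s, sup = o),
        axiom("SubObjectPropertyOf", sub = s, sup = o)))
      next
    }
    if (p == paste0(OWL_NS, "equivalentProperty")) {
      add(if (prop_kind(s) == "data") {
        axiom("EquivalentDataProperties", properties = list(s, o))
      } else {
        axiom("EquivalentObjectProperties", properties = list(s, o))
      })
      next
    }
    if (p == paste0(OWL_NS, "propertyDisjointWith")) {
      add(if (prop_kind(s) == "data") {
        axiom("DisjointDataProperties", properties = list(s, o))
      } else {
        axiom("DisjointObjectProperties", properties = list(s, o))
      })
      next
    }
    if (p == paste0(OWL_NS, "inverseOf")) {
      if (s_kind == "iri") {
        add(axiom("InverseObjectProperties", first = s, second = o))
      }
      next
    }
    if (p == paste0(RDFS_NS, "domain")) {
      k <- prop_kind(s)
      add(switch(k,
        data = axiom("DataPropertyDomain", property = s,
                     ce = parse_ce(o, kind)),
        annotation = axiom("AnnotationPropertyDomain", property = s, iri = o),
        axiom("ObjectPropertyDomain", property = s, ce = parse_ce(o, kind))))
      next
    }
    if (p == paste0(RDFS_NS, "range")) {
      k <- prop_kind(s)
      add(switch(k,
        data = axiom("DataPropertyRange", property = s, range = o),
        annotation = axiom("AnnotationPropertyRange", property = s, iri = o),
        axiom("ObjectPropertyRange", property = s, ce = parse_ce(o, kind))))
      next
    }
    if (p == paste0(OWL_NS, "sameAs")) {
      add(axiom("SameIndividual", individuals = list(s, o)))
      next
    }
    if (p == paste0(OWL_NS, "differentFrom")) {
      add(axiom("DifferentIndividuals", individuals = list(s, o)))
      next
    }
    if (p == paste0(OWL_NS, "hasKey")) {
      add(axiom("HasKey", class = s, properties = as.list(rdf_list(o))))
      next
    }
    pk <- prop_kind(p)
    if (pk == "annotation") {
      add(axiom("AnnotationAssertion", property = p, subject = s,
                value = if (kind == "literal")
                  owl_literal(o, tr$lang[[i]], tr$datatype[[i]]) else o))
      next
    }
    if (pk == "object" && kind != "literal") {
      add(axiom("ObjectPropertyAssertion", property = p, subject = s,
                object = o))
      extra_individuals <- c(extra_individuals, s, o)
      next
    }
    if (pk == "data" || (pk == "object" && kind == "literal")) {
      add(axiom("DataPropertyAssertion", property = p, subject = s,
                value = owl_literal(o, tr$lang[[i]], tr$datatype[[i]])))
      extra_individuals <- c(extra_individuals, s)
      next
    }
    # unknown predicate outside the reserved vocabulary
    if (!reserved_obj(p)) undeclared <- c(undeclared, p)
    if (kind == "literal") {
      add(axiom("AnnotationAssertion", property = p, subject = s,
                value = owl_literal(o, tr$lang[[i]], tr$datatype[[i]])))
    } else {
      add(axiom("ObjectPropertyAssertion", property = p, subject = s,
                object = o))
      extra_individuals <- c(extra_individuals, s, o)
    }
  }

  # de-duplicate on the canonical rendering
  keys <- vapply(axioms, axiom_functional, "")
  model$axioms <- axioms[!duplicated(keys)]

  extra_individuals <- setdiff(
    unique(extra_individuals[!startsWith(extra_individuals, "_:")]),
    c(model$entities$individuals, model$entities$classes,
      model$entities$object_properties, model$entities$data_properties,
      model$entities$annotation_properties))
  model$entities$individuals <- sort(unique(c(model$entities$individuals,
                                              extra_individuals)))
  model$undeclared_properties <- sort(unique(undeclared))

  lab <- Filter(function(a) a$type == "AnnotationAssertion" &&
                  is_literal(a$value), model$axioms)
  if (length(lab)) {
    model$label_annotations <- data.frame(
      iri = vapply(lab, function(a) a$subject, ""),
      property = vapply(lab, function(a) a$property, ""),
      value = vapply(lab, function(a) a$value$value, ""),
      lang = vapply(lab, function(a) a$value$lang %||% "", ""),
      stringsAsFactors = FALSE)
  }
  model
}

## ---- loading -------------------------------------------------------------

#' Load an OWL ontology from RDF/XML or Turtle
#'
#' Parses an ontology serialization into an `ontology_model`: typed entity
#' sets, a list of typed axioms, label annotations and the import list.
#' The format is auto-detected from the file extension and content when no
#' hint is given.  Parsing is deterministic: the same file always yields the
#' same model.
#'
#' @param source Path to an ontology file.
#' @param format_hint Optional; `"turtle"` or `"rdfxml"`.  Auto-detected
#'   when `NULL`.
#' @return An object of class `ontology_model`.
#' @seealso [census_axioms()], [census_elements()], [survey_features()],
#'   [merge_imports()]
#' @export
load_ontology <- function(source, format_hint = NULL) {
  if (!is.character(source) || length(source) != 1L || !file.exists(source)) {
    abort_ontoqc(sprintf("ontology file not found: %s", source),
                 "ontoqc_io_error")
  }
  fmt <- format_hint
  if (is.null(fmt)) {
    ext <- tolower(tools::file_ext(source))
    fmt <- if (ext %in% c("ttl", "turtle", "n3")) {
      "turtle"
    } else if (ext %in% c("rdf", "owl", "xml")) {
      "rdfxml"
    } else {
      head_txt <- readChar(source, nchars = 512L, useBytes = TRUE)
      if (grepl("^\\s*<\\?xml|<rdf:RDF", head_txt)) "rdfxml" else "turtle"
    }
  }
  tr <- if (fmt == "turtle") {
    read_turtle_text(paste(readLines(source, warn = FALSE, encoding = "UTF-8"),
                           collapse = "\n"))
  } else if (fmt == "rdfxml") {
    doc <- tryCatch(xml2::read_xml(source),
      error = function(e) abort_ontoqc(
        sprintf("RDF/XML parse failure in '%s': %s", source,
                conditionMessage(e)),
        "ontoqc_format_error"))
    read_rdfxml_doc(doc)
  } else {
    abort_ontoqc(sprintf("unknown format hint '%s'", fmt),
                 "ontoqc_format_error")
  }
  model <- triples_to_model(tr)
  model$source <- source
  model
}

#' Merge the import closure of an ontology
#'
#' With `follow = FALSE` (the default) the model is returned unchanged and a
#' warning lists any unresolved imports: scores are then computed on what is
#' local to the file.  With `follow = TRUE` every import is resolved,
#' loaded, and merged; the merged axiom set is the de-duplicated union over
#' the import closure.  Merging is idempotent.
#'
#' @param model An `ontology_model`.
#' @param follow Follow `owl:imports`?
#' @param import_map Named character vector mapping import IRIs to local
#'   file paths.  An import IRI absent from the map is tried as a file path
#'   relative to the importing file's directory.
#' @return The (possibly merged) `ontology_model`.
#' @export
merge_imports <- function(model, follow = FALSE, import_map = character()) {
  stopifnot(inherits(model, "ontology_model"))
  if (length(model$imports) == 0L) return(model)
  if (!follow) {
    warn_ontoqc(
      paste0("imports not followed; scoring is local to the file. ",
             "Unresolved: ", paste(model$imports, collapse = ", ")),
      "ontoqc_unresolved_imports")
    return(model)
  }
  resolve1 <- function(iri) {
    if (iri %in% names(import_map)) return(import_map[[iri]])
    cand <- file.path(dirname(model$source %||% "."), basename(iri))
    if (file.exists(cand)) return(cand)
    if (file.exists(iri)) return(iri)
    abort_ontoqc(sprintf("cannot resolve import <%s>", iri),
                 "ontoqc_resolution_error")
  }
  merged <- model
  seen <- character()
  queue <- model$imports
  while (length(queue)) {
    iri <- queue[[1L]]
    queue <- queue[-1L]
    if (iri %in% seen) next
    seen <- c(seen, iri)
    imp <- load_ontology(resolve1(iri))
    queue <- c(queue, setdiff(imp$imports, seen))
    merged$axioms <- c(merged$axioms, imp$axioms)
    for (nm in names(merged$entities)) {
      merged$entities[[nm]] <- sort(unique(c(merged$entities[[nm]],
                                             imp$entities[[nm]])))
    }
    merged$datatypes <- sort(unique(c(merged$datatypes, imp$datatypes)))
    merged$label_annotations <- unique(rbind(merged$label_annotations,
                                             imp$label_annotations))
    merged$undeclared_properties <- sort(unique(c(
      merged$undeclared_properties, imp$undeclared_properties)))
  }
  keys <- vapply(merged$axioms, axiom_functional, "")
  merged$axioms <- merged$axioms[!duplicated(keys)]
  merged$imports <- character()
  merged
}

## ---- model -> triples ----------------------------------------------------

DECL_TYPE_IRIS <- c(
  Class = paste0(OWL_NS, "Class"),
  NamedIndividual = paste0(OWL_NS, "NamedIndividual"),
  ObjectProperty = paste0(OWL_NS, "ObjectProperty"),
  DataProperty = paste0(OWL_NS, "DatatypeProperty"),
  AnnotationProperty = paste0(OWL_NS, "AnnotationProperty"),
  Datatype = paste0(RDFS_NS, "Datatype")
)

model_to_triples <- function(model) {
  st <- new.env(parent = emptyenv())
  st$rows <- list()
  st$bnode <- 0L
  emit <- function(s, p, o, kind = "iri", lang = "", dt = "") {
    st$rows[[length(st$rows) + 1L]] <- list(s, p, o, kind, lang, dt)
  }
  new_bn <- function() {
    st$bnode <- st$bnode + 1L
    sprintf("_:b%d", st$bnode)
  }
  emit_list <- function(members) {
    # members: list of (term, kind); returns head node
    if (length(members) == 0L) return(IRI_RDF_NIL)
    cells <- vapply(members, function(m) new_bn(), "")
    for (k in seq_along(members)) {
      emit(cells[[k]], IRI_RDF_FIRST, members[[k]][[1L]], members[[k]][[2L]])
      if (k < length(members)) {
        emit(cells[[k]], IRI_RDF_REST, cells[[k + 1L]], "blank")
      } else {
        emit(cells[[k]], IRI_RDF_REST, IRI_RDF_NIL, "iri")
      }
    }
    cells[[1L]]
  }
  emit_ce <- function(ce) {
    # returns c(term, kind)
    if (is.character(ce)) return(c(ce, "iri"))
    node <- new_bn()
    owl <- function(x) paste0(OWL_NS, x)
    switch(ce$type,
      ObjectIntersectionOf = ,
      ObjectUnionOf = {
        emit(node, IRI_RDF_TYPE, owl("Class"))
        pred <- if (ce$type == "ObjectIntersectionOf") "intersectionOf"
                else "unionOf"
        head <- emit_list(lapply(ce$operands, emit_ce))
        emit(node, owl(pred), head, if (startsWith(head, "_:")) "blank" else "iri")
      },
      ObjectComplementOf = {
        emit(node, IRI_RDF_TYPE, owl("Class"))
        inner <- emit_ce(ce$operand)
        emit(node, owl("complementOf"), inner[[1L]], inner[[2L]])
      },
      ObjectOneOf = {
        emit(node, IRI_RDF_TYPE, owl("Class"))
        head <- emit_list(lapply(ce$individuals, function(i) c(i, "iri")))
        emit(node, owl("oneOf"), head, if (startsWith(head, "_:")) "blank" else "iri")
      },
      ObjectSomeValuesFrom = ,
      ObjectAllValuesFrom = {
        emit(node, IRI_RDF_TYPE, owl("Restriction"))
        emit(node, owl("onProperty"), ce$property)
        pred <- if (ce$type == "ObjectSomeValuesFrom") "someValuesFrom"
                else "allValuesFrom"
        inner <- emit_ce(ce$filler)
        emit(node, owl(pred), inner[[1L]], inner[[2L]])
      },
      ObjectHasValue = {
        emit(node, IRI_RDF_TYPE, owl("Restriction"))
        emit(node, owl("onProperty"), ce$property)
        emit(node, owl("hasValue"), ce$individual)
      },
      ObjectMinCardinality = ,
      ObjectMaxCardinality = ,
      ObjectExactCardinality = {
        emit(node, IRI_RDF_TYPE, owl("Restriction"))
        emit(node, owl("onProperty"), ce$property)
        pred <- switch(ce$type,
          ObjectMinCardinality = if (is.null(ce$filler)) "minCardinality"
                                 else "minQualifiedCardinality",
          ObjectMaxCardinality = if (is.null(ce$filler)) "maxCardinality"
                                 else "maxQualifiedCardinality",
          if (is.null(ce$filler)) "cardinality" else "qualifiedCardinality")
        emit(node, owl(pred), as.character(ce$n), "literal", "",
             paste0(XSD_NS, "nonNegativeInteger"))
        if (!is.null(ce$filler)) {
          inner <- emit_ce(ce$filler)
          emit(node, owl("onClass"), inner[[1L]], inner[[2L]])
        }
      },
      DataSomeValuesFrom = {
        emit(node, IRI_RDF_TYPE, owl("Restriction"))
        emit(node, owl("onProperty"), ce$property)
        emit(node, owl("someValuesFrom"), ce$range)
      },
      abort_ontoqc(sprintf("cannot serialize expression '%s'", ce$type),
                   "ontoqc_data_error")
    )
    c(node, "blank")
  }
  emit_lit <- function(s, p, lit) {
    emit(s, p, lit$value, "literal", lit$lang %||% "", lit$datatype %||% "")
  }

  if (nzchar(model$ontology_iri)) {
    emit(model$ontology_iri, IRI_RDF_TYPE, paste0(OWL_NS, "Ontology"))
    for (imp in model$imports) {
      emit(model$ontology_iri, paste0(OWL_NS, "imports"), imp)
    }
  }

  owl <- function(x) paste0(OWL_NS, x)
  rdfs <- function(x) paste0(RDFS_NS, x)
  char_pred <- stats::setNames(names(OWL_CHARACTERISTIC_TYPES),
                               OWL_CHARACTERISTIC_TYPES)

  for (ax in model$axioms) {
    switch(ax$type,
      Declaration = emit(ax$iri, IRI_RDF_TYPE, DECL_TYPE_IRIS[[ax$entity_kind]]),
      SubClassOf = {
        s <- emit_ce(ax$sub); o <- emit_ce(ax$sup)
        st$rows[[length(st$rows) + 1L]] <-
          list(s[[1L]], rdfs("subClassOf"), o[[1L]], o[[2L]], "", "")
      },
      EquivalentClasses = {
        s <- emit_ce(ax$classes[[1L]]); o <- emit_ce(ax$classes[[2L]])
        st$rows[[length(st$rows) + 1L]] <-
          list(s[[1L]], owl("equivalentClass"), o[[1L]], o[[2L]], "", "")
      },
      DisjointClasses = {
        if (length(ax$classes) == 2L) {
          s <- emit_ce(ax$classes[[1L]]); o <- emit_ce(ax$classes[[2L]])
          st$rows[[length(st$rows) + 1L]] <-
            list(s[[1L]], owl("disjointWith"), o[[1L]], o[[2L]], "", "")
        } else {
          node <- new_bn()
          emit(node, IRI_RDF_TYPE, owl("AllDisjointClasses"))
          head <- emit_list(lapply(ax$classes, emit_ce))
          emit(node, owl("members"), head, "blank")
        }
      },
      DisjointUnion = {
        head <- emit_list(lapply(ax$disjuncts, emit_ce))
        emit(ax$class, owl("disjointUnionOf"), head, "blank")
      },
      SubObjectPropertyOf = emit(ax$sub, rdfs("subPropertyOf"), ax$sup),
      SubDataPropertyOf = emit(ax$sub, rdfs("subPropertyOf"), ax$sup),
      SubAnnotationPropertyOf = emit(ax$sub, rdfs("subPropertyOf"), ax$sup),
      EquivalentObjectProperties = ,
      EquivalentDataProperties = emit(ax$properties[[1L]],
                                      owl("equivalentProperty"),
                                      ax$properties[[2L]]),
      DisjointObjectProperties = ,
      DisjointDataProperties = emit(ax$properties[[1L]],
                                    owl("propertyDisjointWith"),
                                    ax$properties[[2L]]),
      InverseObjectProperties = emit(ax$first, owl("inverseOf"), ax$second),
      ObjectPropertyDomain = {
        o <- emit_ce(ax$ce)
        st$rows[[length(st$rows) + 1L]] <-
          list(ax$property, rdfs("domain"), o[[1L]], o[[2L]], "", "")
      },
      ObjectPropertyRange = {
        o <- emit_ce(ax$ce)
        st$rows[[length(st$rows) + 1L]] <-
          list(ax$property, rdfs("range"), o[[1L]], o[[2L]], "", "")
      },
      DataPropertyDomain = {
        o <- emit_ce(ax$ce)
        st$rows[[length(st$rows) + 1L]] <-
          list(ax$property, rdfs("domain"), o[[1L]], o[[2L]], "", "")
      },
      DataPropertyRange = emit(ax$property, rdfs("range"), ax$range),
      AnnotationPropertyDomain = emit(ax$property, rdfs("domain"), ax$iri),
      AnnotationPropertyRange = emit(ax$property, rdfs("range"), ax$iri),
      FunctionalObjectProperty = ,
      InverseFunctionalObjectProperty = ,
      ReflexiveObjectProperty = ,
      IrreflexiveObjectProperty = ,
      SymmetricObjectProperty = ,
      AsymmetricObjectProperty = ,
      TransitiveObjectProperty = emit(ax$property, IRI_RDF_TYPE,
                                      owl(char_pred[[ax$type]])),
      FunctionalDataProperty = emit(ax$property, IRI_RDF_TYPE,
                                    owl("FunctionalProperty")),
      SameIndividual = emit(ax$individuals[[1L]], owl("sameAs"),
                            ax$individuals[[2L]]),
      DifferentIndividuals = {
        if (length(ax$individuals) == 2L) {
          emit(ax$individuals[[1L]], owl("differentFrom"),
               ax$individuals[[2L]])
        } else {
          node <- new_bn()
          emit(node, IRI_RDF_TYPE, owl("AllDifferent"))
          head <- emit_list(lapply(ax$individuals, function(i) c(i, "iri")))
          emit(node, owl("members"), head, "blank")
        }
      },
      ClassAssertion = {
        o <- emit_ce(ax$ce)
        st$rows[[length(st$rows) + 1L]] <-
          list(ax$individual, IRI_RDF_TYPE, o[[1L]], o[[2L]], "", "")
      },
      ObjectPropertyAssertion = emit(ax$subject, ax$property, ax$object),
      NegativeObjectPropertyAssertion = {
        node <- new_bn()
        emit(node, IRI_RDF_TYPE, owl("NegativePropertyAssertion"))
        emit(node, owl("sourceIndividual"), ax$subject)
        emit(node, owl("assertionProperty"), ax$property)
        emit(node, owl("targetIndividual"), ax$object)
      },
      DataPropertyAssertion = emit_lit(ax$subject, ax$property, ax$value),
      NegativeDataPropertyAssertion = {
        node <- new_bn()
        emit(node, IRI_RDF_TYPE, owl("NegativePropertyAssertion"))
        emit(node, owl("sourceIndividual"), ax$subject)
        emit(node, owl("assertionProperty"), ax$property)
        emit_lit(node, owl("targetValue"), ax$value)
      },
      HasKey = {
        head <- emit_list(lapply(ax$properties, function(p) c(p, "iri")))
        emit(ax$class, owl("hasKey"), head, "blank")
      },
      DatatypeDefinition = emit(ax$datatype, owl("equivalentClass"),
                                ax$datarange),
      AnnotationAssertion = {
        if (is_literal(ax$value)) {
          emit_lit(ax$subject, ax$property, ax$value)
        } else {
          emit(ax$subject, ax$property, ax$value)
        }
      },
      abort_ontoqc(sprintf("cannot serialize axiom '%s'", ax$type),
                   "ontoqc_data_error")
    )
  }
  make_triples(st$rows)
}

#' Write an ontology model as Turtle
#'
#' Serializes with one absolute-IRI triple per line, sorted, so the output
#' is byte-stable for a fixed model.
#'
#' @param model An `ontology_model`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_ontology <- function(model, path) {
  write_turtle_triples(model_to_triples(model), path)
}
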