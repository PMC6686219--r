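# RDF triples and the Turtle serialization.
#
# Triples live in a plain data.frame with columns subject, predicate,
# object, obj_kind ("iri" | "blank" | "literal"), lang, datatype.  Blank
# nodes are labelled "_:bN".  The reader covers the Turtle constructs OWL
# serializations actually use: @prefix/@base (and SPARQL PREFIX/BASE),
# prefixed names, 'a', literal language tags and datatypes, ';' and ','
# lists, anonymous nodes '[ ... ]' and collections '( ... )'.

empty_triples <- function() {
  data.frame(
    subject = character(), predicate = character(), object = character(),
    obj_kind = character(), lang = character(), datatype = character(),
    stringsAsFactors = FALSE
  )
}

make_triples <- function(rows) {
  if (length(rows) == 0L) return(empty_triples())
  data.frame(
    subject   = vapply(rows, `[[`, "", 1L),
    predicate = vapply(rows, `[[`, "", 2L),
    object    = vapply(rows, `[[`, "", 3L),
    obj_kind  = vapply(rows, `[[`, "", 4L),
    lang      = vapply(rows, `[[`, "", 5L),
    datatype  = vapply(rows, `[[`, "", 6L),
    stringsAsFactors = FALSE
  )
}

## ---- tokenizer -----------------------------------------------------------

TTL_TOKEN_RE <- paste0(
  "^(?:",
  "(?<IRIREF><[^<>\"{}|^`\\\\[:space:]]*>)",
  "|(?<STRING>\"\"\"(?:[^\"\\\\]|\\\\.|\"(?!\"\"))*\"\"\"|\"(?:[^\"\\\\\\n]|\\\\.)*\")",
  "|(?<KW>@prefix|@base|PREFIX|BASE|a|true|false)(?![A-Za-z0-9_:-])",
  "|(?<LANGTAG>@[A-Za-z]+(?:-[A-Za-z0-9]+)*)",
  "|(?<DDHAT>\\^\\^)",
  "|(?<BLANK>_:[A-Za-z0-9][A-Za-z0-9_.-]*)",
  "|(?<PNAME>[A-Za-z][A-Za-z0-9_.-]*)?:(?<LOCAL>[A-Za-z0-9_%](?:[A-Za-z0-9_.%-]*[A-Za-z0-9_%-])?)?",
  "|(?<NUM>[+-]?[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?)",
  "|(?<PUNCT>[.;,\\[\\]()])",
  ")"
)

ttl_tokenize <- function(text) {
  tokens <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    ws <- regmatches(rest, regexpr("^[[:space:]]+", rest))
    if (length(ws) == 1L) {
      pos <- pos + nchar(ws)
      next
    }
    if (substr(text, pos, pos) == "#") {
      nl <- regexpr("\n", substr(text, pos, n), fixed = TRUE)
      if (nl < 0L) break
      pos <- pos + nl
      next
    }
    rest <- substr(text, pos, n)
    m <- regexpr(TTL_TOKEN_RE, rest, perl = TRUE)
    if (m < 0L) {
      line <- length(gregexpr("\n", substr(text, 1L, pos))[[1]]) + 1L
      abort_ontoqc(
        sprintf("Turtle syntax error near line %d: ...%s", line,
                substr(rest, 1L, 40L)),
        "ontoqc_format_error"
      )
    }
    tok <- regmatches(rest, m)
    type <- "OTHER"
    starts <- attr(m, "capture.start")[1L, ]
    for (nm in names(starts)) {
      if (starts[[nm]] > 0L) { type <- nm; break }
    }
    if (type == "LOCAL") type <- "PNAME"
    # the PNAME branch is the only one whose named groups are all optional:
    # a match with no captured group is a bare ":" / ":local" / "prefix:"
    if (type == "OTHER") type <- "PNAME"
    tokens[[length(tokens) + 1L]] <- list(type = type, text = tok)
    pos <- pos + nchar(tok)
  }
  tokens
}

ttl_unescape <- function(s) {
  if (!grepl("\\\\", s)) return(s)
  out <- character()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "\\" && i < n) {
      nxt <- substr(s, i + 1L, i + 1L)
      if (nxt == "u") {
        out <- c(out, intToUtf8(strtoi(substr(s, i + 2L, i + 5L), 16L)))
        i <- i + 6L
      } else if (nxt == "U") {
        out <- c(out, intToUtf8(strtoi(substr(s, i + 2L, i + 9L), 16L)))
        i <- i + 10L
      } else {
        out <- c(out, switch(nxt,
          n = "\n", t = "\t", r = "\r", b = "\b", f = "\f",
          `"` = "\"", `'` = "'", `\\` = "\\", nxt))
        i <- i + 2L
      }
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  paste0(out, collapse = "")
}

## ---- parser --------------------------------------------------------------

# Mutable parser state via environment.
ttl_state <- function(tokens) {
  e <- new.env(parent = emptyenv())
  e$tokens <- tokens
  e$i <- 1L
  e$prefixes <- c(rdf = RDF_NS, rdfs = RDFS_NS, owl = OWL_NS, xsd = XSD_NS)
  e$base <- ""
  e$bnode <- 0L
  e$rows <- vector("list", 256L)
  e$nrow <- 0L
  e
}

ttl_peek <- function(st) if (st$i <= length(st$tokens)) st$tokens[[st$i]] else NULL
ttl_next <- function(st) { tk <- ttl_peek(st); st$i <- st$i + 1L; tk }
ttl_expect <- function(st, text) {
  tk <- ttl_next(st)
  if (is.null(tk) || tk$text != text)
    abort_ontoqc(sprintf("Turtle parse error: expected '%s', got '%s'", text,
                         if (is.null(tk)) "<eof>" else tk$text),
                 "ontoqc_format_error")
  tk
}

ttl_emit <- function(st, s, p, o, kind, lang = "", dt = "") {
  st$nrow <- st$nrow + 1L
  if (st$nrow > length(st$rows)) length(st$rows) <- 2L * length(st$rows)
  st$rows[[st$nrow]] <- list(s, p, o, kind, lang, dt)
}

ttl_new_bnode <- function(st) {
  st$bnode <- st$bnode + 1L
  sprintf("_:b%d", st$bnode)
}

ttl_resolve_iri <- function(st, iriref) {
  iri <- substr(iriref, 2L, nchar(iriref) - 1L)
  if (nzchar(st$base) && !grepl("^[A-Za-z][A-Za-z0-9+.-]*:", iri)) {
    iri <- paste0(st$base, iri)
  }
  iri
}

ttl_resolve_pname <- function(st, pname) {
  colon <- regexpr(":", pname, fixed = TRUE)
  prefix <- substr(pname, 1L, colon - 1L)
  local <- substr(pname, colon + 1L, nchar(pname))
  idx <- match(prefix, names(st$prefixes))
  ns <- if (is.na(idx)) NULL else st$prefixes[[idx]]
  if (is.null(ns) || is.na(ns))
    abort_ontoqc(sprintf("Turtle parse error: undefined prefix '%s:'", prefix),
                 "ontoqc_format_error")
  # percent-decode
  if (grepl("%", local, fixed = TRUE)) local <- utils::URLdecode(local)
  paste0(ns, local)
}

# Returns list(value=, kind=, lang=, datatype=)
ttl_parse_object <- function(st) {
  tk <- ttl_peek(st)
  if (is.null(tk))
    abort_ontoqc("Turtle parse error: unexpected end of input",
                 "ontoqc_format_error")
  if (tk$type == "IRIREF") {
    ttl_next(st)
    return(list(value = ttl_resolve_iri(st, tk$text), kind = "iri",
                lang = "", datatype = ""))
  }
  if (tk$type == "PNAME") {
    ttl_next(st)
    return(list(value = ttl_resolve_pname(st, tk$text), kind = "iri",
                lang = "", datatype = ""))
  }
  if (tk$type == "BLANK") {
    ttl_next(st)
    return(list(value = tk$text, kind = "blank", lang = "", datatype = ""))
  }
  if (tk$type == "KW" && tk$text == "a") {
    abort_ontoqc("Turtle parse error: 'a' in object position",
                 "ontoqc_format_error")
  }
  if (tk$type == "KW" && tk$text %in% c("true", "false")) {
    ttl_next(st)
    return(list(value = tk$text, kind = "literal", lang = "",
                datatype = paste0(XSD_NS, "boolean")))
  }
  if (tk$type == "NUM") {
    ttl_next(st)
    dt <- if (grepl("[.eE]", tk$text)) paste0(XSD_NS, "decimal")
          else paste0(XSD_NS, "integer")
    return(list(value = tk$text, kind = "literal", lang = "", datatype = dt))
  }
  if (tk$type == "STRING") {
    ttl_next(st)
    raw <- tk$text
    body <- if (startsWith(raw, "\"\"\"")) {
      substr(raw, 4L, nchar(raw) - 3L)
    } else {
      substr(raw, 2L, nchar(raw) - 1L)
    }
    value <- ttl_unescape(body)
    lang <- ""
    dt <- ""
    nxt <- ttl_peek(st)
    if (!is.null(nxt) && nxt$type == "LANGTAG") {
      ttl_next(st)
      lang <- substr(nxt$text, 2L, nchar(nxt$text))
    } else if (!is.null(nxt) && nxt$type == "DDHAT") {
      ttl_next(st)
      dt_tk <- ttl_next(st)
      dt <- if (dt_tk$type == "IRIREF") ttl_resolve_iri(st, dt_tk$text)
            else ttl_resolve_pname(st, dt_tk$text)
    }
    return(list(value = value, kind = "literal", lang = lang, datatype = dt))
  }
  if (tk$text == "[") {
    ttl_next(st)
    node <- ttl_new_bnode(st)
    nxt <- ttl_peek(st)
    if (!is.null(nxt) && nxt$text == "]") {
      ttl_next(st)
    } else {
      ttl_parse_predicate_object_list(st, node)
      ttl_expect(st, "]")
    }
    return(list(value = node, kind = "blank", lang = "", datatype = ""))
  }
  if (tk$text == "(") {
    ttl_next(st)
    items <- list()
    while (!is.null(ttl_peek(st)) && ttl_peek(st)$text != ")") {
      items[[length(items) + 1L]] <- ttl_parse_object(st)
    }
    ttl_expect(st, ")")
    if (length(items) == 0L)
      return(list(value = IRI_RDF_NIL, kind = "iri", lang = "", datatype = ""))
    nodes <- vapply(seq_along(items), function(k) ttl_new_bnode(st), "")
    for (k in seq_along(items)) {
      it <- items[[k]]
      ttl_emit(st, nodes[[k]], IRI_RDF_FIRST, it$value, it$kind, it$lang,
               it$datatype)
      rest <- if (k < length(items)) nodes[[k + 1L]] else IRI_RDF_NIL
      rest_kind <- if (k < length(items)) "blank" else "iri"
      ttl_emit(st, nodes[[k]], IRI_RDF_REST, rest, rest_kind)
    }
    return(list(value = nodes[[1L]], kind = "blank", lang = "", datatype = ""))
  }
  abort_ontoqc(sprintf("Turtle parse error: unexpected token '%s'", tk$text),
               "ontoqc_format_error")
}

ttl_parse_predicate_object_list <- function(st, subject) {
  repeat {
    tk <- ttl_next(st)
    if (is.null(tk))
      abort_ontoqc("Turtle parse error: unexpected end in predicate list",
                   "ontoqc_format_error")
    pred <- if (tk$type == "KW" && tk$text == "a") {
      IRI_RDF_TYPE
    } else if (tk$type == "IRIREF") {
      ttl_resolve_iri(st, tk$text)
    } else if (tk$type == "PNAME") {
      ttl_resolve_pname(st, tk$text)
    } else {
      abort_ontoqc(sprintf("Turtle parse error: bad predicate '%s'", tk$text),
                   "ontoqc_format_error")
    }
    repeat {
      obj <- ttl_parse_object(st)
      ttl_emit(st, subject, pred, obj$value, obj$kind, obj$lang, obj$datatype)
      nxt <- ttl_peek(st)
      if (!is.null(nxt) && nxt$text == ",") { ttl_next(st); next }
      break
    }
    nxt <- ttl_peek(st)
    if (!is.null(nxt) && nxt$text == ";") {
      ttl_next(st)
      # allow trailing ';' before '.' or ']'
      nxt2 <- ttl_peek(st)
      if (!is.null(nxt2) && nxt2$text %in% c(".", "]")) break
      next
    }
    break
  }
}

read_turtle_text <- function(text) {
  st <- ttl_state(ttl_tokenize(text))
  repeat {
    tk <- ttl_peek(st)
    if (is.null(tk)) break
    if (tk$type == "KW" && tk$text %in% c("@prefix", "PREFIX")) {
      ttl_next(st)
      pn <- ttl_next(st)   # PNAME with empty local, e.g. "ex:" or ":"
      iri <- ttl_next(st)
      prefix <- sub(":.*$", "", pn$text)
      val <- ttl_resolve_iri(st, iri$text)
      idx <- match(prefix, names(st$prefixes))
      if (is.na(idx)) {
        st$prefixes <- c(st$prefixes, stats::setNames(val, prefix))
      } else {
        st$prefixes[[idx]] <- val
      }
      if (tk$text == "@prefix") ttl_expect(st, ".")
      next
    }
    if (tk$type == "KW" && tk$text %in% c("@base", "BASE")) {
      ttl_next(st)
      iri <- ttl_next(st)
      st$base <- ttl_resolve_iri(st, iri$text)
      if (tk$text == "@base") ttl_expect(st, ".")
      next
    }
    subj <- ttl_parse_object(st)
    if (!subj$kind %in% c("iri", "blank"))
      abort_ontoqc("Turtle parse error: literal in subject position",
                   "ontoqc_format_error")
    nxt <- ttl_peek(st)
    if (!is.null(nxt) && nxt$text == "." &&
        is_blank_node(subj$value)) {
      ttl_next(st)  # bare blank-node property list as a statement
      next
    }
    ttl_parse_predicate_object_list(st, subj$value)
    ttl_expect(st, ".")
  }
  make_triples(st$rows[seq_len(st$nrow)])
}

## ---- writer --------------------------------------------------------------

ttl_escape_literal <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  s
}

ttl_term <- function(value, kind, lang = "", datatype = "") {
  if (kind == "iri") return(paste0("<", value, ">"))
  if (kind == "blank") return(value)
  lit <- paste0("\"", ttl_escape_literal(value), "\"")
  if (nzchar(lang)) return(paste0(lit, "@", lang))
  if (nzchar(datatype)) return(paste0(lit, "^^<", datatype, ">"))
  lit
}

# One triple per line, absolute IRIs, lexicographically sorted: byte-stable
# for a fixed triple set (blank-node labels included in the sort key).
write_turtle_triples <- function(triples, path) {
  subj_kind <- ifelse(startsWith(triples$subject, "_:"), "blank", "iri")
  lines <- sprintf(
    "%s %s %s .",
    mapply(ttl_term, triples$subject, subj_kind, USE.NAMES = FALSE),
    paste0("<", triples$predicate, ">"),
    mapply(ttl_term, triples$object, triples$obj_kind, triples$lang,
           triples$datatype, USE.NAMES = FALSE)
  )
  lines <- sort(unique(lines), method = "radix")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
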