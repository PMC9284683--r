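# Turtle read/write for the dialect the toolkit produces, plus write-only
# OWL/XML. Output is deterministic (byte-stable ordering, C-locale sorts),
# never emits blank nodes, and uses the graph's declared prefixes. The
# reader supports prefixed names, absolute IRIs, literals with datatype or
# language tag, the 'a' keyword, and ';'/',' statement lists; blank-node
# class expressions and RDF collections are recorded as unsupported with a
# warning rather than silently dropped.

RDF_TYPE  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
RDFS_NS   <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS    <- "http://www.w3.org/2002/07/owl#"
XSD_NS    <- "http://www.w3.org/2001/XMLSchema#"

decl_class_iri <- c(
  "class" = paste0(OWL_NS, "Class"),
  "object-property" = paste0(OWL_NS, "ObjectProperty"),
  "data-property" = paste0(OWL_NS, "DatatypeProperty"),
  "annotation-property" = paste0(OWL_NS, "AnnotationProperty"),
  "individual" = paste0(OWL_NS, "NamedIndividual"))

kind_predicate <- c(
  "subclass-of" = paste0(RDFS_NS, "subClassOf"),
  "equivalent-class" = paste0(OWL_NS, "equivalentClass"),
  "disjoint-with" = paste0(OWL_NS, "disjointWith"),
  "inverse-of" = paste0(OWL_NS, "inverseOf"),
  "domain" = paste0(RDFS_NS, "domain"),
  "range" = paste0(RDFS_NS, "range"))

csort <- function(x) sort(x, method = "radix")

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  out <- character(1)
  chars <- strsplit(x, "")[[1]]
  i <- 1L; buf <- character()
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "\\" && i < length(chars)) {
      nxt <- chars[i + 1L]
      buf <- c(buf, switch(nxt, n = "\n", r = "\r", t = "\t",
                           "\"" = "\"", "\\" = "\\", nxt))
      i <- i + 2L
    } else {
      buf <- c(buf, ch)
      i <- i + 1L
    }
  }
  paste(buf, collapse = "")
}

render_term <- function(iri, prefixes) {
  c <- compact_iri(iri, prefixes)
  if (identical(c, iri)) paste0("<", iri, ">") else c
}

render_literal <- function(object, datatype, lang, prefixes) {
  out <- paste0("\"", escape_literal(object), "\"")
  if (!is.na(lang)) out <- paste0(out, "@", lang)
  else if (!is.na(datatype) && datatype != paste0(XSD_NS, "string"))
    out <- paste0(out, "^^", render_term(datatype, prefixes))
  out
}

#' Serialize an ontology graph to Turtle
#'
#' Deterministic: two calls on the same graph give byte-identical text.
#' Terms are grouped into one subject block each (declaration and
#' rdfs:label first, then predicates and objects in C-locale sorted order);
#' no blank nodes are emitted.
#'
#' @param g a closed ontology_graph
#' @param path optional file path to also write the text to
#' @return the Turtle text (invisibly when `path` is given)
#' @export
write_turtle <- function(g, path = NULL) {
  assert_closed(g)
  p <- g$prefixes
  lines <- sprintf("@prefix %s: <%s> .", names(p), unname(p))
  lines <- csort(lines)

  if (!is.na(g$ontology_iri))
    lines <- c(lines, "",
               paste0(render_term(g$ontology_iri, p), " a ",
                      render_term(paste0(OWL_NS, "Ontology"), p), " ."))

  ax <- g$axioms
  subjects <- csort(unique(g$terms$iri))
  for (s in subjects) {
    i <- match(s, g$terms$iri)
    a_objs <- render_term(decl_class_iri[[g$terms$category[i]]], p)
    if (any(ax$kind == "transitive-property" & ax$subject == s))
      a_objs <- c(a_objs, render_term(paste0(OWL_NS, "TransitiveObjectProperty"), p))
    ty <- ax[ax$kind == "type-assertion" & ax$subject == s, , drop = FALSE]
    if (nrow(ty))
      a_objs <- c(a_objs, csort(vapply(ty$object, render_term, "",
                                       prefixes = p)))
    po <- list(a = a_objs)
    if (!is.na(g$terms$label[i]))
      po[[render_term(paste0(RDFS_NS, "label"), p)]] <-
        render_literal(g$terms$label[i], NA_character_, NA_character_, p)
    rest <- ax[ax$subject == s &
                 !ax$kind %in% c("type-assertion", "transitive-property"), ,
               drop = FALSE]
    for (j in seq_len(nrow(rest))) {
      row <- rest[j, ]
      pred <- if (row$kind %in% names(kind_predicate))
        kind_predicate[[row$kind]] else row$predicate
      pred <- render_term(pred, p)
      obj <- if (row$object_type == "literal")
        render_literal(row$object, row$datatype, row$lang, p)
      else render_term(row$object, p)
      po[[pred]] <- c(po[[pred]], obj)
    }
    pred_names <- c("a",
                    csort(setdiff(names(po), "a")))
    block <- vapply(pred_names, function(pn)
      paste0(pn, " ", paste(csort(unique(po[[pn]])), collapse = " , ")), "")
    lines <- c(lines, "",
               paste0(render_term(s, p), " ",
                      paste(block, collapse = " ;\n    "), " ."))
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeChar(txt, con, eos = NULL, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

## ---- Turtle reader ------------------------------------------------------

tokenize_turtle <- function(text) {
  tok_re <- paste0(
    '"""(?s:.*?)"""',
    '|"(?:[^"\\\\\n]|\\\\.)*"',
    "|<[^>]*>",
    "|@prefix|@base",
    "|@[A-Za-z]+(?:-[A-Za-z0-9]+)*",
    "|\\^\\^",
    "|(?:[A-Za-z][A-Za-z0-9_.-]*)?:(?:[A-Za-z0-9_](?:[A-Za-z0-9_.-]*[A-Za-z0-9_-])?)?",
    "|\\ba\\b",
    "|_:[A-Za-z0-9_]+",
    "|[-+]?[0-9]+(?:\\.[0-9]+)?",
    "|[;,.\\[\\]()]",
    "|#[^\n]*")
  m <- gregexpr(tok_re, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(token = character(), line = integer()))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  toks <- substring(text, starts, starts + lens - 1L)
  nl <- gregexpr("\n", text, fixed = TRUE)[[1]]
  nl <- nl[nl > 0]
  line_at <- function(pos) findInterval(pos, nl) + 1L
  # everything between tokens must be whitespace
  gaps_start <- c(1L, starts + lens)
  gaps_end <- c(starts - 1L, nchar(text))
  for (k in seq_along(gaps_start)) {
    if (gaps_start[k] <= gaps_end[k]) {
      gap <- substring(text, gaps_start[k], gaps_end[k])
      if (grepl("[^ \t\r\n]", gap)) {
        stop("Turtle syntax error near line ", line_at(gaps_start[k]),
             ": unexpected '", trimws(gap), "'", call. = FALSE)
      }
    }
  }
  line <- line_at(starts)
  keep <- !startsWith(toks, "#")
  data.frame(token = toks[keep], line = line[keep],
             stringsAsFactors = FALSE)
}

#' Parse Turtle text into an ontology graph
#'
#' Supports the dialect this package writes (see [write_turtle()]).
#' Declarations (`a owl:Class` etc.) populate the term table; rdfs:label
#' triples populate term labels; OWL constructs map to axiom kinds.
#' Undeclared terms are given structurally inferred categories so the result
#' is always closed. Blank nodes, RDF collections and unsupported OWL
#' characteristics (functional properties, property chains) are recorded in
#' the graph's `unsupported` field with a warning.
#'
#' @param input Turtle text or a file path
#' @return a closed ontology_graph
#' @export
read_turtle <- function(input) {
  text <- if (length(input) == 1L && !grepl("\n", input) &&
              file.exists(input)) {
    paste(readLines(input, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  } else paste(input, collapse = "\n")

  tk <- tokenize_turtle(text)
  toks <- tk$token; tlines <- tk$line
  n <- length(toks)
  prefixes <- character()
  stmts <- list()
  unsupported <- character()
  i <- 1L

  perr <- function(msg, at = i) {
    ln <- if (at <= n) tlines[at] else if (n) tlines[n] else 1L
    stop("Turtle parse error at line ", ln, ": ", msg, call. = FALSE)
  }
  peek <- function() if (i <= n) toks[i] else NA_character_
  advance <- function() {
    t <- peek(); i <<- i + 1L
    if (is.na(t)) perr("unexpected end of input", n)
    t
  }
  is_iri_tok <- function(t) !is.na(t) && startsWith(t, "<")
  is_pname <- function(t) !is.na(t) && grepl("^(?:[A-Za-z][A-Za-z0-9_.-]*)?:", t) &&
    !startsWith(t, "_:")
  resolve <- function(t, at = i - 1L) {
    if (is_iri_tok(t)) return(substr(t, 2L, nchar(t) - 1L))
    if (is_pname(t)) {
      m <- regmatches(t, regexec("^([^:]*):(.*)$", t))[[1]]
      ns <- prefixes[m[2]]
      if (is.na(ns)) perr(paste0("unknown prefix '", m[2], "'"), at)
      return(paste0(unname(ns), m[3]))
    }
    perr(paste0("expected IRI or prefixed name, got '", t, "'"), at)
  }
  skip_bracketed <- function(open, close) {
    depth <- 1L
    while (depth > 0L) {
      t <- advance()
      if (t == open) depth <- depth + 1L
      else if (t == close) depth <- depth - 1L
    }
  }
  parse_object <- function() {
    t <- advance()
    if (t == "[") {
      skip_bracketed("[", "]")
      unsupported <<- c(unsupported,
                        sprintf("line %d: blank-node expression", tlines[i - 1L]))
      return(NULL)
    }
    if (t == "(") {
      skip_bracketed("(", ")")
      unsupported <<- c(unsupported,
                        sprintf("line %d: RDF collection", tlines[i - 1L]))
      return(NULL)
    }
    if (startsWith(t, "_:")) {
      unsupported <<- c(unsupported,
                        sprintf("line %d: blank node %s", tlines[i - 1L], t))
      return(NULL)
    }
    if (startsWith(t, "\"")) {
      q <- if (startsWith(t, "\"\"\"")) 3L else 1L
      val <- unescape_literal(substr(t, q + 1L, nchar(t) - q))
      datatype <- NA_character_; lang <- NA_character_
      nxt <- peek()
      if (!is.na(nxt) && nxt == "^^") {
        i <<- i + 1L
        datatype <- resolve(advance())
      } else if (!is.na(nxt) && grepl("^@(?!prefix$|base$)", nxt, perl = TRUE)) {
        lang <- substring(advance(), 2L)
      }
      return(list(type = "literal", value = val, datatype = datatype,
                  lang = lang))
    }
    if (grepl("^[-+]?[0-9]", t)) {
      dt <- if (grepl("\\.", t)) paste0(XSD_NS, "decimal")
            else paste0(XSD_NS, "integer")
      return(list(type = "literal", value = t, datatype = dt,
                  lang = NA_character_))
    }
    if (t == "a") return(list(type = "iri", value = RDF_TYPE))
    list(type = "iri", value = resolve(t))
  }

  while (i <= n) {
    t <- peek()
    if (t %in% c("@prefix", "PREFIX")) {
      i <- i + 1L
      pn <- advance()
      if (!grepl("^[A-Za-z][A-Za-z0-9_.-]*:$|^:$", pn))
        perr("expected prefix name in @prefix directive")
      iri_tok <- advance()
      if (!is_iri_tok(iri_tok)) perr("expected IRI in @prefix directive")
      prefixes[sub(":$", "", pn)] <- substr(iri_tok, 2L, nchar(iri_tok) - 1L)
      if (t == "@prefix") {
        if (advance() != ".") perr("expected '.' after @prefix")
      }
      next
    }
    if (t == "@base") {
      unsupported <- c(unsupported, sprintf("line %d: @base directive",
                                            tlines[i]))
      i <- i + 1L; advance()
      if (peek() == ".") i <- i + 1L
      next
    }
    # subject
    if (t == "[" || startsWith(t, "_:") || t == "(") {
      ln <- tlines[i]
      if (t == "[") { i <- i + 1L; skip_bracketed("[", "]") }
      else if (t == "(") { i <- i + 1L; skip_bracketed("(", ")") }
      else i <- i + 1L
      unsupported <- c(unsupported,
                       sprintf("line %d: blank-node subject", ln))
      while (i <= n && toks[i] != ".") i <- i + 1L
      i <- i + 1L
      next
    }
    subj <- resolve(advance(), i)
    repeat {
      vt <- advance()
      pred <- if (vt == "a") RDF_TYPE else resolve(vt, i - 1L)
      repeat {
        obj <- parse_object()
        if (!is.null(obj))
          stmts[[length(stmts) + 1L]] <-
            list(s = subj, p = pred, o = obj)
        nxt <- advance()
        if (nxt == ",") next
        if (nxt == ";") break
        if (nxt == ".") break
        perr(paste0("expected ',', ';' or '.', got '", nxt, "'"), i - 1L)
      }
      if (nxt == ".") break
      # allow trailing ';' before '.'
      if (!is.na(peek()) && peek() == ".") { i <- i + 1L; break }
    }
  }

  build_graph_from_statements(stmts, prefixes, unsupported)
}

build_graph_from_statements <- function(stmts, prefixes, unsupported) {
  g <- ontology_graph(prefixes = prefixes)
  g$unsupported <- unsupported

  ontology_class <- paste0(OWL_NS, "Ontology")
  transitive_class <- paste0(OWL_NS, "TransitiveObjectProperty")
  unsupported_classes <- c(paste0(OWL_NS, "FunctionalProperty"),
                           paste0(OWL_NS, "InverseFunctionalProperty"),
                           paste0(OWL_NS, "SymmetricProperty"),
                           paste0(OWL_NS, "AsymmetricProperty"),
                           paste0(OWL_NS, "ReflexiveProperty"),
                           paste0(OWL_NS, "IrreflexiveProperty"))
  unsupported_preds <- c(paste0(OWL_NS, "propertyChainAxiom"))
  label_pred <- paste0(RDFS_NS, "label")

  ## pass 1: category assignments
  cat_of <- character()   # iri -> category
  assign_cat <- function(iri, category, force = FALSE) {
    cur <- cat_of[iri]
    if (is.na(cur) || (force && !is.na(cur))) {
      if (is.na(cur)) cat_of[iri] <<- category
    }
  }
  labels <- character()
  ontology_iri <- NA_character_

  decl_cat <- stats::setNames(names(decl_class_iri), unname(decl_class_iri))
  for (st in stmts) {
    if (st$p == RDF_TYPE && st$o$type == "iri") {
      if (st$o$value %in% names(decl_cat)) {
        cat_of[st$s] <- decl_cat[[st$o$value]]
      } else if (st$o$value == ontology_class) {
        ontology_iri <- st$s
      } else if (st$o$value == transitive_class) {
        if (is.na(cat_of[st$s])) cat_of[st$s] <- "object-property"
      }
    }
    if (st$p == label_pred && st$o$type == "literal")
      labels[st$s] <- st$o$value
  }

  # structural inference for anything left undeclared
  infer <- function(iri, category) {
    if (is.na(cat_of[iri])) cat_of[iri] <<- category
  }
  class_preds <- unname(kind_predicate[c("subclass-of", "equivalent-class",
                                         "disjoint-with", "domain", "range")])
  for (st in stmts) {
    if (st$p == RDF_TYPE && st$o$type == "iri") {
      if (!st$o$value %in% c(names(decl_cat), ontology_class,
                             transitive_class, unsupported_classes)) {
        infer(st$o$value, "class")
        infer(st$s, "individual")
      }
      next
    }
    if (st$p == kind_predicate[["inverse-of"]]) {
      infer(st$s, "object-property")
      if (st$o$type == "iri") infer(st$o$value, "object-property")
      next
    }
    if (st$p %in% class_preds) {
      if (st$p %in% kind_predicate[c("domain", "range")]) {
        infer(st$s, "object-property")
      } else infer(st$s, "class")
      if (st$o$type == "iri") infer(st$o$value, "class")
      next
    }
    if (st$p == label_pred) next
    # generic assertion
    infer(st$p, if (st$o$type == "literal") "annotation-property"
          else "object-property")
    infer(st$s, "individual")
    if (st$o$type == "iri") infer(st$o$value, "individual")
  }

  for (iri in names(cat_of))
    g <- add_term(g, iri, cat_of[[iri]],
                  if (iri %in% names(labels)) labels[[iri]] else NA_character_)
  g$ontology_iri <- ontology_iri

  ## pass 2: axioms
  for (st in stmts) {
    s <- st$s; p <- st$p; o <- st$o
    if (p == label_pred) next
    if (p %in% unsupported_preds) {
      g$unsupported <- c(g$unsupported,
                         sprintf("unsupported axiom: <%s> <%s>", s, p))
      next
    }
    if (p == RDF_TYPE && o$type == "iri") {
      if (o$value %in% names(decl_cat) || o$value == ontology_class) next
      if (o$value == transitive_class) {
        g <- add_axiom(g, "transitive-property", s)
      } else if (o$value %in% unsupported_classes) {
        g$unsupported <- c(g$unsupported,
                           sprintf("unsupported axiom: <%s> a <%s>", s,
                                   o$value))
      } else {
        g <- add_axiom(g, "type-assertion", s, object = o$value)
      }
      next
    }
    kind <- names(kind_predicate)[match(p, kind_predicate)]
    if (!is.na(kind)) {
      if (o$type != "iri")
        stop("literal object not allowed for ", kind, call. = FALSE)
      g <- add_axiom(g, kind, s, object = o$value)
      next
    }
    pcat <- term_category(g, p)
    if (o$type == "literal") {
      kind <- if (identical(pcat, "data-property")) "data-property-assertion"
              else "annotation-assertion"
      g <- add_axiom(g, kind, s, predicate = p, object = o$value,
                     literal = TRUE, datatype = o$datatype, lang = o$lang)
    } else {
      kind <- if (identical(pcat, "annotation-property"))
        "annotation-assertion" else "object-property-assertion"
      g <- add_axiom(g, kind, s, predicate = p, object = o$value)
    }
  }

  if (length(g$unsupported))
    warning("input contains ", length(g$unsupported),
            " unsupported construct(s); recorded in graph$unsupported",
            call. = FALSE)
  assert_closed(g)
}

## ---- OWL/XML writer ------------------------------------------------------

owl_term_element <- c("class" = "Class",
                      "object-property" = "ObjectProperty",
                      "data-property" = "DataProperty",
                      "annotation-property" = "AnnotationProperty",
                      "individual" = "NamedIndividual")

#' Serialize an ontology graph to OWL/XML
#'
#' Write-only companion to [write_turtle()]: emits a well-formed OWL/XML
#' ontology document with one declaration per term, one axiom element per
#' axiom, and rdfs:label annotations from the term table. (Schema-level
#' property links between classes are emitted as property assertions on the
#' class IRIs.)
#'
#' @param g closed ontology_graph
#' @param path optional file path
#' @return XML text (invisibly when `path` is given)
#' @export
write_owl_xml <- function(g, path = NULL) {
  assert_closed(g)
  doc <- xml2::xml_new_root(
    "Ontology", xmlns = "http://www.w3.org/2002/07/owl#",
    ontologyIRI = if (is.na(g$ontology_iri)) "urn:ontology" else g$ontology_iri)
  for (pn in csort(names(g$prefixes)))
    xml2::xml_add_child(doc, "Prefix", name = pn, IRI = g$prefixes[[pn]])

  add <- function(parent, name, ...) xml2::xml_add_child(parent, name, ...)
  term_el <- function(parent, iri) {
    cat <- term_category(g, iri)
    add(parent, owl_term_element[[cat]], IRI = iri)
  }
  lit_el <- function(parent, row) {
    e <- add(parent, "Literal")
    if (!is.na(row$lang)) xml2::xml_set_attr(e, "xml:lang", row$lang)
    else if (!is.na(row$datatype))
      xml2::xml_set_attr(e, "datatypeIRI", row$datatype)
    xml2::xml_set_text(e, row$object)
    e
  }

  ord <- order(g$terms$iri, method = "radix")
  for (i in ord) {
    d <- add(doc, "Declaration")
    add(d, owl_term_element[[g$terms$category[i]]], IRI = g$terms$iri[i])
    if (!is.na(g$terms$label[i])) {
      a <- add(doc, "AnnotationAssertion")
      add(a, "AnnotationProperty", IRI = paste0(RDFS_NS, "label"))
      add(a, "IRI")
      xml2::xml_set_text(xml2::xml_child(a, 2), g$terms$iri[i])
      l <- add(a, "Literal")
      xml2::xml_set_text(l, g$terms$label[i])
    }
  }

  ax <- g$axioms
  ax <- ax[order(axiom_key(ax), method = "radix"), , drop = FALSE]
  for (j in seq_len(nrow(ax))) {
    row <- ax[j, ]
    switch(row$kind,
      "subclass-of" = {
        e <- add(doc, "SubClassOf")
        term_el(e, row$subject); term_el(e, row$object)
      },
      "equivalent-class" = {
        e <- add(doc, "EquivalentClasses")
        term_el(e, row$subject); term_el(e, row$object)
      },
      "disjoint-with" = {
        e <- add(doc, "DisjointClasses")
        term_el(e, row$subject); term_el(e, row$object)
      },
      "transitive-property" = {
        e <- add(doc, "TransitiveObjectProperty")
        term_el(e, row$subject)
      },
      "inverse-of" = {
        e <- add(doc, "InverseObjectProperties")
        term_el(e, row$subject); term_el(e, row$object)
      },
      "domain" = {
        nm <- if (term_category(g, row$subject) == "data-property")
          "DataPropertyDomain" else "ObjectPropertyDomain"
        e <- add(doc, nm)
        term_el(e, row$subject); term_el(e, row$object)
      },
      "range" = {
        nm <- if (term_category(g, row$subject) == "data-property")
          "DataPropertyRange" else "ObjectPropertyRange"
        e <- add(doc, nm)
        term_el(e, row$subject); term_el(e, row$object)
      },
      "type-assertion" = {
        e <- add(doc, "ClassAssertion")
        term_el(e, row$object); term_el(e, row$subject)
      },
      "object-property-assertion" = {
        e <- add(doc, "ObjectPropertyAssertion")
        term_el(e, row$predicate)
        add(e, "NamedIndividual", IRI = row$subject)
        add(e, "NamedIndividual", IRI = row$object)
      },
      "data-property-assertion" = {
        e <- add(doc, "DataPropertyAssertion")
        term_el(e, row$predicate)
        add(e, "NamedIndividual", IRI = row$subject)
        lit_el(e, row)
      },
      "annotation-assertion" = {
        e <- add(doc, "AnnotationAssertion")
        term_el(e, row$predicate)
        iri_el <- add(e, "IRI")
        xml2::xml_set_text(iri_el, row$subject)
        if (row$object_type == "literal") lit_el(e, row)
        else {
          o <- add(e, "IRI")
          xml2::xml_set_text(o, row$object)
        }
      })
  }

  txt <- as.character(doc)
  if (!is.null(path)) {
    writeLines(txt, path, sep = "", useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}
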