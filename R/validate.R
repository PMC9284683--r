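# Structural validation of instance graphs against the model card schema.
# Problems are findings (error/warning rows), never exceptions.
#
# Rules:
#   V1 every individual typed by a section class is reachable from some
#      model-card-report individual via asserted has-part edges
#   V2 object-property assertions between individuals satisfy declared
#      domain/range after materialization
#   V3 date annotations parse as ISO 8601
#   V4 every report individual has at least one section part; a warning per
#      absent main section
#   V5 no disjointness violations (delegates to check_consistency)

#' Validate an instance graph against the model card schema
#'
#' @param g instance graph (typically [to_instance_graph()] output)
#' @param schema schema graph (defaults to [build_core_schema()]); used to
#'   identify section classes and the partonomy property
#' @return a `validation_report`: data frame with columns `severity`
#'   (error/warning), `rule` (V1..V5), `subject`, `message`; zero rows means
#'   schema-valid
#' @export
validate_instances <- function(g, schema = build_core_schema()) {
  assert_closed(g)
  p <- g$prefixes
  has_part <- vterm("has_part")
  report_class <- expand_curie("mcro:ModelCardReport", default_prefixes())
  section_classes <- vapply(section_kinds(), function(k)
    expand_curie(paste0("mcro:", k), default_prefixes()), "")
  main_classes <- vapply(section_kinds(main_only = TRUE), function(k)
    expand_curie(paste0("mcro:", k), default_prefixes()), "")

  findings <- data.frame(severity = character(), rule = character(),
                         subject = character(), message = character(),
                         stringsAsFactors = FALSE)
  flag <- function(severity, rule, subject, message) {
    findings <<- rbind(findings, data.frame(
      severity = severity, rule = rule, subject = subject, message = message,
      stringsAsFactors = FALSE))
  }

  m <- materialize(g)
  ty_m <- m$axioms[m$axioms$kind == "type-assertion", , drop = FALSE]
  ty_a <- g$axioms[g$axioms$kind == "type-assertion", , drop = FALSE]
  op_a <- g$axioms[g$axioms$kind == "object-property-assertion" &
                     g$axioms$object_type == "iri" & !g$axioms$inferred, ,
                   drop = FALSE]
  individuals <- g$terms$iri[g$terms$category == "individual"]

  ## V1: section individuals hang off a report via asserted has-part
  reports <- unique(ty_a$subject[ty_a$object == report_class])
  hp <- op_a[op_a$predicate == has_part &
               op_a$subject %in% individuals &
               op_a$object %in% individuals, , drop = FALSE]
  reach <- reports
  repeat {
    nxt <- union(reach, hp$object[hp$subject %in% reach])
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  section_inds <- unique(ty_a$subject[ty_a$object %in% section_classes &
                                        ty_a$subject %in% individuals])
  for (ind in setdiff(section_inds, reach))
    flag("error", "V1", ind,
         "section individual not reachable from any model card report via has-part")

  ## V2: domain/range of asserted object-property assertions
  dom <- g$axioms[g$axioms$kind == "domain", , drop = FALSE]
  rng <- g$axioms[g$axioms$kind == "range", , drop = FALSE]
  types_of <- function(x) ty_m$object[ty_m$subject == x]
  for (j in seq_len(nrow(op_a))) {
    row <- op_a[j, ]
    if (!row$subject %in% individuals || !row$object %in% individuals) next
    d <- dom$object[dom$subject == row$predicate]
    if (length(d) && !any(d %in% types_of(row$subject)))
      flag("error", "V2", row$subject,
           sprintf("subject of <%s> assertion violates declared domain",
                   compact_iri(row$predicate, p)))
    r <- rng$object[rng$subject == row$predicate & rng$object_type == "iri"]
    if (length(r) && !any(r %in% types_of(row$object)))
      flag("error", "V2", row$object,
           sprintf("object of <%s> assertion violates declared range",
                   compact_iri(row$predicate, p)))
  }

  ## V3: date annotations are ISO 8601
  date_prop <- vterm("date")
  dates <- g$axioms[g$axioms$kind == "annotation-assertion" &
                      g$axioms$predicate == date_prop, , drop = FALSE]
  for (j in seq_len(nrow(dates)))
    if (!is_iso8601(dates$object[j]))
      flag("error", "V3", dates$subject[j],
           sprintf("date annotation '%s' is not ISO 8601", dates$object[j]))

  ## V4: report completeness
  for (rep in reports) {
    parts <- hp$object[hp$subject == rep]
    if (!length(parts)) {
      flag("error", "V4", rep, "model card report has no section parts")
      next
    }
    part_types <- unique(ty_a$object[ty_a$subject %in% parts])
    for (mc in setdiff(main_classes, part_types))
      flag("warning", "V4", rep,
           sprintf("main section %s is absent", compact_iri(mc, p)))
  }

  ## V5: disjointness violations
  inc <- check_consistency(g)
  for (j in seq_len(nrow(inc)))
    flag("error", "V5", inc$individual[j],
         sprintf("individual typed by disjoint classes %s and %s",
                 compact_iri(inc$class_a[j], p),
                 compact_iri(inc$class_b[j], p)))

  findings <- findings[order(findings$rule, findings$subject,
                             findings$message), , drop = FALSE]
  rownames(findings) <- NULL
  class(findings) <- c("validation_report", "data.frame")
  findings
}

#' Number of error-level findings in a validation report
#' @param report validation_report
#' @return integer
#' @export
n_errors <- function(report) sum(report$severity == "error")

#' @export
print.validation_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("valid: no findings\n")
    return(invisible(x))
  }
  cat(nrow(x), "finding(s):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %s <%s>: %s\n", x$rule[i], x$severity[i],
                x$subject[i], x$message[i]))
  invisible(x)
}

#' Render a validation report as a machine-readable list
#' @param report validation_report
#' @return list with `n_errors`, `n_warnings` and `findings`
#' @export
report_as_list <- function(report) {
  list(n_errors = n_errors(report),
       n_warnings = sum(report$severity == "warning"),
       findings = lapply(seq_len(nrow(report)), function(i)
         as.list(report[i, c("severity", "rule", "subject", "message")])))
}
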