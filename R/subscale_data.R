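#' Canonical node set: EDI-2 and CTQ subscales
#'
#' Returns the 16 variables the networks are built over: the 11 Eating
#' Disorder Inventory-2 (EDI-2) psychopathology subscales and the 5 Childhood
#' Trauma Questionnaire (CTQ) maltreatment subscales, in canonical order, with
#' their role (`"ED"` symptom node vs `"CM"` childhood-maltreatment node) and
#' default integer score bounds.
#'
#' CTQ subscales have 5 items scored 1-5 under CTQ-SF scoring, hence bounds
#' [5, 25]. EDI-2 item counts are not standardized across translations, so the
#' EDI-2 bounds are permissive defaults, [0, 3 x nominal item count] under 0-3
#' item scoring; they are configuration, not fact, and every generator accepts
#' overrides.
#'
#' @return A data.frame with columns `name`, `role` (`"ED"`/`"CM"`),
#'   `min`, `max`.
#' @export
#' @examples
#' subscale_nodes()
subscale_nodes <- function() {
  ed_items <- c(
    ineffectiveness = 10, social_insecurity = 8, drive_for_thinness = 7,
    interoceptive_awareness = 10, maturity_fear = 8, body_dissatisfaction = 9,
    perfectionism = 6, interpersonal_distrust = 7, impulsivity = 11,
    bulimia = 7, asceticism = 8
  )
  cm <- c("emotional_neglect", "emotional_abuse", "sexual_abuse",
          "physical_neglect", "physical_abuse")
  data.frame(
    name = c(names(ed_items), cm),
    role = c(rep("ED", length(ed_items)), rep("CM", length(cm))),
    min = c(rep(0L, length(ed_items)), rep(5L, length(cm))),
    max = c(3L * unname(ed_items), rep(25L, length(cm))),
    stringsAsFactors = FALSE
  )
}

#' @rdname subscale_nodes
#' @export
cm_nodes <- function() subscale_nodes()$name[subscale_nodes()$role == "CM"]

#' @rdname subscale_nodes
#' @export
ed_specific_nodes <- function() c("body_dissatisfaction", "bulimia")

#' Assemble a subscale score dataset
#'
#' The common input container of the pipeline: one row per participant, one
#' column per subscale, integer score points, plus a group label and the
#' CM/ED role of each variable.
#'
#' @param scores integer matrix (or data.frame), subjects x variables, with
#'   column names.
#' @param variable_role character vector, `"CM"` or `"ED"` per column.
#'   Defaults to the canonical roles for recognized names.
#' @param group_label free-text group tag (e.g. `"BN"`, `"BED"`).
#' @param provenance `"synthetic"` or `"file"`; `provenance_detail` carries the
#'   seed or file name.
#' @param bounds optional data.frame with columns `name`, `min`, `max`; when
#'   given, scores are checked against it.
#' @param provenance_detail character scalar, see `provenance`.
#' @return An object of class `subscale_data`: a list with elements `scores`
#'   (integer matrix), `variable_names`, `variable_role`, `group_label`,
#'   `provenance`.
#' @export
subscale_dataset <- function(scores, variable_role = NULL, group_label = "",
                             provenance = "file", provenance_detail = "",
                             bounds = NULL) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) {
    stop("`scores` must have column names identifying the subscales")
  }
  if (any(is.na(scores))) {
    stop("`scores` contains missing cells; ingest through read_scores() for complete-case handling")
  }
  storage.mode(scores) <- "integer"
  nm <- colnames(scores)
  if (is.null(variable_role)) {
    canon <- subscale_nodes()
    variable_role <- canon$role[match(nm, canon$name)]
    if (anyNA(variable_role)) {
      stop("unrecognized variable name(s): ",
           paste(nm[is.na(variable_role)], collapse = ", "),
           "; supply `variable_role` explicitly")
    }
  }
  variable_role <- match.arg(variable_role, c("CM", "ED"), several.ok = TRUE)
  if (length(variable_role) != ncol(scores)) {
    stop("`variable_role` must have one entry per column")
  }
  if (!is.null(bounds)) {
    m <- match(nm, bounds$name)
    lo <- bounds$min[m]; hi <- bounds$max[m]
    bad <- which(!is.na(m) &
                   (apply(scores, 2, min) < lo | apply(scores, 2, max) > hi))
    if (length(bad)) {
      stop("scores outside declared bounds for: ", paste(nm[bad], collapse = ", "))
    }
  }
  structure(
    list(scores = scores, variable_names = nm,
         variable_role = stats::setNames(variable_role, nm),
         group_label = group_label,
         provenance = list(kind = provenance, detail = provenance_detail)),
    class = "subscale_data"
  )
}

#' @export
print.subscale_data <- function(x, ...) {
  cat(sprintf("Subscale dataset: %d subjects x %d variables (%d CM, %d ED)\n",
              nrow(x$scores), ncol(x$scores),
              sum(x$variable_role == "CM"), sum(x$variable_role == "ED")))
  if (nzchar(x$group_label)) cat("  group:", x$group_label, "\n")
  cat(sprintf("  provenance: %s %s\n", x$provenance$kind, x$provenance$detail))
  invisible(x)
}

#' @export
dim.subscale_data <- function(x) dim(x$scores)

#' @export
as.matrix.subscale_data <- function(x, ...) x$scores
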