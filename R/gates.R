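#' Construct a spot gate rule
#'
#' A gate rule is a conjunction of clauses, each clause a disjunction of
#' gene-positivity atoms: a spot passes when, in every clause, at least one
#' listed gene is positive. For example the T-cell/IL26 gate
#' `(CD3D | CD3E | CD3G) & IL26` has two clauses.
#'
#' @param name Rule name.
#' @param clauses List of character vectors; each vector is one disjunctive
#'   clause of gene ids.
#' @return Object of class `gate_rule`.
#' @seealso [parse_gate_rule()] for the text form, [gate_spots()] to apply.
#' @export
gate_rule <- function(name, clauses) {
  stopifnot(is.character(name), length(name) == 1, length(clauses) >= 1)
  clauses <- lapply(clauses, as.character)
  if (any(!lengths(clauses))) stop("empty clause in gate rule ", name)
  structure(list(name = name, clauses = clauses), class = "gate_rule")
}

#' Parse a gate rule from text
#'
#' Grammar: `NAME := CLAUSE & CLAUSE & ...` where each clause is either a
#' gene id or a parenthesized disjunction `(G1|G2|...)`. Whitespace is
#' ignored.
#'
#' @param text Rule string, e.g. `"t_il26 := (CD3D|CD3E|CD3G) & IL26"`.
#' @return A `gate_rule`.
#' @export
parse_gate_rule <- function(text) {
  parts <- strsplit(text, ":=", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("gate rule must have the form 'NAME := EXPR'")
  name <- trimws(parts[1])
  clauses_txt <- strsplit(parts[2], "&", fixed = TRUE)[[1]]
  clauses <- lapply(clauses_txt, function(cl) {
    cl <- gsub("[()\\s]", "", cl, perl = TRUE)
    atoms <- strsplit(cl, "|", fixed = TRUE)[[1]]
    atoms <- atoms[nzchar(atoms)]
    if (!length(atoms)) stop("empty clause in gate rule ", name)
    atoms
  })
  gate_rule(name, clauses)
}

#' @export
print.gate_rule <- function(x, ...) {
  cl <- vapply(x$clauses, function(a) {
    if (length(a) > 1) paste0("(", paste(a, collapse = "|"), ")") else a
  }, character(1))
  cat(sprintf("%s := %s\n", x$name, paste(cl, collapse = " & ")))
  invisible(x)
}

#' Default marker gate rules for skin spatial data
#'
#' The stock gates used throughout the spatial analysis: IL26- and
#' IFNG-expressing T-cell spots (any CD3 chain plus the cytokine),
#' TGFB1-expressing keratinocyte spots (KRTDAP and TGFB1), IL17A T-cell
#' spots, and the keratin-based epidermis gate.
#'
#' @return Named list of `gate_rule` objects: `t_il26`, `t_ifng`,
#'   `t_il17a`, `kc_tgfb1`, `epidermis`.
#' @export
default_gate_rules <- function() {
  list(
    t_il26 = gate_rule("t_il26", list(c("CD3D", "CD3E", "CD3G"), "IL26")),
    t_ifng = gate_rule("t_ifng", list(c("CD3D", "CD3E", "CD3G"), "IFNG")),
    t_il17a = gate_rule("t_il17a", list(c("CD3D", "CD3E", "CD3G"), "IL17A")),
    kc_tgfb1 = gate_rule("kc_tgfb1", list("KRTDAP", "TGFB1")),
    epidermis = gate_rule("epidermis",
                          list(c("KRT5", "KRT14", "KRT1", "KRT10", "KRTDAP")))
  )
}

#' Apply a gate rule to positivity calls
#'
#' @param calls Logical positivity matrix (genes x spots) from
#'   [call_positive()].
#' @param rule A `gate_rule`.
#' @return Named logical vector over spots.
#' @export
gate_spots <- function(calls, rule) {
  stopifnot(inherits(rule, "gate_rule"))
  genes <- unique(unlist(rule$clauses))
  unknown <- setdiff(genes, rownames(calls))
  if (length(unknown)) {
    stop("gate rule ", rule$name, " references unknown gene(s): ",
         paste(unknown, collapse = ", "))
  }
  res <- rep(TRUE, ncol(calls))
  for (cl in rule$clauses) {
    res <- res & (colSums(calls[cl, , drop = FALSE]) > 0)
  }
  stats::setNames(res, colnames(calls))
}
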