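#' Load a glycosylation rule set
#'
#' Reads a rule-set JSON file (enzymes plus reaction rules).  The bundled
#' default describes mucin-type O-glycosylation in CHO cells: 20 enzymes
#' and 30 reaction rules, 12 enzymes flagged as transiently transfected in
#' at least one experiment.  Enzyme families catalyzing the same reaction
#' (B3GNT, B4GALT, ST3GAL, ST6GALNAC) are collapsed to single model
#' enzymes; enzymes acting on several substrates carry suffixed sub-rules
#' (`"_a"`, `"_b"`, ...).
#'
#' @param path Path to a rule-set JSON file; default is the bundled set.
#' @return An object of class `"ruleset"`: list with `enzymes`
#'   (data.frame: enzyme, name, ec, transfected) and `rules` (named list
#'   of rule objects).
#' @examples
#' rs <- default_ruleset()
#' nrow(rs$enzymes)      # 20
#' length(rs$rules)      # 30
#' @export
load_ruleset <- function(path) {
  raw <- jsonlite::read_json(path)
  enz <- do.call(rbind, lapply(raw$enzymes, function(e)
    data.frame(enzyme = e$enzyme, name = e$name, ec = e$ec,
               transfected = isTRUE(e$transfected),
               stringsAsFactors = FALSE)))
  rules <- raw$rules
  ids <- vapply(rules, function(r) r$rule_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate rule_id in rule set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  bad <- setdiff(vapply(rules, function(r) r$enzyme, character(1)), enz$enzyme)
  if (length(bad))
    stop("rules reference unknown enzymes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  names(rules) <- ids
  structure(list(enzymes = enz, rules = rules, source = path),
            class = "ruleset")
}

.ruleset_cache <- new.env(parent = emptyenv())

#' @rdname load_ruleset
#' @export
default_ruleset <- function() {
  if (is.null(.ruleset_cache$default)) {
    path <- system.file("extdata", "rules.json", package = "oglycosim",
                        mustWork = TRUE)
    .ruleset_cache$default <- load_ruleset(path)
  }
  .ruleset_cache$default
}

#' @export
print.ruleset <- function(x, ...) {
  cat("<ruleset> ", length(x$rules), " rules, ", nrow(x$enzymes),
      " enzymes (", sum(x$enzymes$transfected), " transfectable)\n", sep = "")
  invisible(x)
}

# --- acceptor pattern matching --------------------------------------------

.child_at <- function(node, pos) {
  for (k in node$children) if (identical(k$parent_pos, as.integer(pos))) return(k)
  NULL
}

# one child constraint: list(pos, residue?, anomer?, present?, child?)
.match_child_constraint <- function(node, cc) {
  kid <- .child_at(node, cc$pos)
  present <- !isFALSE(cc$present)
  if (!present) {
    # forbidden: no child at pos, or no child of the given residue
    if (is.null(kid)) return(TRUE)
    if (!is.null(cc$residue)) return(kid$residue != cc$residue)
    return(FALSE)
  }
  if (is.null(kid)) return(FALSE)
  if (!is.null(cc$residue) && kid$residue != cc$residue) return(FALSE)
  if (!is.null(cc$anomer) && !identical(kid$anomer, cc$anomer)) return(FALSE)
  if (!is.null(cc$child) && !.match_child_constraint(kid, cc$child)) return(FALSE)
  TRUE
}

.match_pattern <- function(pattern, node, is_root, parent) {
  if (node$residue != pattern$residue) return(FALSE)
  if (isTRUE(pattern$is_root) && !is_root) return(FALSE)
  if (isTRUE(pattern$terminal) && length(node$children) > 0L) return(FALSE)
  if (!is.null(pattern$parent_anomer) || !is.null(pattern$parent_pos) ||
      isTRUE(pattern$parent_is_root)) {
    if (is_root) return(FALSE)
    if (!is.null(pattern$parent_anomer) &&
        !identical(node$anomer, pattern$parent_anomer)) return(FALSE)
    if (!is.null(pattern$parent_pos) &&
        !identical(node$parent_pos, as.integer(pattern$parent_pos))) return(FALSE)
    if (isTRUE(pattern$parent_is_root) && !is.null(parent)) return(FALSE)
  }
  for (cc in pattern$children %||% list())
    if (!.match_child_constraint(node, cc)) return(FALSE)
  TRUE
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Find acceptor sites for a reaction rule on a glycan
#'
#' Returns every node of `tree` whose context satisfies the rule's
#' acceptor pattern and whose attachment position is unoccupied, in
#' deterministic pre-order.
#'
#' @param rule A rule object (element of `default_ruleset()$rules`).
#' @param tree A `"glycan"` object.
#' @return List of integer paths (see [attach_residue()]); empty if the
#'   rule does not apply.
#' @examples
#' rs <- default_ruleset()
#' match_sites(rs$rules$C1GALT1, parse_glycan("GalNAcol"))
#' @export
match_sites <- function(rule, tree) {
  stopifnot(inherits(tree, "glycan"))
  attach_pos <- as.integer(rule$attach$parent_pos)
  out <- list()
  walk <- function(node, path, is_root, parent) {
    if (.match_pattern(rule$pattern, node, is_root, parent) &&
        is.null(.child_at(node, attach_pos)))
      out[[length(out) + 1L]] <<- path
    for (i in seq_along(node$children))
      walk(node$children[[i]], c(path, i), FALSE,
           if (is_root) NULL else node)
  }
  walk(tree, integer(0), TRUE, NULL)
  out
}

#' Apply a reaction rule at a matched site
#'
#' Attaches the rule's residue at `site` and returns the canonical
#' product tree; the input tree is unmodified.
#'
#' @param rule A rule object.
#' @param tree A `"glycan"` object.
#' @param site An element of `match_sites(rule, tree)`.
#' @return The product `"glycan"`.
#' @export
apply_rule <- function(rule, tree, site) {
  ok <- any(vapply(match_sites(rule, tree),
                   function(p) identical(as.integer(p), as.integer(site)),
                   logical(1)))
  if (!ok)
    stop("site is not a match for rule '", rule$rule_id, "' on ",
         format(tree), call. = FALSE)
  at <- rule$attach
  attach_residue(tree, as.integer(site), at$residue,
                 at$anomer %||% NA_character_,
                 at$donor_pos %||% NA_integer_,
                 at$parent_pos)
}
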