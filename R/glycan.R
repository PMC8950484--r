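# Residues known to the condensed-IUPAC dialect.  Sulfate never appears as a
# free token: it is written as a "6S" prefix on its carrier (e.g. "6SGlcNAc",
# the spelling used for 6-O-sulfated GlcNAc in the field).
.RESIDUES <- c("GalNAc", "GlcNAc", "NeuAc", "NeuGc", "Gal", "Fuc")

.GREEK_ALPHA <- "α"
.GREEK_BETA <- "β"

#' Construct a glycan tree node
#'
#' Internal constructor; users normally obtain trees from
#' [parse_glycan()] or [apply_rule()].
#'
#' @param residue One of `"GalNAc"`, `"Gal"`, `"GlcNAc"`, `"Fuc"`,
#'   `"NeuAc"`, `"NeuGc"`, `"Sulfate"`.
#' @param anomer `"alpha"`, `"beta"` or `NA` (sulfate, root).
#' @param parent_pos Carbon position on the parent residue (2--6), `NA`
#'   for the root.
#' @param donor_pos Anomeric carbon of the incoming residue (1 for
#'   hexoses/HexNAcs, 2 for sialic acids, `NA` for sulfate and root).
#' @param children List of child nodes.
#' @keywords internal
glycan_node <- function(residue, anomer = NA_character_, parent_pos = NA_integer_,
                        donor_pos = NA_integer_, children = list()) {
  if (!residue %in% c(.RESIDUES, "Sulfate"))
    stop("unknown residue '", residue, "'", call. = FALSE)
  structure(
    list(residue = residue, anomer = anomer,
         parent_pos = as.integer(parent_pos),
         donor_pos = as.integer(donor_pos),
         children = children),
    class = "glycan_node")
}

#' Parse a condensed-IUPAC O-glycan string
#'
#' Parses structure strings such as `"Galβ1-3(NeuAcα2-6)GalNAcol"`
#' into a rooted tree of monosaccharide (and sulfate) nodes.  The root is
#' always the protein-proximal GalNAc; both the reduced spelling
#' (`"GalNAcol"`, as in mass-spectrometric profiles) and the peptide-linked
#' spelling (`"GalNAca1-"` / `"GalNAcα1-"`) are accepted and normalized
#' to the same species.  Greek anomeric letters and their ASCII fallbacks
#' (`a`/`b`) are both accepted; canonical output uses Greek letters.
#'
#' 6-O-sulfation is written as a `"6S"` prefix on the carrier residue
#' (`"6SGlcNAc"`) and is stored as a sulfate leaf node at position 6.
#'
#' @param text A condensed-IUPAC structure string.
#' @return An object of class `"glycan"`: a rooted node tree.  Its
#'   canonical serialization is available via [format()] /
#'   [as.character()].
#' @examples
#' g <- parse_glycan("Galβ1-3(NeuAcα2-6)GalNAcol")
#' format(g)
#' glycan_charge(g)
#' @seealso [glycan_charge()], [residue_count()]
#' @export
parse_glycan <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("'text' must be a single non-empty string", call. = FALSE)
  toks <- .tokenize_glycan(text)
  res <- .parse_tokens(toks, 1L, length(toks), text)
  root <- res
  if (root$residue != "GalNAc")
    stop("parse error in '", text, "': root residue must be GalNAc, got '",
         root$residue, "'", call. = FALSE)
  # root carries no linkage
  root$anomer <- NA_character_
  root$parent_pos <- NA_integer_
  root$donor_pos <- NA_integer_
  class(root) <- c("glycan", class(root))
  root
}

# --- tokenizer -------------------------------------------------------------

# Token: list(kind = "open" | "close" | "residue", residue, anomer,
#             donor_pos, parent_pos, sulfated, is_root_form, offset)
.tokenize_glycan <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  toks <- list()
  push <- function(tok) toks[[length(toks) + 1L]] <<- tok
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") { push(list(kind = "open", offset = i)); i <- i + 1L; next }
    if (ch == ")") { push(list(kind = "close", offset = i)); i <- i + 1L; next }
    start <- i
    sulfated <- FALSE
    if (i + 1L <= n && chars[i] == "6" && chars[i + 1L] == "S") {
      sulfated <- TRUE
      i <- i + 2L
    }
    rest <- substr(text, i, n)
    hit <- NA_character_
    for (r in .RESIDUES) {
      if (startsWith(rest, r)) { hit <- r; break }
    }
    if (is.na(hit))
      stop("parse error in '", text, "': unknown residue at offset ", start,
           " ('", substr(text, start, min(n, start + 5L)), "')", call. = FALSE)
    i <- i + nchar(hit)
    # reduced root form
    if (substr(text, i, i + 1L) == "ol") {
      push(list(kind = "residue", residue = hit, anomer = NA_character_,
                donor_pos = NA_integer_, parent_pos = NA_integer_,
                sulfated = sulfated, is_root_form = TRUE, offset = start))
      i <- i + 2L
      next
    }
    am <- chars[i]
    if (is.na(am) || !am %in% c("a", "b", .GREEK_ALPHA, .GREEK_BETA))
      stop("parse error in '", text, "': expected anomer after '", hit,
           "' at offset ", i, call. = FALSE)
    anomer <- if (am %in% c("a", .GREEK_ALPHA)) "alpha" else "beta"
    i <- i + 1L
    dp <- chars[i]
    if (is.na(dp) || !dp %in% c("1", "2"))
      stop("parse error in '", text, "': expected donor position 1 or 2 at offset ",
           i, call. = FALSE)
    donor_pos <- as.integer(dp)
    i <- i + 1L
    if (is.na(chars[i]) || chars[i] != "-")
      stop("parse error in '", text, "': expected '-' at offset ", i, call. = FALSE)
    i <- i + 1L
    pp <- chars[i]
    if (!is.na(pp) && pp %in% as.character(2:6)) {
      parent_pos <- as.integer(pp)
      i <- i + 1L
      is_root_form <- FALSE
    } else if (is.na(pp) || pp %in% c("(", ")")) {
      # peptide-linked root spelling "GalNAca1-" (no acceptor position)
      parent_pos <- NA_integer_
      is_root_form <- TRUE
    } else {
      stop("parse error in '", text, "': expected acceptor position 2-6 at offset ",
           i, call. = FALSE)
    }
    push(list(kind = "residue", residue = hit, anomer = anomer,
              donor_pos = donor_pos, parent_pos = parent_pos,
              sulfated = sulfated, is_root_form = is_root_form,
              offset = start))
  }
  if (length(toks) == 0L)
    stop("parse error: empty structure string", call. = FALSE)
  toks
}

# --- recursive-descent over the token span [lo, hi] ------------------------

.parse_tokens <- function(toks, lo, hi, text) {
  if (hi < lo)
    stop("parse error in '", text, "': empty group", call. = FALSE)
  last <- toks[[hi]]
  if (last$kind != "residue")
    stop("parse error in '", text, "': expected residue at offset ",
         last$offset, call. = FALSE)
  node <- glycan_node(last$residue, last$anomer, last$parent_pos, last$donor_pos)
  if (isTRUE(last$sulfated))
    node <- .attach_child(node, glycan_node("Sulfate", NA, 6L, NA), text)
  i <- hi - 1L
  while (i >= lo) {
    tk <- toks[[i]]
    if (tk$kind == "close") {
      depth <- 1L
      j <- i - 1L
      while (j >= lo && depth > 0L) {
        if (toks[[j]]$kind == "close") depth <- depth + 1L
        if (toks[[j]]$kind == "open") depth <- depth - 1L
        if (depth == 0L) break
        j <- j - 1L
      }
      if (depth != 0L)
        stop("parse error in '", text, "': unbalanced parentheses", call. = FALSE)
      child <- .parse_tokens(toks, j + 1L, i - 1L, text)
      node <- .attach_child(node, child, text)
      i <- j - 1L
    } else if (tk$kind == "residue") {
      child <- .parse_tokens(toks, lo, i, text)
      node <- .attach_child(node, child, text)
      i <- lo - 1L
    } else {
      stop("parse error in '", text, "': unexpected '(' at offset ",
           tk$offset, call. = FALSE)
    }
  }
  node
}

.attach_child <- function(node, child, text = NULL) {
  if (is.na(child$parent_pos))
    stop("parse error", if (!is.null(text)) paste0(" in '", text, "'"),
         ": branch residue '", child$residue, "' lacks an acceptor position",
         call. = FALSE)
  occupied <- vapply(node$children, function(k) k$parent_pos, integer(1))
  if (child$parent_pos %in% occupied)
    stop("parse error", if (!is.null(text)) paste0(" in '", text, "'"),
         ": position ", child$parent_pos, " of ", node$residue,
         " occupied twice", call. = FALSE)
  node$children <- c(node$children, list(child))
  ord <- order(vapply(node$children, function(k) k$parent_pos, integer(1)))
  node$children <- node$children[ord]
  node
}

# --- serialization ---------------------------------------------------------

.subtree_depth <- function(node) {
  if (node$residue == "Sulfate") return(0L)
  if (length(node$children) == 0L) return(1L)
  1L + max(vapply(node$children, .subtree_depth, integer(1)))
}

.anomer_char <- function(a) {
  if (is.na(a)) "" else if (a == "alpha") .GREEK_ALPHA else .GREEK_BETA
}

.serialize_node <- function(node, is_root) {
  kids <- node$children
  sulf <- vapply(kids, function(k) k$residue == "Sulfate", logical(1))
  prefix6s <- if (any(sulf)) "6S" else ""
  kids <- kids[!sulf]
  tok <- if (is_root) {
    paste0(prefix6s, node$residue, "ol")
  } else {
    paste0(prefix6s, node$residue, .anomer_char(node$anomer),
           node$donor_pos, "-", node$parent_pos)
  }
  if (length(kids) == 0L) return(tok)
  # condensed-IUPAC backbone convention: the deepest child subtree carries
  # the main chain (ties broken by lowest attachment position); remaining
  # branches are parenthesized in ascending position order
  depths <- vapply(kids, .subtree_depth, integer(1))
  main_i <- which.max(depths)  # kids sorted by position, ties pick lowest
  main <- .serialize_node(kids[[main_i]], FALSE)
  branches <- vapply(kids[-main_i],
                     function(k) paste0("(", .serialize_node(k, FALSE), ")"),
                     character(1))
  paste0(main, paste0(branches, collapse = ""), tok)
}

#' @export
format.glycan <- function(x, ...) .serialize_node(x, TRUE)

#' @export
as.character.glycan <- function(x, ...) format(x)

#' @export
print.glycan <- function(x, ...) {
  cat("<glycan> ", format(x), "\n", sep = "")
  cat("  residues: ", residue_count(x),
      if (substituent_count(x) > 0)
        paste0("  sulfates: ", substituent_count(x)),
      "  charge: ", glycan_charge(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.glycan` <- function(e1, e2) {
  format(e1) == if (inherits(e2, "glycan")) format(e2) else as.character(e2)
}

# --- traversal helpers -----------------------------------------------------

.get_node <- function(tree, path) {
  node <- tree
  for (idx in path) node <- node$children[[idx]]
  node
}

.modify_node <- function(tree, path, f) {
  if (length(path) == 0L) return(f(tree))
  i <- path[1L]
  tree$children[[i]] <- .modify_node(tree$children[[i]], path[-1L], f)
  tree
}

# Pre-order list of paths (root first); each path is an integer vector of
# child indices.
.all_paths <- function(tree) {
  out <- list()
  walk <- function(node, path) {
    out[[length(out) + 1L]] <<- path
    for (i in seq_along(node$children)) walk(node$children[[i]], c(path, i))
  }
  walk(tree, integer(0))
  out
}

#' Count negatively charged residues of a glycan
#'
#' Sialic acids (NeuAc, NeuGc) and sulfate groups each contribute one
#' negative charge; this count drives the charge-based intensity
#' adjustment of mass-spectrometric profiles.
#'
#' @param tree A `"glycan"` object.
#' @return Integer charge count.
#' @export
glycan_charge <- function(tree) {
  stopifnot(inherits(tree, "glycan") || inherits(tree, "glycan_node"))
  n <- 0L
  for (p in .all_paths(tree)) {
    r <- .get_node(tree, p)$residue
    if (r %in% c("NeuAc", "NeuGc", "Sulfate")) n <- n + 1L
  }
  n
}

#' Number of monosaccharide residues in a glycan
#'
#' Sulfate substituents are not counted here; see
#' [substituent_count()].
#'
#' @param tree A `"glycan"` object.
#' @return Integer residue count (>= 1; the root GalNAc counts).
#' @export
residue_count <- function(tree) {
  sum(vapply(.all_paths(tree),
             function(p) .get_node(tree, p)$residue != "Sulfate", logical(1)))
}

#' Number of sulfate substituents in a glycan
#' @param tree A `"glycan"` object.
#' @return Integer sulfate count.
#' @export
substituent_count <- function(tree) {
  sum(vapply(.all_paths(tree),
             function(p) .get_node(tree, p)$residue == "Sulfate", logical(1)))
}

#' Attach a residue to a glycan tree
#'
#' Low-level tree editor used by the rule engine and handy for building
#' structures programmatically in tests.  The result is re-canonicalized,
#' so attachment order never affects the serialized string.
#'
#' @param tree A `"glycan"` object.
#' @param path Integer vector of child indices from the root selecting
#'   the acceptor node (`integer(0)` is the root).
#' @param residue,anomer,donor_pos,parent_pos Fields of the new node.
#' @return A new `"glycan"`; the input is unmodified.
#' @export
attach_residue <- function(tree, path, residue, anomer, donor_pos, parent_pos) {
  child <- glycan_node(residue, anomer, parent_pos, donor_pos)
  out <- .modify_node(tree, path, function(node) .attach_child(node, child))
  class(out) <- class(tree)
  out
}
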