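#' Generate a glycosylation reaction network
#'
#' Breadth-first closure from the Tn antigen (`"GalNAcol"`) under the
#' active reaction rules: every active rule is applied at every matching
#' site of every species, products are canonicalized and de-duplicated,
#' and species whose residue count exceeds `max_residues` are kept but
#' not expanded further (the poly-LacNAc rules make the closure infinite
#' otherwise).  The resulting species set is independent of expansion
#' order.
#'
#' @param ruleset A `"ruleset"` (default: bundled CHO set).
#' @param active_rule_ids Character vector of active rule ids (subset of
#'   `names(ruleset$rules)`).  An empty set yields the root-only network.
#' @param max_residues Expansion cutoff on monosaccharide count
#'   (default 10, comfortably above every profiled structure).
#' @return Object of class `"glyconet"`: list with `species` (character,
#'   canonical strings; first is the root), `reactions` (data.frame:
#'   substrate, product, rule_id, enzyme, n_sites) and `root`.
#' @examples
#' net <- build_network(active_rule_ids =
#'   c("C1GALT1", "ST3GAL_a", "ST6GALNAC_a", "ST6GALNAC_b", "ST6GALNAC_c"))
#' net
#' @export
build_network <- function(ruleset = default_ruleset(),
                          active_rule_ids = character(),
                          max_residues = 10L) {
  stopifnot(inherits(ruleset, "ruleset"), max_residues >= 1L)
  active_rule_ids <- as.character(active_rule_ids)
  unknown <- setdiff(active_rule_ids, names(ruleset$rules))
  if (length(unknown))
    stop("unknown rule ids: ", paste(unknown, collapse = ", "), call. = FALSE)
  rules <- ruleset$rules[active_rule_ids]

  root <- "GalNAcol"
  species <- root
  trees <- list(parse_glycan(root))
  names(trees) <- root
  queue <- root
  rx <- list()
  while (length(queue)) {
    s <- queue[[1L]]; queue <- queue[-1L]
    tree <- trees[[s]]
    if (residue_count(tree) > max_residues) next
    for (r in rules) {
      sites <- match_sites(r, tree)
      if (!length(sites)) next
      prods <- vapply(sites, function(p) format(apply_rule(r, tree, p)),
                      character(1))
      for (prod in unique(prods)) {
        if (!prod %in% species) {
          species <- c(species, prod)
          trees[[prod]] <- parse_glycan(prod)
          queue <- c(queue, prod)
        }
        rx[[length(rx) + 1L]] <- list(substrate = s, product = prod,
                                      rule_id = r$rule_id,
                                      enzyme = r$enzyme,
                                      n_sites = sum(prods == prod))
      }
    }
  }
  reactions <- if (length(rx)) {
    data.frame(substrate = vapply(rx, `[[`, "", "substrate"),
               product = vapply(rx, `[[`, "", "product"),
               rule_id = vapply(rx, `[[`, "", "rule_id"),
               enzyme = vapply(rx, `[[`, "", "enzyme"),
               n_sites = vapply(rx, function(x) as.integer(x$n_sites), 1L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(substrate = character(), product = character(),
               rule_id = character(), enzyme = character(),
               n_sites = integer(), stringsAsFactors = FALSE)
  }
  structure(list(species = species, reactions = reactions, root = root,
                 active_rule_ids = active_rule_ids,
                 max_residues = as.integer(max_residues)),
            class = "glyconet")
}

#' @export
print.glyconet <- function(x, ...) {
  cat("<glyconet> ", length(x$species), " species, ", nrow(x$reactions),
      " reactions (", length(x$active_rule_ids), " active rules)\n", sep = "")
  invisible(x)
}

#' Check observed structures against a reaction network
#'
#' For each observed structure, reports whether it is a species of the
#' network, and if so one shortest rule sequence synthesizing it from the
#' Tn antigen root.
#'
#' @param network A `"glyconet"`.
#' @param observed Character vector of structure strings (any accepted
#'   spelling; canonicalized before lookup).
#' @return data.frame with columns `structure` (canonical), `reachable`,
#'   `n_steps` (NA if unreachable) and `path` (rule ids, "+"-separated).
#' @export
reachability_report <- function(network, observed) {
  stopifnot(inherits(network, "glyconet"))
  canon <- vapply(observed, function(s) format(parse_glycan(s)), character(1))
  res <- data.frame(structure = canon, reachable = FALSE,
                    n_steps = NA_integer_, path = NA_character_,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (nrow(network$reactions)) {
    g <- igraph::graph_from_data_frame(
      network$reactions[, c("substrate", "product")],
      directed = TRUE,
      vertices = data.frame(name = network$species))
  } else {
    g <- igraph::make_empty_graph() + igraph::vertices(network$species)
  }
  for (i in seq_along(canon)) {
    s <- canon[i]
    if (!s %in% network$species) next
    res$reachable[i] <- TRUE
    if (s == network$root) {
      res$n_steps[i] <- 0L
      res$path[i] <- ""
      next
    }
    sp <- igraph::shortest_paths(g, from = network$root, to = s,
                                 mode = "out", output = "vpath")
    vp <- sp$vpath[[1L]]
    if (length(vp) == 0L) { res$reachable[i] <- FALSE; next }
    nodes <- igraph::V(g)$name[vp]
    steps <- character(length(nodes) - 1L)
    for (j in seq_along(steps)) {
      hit <- network$reactions$rule_id[
        network$reactions$substrate == nodes[j] &
        network$reactions$product == nodes[j + 1L]]
      steps[j] <- hit[1L]
    }
    res$n_steps[i] <- length(steps)
    res$path[i] <- paste(steps, collapse = "+")
  }
  res
}

#' Export a reaction network
#'
#' Writes the reaction edge list as CSV, or the full graph as GraphML.
#'
#' @param network A `"glyconet"`.
#' @param file Output path.
#' @param format `"csv"` (substrate, product, rule_id edge list) or
#'   `"graphml"`.
#' @return `file`, invisibly.
#' @export
write_network <- function(network, file, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(network$reactions[, c("substrate", "product", "rule_id")],
                     file, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      network$reactions[, c("substrate", "product", "rule_id")],
      directed = TRUE, vertices = data.frame(name = network$species))
    igraph::write_graph(g, file, format = "graphml")
  }
  invisible(file)
}
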