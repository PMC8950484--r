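#' Load the bundled transfection experiment configurations
#'
#' Returns the 25 experiment configurations: the transiently transfected
#' glycosyltransferases of each engineered CHO line, the active rule set
#' of its model (transfected enzymes plus the endogenous rules required
#' to reach every structure of its observed profile), and the observed
#' structure list.  Configurations are validated against the rule set:
#' every transfected enzyme must carry the transfected flag in the
#' enzyme table, every active rule id must exist.
#'
#' @param path Path to an experiment-bundle JSON; default is the bundled
#'   set of 25.
#' @param ruleset Rule set used for validation.
#' @return List of experiment configurations (name, aliases,
#'   transfected, active_rule_ids, observed_structures).
#' @examples
#' exps <- load_experiments()
#' length(exps)                       # 25
#' experiment_config("Slex on C3")$transfected
#' @export
load_experiments <- function(path = NULL, ruleset = default_ruleset()) {
  if (is.null(path))
    path <- system.file("extdata", "experiments.json", package = "oglycosim",
                        mustWork = TRUE)
  raw <- jsonlite::read_json(path)
  cfgs <- lapply(raw$experiments, function(e) {
    for (field in c("name", "active_rule_ids", "observed_structures"))
      if (is.null(e[[field]]))
        stop("experiment configuration missing field '", field, "'",
             call. = FALSE)
    e$transfected <- as.character(unlist(e$transfected))
    e$active_rule_ids <- as.character(unlist(e$active_rule_ids))
    e$observed_structures <- as.character(unlist(e$observed_structures))
    e$aliases <- as.character(unlist(e$aliases))
    flagged <- ruleset$enzymes$enzyme[ruleset$enzymes$transfected]
    bad <- setdiff(e$transfected, flagged)
    if (length(bad))
      stop("experiment '", e$name, "': transfected enzymes not in the ",
           "transfectable enzyme table: ", paste(bad, collapse = ", "),
           call. = FALSE)
    bad <- setdiff(e$active_rule_ids, names(ruleset$rules))
    if (length(bad))
      stop("experiment '", e$name, "': unknown rule ids: ",
           paste(bad, collapse = ", "), call. = FALSE)
    e
  })
  cfgs
}

#' @rdname load_experiments
#' @param name Experiment name or alias (e.g. `"CHO-WT"` for
#'   `"CHO/CHO-WT"`).
#' @param experiments An experiment bundle.
#' @export
experiment_config <- function(name, experiments = load_experiments()) {
  for (e in experiments)
    if (identical(e$name, name) || name %in% e$aliases) return(e)
  stop("unknown experiment '", name, "'", call. = FALSE)
}

#' Glycan profile constructor
#'
#' A glycan profile is a set of (structure, value) records with the
#' charge count of each structure.  `kind = "raw_intensity"` marks
#' unadjusted mass-spectrometric intensities; `kind = "adjusted"` marks
#' relative abundances in percent (summing to 100).
#'
#' @param structures Character vector of structure strings (any accepted
#'   spelling; canonicalized).
#' @param values Non-negative numeric vector.
#' @param kind `"raw_intensity"` or `"adjusted"`.
#' @return Object of class `"glycan_profile"`: data.frame with columns
#'   `structure`, `value`, `charge` and attribute `kind`.
#' @export
glycan_profile <- function(structures, values,
                           kind = c("adjusted", "raw_intensity")) {
  kind <- match.arg(kind)
  stopifnot(length(structures) == length(values), all(values >= 0))
  canon <- vapply(structures, function(s) format(parse_glycan(s)), character(1))
  charge <- vapply(structures, function(s) glycan_charge(parse_glycan(s)),
                   integer(1))
  if (kind == "adjusted" && abs(sum(values) - 100) > 1e-6)
    stop("adjusted profiles must sum to 100 (got ", sum(values), ")",
         call. = FALSE)
  structure(data.frame(structure = unname(canon), value = unname(values),
                       charge = unname(charge), stringsAsFactors = FALSE),
            kind = kind, class = c("glycan_profile", "data.frame"))
}

#' Charge-based intensity adjustment of a mass-spectrometric profile
#'
#' Negatively charged glycans (sialylated and/or sulfated) ionize more
#' efficiently, biasing raw MS intensities.  Raw intensities are
#' multiplied by 1.0 (neutral), 0.3 (singly charged) or 0.4 (doubly
#' charged) and then renormalized to 100 percent.  Charges above 2 are
#' rejected: no adjustment factor is defined for them.
#'
#' @param raw A `"glycan_profile"` with `kind = "raw_intensity"`.
#' @return An adjusted `"glycan_profile"` summing to 100.
#' @examples
#' p <- glycan_profile(c("Galb1-4GlcNAcb1-3GalNAcol",
#'                       "NeuAca2-3Galb1-3GalNAcol"),
#'                     c(70, 100), kind = "raw_intensity")
#' adjust_profile(p)$value   # 70, 30
#' @export
adjust_profile <- function(raw) {
  stopifnot(inherits(raw, "glycan_profile"))
  if (attr(raw, "kind") != "raw_intensity")
    stop("profile is already adjusted", call. = FALSE)
  if (any(raw$charge > 2L))
    stop("no adjustment factor defined for charge > 2 (structure '",
         raw$structure[which(raw$charge > 2L)[1L]], "')", call. = FALSE)
  fac <- c(1, 0.3, 0.4)[raw$charge + 1L]
  w <- raw$value * fac
  if (sum(w) <= 0) stop("profile has zero total intensity", call. = FALSE)
  glycan_profile(raw$structure, 100 * w / sum(w), kind = "adjusted")
}

#' Compare simulated and observed glycan profiles
#'
#' Builds the union of the two structure sets (absent entries count as
#' zero) and reports per-structure residuals plus summary statistics.
#'
#' @param simulated,observed Named numeric vectors (structure ->
#'   percent) or `"glycan_profile"` objects.
#' @return List with `table` (structure, simulated, observed, residual =
#'   simulated - observed), `ssr` and `max_abs_residual`.
#' @export
compare_profiles <- function(simulated, observed) {
  as_named <- function(p) {
    if (inherits(p, "glycan_profile"))
      return(stats::setNames(p$value, p$structure))
    stopifnot(is.numeric(p), !is.null(names(p)))
    stats::setNames(unname(p),
                    vapply(names(p), function(s) format(parse_glycan(s)), ""))
  }
  s <- as_named(simulated)
  o <- as_named(observed)
  all_s <- union(names(s), names(o))
  sv <- ifelse(all_s %in% names(s), s[all_s], 0)
  ov <- ifelse(all_s %in% names(o), o[all_s], 0)
  tab <- data.frame(structure = all_s, simulated = unname(sv),
                    observed = unname(ov), residual = unname(sv - ov),
                    stringsAsFactors = FALSE)
  list(table = tab, ssr = sum(tab$residual^2),
       max_abs_residual = max(abs(tab$residual)))
}

#' Read and write glycan profiles as JSON
#'
#' The JSON profile format is a single object
#' `{"kind": ..., "entries": {structure: value, ...}}`.
#'
#' @param profile A `"glycan_profile"`.
#' @param file Path.
#' @return `write_profile` returns `file` invisibly; `read_profile`
#'   returns a `"glycan_profile"`.
#' @export
write_profile <- function(profile, file) {
  stopifnot(inherits(profile, "glycan_profile"))
  jsonlite::write_json(
    list(kind = attr(profile, "kind"),
         entries = as.list(stats::setNames(profile$value, profile$structure))),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_profile
#' @export
read_profile <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  glycan_profile(names(raw$entries), unlist(raw$entries), kind = raw$kind)
}
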