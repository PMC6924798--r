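#' Exclusion rule sets
#'
#' An exclusion rule is a partial level assignment; a profile is excluded if
#' it matches every attribute = level pair of at least one rule.  Rule sets
#' are used to remove unrealistic vignettes or systems from the enumerated
#' Cartesian product before design generation.
#'
#' @param rules A list of rules; each rule is a list with elements `match`
#'   (named list/character vector of attribute = level) and optionally
#'   `description`.
#' @param family `"child"` or `"system"`.
#' @return An object of class `dce_exclusions`.
#' @export
exclusion_ruleset <- function(rules, family = c("child", "system")) {
  family <- match.arg(family)
  rules <- lapply(rules, function(r) {
    if (!is.list(r) || is.null(r$match))
      r <- list(match = r)
    r$match <- unlist(r$match)
    if (!length(r$match) || is.null(names(r$match)) ||
        any(!nzchar(names(r$match))))
      stop("each rule needs a named attribute = level assignment",
           call. = FALSE)
    r
  })
  structure(list(family = family, rules = rules), class = "dce_exclusions")
}

#' Read an exclusion rule set from JSON
#'
#' The JSON layout is `{"family": ..., "rules": [{"description": ...,
#' "match": {attribute: level, ...}}, ...]}`.
#'
#' @param path Path to a JSON file.
#' @return A `dce_exclusions` object.
#' @export
read_exclusion_rules <- function(path) {
  x <- jsonlite::read_json(path)
  exclusion_ruleset(x$rules, family = x$family)
}

#' Illustrative exclusion rule fixtures for the default AAC scheme
#'
#' Synthetic rule sets shipped with the package that reproduce the
#' cardinalities of the motivating study's unpublished removals: 18 of the
#' 54 vignettes and 158 of the 432 systems.  The rules themselves encode
#' plausibility arguments and are meant to be edited, not treated as the
#' study's actual lists.
#'
#' @return A `dce_exclusions` object.
#' @export
#' @examples
#' sch <- aac_scheme()
#' nrow(apply_exclusions(enumerate_systems(sch), aac_system_exclusions(), sch))
aac_child_exclusions <- function() {
  read_exclusion_rules(system.file("extdata", "child_exclusions.json",
                                   package = "aacdce", mustWork = TRUE))
}

#' @rdname aac_child_exclusions
#' @export
aac_system_exclusions <- function() {
  read_exclusion_rules(system.file("extdata", "system_exclusions.json",
                                   package = "aacdce", mustWork = TRUE))
}

#' Remove profiles matched by an exclusion rule set
#'
#' A profile is removed iff it matches at least one rule's partial
#' assignment.  Order of the surviving profiles is preserved, so the
#' operation is idempotent.
#'
#' @param profiles Data frame of level names (one column per attribute).
#' @param exclusions A `dce_exclusions` object (or something coercible via
#'   [exclusion_ruleset()]).
#' @param scheme Optional `dce_scheme`; when supplied, rule attribute and
#'   level names are validated against the rule set's family.
#' @return The filtered data frame; the number of removals is reported via
#'   `message()`.
#' @export
apply_exclusions <- function(profiles, exclusions, scheme = NULL) {
  if (!inherits(exclusions, "dce_exclusions"))
    exclusions <- exclusion_ruleset(exclusions)
  if (!is.null(scheme)) {
    attrs <- family_attrs(scheme, exclusions$family)
    for (r in exclusions$rules) {
      bad <- setdiff(names(r$match), names(attrs))
      if (length(bad))
        stop("exclusion rule names unknown attribute(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      for (nm in names(r$match))
        if (!r$match[[nm]] %in% attrs[[nm]]$levels)
          stop("exclusion rule names unknown level '", r$match[[nm]],
               "' for attribute '", nm, "'", call. = FALSE)
    }
  }
  keep <- !matches_any_rule(profiles, exclusions)
  message(sum(!keep), " of ", nrow(profiles),
          " profiles removed by exclusion rules; ", sum(keep), " remain")
  out <- profiles[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

matches_any_rule <- function(profiles, exclusions) {
  hit <- rep(FALSE, nrow(profiles))
  for (r in exclusions$rules) {
    miss <- setdiff(names(r$match), names(profiles))
    if (length(miss))
      stop("exclusion rule references missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    h <- rep(TRUE, nrow(profiles))
    for (nm in names(r$match))
      h <- h & (as.character(profiles[[nm]]) == r$match[[nm]])
    hit <- hit | h
  }
  hit
}

#' @export
print.dce_exclusions <- function(x, ...) {
  cat("Exclusion rule set (", x$family, " family, ", length(x$rules),
      " rules)\n", sep = "")
  for (r in x$rules) {
    cat("  -", paste(names(r$match), unname(r$match), sep = " = ",
                     collapse = ", "), "\n")
  }
  invisible(x)
}
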