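#' Define a single DCE attribute
#'
#' An attribute is a named dimension of a profile (a child vignette or an
#' AAC system) together with its possible levels and a designated baseline
#' level.  Coefficients are always interpreted relative to the baseline via
#' dummy coding.
#'
#' @param name Attribute name, unique within its family.
#' @param levels Character vector of at least two distinct level names.
#' @param baseline The reference level; defaults to the first level.
#' @return An object of class `dce_attribute`.
#' @export
#' @examples
#' dce_attribute("size_of_vocabulary",
#'               c("up_to_50", "from_50_to_1000", "over_1000"))
dce_attribute <- function(name, levels, baseline = levels[1]) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (length(levels) < 2L)
    stop("attribute '", name, "' must have at least 2 levels", call. = FALSE)
  if (anyDuplicated(levels))
    stop("attribute '", name, "' has duplicated level names", call. = FALSE)
  if (!is.character(baseline) || length(baseline) != 1L ||
      !baseline %in% levels)
    stop("baseline of '", name, "' must be one of its levels", call. = FALSE)
  structure(list(name = name, levels = levels, baseline = baseline),
            class = "dce_attribute")
}

#' Assemble an attribute scheme
#'
#' A scheme holds the two attribute families of a vignette-conditioned DCE:
#' the child (vignette) attributes and the choice-object (AAC system)
#' attributes.  The dummy dimension of a family is the sum over its
#' attributes of (number of levels - 1).
#'
#' @param child,system Lists of [dce_attribute()] objects.
#' @return An object of class `dce_scheme`.
#' @seealso [aac_scheme()] for the default scheme.
#' @export
attribute_scheme <- function(child, system) {
  validate_family <- function(attrs, family) {
    if (!length(attrs))
      stop("family '", family, "' has no attributes", call. = FALSE)
    if (!all(vapply(attrs, inherits, logical(1), "dce_attribute")))
      stop("family '", family, "' must be a list of dce_attribute objects",
           call. = FALSE)
    nms <- vapply(attrs, `[[`, character(1), "name")
    if (anyDuplicated(nms))
      stop("duplicated attribute names in family '", family, "'",
           call. = FALSE)
    names(attrs) <- nms
    attrs
  }
  structure(list(child = validate_family(child, "child"),
                 system = validate_family(system, "system")),
            class = "dce_scheme")
}

#' Default AAC scheme: four child attributes and five system attributes
#'
#' The child family covers language ability, experience communicating with
#' AAC, motivation to communicate, and the predicted trajectory of skills;
#' the system family covers the provided vocabulary sets, consistency of
#' interface layout, vocabulary organisation, vocabulary size and graphical
#' representation.  Baselines correspond to the most challenging child
#' profile (delayed language, no AAC experience, not motivated, predicted
#' regression) and to the plainest system levels.  Child dummy dimension is
#' 7, system dummy dimension is 12.
#'
#' @return A `dce_scheme`.
#' @export
#' @examples
#' sch <- aac_scheme()
#' dummy_dim(sch, "child")   # 7
#' dummy_dim(sch, "system")  # 12
aac_scheme <- function() {
  attribute_scheme(
    child = list(
      dce_attribute("language",
                    c("delayed", "receptive_exceeds_expressive")),
      dce_attribute("communication_ability",
                    c("no_aac_experience", "few_functions",
                      "range_of_functions")),
      dce_attribute("determination",
                    c("not_motivated", "motivated_via_symbols",
                      "motivated_other_methods")),
      dce_attribute("predicted_future",
                    c("regression", "plateau", "progression"))
    ),
    system = list(
      dce_attribute("vocabulary_sets",
                    c("none", "fixed", "staged_progression")),
      dce_attribute("layout_consistency",
                    c("some_aspects", "all_aspects", "idiosyncratic")),
      dce_attribute("vocabulary_organisation",
                    c("visual_scene", "taxonomic", "semantic_syntactic",
                      "pragmatic")),
      dce_attribute("size_of_vocabulary",
                    c("up_to_50", "from_50_to_1000", "over_1000")),
      dce_attribute("graphical_representation",
                    c("photos", "pictographic", "ideographic", "text"))
    )
  )
}

family_attrs <- function(scheme, family = c("child", "system")) {
  stopifnot(inherits(scheme, "dce_scheme"))
  scheme[[match.arg(family)]]
}

#' Dummy dimension and dummy names of a scheme family
#'
#' Dummies are named `<attribute>.<level>` for every non-baseline level, in
#' attribute order then level order.
#'
#' @param scheme A `dce_scheme`.
#' @param family `"child"` or `"system"`.
#' @return `dummy_dim()`: an integer; `dummy_names()`: a character vector.
#' @export
dummy_dim <- function(scheme, family) {
  length(dummy_names(scheme, family))
}

#' @rdname dummy_dim
#' @export
dummy_names <- function(scheme, family) {
  attrs <- family_attrs(scheme, family)
  unlist(lapply(attrs, function(a) {
    paste(a$name, setdiff(a$levels, a$baseline), sep = ".")
  }), use.names = FALSE)
}

#' Enumerate all profiles of a scheme family
#'
#' Returns the full Cartesian product of attribute levels in deterministic
#' lexicographic order: the first attribute of the family varies slowest,
#' the last fastest, with levels in the order they were declared.
#'
#' @param scheme A `dce_scheme`.
#' @return A data frame with one character column per attribute and one row
#'   per profile.
#' @export
#' @examples
#' nrow(enumerate_vignettes(aac_scheme()))  # 54
#' nrow(enumerate_systems(aac_scheme()))    # 432
enumerate_vignettes <- function(scheme) {
  enumerate_profiles(scheme, "child")
}

#' @rdname enumerate_vignettes
#' @export
enumerate_systems <- function(scheme) {
  enumerate_profiles(scheme, "system")
}

enumerate_profiles <- function(scheme, family) {
  attrs <- family_attrs(scheme, family)
  lv <- lapply(attrs, `[[`, "levels")
  # expand.grid varies the first factor fastest; reverse to make the first
  # attribute most significant (lexicographic in declared attribute order)
  g <- expand.grid(rev(lv), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(g)), drop = FALSE]
  names(g) <- names(attrs)
  rownames(g) <- NULL
  g
}

#' Dummy-code profiles against a scheme family
#'
#' @param profiles Data frame of level names, one column per attribute of
#'   the family (as produced by [enumerate_vignettes()] or
#'   [enumerate_systems()]).
#' @param scheme A `dce_scheme`.
#' @param family `"child"` or `"system"`.
#' @return A 0/1 matrix with `nrow(profiles)` rows and one column per
#'   non-baseline level, named as in [dummy_names()].
#' @export
dummy_code <- function(profiles, scheme, family) {
  attrs <- family_attrs(scheme, family)
  miss <- setdiff(names(attrs), names(profiles))
  if (length(miss))
    stop("profiles lack attribute column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  nms <- dummy_names(scheme, family)
  out <- matrix(0, nrow(profiles), length(nms), dimnames = list(NULL, nms))
  for (a in attrs) {
    vals <- as.character(profiles[[a$name]])
    bad <- setdiff(unique(vals), a$levels)
    if (length(bad))
      stop("unknown level(s) for '", a$name, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    for (l in setdiff(a$levels, a$baseline))
      out[, paste(a$name, l, sep = ".")] <- as.numeric(vals == l)
  }
  out
}

#' Construct a single child vignette
#'
#' Unspecified attributes sit at their baseline level.
#'
#' @param scheme A `dce_scheme`.
#' @param ... Named attribute = level pairs.
#' @return A one-row data frame of level names.
#' @export
#' @examples
#' child_vignette(aac_scheme(), determination = "motivated_via_symbols")
child_vignette <- function(scheme, ...) {
  profile_at(scheme, "child", ...)
}

#' @rdname child_vignette
#' @export
baseline_vignette <- function(scheme) {
  profile_at(scheme, "child")
}

#' @rdname child_vignette
#' @param family `"child"` or `"system"`.
#' @export
profile_at <- function(scheme, family, ...) {
  attrs <- family_attrs(scheme, family)
  spec <- list(...)
  bad <- setdiff(names(spec), names(attrs))
  if (length(bad))
    stop("unknown attribute(s): ", paste(bad, collapse = ", "), call. = FALSE)
  lv <- lapply(attrs, function(a) {
    v <- if (a$name %in% names(spec)) as.character(spec[[a$name]]) else a$baseline
    if (!v %in% a$levels)
      stop("'", v, "' is not a level of '", a$name, "'", call. = FALSE)
    v
  })
  as.data.frame(lv, stringsAsFactors = FALSE)
}

#' Read and write attribute schemes as JSON
#'
#' Layout: `{"child": [{"name": ..., "levels": [...], "baseline": ...},
#' ...], "system": [...]}`.
#'
#' @param scheme A `dce_scheme`.
#' @param path File path.
#' @return `read_attribute_scheme()` returns a `dce_scheme`.
#' @export
write_attribute_scheme <- function(scheme, path) {
  enc <- function(attrs) lapply(unname(attrs), function(a)
    list(name = a$name, levels = a$levels, baseline = a$baseline))
  jsonlite::write_json(list(child = enc(scheme$child),
                            system = enc(scheme$system)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_attribute_scheme
#' @export
read_attribute_scheme <- function(path) {
  x <- jsonlite::read_json(path)
  dec <- function(lst) lapply(lst, function(a)
    dce_attribute(a$name, unlist(a$levels), a$baseline))
  attribute_scheme(child = dec(x$child), system = dec(x$system))
}

#' @export
print.dce_scheme <- function(x, ...) {
  cat("DCE attribute scheme\n")
  for (fam in c("child", "system")) {
    cat(sprintf("  %s family (%d attributes, dummy dimension %d):\n",
                fam, length(x[[fam]]), dummy_dim(x, fam)))
    for (a in x[[fam]]) {
      lv <- ifelse(a$levels == a$baseline, paste0(a$levels, "*"), a$levels)
      cat("    ", a$name, ": ", paste(lv, collapse = ", "), "\n", sep = "")
    }
  }
  cat("  (* baseline level)\n")
  invisible(x)
}
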