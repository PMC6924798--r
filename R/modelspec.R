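#' Mixed logit model specifications
#'
#' A specification records which mean and SD coefficients of the
#' interaction mixed logit are free: logical matrices over (system dummy,
#' `"(constant)"` or child dummy) cells, plus a flag for on-screen position
#' constants.  Validity requires every active mean interaction to have its
#' constant active, and every active SD interaction its SD base.
#'
#' @param scheme A `dce_scheme`.
#' @param mean,sd Logical matrices (or `NULL` for all-false) with rows the
#'   system dummies and columns `("(constant)", <child dummies>)`; partial
#'   matrices are matched by dimnames.
#' @param include_position Estimate alternative-specific position
#'   constants (first slot fixed at 0)?
#' @return An object of class `mixl_spec`.
#' @export
mixl_spec <- function(scheme, mean = NULL, sd = NULL,
                      include_position = TRUE) {
  sys <- dummy_names(scheme, "system")
  kid <- c("(constant)", dummy_names(scheme, "child"))
  template <- matrix(FALSE, length(sys), length(kid),
                     dimnames = list(sys, kid))
  fill <- function(m) {
    if (is.null(m)) return(template)
    out <- template
    if (is.null(dimnames(m))) {
      stopifnot(all(dim(m) == dim(template)))
      out[, ] <- as.logical(m)
    } else {
      out[rownames(m), colnames(m)] <- as.logical(m)
    }
    out
  }
  spec <- structure(list(mean = fill(mean), sd = fill(sd),
                         include_position = isTRUE(include_position),
                         system_dummies = sys, child_dummies = kid[-1]),
                    class = "mixl_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  bad <- rowSums(spec$mean[, -1, drop = FALSE]) > 0 & !spec$mean[, 1]
  if (any(bad))
    stop("mean interaction active without its constant for: ",
         paste(names(which(bad)), collapse = ", "), call. = FALSE)
  bad <- rowSums(spec$sd[, -1, drop = FALSE]) > 0 & !spec$sd[, 1]
  if (any(bad))
    stop("SD interaction active without its SD base for: ",
         paste(names(which(bad)), collapse = ", "), call. = FALSE)
  invisible(spec)
}

#' Full specification: every mean, every SD, position constants
#'
#' For the default AAC scheme this has `12 * 8` mean terms, `12 * 8` SD
#' terms and 2 position constants: 194 free parameters.
#'
#' @param scheme A `dce_scheme`.
#' @param include_position Include position constants (default `TRUE`).
#' @return A `mixl_spec`.
#' @export
full_spec <- function(scheme, include_position = TRUE) {
  sys <- dummy_names(scheme, "system")
  kid <- c("(constant)", dummy_names(scheme, "child"))
  all_on <- matrix(TRUE, length(sys), length(kid),
                   dimnames = list(sys, kid))
  mixl_spec(scheme, mean = all_on, sd = all_on,
            include_position = include_position)
}

#' Specification whose free cells are the nonzero cells of a parameter set
#'
#' @param params A `mixl_parameters` object.
#' @param scheme A `dce_scheme`.
#' @param include_position Include position constants?
#' @return A `mixl_spec`.
#' @export
spec_from_parameters <- function(params, scheme,
                                 include_position = TRUE) {
  mean <- params$mean != 0
  sd <- params$sd != 0
  # activate constants implied by interactions so the spec is valid
  mean[, 1] <- mean[, 1] | rowSums(mean[, -1, drop = FALSE]) > 0
  sd[, 1] <- sd[, 1] | rowSums(sd[, -1, drop = FALSE]) > 0
  mixl_spec(scheme, mean = mean, sd = sd,
            include_position = include_position)
}

#' The reference 50-parameter specification for the default scheme
#'
#' The sparsity pattern of [reference_parameters()]: 24 mean terms, 24 SD
#' terms and 2 position constants.
#'
#' @inheritParams full_spec
#' @return A `mixl_spec`.
#' @export
reference_spec <- function(scheme = aac_scheme(), include_position = TRUE) {
  spec_from_parameters(reference_parameters(scheme), scheme,
                       include_position = include_position)
}

#' Number of free parameters in a specification
#'
#' @param spec A `mixl_spec`.
#' @param n_positions Number of on-screen slots (default 3; the first is
#'   the reference).
#' @return An integer.
#' @export
n_parameters <- function(spec, n_positions = 3L) {
  sum(spec$mean) + sum(spec$sd) +
    if (spec$include_position) n_positions - 1L else 0L
}

# ordered cell index data frame for one side ("mean" or "sd")
spec_cells <- function(spec, side) {
  m <- spec[[side]]
  idx <- which(m, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(sys = character(0), child = character(0),
                      label = character(0)))
  }
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  sys <- rownames(m)[idx[, 1]]
  child <- colnames(m)[idx[, 2]]
  label <- ifelse(child == "(constant)", sys, paste(sys, child, sep = ":"))
  data.frame(sys = sys, child = child,
             label = paste0(side, ".", label),
             stringsAsFactors = FALSE)
}

#' Read and write model specifications as JSON
#'
#' @param spec A `mixl_spec`.
#' @param path File path.
#' @param scheme A `dce_scheme` (for reading).
#' @return `read_model_spec()` returns a `mixl_spec`.
#' @export
write_model_spec <- function(spec, path) {
  cells <- function(side) {
    d <- spec_cells(spec, side)
    lapply(seq_len(nrow(d)), function(i)
      list(system_dummy = d$sys[i], child_dummy = d$child[i]))
  }
  jsonlite::write_json(
    list(mean = cells("mean"), sd = cells("sd"),
         include_position = spec$include_position),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path, scheme) {
  x <- jsonlite::read_json(path)
  sys <- dummy_names(scheme, "system")
  kid <- c("(constant)", dummy_names(scheme, "child"))
  build <- function(cells) {
    m <- matrix(FALSE, length(sys), length(kid),
                dimnames = list(sys, kid))
    for (cell in cells) m[cell$system_dummy, cell$child_dummy] <- TRUE
    m
  }
  mixl_spec(scheme, mean = build(x$mean), sd = build(x$sd),
            include_position = isTRUE(x$include_position))
}

#' @export
print.mixl_spec <- function(x, ...) {
  cat("Mixed logit specification:", sum(x$mean), "mean terms,",
      sum(x$sd), "SD terms,",
      if (x$include_position) "with" else "without",
      "position constants\n")
  cat("  free parameters:", n_parameters(x), "\n")
  invisible(x)
}
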