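#' Relative attribute importance under a given vignette
#'
#' The classical DCE summary: for each system attribute, the importance is
#' the range over its levels (baseline contributing 0) of the
#' vignette-specific mean utility contribution
#' `gamma_al0 + gamma_al' z`; shares are normalised to sum to one.
#'
#' @param object A `mixl_fit` or `mixl_parameters`.
#' @param vignette One-row vignette data frame; default baseline.
#' @param scheme A `dce_scheme`; taken from the fit when available.
#' @return Named numeric vector of shares over system attributes.
#' @export
relative_attribute_importance <- function(object, vignette = NULL,
                                          scheme = NULL) {
  if (is.null(scheme)) scheme <- object$scheme
  if (is.null(scheme)) scheme <- aac_scheme()
  if (is.null(vignette)) vignette <- baseline_vignette(scheme)
  mm <- mean_matrix(object, scheme)
  z <- drop(dummy_code(vignette, scheme, "child"))
  contrib <- drop(mm %*% c(1, z))  # per system dummy
  attrs <- family_attrs(scheme, "system")
  imp <- vapply(attrs, function(a) {
    dums <- paste(a$name, setdiff(a$levels, a$baseline), sep = ".")
    vals <- c(0, contrib[dums])  # baseline level contributes 0
    max(vals) - min(vals)
  }, numeric(1))
  imp / sum(imp)
}

#' Relative interaction attribute importance (RIAI)
#'
#' RIAI measures how strongly each child (vignette) attribute shifts
#' preferences for each system attribute.  For system attribute `a` and
#' child attribute `K`, the impact is an aggregate over the model's active
#' interaction means `gamma_alk` with level `l` of `a` and dummy `k`
#' belonging to `K`; per-attribute RIAI shares normalise the impacts to sum
#' to one over child attributes, and the overall table averages the
#' per-attribute shares over the system attributes that carry at least one
#' interaction (interaction-free attributes are omitted, as a
#' consistency-of-layout attribute would be).  The aggregation strategy is
#' pluggable: `"max"` (default) takes `max |gamma|`, `"sum"` takes
#' `sum |gamma|`, `"range"` takes `max(gamma, 0) - min(gamma, 0)`.
#' Shares are invariant to positive rescaling of the interaction
#' coefficients.
#'
#' Confidence intervals: `ci_method = "krinsky-robb"` draws coefficient
#' vectors from the fit's asymptotic normal distribution and reports
#' percentile intervals of the recomputed shares (the standard DCE
#' practice); `"bootstrap"` resamples respondents and refits, which is
#' faithful but expensive; `"none"` skips intervals.
#'
#' @param object A `mixl_fit` (required for intervals) or
#'   `mixl_parameters`.
#' @param scheme A `dce_scheme`.
#' @param aggregate Aggregation strategy, see above.
#' @param ci_method `"none"`, `"krinsky-robb"` or `"bootstrap"`.
#' @param B Number of coefficient draws / bootstrap refits.
#' @param level Confidence level (default 0.95).
#' @param data,... Choice data and fit arguments, required for
#'   `ci_method = "bootstrap"`.
#' @return A `riai_result`: `per_attribute` (matrix of shares, one row per
#'   system attribute with interactions), `overall` (named vector), and
#'   optional `ci_lower` / `ci_upper` matrices (rows as in
#'   `per_attribute` plus an `"overall"` row).
#' @export
compute_riai <- function(object, scheme = NULL,
                         aggregate = c("max", "sum", "range"),
                         ci_method = c("none", "krinsky-robb", "bootstrap"),
                         B = 200L, level = 0.95, data = NULL, ...) {
  aggregate <- match.arg(aggregate)
  ci_method <- match.arg(ci_method)
  if (is.null(scheme)) scheme <- object$scheme
  if (is.null(scheme)) scheme <- aac_scheme()

  point <- riai_from_means(mean_matrix(object, scheme),
                           active_interactions(object, scheme),
                           scheme, aggregate)
  if (is.null(point)) {
    message("model contains no vignette interactions; RIAI is empty")
    return(structure(list(per_attribute = NULL, overall = NULL,
                          aggregate = aggregate),
                     class = "riai_result"))
  }
  out <- structure(c(point, list(aggregate = aggregate)),
                   class = "riai_result")

  if (ci_method == "none") return(out)
  if (!inherits(object, "mixl_fit"))
    stop("confidence intervals require a mixl_fit", call. = FALSE)
  tabs <- vector("list", B)
  if (ci_method == "krinsky-robb") {
    if (is.null(object$vcov))
      stop("fit has no covariance matrix; cannot draw coefficients",
           call. = FALSE)
    ch <- chol(nearest_pd(object$vcov))
    th0 <- object$coefficients
    zs <- with_local_seed(object$seed,
                          matrix(stats::rnorm(B * length(th0)), B))
    for (b in seq_len(B)) {
      obj_b <- object
      obj_b$coefficients <- th0 + drop(zs[b, ] %*% ch)
      tabs[[b]] <- riai_from_means(mean_matrix(obj_b, scheme),
                                   active_interactions(object, scheme),
                                   scheme, aggregate)
    }
  } else {
    if (is.null(data))
      stop("bootstrap CIs need the choice data", call. = FALSE)
    resp <- unique(data$respondent)
    boot_seeds <- with_local_seed(object$seed,
                                  sample.int(.Machine$integer.max, B))
    for (b in seq_len(B)) {
      dat_b <- with_local_seed(boot_seeds[b], {
        pick <- sample(resp, length(resp), replace = TRUE)
        pieces <- lapply(seq_along(pick), function(i) {
          d <- data[data$respondent == pick[i], , drop = FALSE]
          d$respondent <- i
          d
        })
        do.call(rbind, pieces)
      })
      fit_b <- tryCatch(
        fit_mixed_logit(dat_b, object$spec, scheme,
                        n_draws = max(object$n_draws, 1L),
                        seed = object$seed, ...),
        error = function(e) NULL)
      if (!is.null(fit_b))
        tabs[[b]] <- riai_from_means(mean_matrix(fit_b, scheme),
                                     active_interactions(object, scheme),
                                     scheme, aggregate)
    }
    tabs <- Filter(Negate(is.null), tabs)
  }

  all_rows <- rbind(out$per_attribute,
                    overall = out$overall)
  lo <- hi <- all_rows * NA
  alpha <- (1 - level) / 2
  for (r in rownames(all_rows)) {
    for (cn in colnames(all_rows)) {
      vals <- vapply(tabs, function(tb) {
        if (is.null(tb)) return(NA_real_)
        m <- rbind(tb$per_attribute, overall = tb$overall)
        if (r %in% rownames(m)) m[r, cn] else NA_real_
      }, numeric(1))
      qs <- stats::quantile(vals, c(alpha, 1 - alpha), na.rm = TRUE)
      lo[r, cn] <- qs[1]; hi[r, cn] <- qs[2]
    }
  }
  out$ci_lower <- lo
  out$ci_upper <- hi
  out$ci_method <- ci_method
  out
}

# interaction cells considered "active": free cells of the spec for a fit,
# nonzero cells for a parameter object
active_interactions <- function(object, scheme) {
  if (inherits(object, "mixl_fit"))
    object$spec$mean[, -1, drop = FALSE]
  else
    object$mean[, -1, drop = FALSE] != 0
}

riai_from_means <- function(mm, active, scheme, aggregate) {
  sys_attrs <- family_attrs(scheme, "system")
  child_attrs <- family_attrs(scheme, "child")
  gam <- mm[, -1, drop = FALSE]
  agg_fun <- switch(aggregate,
                    max = function(v) max(abs(v)),
                    sum = function(v) sum(abs(v)),
                    range = function(v) max(v, 0) - min(v, 0))
  per <- matrix(0, length(sys_attrs), length(child_attrs),
                dimnames = list(names(sys_attrs), names(child_attrs)))
  for (sa in sys_attrs) {
    dums <- paste(sa$name, setdiff(sa$levels, sa$baseline), sep = ".")
    for (ca in child_attrs) {
      kdums <- paste(ca$name, setdiff(ca$levels, ca$baseline), sep = ".")
      on <- active[dums, kdums, drop = FALSE]
      if (!any(on)) next
      per[sa$name, ca$name] <- agg_fun(gam[dums, kdums, drop = FALSE][on])
    }
  }
  keep <- rowSums(per) > 0
  if (!any(keep)) return(NULL)
  per <- per[keep, , drop = FALSE]
  per <- per / rowSums(per)
  overall <- colMeans(per)
  overall <- overall / sum(overall)
  list(per_attribute = per, overall = overall)
}

# smallest diagonal inflation making a symmetric matrix positive definite
nearest_pd <- function(V) {
  V <- (V + t(V)) / 2
  eps <- 0
  for (i in 0:12) {
    ok <- tryCatch({ chol(V + diag(eps, nrow(V))); TRUE },
                   error = function(e) FALSE)
    if (ok) return(V + diag(eps, nrow(V)))
    eps <- max(eps * 10, 1e-10)
  }
  stop("covariance matrix is too far from positive definite", call. = FALSE)
}

#' @export
print.riai_result <- function(x, ...) {
  if (is.null(x$per_attribute)) {
    cat("RIAI: no vignette interactions in the model\n")
    return(invisible(x))
  }
  cat("Relative interaction attribute importance (aggregate = ",
      x$aggregate, ")\n", sep = "")
  tab <- rbind(x$per_attribute, overall = x$overall)
  print(round(tab, 3))
  invisible(x)
}

#' Observed on-screen position shares
#'
#' Fraction of choices falling on each on-screen slot; sums to one.
#'
#' @param data A `choice_data` data frame.
#' @return Named numeric vector, one share per slot.
#' @export
position_shares <- function(data) {
  ch <- data[data$chosen == 1, ]
  tab <- table(factor(ch$position, levels = sort(unique(data$position))))
  shares <- as.numeric(tab) / sum(tab)
  names(shares) <- paste0("position_", names(tab))
  shares
}

#' Coefficient table grouped by system attribute
#'
#' Formats an estimation result the way final DCE models are reported: one
#' row per mean coefficient (constants first, then vignette interactions)
#' with the matching SD magnitude, standard errors, and significance stars
#' from Holm-adjusted p-values at the 5% level.  Baseline levels are
#' annotated in the attribute column.
#'
#' @param fit A `mixl_fit`.
#' @param path Optional CSV path; the emitted file re-parses to identical
#'   values.
#' @return A data frame (invisibly written to `path` when given).
#' @export
render_results_table <- function(fit, path = NULL) {
  scheme <- fit$scheme
  spec <- fit$spec
  cells <- spec_cells(spec, "mean")
  sd_cells <- spec_cells(spec, "sd")
  parent <- dummy_parent(scheme, "system")
  attrs <- family_attrs(scheme, "system")
  star <- function(ph) ifelse(!is.na(ph) & ph < 0.05, "*", "")
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    lab <- cells$label[i]
    sd_lab <- sub("^mean\\.", "sd.", lab)
    has_sd <- sd_lab %in% sd_cells$label
    a <- parent[[cells$sys[i]]]
    data.frame(
      system_attribute = sprintf("%s (baseline %s)", a, attrs[[a]]$baseline),
      level = sub(paste0("^", a, "\\."), "", cells$sys[i]),
      child_attribute = if (cells$child[i] == "(constant)") "Constant"
                        else cells$child[i],
      mean = unname(fit$coefficients[lab]),
      se_mean = unname(fit$se[lab]),
      sig_mean = star(fit$p_holm[lab]),
      sd = if (has_sd) abs(unname(fit$coefficients[sd_lab])) else NA_real_,
      se_sd = if (has_sd) unname(fit$se[sd_lab]) else NA_real_,
      sig_sd = if (has_sd) star(fit$p_holm[sd_lab]) else "",
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(system_attribute = character(0), level = character(0),
               child_attribute = character(0), mean = numeric(0),
               se_mean = numeric(0), sig_mean = character(0),
               sd = numeric(0), se_sd = numeric(0),
               sig_sd = character(0))
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

dummy_parent <- function(scheme, family) {
  attrs <- family_attrs(scheme, family)
  out <- list()
  for (a in attrs)
    for (l in setdiff(a$levels, a$baseline))
      out[[paste(a$name, l, sep = ".")]] <- a$name
  out
}

#' Write an estimation result bundle to JSON
#'
#' @param fit A `mixl_fit`.
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(method = fit$method,
         coefficients = as.list(fit$coefficients),
         se = as.list(fit$se), p = as.list(fit$p),
         p_holm = as.list(fit$p_holm),
         loglik = fit$loglik, bic = fit$bic, k = fit$k,
         n_respondents = fit$n_respondents, n_draws = fit$n_draws,
         seed = fit$seed, converged = fit$converged),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
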