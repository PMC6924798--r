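#' Backward step-wise model selection by BIC
#'
#' Starting from the full interaction model (or, when the full model is not
#' identifiable on the data, from all mean terms plus SD bases only), each
#' step considers dropping one removable term group, trying candidates in
#' order of decreasing raw p-value (least significant first) and accepting
#' the first drop that lowers the BIC.  The search stops when no drop
#' lowers the BIC.  Constants and SD bases are never dropped; by default
#' the mean and SD interaction of a term are dropped jointly
#' (`sd_mode = "joint"`), mirroring final models in which every retained
#' mean has a matching SD.  The same draw seed is used for every candidate
#' fit so that BIC comparisons are not confounded by simulation noise, and
#' the whole trace is reproducible given the seed.
#'
#' @param data A `choice_data` data frame.
#' @param scheme A `dce_scheme`.
#' @param n_draws Draws per respondent during the search (default 200).
#' @param seed Draw seed used for every fit.
#' @param start_spec Optional starting `mixl_spec`.
#' @param sd_mode `"joint"` (drop mean+SD interaction together),
#'   `"separate"` (each its own candidate) or `"none"` (model has no SD
#'   terms at all; every fit is a conditional logit).
#' @param final_draws Draws for the final refit (default `n_draws`).
#' @param max_steps Safety cap on accepted drops.
#' @param ... Passed to [fit_mixed_logit()].
#' @return A `selection_trace`: `steps` data frame (one row per accepted
#'   drop plus the starting model: `removed`, `k`, `loglik`, `bic`),
#'   `final_spec`, `final_fit`, and `failed` (labels of candidate fits that
#'   did not converge and were skipped).
#' @export
stepwise_select <- function(data, scheme, n_draws = 200L, seed = 1L,
                            start_spec = NULL,
                            sd_mode = c("joint", "separate", "none"),
                            final_draws = NULL, max_steps = Inf, ...) {
  sd_mode <- match.arg(sd_mode)
  if (is.null(final_draws)) final_draws <- n_draws

  if (is.null(start_spec)) {
    start_spec <- full_spec(scheme)
    if (sd_mode == "none") start_spec$sd[] <- FALSE
    ok <- tryCatch({
      build_mixl_matrices(data, start_spec, scheme)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      # fall back: all means, SD bases only
      capped <- start_spec
      capped$sd[, -1] <- FALSE
      start_spec <- tryCatch({
        build_mixl_matrices(data, capped, scheme)
        capped
      }, error = function(e) stop(
        "neither the full model nor the means + SD-bases model is ",
        "identifiable on these data; supply start_spec", call. = FALSE))
    }
  }

  fit_spec <- function(spec) {
    if (sum(spec$sd) == 0L)
      fit_conditional_logit(data, spec, scheme)
    else
      fit_mixed_logit(data, spec, scheme, n_draws = n_draws, seed = seed,
                      ...)
  }

  spec <- start_spec
  fit <- fit_spec(spec)
  steps <- data.frame(removed = NA_character_, k = fit$k,
                      loglik = fit$loglik, bic = fit$bic,
                      stringsAsFactors = FALSE)
  failed <- character(0)
  n_accepted <- 0L

  repeat {
    groups <- removable_groups(spec, sd_mode)
    if (!nrow(groups)) break
    gp <- vapply(seq_len(nrow(groups)), function(i) {
      labs <- intersect(strsplit(groups$members[i], ";")[[1]],
                        names(fit$p))
      if (!length(labs)) return(NA_real_)
      min(fit$p[labs], na.rm = TRUE)  # most significant member
    }, numeric(1))
    ord <- order(gp, decreasing = TRUE, na.last = FALSE)
    accepted <- FALSE
    for (i in ord) {
      cand_spec <- drop_group(spec, groups[i, ])
      cand_fit <- tryCatch(fit_spec(cand_spec), error = function(e) NULL)
      if (is.null(cand_fit) || !cand_fit$converged) {
        failed <- c(failed, groups$label[i])
        next
      }
      if (cand_fit$bic < fit$bic) {
        spec <- cand_spec
        fit <- cand_fit
        steps <- rbind(steps,
                       data.frame(removed = groups$label[i], k = fit$k,
                                  loglik = fit$loglik, bic = fit$bic,
                                  stringsAsFactors = FALSE))
        n_accepted <- n_accepted + 1L
        accepted <- TRUE
        break
      }
    }
    if (!accepted || n_accepted >= max_steps) break
  }

  final_fit <- if (final_draws != n_draws && sum(spec$sd) > 0L)
    fit_mixed_logit(data, spec, scheme, n_draws = final_draws,
                    seed = seed, ...)
  else fit

  structure(list(steps = steps, final_spec = spec, final_fit = final_fit,
                 failed = failed, seed = seed, n_draws = n_draws,
                 sd_mode = sd_mode),
            class = "selection_trace")
}

# removable term groups of a spec: interaction cells only (constants and SD
# bases are kept).  Returns a data frame with label, side info and member
# parameter labels (";"-separated).
removable_groups <- function(spec, sd_mode) {
  rows <- list()
  sys <- spec$system_dummies
  kids <- spec$child_dummies
  for (a in sys) {
    for (k in kids) {
      m_on <- spec$mean[a, k]
      s_on <- spec$sd[a, k]
      lab <- paste(a, k, sep = ":")
      if (sd_mode == "joint") {
        if (m_on || s_on) {
          members <- c(if (m_on) paste0("mean.", lab),
                       if (s_on) paste0("sd.", lab))
          rows[[length(rows) + 1L]] <-
            data.frame(label = lab, sys = a, child = k,
                       drop_mean = m_on, drop_sd = s_on,
                       members = paste(members, collapse = ";"),
                       stringsAsFactors = FALSE)
        }
      } else {
        if (m_on)
          rows[[length(rows) + 1L]] <-
            data.frame(label = paste0("mean.", lab), sys = a, child = k,
                       drop_mean = TRUE, drop_sd = FALSE,
                       members = paste0("mean.", lab),
                       stringsAsFactors = FALSE)
        if (s_on && sd_mode == "separate")
          rows[[length(rows) + 1L]] <-
            data.frame(label = paste0("sd.", lab), sys = a, child = k,
                       drop_mean = FALSE, drop_sd = TRUE,
                       members = paste0("sd.", lab),
                       stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(label = character(0), sys = character(0),
                      child = character(0), drop_mean = logical(0),
                      drop_sd = logical(0), members = character(0)))
  do.call(rbind, rows)
}

drop_group <- function(spec, group) {
  out <- spec
  if (group$drop_mean) out$mean[group$sys, group$child] <- FALSE
  if (group$drop_sd) out$sd[group$sys, group$child] <- FALSE
  out
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Step-wise BIC selection (", nrow(x$steps) - 1L, " drops, sd_mode = ",
      x$sd_mode, ")\n", sep = "")
  print(x$steps, row.names = FALSE)
  cat("Final model: ")
  print(x$final_fit)
  invisible(x)
}

#' Write a selection trace (every step's BIC) to JSON
#'
#' @param trace A `selection_trace`.
#' @param path File path.
#' @export
write_selection_trace <- function(trace, path) {
  jsonlite::write_json(
    list(steps = trace$steps, failed = trace$failed,
         seed = trace$seed, n_draws = trace$n_draws,
         sd_mode = trace$sd_mode,
         final_labels = spec_labels(trace$final_spec)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
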