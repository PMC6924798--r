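# Internal: turn a long-format choice dataset and a model specification
# into the matrices consumed by the C++ likelihood kernel.
#
# Rows are sorted by (respondent, task, position); tasks are contiguous row
# blocks, tasks of a respondent contiguous task blocks.  Xm holds position
# dummies (slots 2..J; slot 1 is the reference) followed by one column per
# active mean cell (system dummy, optionally multiplied by a vignette
# dummy); Xs holds one column per active SD cell, with sd_dim mapping each
# column to its random dimension (one eta per system dummy with any active
# SD term).
build_mixl_matrices <- function(data, spec, scheme) {
  validate_choice_data(data, scheme)
  ord <- order(data$respondent, data$task, data$position)
  data <- data[ord, , drop = FALSE]

  xcols <- paste0("x_", spec$system_dummies)
  miss <- setdiff(xcols, names(data))
  if (length(miss))
    stop("data lacks system dummy column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(data[xcols])
  colnames(X) <- spec$system_dummies

  mcells <- spec_cells(spec, "mean")
  scells <- spec_cells(spec, "sd")
  zneed <- unique(c(mcells$child, scells$child))
  zneed <- setdiff(zneed, "(constant)")
  zcols <- paste0("z_", zneed, recycle0 = TRUE)
  miss <- setdiff(zcols, names(data))
  if (length(miss))
    stop("data lacks vignette dummy column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  Z <- if (length(zneed)) {
    z <- as.matrix(data[zcols]); colnames(z) <- zneed; z
  } else matrix(0, nrow(data), 0)

  cell_cols <- function(cells) {
    if (!nrow(cells)) return(matrix(0, nrow(data), 0))
    out <- matrix(0, nrow(data), nrow(cells),
                  dimnames = list(NULL, cells$label))
    for (i in seq_len(nrow(cells))) {
      v <- X[, cells$sys[i]]
      if (cells$child[i] != "(constant)")
        v <- v * Z[, cells$child[i]]
      out[, i] <- v
    }
    out
  }

  n_pos <- max(data$position)
  Xpos <- if (spec$include_position && n_pos > 1L) {
    p <- vapply(2:n_pos, function(s) as.numeric(data$position == s),
                numeric(nrow(data)))
    colnames(p) <- paste0("position.", 2:n_pos)
    p
  } else matrix(0, nrow(data), 0)

  Xm <- cbind(Xpos, cell_cols(mcells))
  Xs <- cell_cols(scells)
  sd_sys <- unique(scells$sys)
  sd_sys <- spec$system_dummies[spec$system_dummies %in% sd_sys]
  sd_dim <- if (nrow(scells)) match(scells$sys, sd_sys) - 1L else integer(0)

  tid <- cumsum(!duplicated(data.frame(data$respondent, data$task)))
  task_sizes <- tabulate(tid)
  task_start <- c(0L, cumsum(task_sizes))
  chosen_row <- which(data$chosen == 1) - 1L
  if (length(chosen_row) != max(tid))
    stop("each task must have exactly one chosen alternative", call. = FALSE)
  first_of_task <- which(!duplicated(tid))
  resp_of_task <- data$respondent[first_of_task]
  resp_task_sizes <- tabulate(as.integer(factor(resp_of_task,
                                                unique(resp_of_task))))
  resp_task_start <- c(0L, cumsum(resp_task_sizes))

  # identifiability: every column must vary within at least one task
  for (M in list(Xm, Xs)) {
    if (!ncol(M)) next
    for (j in seq_len(ncol(M))) {
      centred <- M[, j] - stats::ave(M[, j], tid)
      if (all(abs(centred) < 1e-12))
        stop("column '", colnames(M)[j],
             "' never varies within a choice task; not identifiable",
             call. = FALSE)
    }
  }

  list(Xm = Xm, Xs = Xs, sd_dim = sd_dim,
       task_start = task_start, chosen_row = chosen_row,
       resp_task_start = resp_task_start,
       n_respondents = length(resp_task_sizes),
       n_tasks = max(tid), tid = tid,
       labels = c(colnames(Xm), colnames(Xs)),
       n_mean = ncol(Xm), n_sd = ncol(Xs),
       sd_sys = sd_sys)
}

#' Simulated log-likelihood of the interaction mixed logit
#'
#' For each respondent, the likelihood is the average over quasi-random
#' draws of the product across that respondent's tasks of the multinomial
#' logit probability of the chosen alternative, with per-draw coefficients
#' `(gamma_al0 + gamma_al' z) + (sigma_al0 + sigma_al' z) * eta`.  Returns
#' the sum over respondents of the log of that average, which is always
#' non-positive.  With all SD terms zero this is exactly the closed-form
#' conditional logit log-likelihood, whatever the draw count.
#'
#' @param theta Parameter vector: position constants (if any), then active
#'   mean terms, then active SD terms, in the order of
#'   `spec_labels(spec)`.
#' @param data A `choice_data` data frame.
#' @param spec A `mixl_spec`.
#' @param scheme A `dce_scheme`.
#' @param draws Standard-normal draw matrix from [halton_draws()] (rows
#'   `n_respondents * n_draws`, one column per random dimension), or any
#'   matrix of that shape (explicit draws are handy for hand-checked
#'   examples).
#' @param n_draws Number of draws per respondent; inferred from the
#'   attribute on `draws` when present.
#' @return The scalar simulated log-likelihood.
#' @export
mixl_loglik <- function(theta, data, spec, scheme, draws = NULL,
                        n_draws = NULL) {
  mats <- build_mixl_matrices(data, spec, scheme)
  D <- length(mats$sd_sys)
  if (D > 0L) {
    if (is.null(draws))
      stop("draws are required when SD terms are active", call. = FALSE)
    if (is.null(n_draws)) n_draws <- attr(draws, "n_draws")
    if (is.null(n_draws))
      stop("supply n_draws (rows must be n_respondents * n_draws)",
           call. = FALSE)
    cube <- draws_to_cube(draws, mats$n_respondents, n_draws, seq_len(D))
  } else {
    cube <- array(0, dim = c(1, 1, mats$n_respondents))
  }
  eval_mixl(theta, mats, cube, want_grad = FALSE)$loglik
}

#' Ordered parameter labels of a specification
#'
#' @param spec A `mixl_spec`.
#' @param n_positions Number of on-screen slots.
#' @return Character vector naming the entries of the parameter vector.
#' @export
spec_labels <- function(spec, n_positions = 3L) {
  pos <- if (spec$include_position && n_positions > 1L)
    paste0("position.", 2:n_positions) else character(0)
  c(pos, spec_cells(spec, "mean")$label, spec_cells(spec, "sd")$label)
}

eval_mixl <- function(theta, mats, cube, want_grad = TRUE,
                      want_scores = FALSE) {
  Km <- mats$n_mean; Ks <- mats$n_sd
  if (length(theta) != Km + Ks)
    stop("theta has length ", length(theta), ", expected ", Km + Ks,
         call. = FALSE)
  res <- cpp_mixl_eval(theta[seq_len(Km)],
                       if (Ks) theta[Km + seq_len(Ks)] else numeric(0),
                       mats$Xm, mats$Xs, mats$sd_dim,
                       mats$task_start, mats$chosen_row,
                       mats$resp_task_start, cube,
                       want_grad, want_scores)
  if (!is.finite(res$loglik)) {
    stop("non-finite simulated likelihood; check parameter values",
         call. = FALSE)
  }
  if (!is.null(res$gradient)) res$gradient <- drop(res$gradient)
  res
}
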