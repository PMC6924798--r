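#' D-error of a choice design
#'
#' The D-error of a design is `det(M)^(-1/K)` where `M` is the Fisher
#' information of the conditional logit model evaluated at prior
#' coefficients and `K` the number of parameters.  Lower is better;
#' D-efficiency is its reciprocal.  With zero priors (the default, a
#' utility-neutral design) all alternatives in a task are equally likely.
#'
#' @param design A `choice_design` or a data frame with columns `task` and
#'   the system attribute columns.
#' @param scheme A `dce_scheme`.
#' @param priors Numeric vector of prior coefficients, one per system
#'   dummy; defaults to zeros.
#' @return A scalar D-error; `Inf` (with attribute `singular = TRUE`) when
#'   the information matrix is singular.
#' @export
d_error <- function(design, scheme, priors = NULL) {
  df <- as.data.frame(design)
  X <- dummy_code(df, scheme, "system")
  d_error_matrix(X, df$task, priors)
}

# X: (rows = alternatives) dummy matrix; task: grouping vector aligned to X
d_error_matrix <- function(X, task, priors = NULL) {
  K <- ncol(X)
  if (is.null(priors)) priors <- numeric(K)
  if (length(priors) != K)
    stop("priors must have length ", K, " (one per system dummy)",
         call. = FALSE)
  M <- matrix(0, K, K)
  for (rows in split(seq_len(nrow(X)), task)) {
    Xt <- X[rows, , drop = FALSE]
    v <- drop(Xt %*% priors)
    p <- exp(v - max(v)); p <- p / sum(p)
    xbar <- drop(crossprod(Xt, p))
    Xc <- sweep(Xt, 2, xbar, "-")
    M <- M + crossprod(Xc * sqrt(p))
  }
  dt <- determinant(M, logarithm = TRUE)
  if (dt$sign <= 0 || !is.finite(dt$modulus) ||
      dt$modulus < log(.Machine$double.eps) * K) {
    return(structure(Inf, singular = TRUE))
  }
  exp(-as.numeric(dt$modulus) / K)
}

#' Generate a D-efficient blocked choice design by coordinate exchange
#'
#' Random-restart coordinate exchange: starting from a random design, each
#' pass visits every task/alternative slot and tries every candidate
#' profile in its place, accepting a swap only if the D-error strictly
#' decreases; a restart terminates at a local optimum or after `max_passes`
#' full passes.  The best restart is kept.  Tasks are then assigned to
#' blocks of equal size by greedy minimisation of the variance of attribute
#' level frequencies across blocks, avoiding identical tasks within a
#' block.  Fully reproducible given `seed`.
#'
#' @param candidates Data frame of admissible system profiles (e.g. the
#'   output of [apply_exclusions()]).
#' @param scheme A `dce_scheme`.
#' @param n_tasks Total number of choice tasks (divisible by `n_blocks`).
#' @param n_alts Alternatives per task.
#' @param n_blocks Number of blocks.
#' @param priors Prior coefficients for the D-error (default zeros).
#' @param seed Integer seed.
#' @param n_restarts Number of random restarts (default 10).
#' @param max_passes Cap on full exchange passes per restart (default 50).
#' @return A `choice_design`: list with `design` (data frame `block`,
#'   `task`, `alt`, attribute columns), `d_error`, `n_blocks`, `n_alts`.
#' @export
generate_design <- function(candidates, scheme, n_tasks, n_alts, n_blocks,
                            priors = NULL, seed = 1L, n_restarts = 10L,
                            max_passes = 50L) {
  if (n_tasks %% n_blocks != 0L)
    stop("n_tasks must be divisible by n_blocks", call. = FALSE)
  if (nrow(candidates) < n_alts)
    stop("need at least n_alts candidate profiles", call. = FALSE)
  Xc <- dummy_code(candidates, scheme, "system")
  K <- ncol(Xc)
  if (is.null(priors)) priors <- numeric(K)
  if (length(priors) != K)
    stop("priors must have length ", K, call. = FALSE)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- t(vapply(seq_len(n_tasks),
                     function(i) sample.int(nrow(Xc), n_alts),
                     integer(n_alts)))
    res <- cpp_coordinate_exchange(Xc, init - 1L, priors,
                                   as.integer(max_passes))
    if (is.null(best) || res$d_error < best$d_error) best <- res
  }
  tasks <- best$tasks + 1L  # back to 1-based candidate indices
  blocks <- assign_blocks(tasks, candidates, n_blocks)

  ord <- order(blocks, seq_len(n_tasks))
  rows <- do.call(rbind, lapply(seq_along(ord), function(i) {
    t0 <- ord[i]
    data.frame(block = blocks[t0], task = i,
               alt = seq_len(n_alts),
               candidates[tasks[t0, ], , drop = FALSE],
               row.names = NULL, check.names = FALSE)
  }))
  structure(list(design = rows, d_error = best$d_error,
                 n_blocks = n_blocks, n_alts = n_alts,
                 priors = priors, seed = seed),
            class = "choice_design")
}

# Greedy block assignment balancing attribute-level frequencies.
# tasks: T x J matrix of candidate row indices.
assign_blocks <- function(tasks, candidates, n_blocks) {
  n_tasks <- nrow(tasks)
  per_block <- n_tasks / n_blocks
  lev_cols <- lapply(names(candidates), function(a)
    paste(a, as.character(candidates[[a]][tasks]), sep = "."))
  # per-task level multiset, as a count vector over all attribute.level keys
  keys <- sort(unique(unlist(lev_cols)))
  task_counts <- matrix(0, n_tasks, length(keys),
                        dimnames = list(NULL, keys))
  for (a in names(candidates)) {
    vals <- matrix(paste(a, as.character(candidates[[a]][tasks]), sep = "."),
                   nrow = n_tasks)
    for (j in seq_len(ncol(vals))) {
      idx <- cbind(seq_len(n_tasks), match(vals[, j], keys))
      task_counts[idx] <- task_counts[idx] + 1
    }
  }
  task_key <- apply(tasks, 1, function(z) paste(sort(z), collapse = "-"))
  block_counts <- matrix(0, n_blocks, length(keys))
  block_size <- integer(n_blocks)
  block_tasks <- vector("list", n_blocks)
  assignment <- integer(n_tasks)
  ord <- sample.int(n_tasks)  # seeded by caller
  for (t0 in ord) {
    open <- which(block_size < per_block)
    no_dup <- open[!vapply(open, function(b)
      task_key[t0] %in% task_key[unlist(block_tasks[b])], logical(1))]
    cand <- if (length(no_dup)) no_dup else open
    # cost: dispersion of level frequencies across blocks after assignment
    cost <- vapply(cand, function(b) {
      bc <- block_counts
      bc[b, ] <- bc[b, ] + task_counts[t0, ]
      sum(sweep(bc, 2, colMeans(bc))^2)
    }, numeric(1))
    b <- cand[which.min(cost)]
    block_counts[b, ] <- block_counts[b, ] + task_counts[t0, ]
    block_size[b] <- block_size[b] + 1L
    block_tasks[[b]] <- c(block_tasks[[b]], t0)
    assignment[t0] <- b
  }
  assignment
}

#' Exhaustive D-error search over small design spaces
#'
#' Enumerates every design formed from unordered tasks of `n_alts` distinct
#' candidate profiles, with no task repeated within the design, and returns
#' the design minimising the D-error.  Intended as a validation oracle for
#' [generate_design()] on spaces with a few hundred designs at most.
#'
#' @inheritParams generate_design
#' @param max_designs Guard on the number of designs enumerated.
#' @return A list with `tasks` (matrix of candidate indices), `d_error`.
#' @export
exhaustive_design <- function(candidates, scheme, n_tasks, n_alts,
                              priors = NULL, max_designs = 10000L) {
  Xc <- dummy_code(candidates, scheme, "system")
  task_sets <- utils::combn(nrow(Xc), n_alts)
  n_task_space <- ncol(task_sets)
  n_designs <- choose(n_task_space, n_tasks)
  if (n_designs > max_designs)
    stop("design space too large for exhaustive search (", n_designs,
         " designs)", call. = FALSE)
  design_sets <- utils::combn(n_task_space, n_tasks)
  best <- list(tasks = NULL, d_error = Inf)
  for (j in seq_len(ncol(design_sets))) {
    tasks <- t(task_sets[, design_sets[, j], drop = FALSE])
    X <- Xc[as.vector(t(tasks)), , drop = FALSE]
    de <- d_error_matrix(X, rep(seq_len(n_tasks), each = n_alts), priors)
    if (de < best$d_error) best <- list(tasks = tasks, d_error = de)
  }
  best
}

#' @export
print.choice_design <- function(x, ...) {
  cat(sprintf(paste0("Blocked choice design: %d tasks x %d alternatives,",
                     " %d blocks\n"),
              length(unique(x$design$task)), x$n_alts, x$n_blocks))
  cat(sprintf("  D-error %.6g (D-efficiency %.6g)\n",
              x$d_error, 1 / x$d_error))
  invisible(x)
}

#' @export
as.data.frame.choice_design <- function(x, ...) x$design

#' Read and write choice designs as CSV
#'
#' Columns: `block`, `task`, `alt`, then one column of level names per
#' system attribute.
#'
#' @param design A `choice_design`.
#' @param path File path.
#' @param scheme A `dce_scheme` used to validate columns on read.
#' @return `read_design_csv()` returns a `choice_design` (without a stored
#'   D-error unless recomputed).
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path, scheme) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("block", "task", "alt", names(family_attrs(scheme, "system")))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("design CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n_alts <- max(df$alt)
  structure(list(design = df[need],
                 d_error = d_error(df, scheme),
                 n_blocks = length(unique(df$block)), n_alts = n_alts),
            class = "choice_design")
}
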