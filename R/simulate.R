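#' Simulate panel choice data from the random-utility model
#'
#' Emulates the survey structure of the motivating study.  Each respondent
#' is assigned one design block uniformly at random and a set of distinct
#' child vignettes sampled uniformly without replacement; the block's tasks
#' are split evenly across the vignettes (with the default design: 12
#' tasks, 3 vignettes, 4 tasks per vignette).  One standard-normal vector
#' `eta` (one entry per system dummy) is drawn per respondent and held
#' fixed across all of that respondent's tasks — this is the panel mixed
#' logit structure.  On-screen position of alternatives is randomised per
#' task.  The utility of an alternative with system dummies `x` shown for
#' vignette `z` at slot `s` is
#'
#'   `u = alpha_s + sum_al [ (gamma_al0 + gamma_al' z) +
#'        (sigma_al0 + sigma_al' z) * eta_al ] * x_al + Gumbel(0, 1)`
#'
#' and the argmax is recorded as chosen.
#'
#' @param design A `choice_design` (or its data frame).
#' @param vignettes Data frame of admissible child vignettes (level names).
#' @param params A `mixl_parameters` ground truth.
#' @param n_respondents Number of respondents.
#' @param scheme A `dce_scheme`.
#' @param seed Integer seed; output is reproducible bit for bit.
#' @param n_vignettes_per_respondent Vignettes sampled per respondent
#'   (default 3; must divide the tasks per block).
#' @param include_noise Add the i.i.d. Gumbel error?  Disabling it makes
#'   choices deterministic given the respondent draws, which is useful for
#'   verifying the panel structure.
#' @return A `choice_data` data frame in long format: one row per
#'   alternative with columns `respondent`, `block`, `vignette` (row index
#'   into `vignettes`), `task` (1..tasks-per-respondent), `position`,
#'   `chosen`, the system dummies `x_*` and vignette dummies `z_*`.
#' @export
simulate_dataset <- function(design, vignettes, params, n_respondents,
                             scheme, seed = 1L,
                             n_vignettes_per_respondent = 3L,
                             include_noise = TRUE) {
  if (is.null(vignettes) || nrow(vignettes) == 0L)
    stop("vignette list is empty", call. = FALSE)
  ddf <- as.data.frame(design)
  Xd <- dummy_code(ddf, scheme, "system")
  Zv <- dummy_code(vignettes, scheme, "child")
  n_sys <- ncol(Xd)
  blocks <- sort(unique(ddf$block))
  block_rows <- lapply(blocks, function(b) which(ddf$block == b))
  tasks_of <- lapply(block_rows, function(r) split(r, ddf$task[r]))
  tpb <- length(tasks_of[[1]])
  if (tpb %% n_vignettes_per_respondent != 0L)
    stop("tasks per block (", tpb, ") not divisible by ",
         n_vignettes_per_respondent, " vignettes", call. = FALSE)
  if (nrow(vignettes) < n_vignettes_per_respondent)
    stop("need at least ", n_vignettes_per_respondent, " vignettes",
         call. = FALSE)
  tasks_per_vig <- tpb %/% n_vignettes_per_respondent

  out <- with_local_seed(seed, {
    res <- vector("list", n_respondents)
    for (i in seq_len(n_respondents)) {
      b <- sample.int(length(blocks), 1L)
      vig <- sample.int(nrow(Zv), n_vignettes_per_respondent)
      eta <- stats::rnorm(n_sys)
      tasks <- tasks_of[[b]]
      nrow_i <- sum(lengths(tasks))
      rows <- integer(nrow_i); posn <- integer(nrow_i)
      vigrow <- integer(nrow_i); taskid <- integer(nrow_i)
      chosen <- integer(nrow_i)
      at <- 0L
      for (t in seq_along(tasks)) {
        r <- tasks[[t]]
        J <- length(r)
        v <- vig[(t - 1L) %/% tasks_per_vig + 1L]
        slot <- sample.int(J)           # alternative -> on-screen slot
        ord <- order(slot)              # rows emitted in slot order
        z <- Zv[v, ]
        bmean <- drop(params$mean %*% c(1, z))
        bsd <- drop(params$sd %*% c(1, z))
        beta <- bmean + bsd * eta
        u <- params$alpha[slot] + drop(Xd[r, , drop = FALSE] %*% beta)
        if (include_noise) u <- u - log(-log(stats::runif(J)))
        ch <- which.max(u)
        idx <- at + seq_len(J)
        rows[idx] <- r[ord]
        posn[idx] <- seq_len(J)
        vigrow[idx] <- v
        taskid[idx] <- t
        chosen[idx] <- as.integer(ord == ch)
        at <- at + J
      }
      res[[i]] <- data.frame(respondent = i, block = blocks[b],
                             vignette = vigrow, task = taskid,
                             position = posn, chosen = chosen,
                             row = rows)
    }
    do.call(rbind, res)
  })
  x <- Xd[out$row, , drop = FALSE]
  colnames(x) <- paste0("x_", colnames(x))
  z <- Zv[out$vignette, , drop = FALSE]
  colnames(z) <- paste0("z_", colnames(z))
  dat <- cbind(out[c("respondent", "block", "vignette", "task",
                     "position", "chosen")], x, z)
  rownames(dat) <- NULL
  class(dat) <- c("choice_data", "data.frame")
  dat
}

#' Validate the structural invariants of a long-format choice dataset
#'
#' Checks exactly one chosen alternative per (respondent, task), valid 0/1
#' dummy columns and per-attribute dummy exclusivity.
#'
#' @param data A `choice_data` data frame.
#' @param scheme A `dce_scheme`.
#' @return Invisibly `TRUE`; stops with a message otherwise.
#' @export
validate_choice_data <- function(data, scheme) {
  need <- c("respondent", "task", "position", "chosen")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("choice data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tallies <- tapply(data$chosen, interaction(data$respondent, data$task,
                                             drop = TRUE), sum)
  if (any(tallies != 1))
    stop("each (respondent, task) must have exactly one chosen alternative",
         call. = FALSE)
  for (fam in c("system", "child")) {
    pre <- if (fam == "system") "x_" else "z_"
    for (a in family_attrs(scheme, fam)) {
      cols <- paste0(pre, a$name, ".", setdiff(a$levels, a$baseline))
      cols <- intersect(cols, names(data))
      if (!length(cols)) next
      m <- as.matrix(data[cols])
      if (!all(m %in% c(0, 1)) || any(rowSums(m) > 1))
        stop("invalid dummy coding for attribute '", a$name, "'",
             call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write / read long-format choice data as CSV (+ JSON sidecar)
#'
#' The sidecar records the seed and a snapshot of the generating
#' parameters, when known.
#'
#' @param data A `choice_data` data frame.
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @param seed,params Optional provenance stored in the sidecar.
#' @return `read_choice_data()` returns a `choice_data` data frame.
#' @export
write_choice_data <- function(data, path, seed = NULL, params = NULL) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  side <- list(seed = seed)
  if (!is.null(params))
    side$parameters <- list(alpha = params$alpha,
                            mean = as.data.frame(params$mean),
                            sd = as.data.frame(params$sd))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_choice_data
#' @export
read_choice_data <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  class(dat) <- c("choice_data", "data.frame")
  dat
}
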