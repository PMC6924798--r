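# a one-dummy scheme for hand-computed information matrices
one_dummy_scheme <- function() {
  attribute_scheme(
    child = list(dce_attribute("c", c("x", "y"))),
    system = list(dce_attribute("s", c("off", "on"))))
}

test_that("D-error matches the hand-computed information matrix", {
  sch <- one_dummy_scheme()
  # 2 tasks x 2 alternatives, each task {off, on}; at zero priors p = 1/2,
  # each alternative contributes p*(x - xbar)^2 = 0.5 * 0.25, so each task
  # adds 0.25 and M = 0.5; d_error = det(M)^(-1/1) = 2
  df <- data.frame(block = 1, task = rep(1:2, each = 2), alt = rep(1:2, 2),
                   s = rep(c("off", "on"), 2))
  expect_equal(d_error(df, sch), 2)

  # duplicating every task doubles M, which halves the D-error
  df2 <- rbind(df, transform(df, task = task + 2))
  expect_equal(d_error(df2, sch), 1)
})

test_that("non-informative designs are flagged singular, not an error", {
  sch <- one_dummy_scheme()
  df <- data.frame(block = 1, task = rep(1:2, each = 3), alt = rep(1:3, 2),
                   s = "on")  # three identical profiles per task
  de <- d_error(df, sch)
  expect_true(is.infinite(de))
  expect_true(isTRUE(attr(de, "singular")))
})

test_that("priors shift the information matrix as in the logit formula", {
  sch <- one_dummy_scheme()
  df <- data.frame(block = 1, task = c(1, 1), alt = 1:2,
                   s = c("off", "on"))
  b <- 1.2
  p <- exp(b) / (1 + exp(b))
  info <- p * (1 - p)  # binary logit information for one task
  expect_equal(d_error(df, sch, priors = b), 1 / info, tolerance = 1e-12)
  expect_error(d_error(df, sch, priors = c(1, 2)), "length")
})

test_that("coordinate exchange finds the exhaustive optimum on small spaces", {
  sch <- tiny_scheme()
  cand <- enumerate_systems(sch)[c(1, 3, 5, 6), ]
  ex <- exhaustive_design(cand, sch, n_tasks = 3, n_alts = 2)
  expect_true(is.finite(ex$d_error))
  for (seed in c(2, 9, 31)) {
    got <- generate_design(cand, sch, n_tasks = 3, n_alts = 2,
                           n_blocks = 1, seed = seed)
    expect_equal(got$d_error, ex$d_error, tolerance = 1e-10)
  }
})

test_that("exchange never worsens its starting design and is reproducible", {
  sch <- tiny_scheme()
  cand <- enumerate_systems(sch)
  raw <- generate_design(cand, sch, n_tasks = 6, n_alts = 3, n_blocks = 2,
                         seed = 5, n_restarts = 1, max_passes = 0)
  opt <- generate_design(cand, sch, n_tasks = 6, n_alts = 3, n_blocks = 2,
                         seed = 5, n_restarts = 1, max_passes = 50)
  expect_lte(opt$d_error, raw$d_error)

  again <- generate_design(cand, sch, n_tasks = 6, n_alts = 3, n_blocks = 2,
                           seed = 5, n_restarts = 1, max_passes = 50)
  expect_identical(opt$design, again$design)
  expect_identical(opt$d_error, again$d_error)
})

test_that("blocked designs have equal blocks and no within-block repeats", {
  sch <- tiny_scheme()
  des <- generate_design(enumerate_systems(sch), sch, n_tasks = 6,
                         n_alts = 3, n_blocks = 2, seed = 5,
                         n_restarts = 2, max_passes = 20)
  df <- as.data.frame(des)
  sys_cols <- c("size", "organisation")
  # equal block sizes
  expect_equal(as.vector(table(df$block[df$alt == 1])), rep(3L, 2))
  # no task repeats another task of the same block (tasks compared as
  # unordered profile sets) and no task holds two identical profiles
  task_df <- split(df, df$task)
  task_key <- vapply(task_df, function(d)
    paste(sort(apply(d[sys_cols], 1, paste, collapse = "|")),
          collapse = "~"), character(1))
  blk <- vapply(task_df, function(d) d$block[1], numeric(1))
  expect_false(any(duplicated(paste(blk, task_key))))
  for (d in task_df)
    expect_false(any(duplicated(d[sys_cols])))
})

test_that("infeasible design requests are rejected", {
  sch <- tiny_scheme()
  cand <- enumerate_systems(sch)
  expect_error(generate_design(cand, sch, n_tasks = 7, n_alts = 3,
                               n_blocks = 2, seed = 1), "divisible")
  expect_error(generate_design(cand[1:2, ], sch, n_tasks = 2, n_alts = 3,
                               n_blocks = 1, seed = 1), "n_alts")
})

test_that("designs round-trip through CSV", {
  des <- aac_small_design()
  path <- withr::local_tempfile(fileext = ".csv")
  write_design_csv(des, path)
  back <- read_design_csv(path, aac_scheme())
  expect_equal(as.data.frame(back), as.data.frame(des))
  expect_equal(back$d_error, des$d_error, tolerance = 1e-12)
})
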