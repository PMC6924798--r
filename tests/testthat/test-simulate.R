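test_that("simulated datasets satisfy the panel survey structure", {
  sch <- aac_scheme()
  dat <- simulate_dataset(aac_small_design(), aac_admissible_vignettes(),
                          reference_parameters(), n_respondents = 40,
                          scheme = sch, seed = 2)
  expect_s3_class(dat, "choice_data")
  expect_true(validate_choice_data(dat, sch))
  by_resp <- split(dat, dat$respondent)
  expect_length(by_resp, 40L)
  for (d in by_resp[c(1, 17, 40)]) {
    expect_equal(length(unique(d$task)), 12L)
    expect_equal(sum(d$chosen), 12L)
    # three vignettes, four tasks each
    vt <- table(d$vignette[d$position == 1])
    expect_equal(sort(as.vector(vt)), c(4L, 4L, 4L))
  }
})

test_that("zero parameters give uniform position shares", {
  sch <- tiny_scheme()
  nil <- mixl_parameters(sch)
  dat <- simulate_dataset(tiny_design(), enumerate_vignettes(sch), nil,
                          n_respondents = 2000, scheme = sch, seed = 8,
                          n_vignettes_per_respondent = 2L)
  shares <- position_shares(dat)
  n_choices <- 2000 * 8
  band <- 3 * sqrt((1 / 3) * (2 / 3) / n_choices)
  expect_true(all(abs(shares - 1 / 3) < band))
})

test_that("a dominant coefficient drives choices where its dummy is unique", {
  sch <- tiny_scheme()
  m <- matrix(0, 1, 3, dimnames = list("size.large",
                                       c("(constant)",
                                         dummy_names(sch, "child"))))
  m["size.large", "(constant)"] <- 10
  p <- mixl_parameters(sch, mean = m)
  dat <- simulate_dataset(tiny_design(), enumerate_vignettes(sch), p,
                          n_respondents = 300, scheme = sch, seed = 5,
                          n_vignettes_per_respondent = 2L)
  key <- paste(dat$respondent, dat$task)
  carrier_count <- tapply(dat$x_size.large, key, sum)
  tasks_with_unique <- names(carrier_count)[carrier_count == 1]
  expect_gt(length(tasks_with_unique), 100)
  chosen_carrier <- tapply(dat$chosen * dat$x_size.large, key, sum)
  expect_gt(mean(chosen_carrier[tasks_with_unique]), 0.99)
})

test_that("simulation is reproducible bit for bit, including on disk", {
  sch <- tiny_scheme()
  a <- tiny_dataset(n = 25, seed = 99)
  b <- tiny_dataset(n = 25, seed = 99)
  expect_identical(a, b)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_choice_data(a, f1, seed = 99)
  write_choice_data(b, f2, seed = 99)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_choice_data(f1)
  expect_equal(back$chosen, a$chosen)
})

test_that("respondent-level draws are constant within respondent", {
  # one random dummy, no noise: with tasks {off, on}, a respondent picks
  # "on" iff their personal coefficient is positive, so choices agree
  # across all of their tasks
  sch <- attribute_scheme(
    child = list(dce_attribute("c", c("x", "y"))),
    system = list(dce_attribute("s", c("off", "on"))))
  m <- matrix(0, 1, 2, dimnames = list("s.on", c("(constant)", "c.y")))
  s <- m; s["s.on", "(constant)"] <- 1.5
  p <- mixl_parameters(sch, mean = m, sd = s)
  des <- structure(list(design = data.frame(
    block = 1L, task = rep(1:4, each = 2), alt = rep(1:2, 4),
    s = rep(c("off", "on"), 4)), d_error = NA, n_blocks = 1L, n_alts = 2L),
    class = "choice_design")
  dat <- simulate_dataset(des, enumerate_vignettes(sch), p,
                          n_respondents = 200, scheme = sch, seed = 4,
                          n_vignettes_per_respondent = 2L,
                          include_noise = FALSE)
  picked_on <- tapply(dat$chosen * dat$x_s.on,
                      list(dat$respondent, dat$task), sum)
  # each row (respondent) is all 0s or all 1s
  expect_true(all(apply(picked_on, 1, function(r) all(r == r[1]))))
  # and both behaviours occur across respondents
  expect_true(length(unique(picked_on[, 1])) == 2L)
})

test_that("an empty vignette list is rejected", {
  sch <- tiny_scheme()
  expect_error(simulate_dataset(tiny_design(),
                                enumerate_vignettes(sch)[0, ],
                                mixl_parameters(sch), 5, sch, seed = 1),
               "empty")
})
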