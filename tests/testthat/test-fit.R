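# data for a single-dummy conditional logit with known closed form:
# T two-alternative tasks {off, on}, the "on" alternative chosen in a
# fraction p of tasks -> coefficient ln(p / (1 - p))
closed_form_data <- function(n_on, n_off) {
  n <- n_on + n_off
  dat <- data.frame(
    respondent = rep(seq_len(n), each = 2), block = 1, vignette = 1,
    task = 1, position = rep(1:2, n),
    chosen = as.vector(vapply(seq_len(n), function(i)
      if (i <= n_on) c(1L, 0L) else c(0L, 1L), integer(2))),
    x_s.on = rep(c(1, 0), n), z_c.y = 0)
  class(dat) <- c("choice_data", "data.frame")
  dat
}

one_dummy_spec <- function(include_sd = FALSE) {
  sch <- attribute_scheme(
    child = list(dce_attribute("c", c("x", "y"))),
    system = list(dce_attribute("s", c("off", "on"))))
  on <- matrix(c(TRUE, FALSE), 1, 2,
               dimnames = list("s.on", c("(constant)", "c.y")))
  list(scheme = sch,
       spec = mixl_spec(sch, mean = on, sd = if (include_sd) on else NULL,
                        include_position = FALSE))
}

test_that("conditional logit recovers the closed-form coefficient", {
  od <- one_dummy_spec()
  fit <- fit_conditional_logit(closed_form_data(60, 40), od$spec, od$scheme)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), log(60 / 40), tolerance = 1e-7)
  # zero-information data: balanced choices give a zero coefficient
  fit0 <- fit_conditional_logit(closed_form_data(50, 50), od$spec, od$scheme)
  expect_equal(unname(coef(fit0)), 0, tolerance = 1e-8)
})

test_that("conditional logit agrees with an independent survival fit", {
  skip_if_not_installed("survival")
  library(survival)
  dat <- tiny_dataset(n = 80)
  sch <- tiny_scheme()
  spec <- spec_from_parameters(tiny_params(), sch)
  ours <- fit_conditional_logit(dat, spec, sch)
  df <- as.data.frame(dat)
  df$strat <- paste(df$respondent, df$task)
  df$inter <- df$x_size.large * df$z_motivation.yes
  df$pos2 <- as.numeric(df$position == 2)
  df$pos3 <- as.numeric(df$position == 3)
  sv <- survival::clogit(
    chosen ~ x_size.large + x_organisation.themed + x_organisation.grammar +
      inter + pos2 + pos3 + strata(strat),
    data = df)
  sv_named <- c(
    "mean.size.large" = unname(coef(sv)["x_size.large"]),
    "mean.organisation.themed" = unname(coef(sv)["x_organisation.themed"]),
    "mean.organisation.grammar" = unname(coef(sv)["x_organisation.grammar"]),
    "mean.size.large:motivation.yes" = unname(coef(sv)["inter"]),
    "position.2" = unname(coef(sv)["pos2"]),
    "position.3" = unname(coef(sv)["pos3"]))
  expect_equal(coef(ours)[names(sv_named)], sv_named, tolerance = 1e-5)
})

test_that("IIA: restricting to two alternatives leaves estimates consistent", {
  dat <- tiny_dataset(n = 400)
  sch <- tiny_scheme()
  spec <- spec_from_parameters(tiny_params(), sch)
  spec$sd[] <- FALSE
  spec$include_position <- FALSE
  full <- fit_conditional_logit(dat, spec, sch)
  # condition each task on the choice falling in slots {1, 2} and drop the
  # slot-3 alternative; by IIA the two-alternative logit has the same
  # coefficients
  key <- paste(dat$respondent, dat$task)
  third_not_chosen <- ave(dat$chosen * (dat$position == 3), key,
                          FUN = max) == 0
  sub <- dat[third_not_chosen & dat$position != 3, ]
  class(sub) <- c("choice_data", "data.frame")
  reduced <- fit_conditional_logit(sub, spec, sch)
  expect_true(reduced$converged)
  se2 <- sqrt(full$se^2 + reduced$se^2)
  expect_true(all(abs(coef(full) - coef(reduced)) < 3.5 * se2))
})

test_that("MSLE with an SD-free spec matches the conditional logit", {
  dat <- tiny_dataset(n = 80, params = tiny_params(sd_base = 0))
  sch <- tiny_scheme()
  spec <- spec_from_parameters(tiny_params(), sch)
  spec$sd[] <- FALSE
  cl <- fit_conditional_logit(dat, spec, sch)
  ms <- fit_mixed_logit(dat, spec, sch, n_draws = 5, seed = 1)
  expect_equal(coef(ms), coef(cl), tolerance = 1e-4)
  expect_equal(ms$loglik, cl$loglik, tolerance = 1e-8)
})

test_that("estimation is reproducible and flags identification failures", {
  dat <- tiny_dataset(n = 50)
  sch <- tiny_scheme()
  spec <- spec_from_parameters(tiny_params(), sch)
  f1 <- fit_mixed_logit(dat, spec, sch, n_draws = 12, seed = 7)
  f2 <- fit_mixed_logit(dat, spec, sch, n_draws = 12, seed = 7)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$loglik, f2$loglik)

  # a dummy that never varies within tasks is caught up front
  bad <- dat
  bad$x_size.large <- 1
  expect_error(fit_mixed_logit(bad, spec, sch, n_draws = 5, seed = 1),
               "never varies")
})

test_that("separation in the conditional logit is flagged, not returned", {
  od <- one_dummy_spec()
  fit <- fit_conditional_logit(closed_form_data(70, 0), od$spec, od$scheme)
  expect_false(fit$converged)
})

test_that("confidence intervals cover true means at the nominal rate", {
  # desk-scale recovery: a one-dummy mixed logit, 50 replicates
  sch <- attribute_scheme(
    child = list(dce_attribute("c", c("x", "y"))),
    system = list(dce_attribute("s", c("off", "on"))))
  m <- matrix(0, 1, 2, dimnames = list("s.on", c("(constant)", "c.y")))
  s <- m
  m["s.on", "(constant)"] <- 0.9
  s["s.on", "(constant)"] <- 0.7
  p <- mixl_parameters(sch, mean = m, sd = s)
  spec <- spec_from_parameters(p, sch, include_position = FALSE)
  des <- structure(list(design = data.frame(
    block = 1L, task = rep(1:4, each = 2), alt = rep(1:2, 4),
    s = rep(c("off", "on"), 4)), d_error = NA, n_blocks = 1L, n_alts = 2L),
    class = "choice_design")
  vg <- enumerate_vignettes(sch)
  covered <- logical(50)
  for (r in seq_len(50)) {
    dat <- simulate_dataset(des, vg, p, n_respondents = 150, scheme = sch,
                            seed = 1000 + r, n_vignettes_per_respondent = 2L)
    fit <- fit_mixed_logit(dat, spec, sch, n_draws = 24, seed = r,
                           draw_method = "mlhs")
    est <- coef(fit)["mean.s.on"]
    se <- fit$se["mean.s.on"]
    covered[r] <- abs(est - 0.9) < 1.96 * se
  }
  expect_gte(mean(covered), 0.88)
})
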