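test_that("relative attribute importance matches a brute-force oracle", {
  p <- reference_parameters()
  sch <- aac_scheme()
  for (vig in list(baseline_vignette(sch),
                   child_vignette(sch,
                                  determination = "motivated_via_symbols",
                                  predicted_future = "progression"))) {
    shares <- relative_attribute_importance(p, vig, sch)
    # oracle: enumerate every level's utility contribution directly
    z <- drop(dummy_code(vig, sch, "child"))
    imp <- vapply(aac_scheme()$system, function(a) {
      vals <- vapply(a$levels, function(l) {
        if (l == a$baseline) return(0)
        dum <- paste(a$name, l, sep = ".")
        sum(p$mean[dum, ] * c(1, z))
      }, numeric(1))
      max(vals) - min(vals)
    }, numeric(1))
    expect_equal(shares, imp / sum(imp), tolerance = 1e-12)
    expect_equal(sum(shares), 1, tolerance = 1e-9)
  }
})

test_that("importance shares normalise simple ranges", {
  sch <- tiny_scheme()
  m <- matrix(0, 3, 3,
              dimnames = list(dummy_names(sch, "system"),
                              c("(constant)", dummy_names(sch, "child"))))
  m["size.large", "(constant)"] <- 3       # range 3
  m["organisation.themed", "(constant)"] <- 1  # range 1
  p <- mixl_parameters(sch, mean = m)
  shares <- relative_attribute_importance(p, scheme = sch)
  expect_equal(unname(shares), c(0.75, 0.25))
})

test_that("RIAI reproduces the hand-normalised vocabulary-size shares", {
  p <- reference_parameters()
  r <- compute_riai(p, aac_scheme())
  got <- r$per_attribute["size_of_vocabulary", ]
  expect_equal(unname(got["language"]), 0.171, tolerance = 1e-3)
  expect_equal(unname(got["communication_ability"]), 0.282, tolerance = 1e-3)
  expect_equal(unname(got["determination"]), 0.324, tolerance = 1e-3)
  expect_equal(unname(got["predicted_future"]), 0.223, tolerance = 1e-3)
  # interaction-free system attributes are omitted from the table
  expect_false("layout_consistency" %in% rownames(r$per_attribute))
  # every row and the overall table sum to one
  expect_equal(unname(rowSums(r$per_attribute)),
               rep(1, nrow(r$per_attribute)), tolerance = 1e-9)
  expect_equal(sum(r$overall), 1, tolerance = 1e-9)
})

test_that("RIAI is invariant to positive rescaling of interactions", {
  p <- reference_parameters()
  for (agg in c("max", "sum", "range")) {
    r1 <- compute_riai(p, aac_scheme(), aggregate = agg)
    p2 <- p
    p2$mean[, -1] <- 3.7 * p2$mean[, -1]
    r2 <- compute_riai(p2, aac_scheme(), aggregate = agg)
    expect_equal(r1$per_attribute, r2$per_attribute, tolerance = 1e-12)
    expect_equal(r1$overall, r2$overall, tolerance = 1e-12)
  }
})

test_that("single-source interactions get a share of one", {
  sch <- tiny_scheme()
  m <- matrix(0, 3, 3,
              dimnames = list(dummy_names(sch, "system"),
                              c("(constant)", dummy_names(sch, "child"))))
  m["size.large", "(constant)"] <- 0.5
  m["size.large", "motivation.yes"] <- 0.8
  p <- mixl_parameters(sch, mean = m)
  r <- compute_riai(p, sch)
  expect_equal(unname(r$per_attribute["size", "motivation"]), 1)
  expect_equal(unname(r$overall["motivation"]), 1)
})

test_that("interaction-free models yield an empty RIAI with a message", {
  sch <- tiny_scheme()
  m <- matrix(0, 3, 3,
              dimnames = list(dummy_names(sch, "system"),
                              c("(constant)", dummy_names(sch, "child"))))
  m["size.large", "(constant)"] <- 1
  p <- mixl_parameters(sch, mean = m)
  expect_message(r <- compute_riai(p, sch), "no vignette interactions")
  expect_null(r$per_attribute)
})

test_that("position shares count choices by slot", {
  dat <- tiny_dataset(n = 40)
  sh <- position_shares(dat)
  expect_equal(sum(sh), 1)
  one_slot <- dat
  one_slot$chosen <- as.integer(one_slot$position == 1)
  expect_equal(unname(position_shares(one_slot)), c(1, 0, 0))
})

test_that("position constants reproduce the logit ordering of shares", {
  sch <- tiny_scheme()
  p <- mixl_parameters(sch, alpha = c(0.2, 0, -0.2))
  dat <- simulate_dataset(tiny_design(), enumerate_vignettes(sch), p,
                          n_respondents = 1500, scheme = sch, seed = 6,
                          n_vignettes_per_respondent = 2L)
  sh <- position_shares(dat)
  expect_true(sh[1] > sh[2] && sh[2] > sh[3])
  theory <- exp(c(0.2, 0, -0.2)) / sum(exp(c(0.2, 0, -0.2)))
  expect_equal(unname(sh), theory, tolerance = 0.03)
})

test_that("Krinsky-Robb intervals bracket the point estimates", {
  dat <- tiny_dataset(n = 120)
  sch <- tiny_scheme()
  spec <- spec_from_parameters(tiny_params(), sch)
  fit <- fit_mixed_logit(dat, spec, sch, n_draws = 16, seed = 3)
  r <- compute_riai(fit, sch, ci_method = "krinsky-robb", B = 200)
  pt <- rbind(r$per_attribute, overall = r$overall)
  nz <- pt > 0
  expect_true(all(r$ci_lower[nz] <= pt[nz] + 1e-8))
  expect_true(all(r$ci_upper[nz] >= pt[nz] - 1e-8))
})

test_that("results tables mirror the grouped reporting layout", {
  # a fixture estimation result assembled from the reference coefficients
  sch <- aac_scheme()
  spec <- reference_spec(sch)
  labs <- spec_labels(spec)
  p <- reference_parameters()
  th <- vapply(labs, function(lab) {
    if (startsWith(lab, "position.")) return(0)
    side <- sub("[.].*", "", lab)
    key <- sub("^(mean|sd)[.]", "", lab)
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    mm <- if (side == "mean") p$mean else p$sd
    if (length(parts) == 1) mm[parts[1], "(constant)"]
    else mm[parts[1], parts[2]]
  }, numeric(1))
  fake <- structure(list(coefficients = th,
                         se = setNames(abs(th) / 4 + 0.05, labs),
                         tstat = th,
                         p = setNames(rep(0.01, length(th)), labs),
                         p_holm = setNames(rep(0.04, length(th)), labs),
                         spec = spec, scheme = sch),
                    class = "mixl_fit")
  tab <- render_results_table(fake)
  expect_equal(nrow(tab), 24L)  # the final model's coefficient rows
  expect_true(all(tab$sd >= 0, na.rm = TRUE))
  expect_true(all(tab$sig_mean == "*"))

  path <- withr::local_tempfile(fileext = ".csv")
  render_results_table(fake, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$mean, tab$mean)
  expect_equal(back$sd, tab$sd)

  # empty model: header-only table
  empty_spec <- mixl_spec(sch, include_position = FALSE)
  fake0 <- structure(list(coefficients = numeric(0), se = numeric(0),
                          p_holm = numeric(0), spec = empty_spec,
                          scheme = sch),
                     class = "mixl_fit")
  expect_equal(nrow(render_results_table(fake0)), 0L)
})
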