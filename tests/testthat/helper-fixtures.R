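# Shared fixtures, built in code.  Expensive objects are cached for the
# duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# a small scheme: 3 system dummies, 2 child dummies
tiny_scheme <- function() {
  attribute_scheme(
    child = list(
      dce_attribute("ability", c("low", "high")),
      dce_attribute("motivation", c("no", "yes"))
    ),
    system = list(
      dce_attribute("size", c("small", "large")),
      dce_attribute("organisation", c("plain", "themed", "grammar"))
    )
  )
}

# a hand-built design for the tiny scheme: 8 tasks x 3 alternatives in one
# block, covering all 6 system profiles
tiny_design <- function() {
  sch <- tiny_scheme()
  sys <- enumerate_systems(sch)  # 6 profiles
  picks <- rbind(c(1, 2, 3), c(4, 5, 6), c(1, 4, 5), c(2, 3, 6),
                 c(1, 3, 5), c(2, 4, 6), c(1, 2, 6), c(3, 4, 5))
  df <- do.call(rbind, lapply(seq_len(nrow(picks)), function(t)
    data.frame(block = 1L, task = t, alt = 1:3,
               sys[picks[t, ], , drop = FALSE], row.names = NULL)))
  structure(list(design = df, d_error = d_error(df, sch),
                 n_blocks = 1L, n_alts = 3L),
            class = "choice_design")
}

# ground truth on the tiny scheme: strong constants, one mean interaction,
# one SD base
tiny_params <- function(sd_base = 0.6) {
  sch <- tiny_scheme()
  mean <- matrix(0, 3, 3,
                 dimnames = list(dummy_names(sch, "system"),
                                 c("(constant)", dummy_names(sch, "child"))))
  sd <- mean
  mean["size.large", "(constant)"] <- 0.8
  mean["organisation.themed", "(constant)"] <- 0.4
  mean["organisation.grammar", "(constant)"] <- -0.5
  mean["size.large", "motivation.yes"] <- 1.0
  sd["size.large", "(constant)"] <- sd_base
  mixl_parameters(sch, alpha = c(0, 0, 0), mean = mean, sd = sd)
}

tiny_dataset <- function(n = 120, seed = 42, params = tiny_params()) {
  sch <- tiny_scheme()
  vg <- enumerate_vignettes(sch)
  simulate_dataset(tiny_design(), vg, params, n_respondents = n,
                   scheme = sch, seed = seed,
                   n_vignettes_per_respondent = 2L)
}

# default-scheme objects, cached
aac_admissible_vignettes <- function() cached("aac_vg", function() {
  suppressMessages(apply_exclusions(enumerate_vignettes(aac_scheme()),
                                    aac_child_exclusions(), aac_scheme()))
})

aac_admissible_systems <- function() cached("aac_sy", function() {
  suppressMessages(apply_exclusions(enumerate_systems(aac_scheme()),
                                    aac_system_exclusions(), aac_scheme()))
})

aac_small_design <- function() cached("aac_design", function() {
  generate_design(aac_admissible_systems(), aac_scheme(),
                  n_tasks = 12, n_alts = 3, n_blocks = 1,
                  seed = 20, n_restarts = 2, max_passes = 5)
})

# look up the generating truth for a fitted coefficient label
true_value_of <- function(label, params) {
  side <- sub("\\..*$", "", label)
  key <- sub("^(mean|sd)\\.", "", label)
  if (startsWith(label, "position.")) return(0)
  parts <- strsplit(key, ":", fixed = TRUE)[[1]]
  m <- if (side == "mean") params$mean else params$sd
  v <- if (length(parts) == 1L) m[parts[1], "(constant)"]
       else m[parts[1], parts[2]]
  if (side == "sd") abs(v) else v
}
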