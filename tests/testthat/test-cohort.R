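test_that("generation is bit-reproducible under a fixed seed", {
  a <- simulate_cohort(cohort_config(n = 100, seed = 7))
  b <- simulate_cohort(cohort_config(n = 100, seed = 7))
  expect_identical(a, b)
  c0 <- simulate_cohort(cohort_config(n = 100, seed = 8))
  expect_false(identical(a, c0))
})

test_that("likert scores respect their bounds and delta arithmetic", {
  co <- simulate_cohort(cohort_config(n = 400, seed = 3))
  likert <- setdiff(framecast:::.T1_SCALES, "past_behavior")
  for (v in likert) expect_true(all(co[[v]] >= 1 & co[[v]] <= 7))
  expect_true(all(co$past_behavior >= 0))
  expect_true(all(co$future_intention >= 1 & co$future_intention <= 7))
  expect_equal(co$delta_intention,
               co$future_intention - co$baseline_intention)
  expect_true(all(abs(co$delta_intention) <= 6))
  expect_setequal(levels(co$condition), FRAMINGS)
})

test_that("clipped draws reproduce configured means for mid-scale sds", {
  ## moment-matched clipping: realized means within Monte-Carlo error
  sc <- scale_defaults()
  feasible <- sc$scale[sc$sd <= 1.5 & sc$scale != "past_behavior" &
                         !sc$scale %in% framecast:::.T2_SCALES]
  ms <- sapply(1:30, function(r)
    colMeans(simulate_cohort(cohort_config(n = 545, seed = 100 + r))[feasible]))
  for (v in feasible) {
    target <- sc$mean[sc$scale == v]
    se <- stats::sd(ms[v, ]) / sqrt(ncol(ms))
    expect_lt(abs(mean(ms[v, ]) - target), max(4 * se, 0.02))
  }
})

test_that("condition is randomized independently of Time-1 variables", {
  co <- simulate_cohort(cohort_config(n = 1e5, seed = 11))
  for (v in c("attitude", "prevention_focus", "food_involvement")) {
    bins <- cut(co[[v]], breaks = stats::quantile(co[[v]], c(0, 1/3, 2/3, 1)),
                include.lowest = TRUE)
    mi <- information_gain(as.character(co$condition), as.character(bins))
    expect_lt(mi, 0.005)
  }
})

test_that("exclusion rules filter in order with disjoint counts", {
  roster <- data.frame(
    id = 1:10,
    special_diet = c(TRUE, TRUE, rep(FALSE, 8)),
    past_behavior = c(9, 9, 1, 2, 2.5, rep(9, 5)),
    complete = c(rep(TRUE, 5), FALSE, rep(TRUE, 4)))
  ex <- apply_exclusions(roster)
  expect_equal(unname(ex$counts), c(2, 3, 1))
  expect_equal(nrow(ex$cohort), 4)
  expect_equal(nrow(ex$cohort) + sum(ex$counts), nrow(roster))

  ## no flags set: identity
  clean <- data.frame(special_diet = FALSE, past_behavior = 5,
                      complete = TRUE)[rep(1, 6), ]
  expect_equal(nrow(apply_exclusions(clean)$cohort), 6)

  ## a record triggering two rules counts under the first rule only
  both <- data.frame(special_diet = c(TRUE, FALSE),
                     past_behavior = c(1, 5), complete = c(FALSE, TRUE))
  ex2 <- apply_exclusions(both)
  expect_equal(unname(ex2$counts), c(1, 0, 0))

  expect_error(apply_exclusions(data.frame(x = 1)), "lacks column")
})

test_that("default exclusion burden matches the study conditions", {
  counts <- sapply(1:20, function(r) {
    ex <- apply_exclusions(simulate_cohort(cohort_config(seed = 200 + r)))
    c(ex$counts, survivors = nrow(ex$cohort))
  })
  m <- rowMeans(counts)
  expect_equal(unname(m["special_diet"]), 124, tolerance = 0.1)
  expect_equal(unname(m["low_meat"]), 96, tolerance = 0.25)
  expect_equal(unname(m["incomplete"]), 70, tolerance = 0.15)
  ## survivors hover around the 544/545 the published counts imply
  expect_gt(m["survivors"], 515)
  expect_lt(m["survivors"], 575)
})

test_that("delta intention validates its range", {
  expect_equal(delta_intention(4, 4), 0)
  expect_equal(delta_intention(4.33, 3.00), -1.33)
  expect_equal(delta_intention(1, 7), 6)
  expect_error(delta_intention(0.5, 4), "must lie")
  expect_error(delta_intention(4, 7.2), "must lie")
})

test_that("categorical mode samples from the supplied ground truth", {
  s <- rpmc_network()
  cp <- rpmc_cpts(s)
  cc <- cohort_config(n = 1e5, seed = 5)
  d <- simulate_cohort(cc, mode = "categorical",
                       network = list(structure = s, cpts = cp))
  expect_equal(nrow(d), 1e5)
  ## empirical root marginals match the generator (uniform thirds)
  tab <- table(d$prevention_focus) / nrow(d)
  expect_true(all(abs(tab - 1/3) < 0.02))
  ## conditional frequencies of the mediator match its CPT within 0.02
  sp <- cp$systematic_processing
  sub <- d[d$condition == "gain" & d$promotion_focus == "high" &
             d$food_involvement == "high" &
             d$perceived_behavioral_control == "high" &
             d$desensitization == "low", ]
  key <- "gain|high|high|high|low"
  emp <- table(sub$systematic_processing) / nrow(sub)
  expect_true(all(abs(emp - sp$prob[key, ]) < 0.02))
})

test_that("generator config validates and round-trips through JSON", {
  expect_error(cohort_config(n = 0, seed = 1), "positive")
  expect_error(cohort_config(seed = 1, arms = c(gain = 1)), "arms")
  bad_sc <- scale_defaults(); bad_sc$scale[1] <- "not_a_scale"
  expect_error(cohort_config(seed = 1, scales = bad_sc), "unknown scale")
  eff <- effect_defaults()
  colnames(eff$interactions)[1] <- "attitude_wrong"
  expect_error(cohort_config(seed = 1, effects = eff), "absent variable")

  cc <- cohort_config(n = 50, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_cohort_config(cc, path)
  cc2 <- read_cohort_config(path)
  expect_identical(simulate_cohort(cc), simulate_cohort(cc2))
})

test_that("cohort CSV round-trips with the fixed dialect", {
  co <- simulate_cohort(cohort_config(n = 40, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  header <- readLines(path, n = 1L)
  expect_match(header, '^"id","attitude",')
  co2 <- read_cohort(path)
  expect_equal(co2$attitude, co$attitude)
  expect_identical(levels(co2$condition), FRAMINGS)
})
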