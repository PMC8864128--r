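test_that("structure validation enforces the graph-class constraints", {
  v <- function(n, s, k = 2) bn_variable(n, s, paste0("c", 1:k))
  ## arc against time
  expect_error(bn_structure(list(v("a", "T2"), v("z", "OUTCOME"),
                                 v("b", "T1")),
                            list(c("a", "b"), c("b", "z"))),
               "orientation of time")
  ## arc into the message node
  expect_error(bn_structure(list(v("a", "T1"), v("m", "MESSAGE", 4),
                                 v("z", "OUTCOME")),
                            list(c("a", "m"))),
               "no parents")
  ## outcome with children
  expect_error(bn_structure(list(v("z", "OUTCOME"), v("y", "OUTCOME")),
                            NULL),
               "exactly one OUTCOME")
  ## cycle within a slice
  expect_error(bn_structure(list(v("a", "T1"), v("b", "T1"),
                                 v("z", "OUTCOME")),
                            list(c("a", "b"), c("b", "a"))),
               "cycle")
  ## message cardinality
  expect_error(bn_variable("m", "MESSAGE", c("x", "y")), "exactly 4")
})

test_that("smoothed CPT rows follow the (count + alpha) rule", {
  v <- list(bn_variable("x", "T1", c("a", "b", "c")),
            bn_variable("z", "OUTCOME", c("u", "v")))
  s <- bn_structure(v, NULL)
  d <- data.frame(x = c("a", "a"), z = c("u", "v"))
  cp <- fit_cpts(s, d, alpha = 1)
  expect_equal(unname(cp$x$prob[1, ]), c(3, 1, 1) / 5)
  ## unsmoothed fitting is refused when a parent configuration is unseen
  s_pa <- bn_structure(v, list(c("x", "z")))
  expect_error(fit_cpts(s_pa, d, alpha = 0), "zero-support")

  ## deterministic relation with alpha = 0 gives indicator rows
  s2 <- bn_structure(list(bn_variable("x", "T1", c("a", "b")),
                          bn_variable("z", "OUTCOME", c("u", "v"))),
                     list(c("x", "z")))
  d2 <- data.frame(x = rep(c("a", "b"), 10),
                   z = rep(c("u", "v"), 10))
  cp2 <- fit_cpts(s2, d2, alpha = 0)
  expect_equal(unname(cp2$z$prob), rbind(c(1, 0), c(0, 1)))
})

test_that("CPT estimates converge to the generating tables", {
  s <- bn_structure(list(bn_variable("a", "T1", c("x", "y")),
                         bn_variable("b", "T1", c("x", "y", "z")),
                         bn_variable("z", "OUTCOME", c("u", "v", "w"))),
                    list(c("a", "z"), c("b", "z"), c("a", "b")))
  truth <- random_cpts(s, seed = 31)
  set.seed(32)
  d <- sample_network(s, truth, 1e4)
  est <- fit_cpts(s, d, alpha = 1)
  for (v0 in s$order)
    expect_lt(max(abs(est[[v0]]$prob - truth[[v0]]$prob)), 0.05)
})

test_that("joint probability matches hand arithmetic on small nets", {
  ## two-node chain: p(a) = .4, p(b|a) = .5 -> p(a, b) = .2
  s <- bn_structure(list(bn_variable("a", "T1", c("a1", "a2")),
                         bn_variable("b", "OUTCOME", c("b1", "b2"))),
                    list(c("a", "b")))
  cp <- list(a = list(node = "a", parents = character(),
                      prob = matrix(c(.4, .6), 1,
                                    dimnames = list("", c("a1", "a2")))),
             b = list(node = "b", parents = "a",
                      prob = matrix(c(.5, .3, .5, .7), 2,
                                    dimnames = list(c("a1", "a2"),
                                                    c("b1", "b2")))))
  class(cp) <- "bn_cpts"
  expect_equal(joint_probability(s, cp, c(a = "a1", b = "b1")), 0.2)

  ## edgeless network: product of marginals
  s2 <- bn_structure(list(bn_variable("a", "T1", c("a1", "a2")),
                          bn_variable("z", "OUTCOME", c("z1", "z2"))), NULL)
  cp2 <- random_cpts(s2, seed = 5)
  expect_equal(joint_probability(s2, cp2, c(a = "a1", z = "z2")),
               cp2$a$prob[1, "a1"] * cp2$z$prob[1, "z2"])
  expect_error(joint_probability(s2, cp2, c(a = "a1")), "incomplete")
})

test_that("exact inference equals brute-force joint computation", {
  ## randomized property over networks of <= 7 nodes
  for (seed in 1:25) {
    s <- random_network(seed)
    cp <- random_cpts(s, seed + 1000)
    joint <- brute_joint(s, cp)
    expect_equal(sum(joint$p), 1, tolerance = 1e-12)

    ## factorized joint equals the brute-force table on a random row
    i <- sample(nrow(joint), 1L)
    asg <- unlist(joint[i, s$order])
    expect_equal(joint_probability(s, cp, asg), joint$p[i],
                 tolerance = 1e-12)

    ## posterior under random partial evidence
    z <- framecast:::.outcome_var(s)
    others <- setdiff(s$order, z)
    nev <- sample(0:length(others), 1L)
    ev <- if (nev) {
      vs <- sample(others, nev)
      stats::setNames(vapply(vs, function(v0)
        sample(s$variables[[v0]]$categories, 1L), ""), vs)
    } else NULL
    post <- posterior_target(s, cp, ev)
    oracle <- brute_posterior(joint, z, ev)
    expect_equal(sum(post), 1, tolerance = 1e-12)
    expect_lt(max(abs(post - oracle[names(post)])), 1e-9)
  }
})

test_that("posterior special cases and the tie-break rule hold", {
  s <- rpmc_network()
  cp <- rpmc_cpts(s)
  ## full evidence on all parents of the outcome returns its CPT row
  t1 <- c(baseline_intention = "high", prevention_focus = "low",
          perceived_severity = "medium", diffused_responsibility = "low",
          systematic_processing = "high")
  post <- posterior_target(s, cp, t1, message = "loss")
  ## key order follows the declared parent order of the outcome
  pa <- s$parents$delta_intention
  key <- paste(c(condition = "loss", t1)[pa], collapse = "|")
  expect_equal(unname(post), unname(cp$delta_intention$prob[key, ]),
               tolerance = 1e-12)

  ## observing the outcome is rejected; zero-probability context signals
  expect_error(posterior_target(s, cp, c(delta_intention = "neutral")),
               "target")

  ## argmax tie-break by category order (most negative first)
  s2 <- bn_structure(list(bn_variable("z", "OUTCOME", OUTCOME_CATS)), NULL)
  cp2 <- list(z = list(node = "z", parents = character(),
                       prob = matrix(c(.1, .1, .1, .35, .35), 1,
                                     dimnames = list("", OUTCOME_CATS)),
                       alpha = 0))
  class(cp2) <- "bn_cpts"
  expect_equal(predict_target(s2, cp2), "low-positive")
  cp2$z$prob <- matrix(c(.1, .1, .6, .1, .1), 1,
                       dimnames = list("", OUTCOME_CATS))
  expect_equal(predict_target(s2, cp2), "neutral")
})

test_that("posterior is invariant to variable declaration order", {
  v <- list(bn_variable("a", "T1", c("x", "y")),
            bn_variable("b", "T1", c("x", "y", "z")),
            bn_variable("z", "OUTCOME", c("u", "v")))
  arcs <- list(c("a", "z"), c("b", "z"))
  s1 <- bn_structure(v, arcs)
  s2 <- bn_structure(v[c(2, 1, 3)], arcs)
  cp1 <- random_cpts(s1, 77)
  cp2 <- cp1[s2$order]
  class(cp2) <- "bn_cpts"
  p1 <- posterior_target(s1, cp1, c(a = "x"))
  p2 <- posterior_target(s2, cp2, c(a = "x"))
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("smoothing limits: alpha -> Inf flattens, n -> Inf sharpens", {
  s <- bn_structure(list(bn_variable("z", "OUTCOME", c("u", "v", "w"))), NULL)
  d <- data.frame(z = c(rep("u", 70), rep("v", 20), rep("w", 10)))
  flat <- fit_cpts(s, d, alpha = 1e7)$z$prob
  expect_equal(unname(flat[1, ]), rep(1/3, 3), tolerance = 1e-4)
  big <- d[rep(1:100, 100), , drop = FALSE]
  sharp <- fit_cpts(s, big, alpha = 1)$z$prob
  expect_equal(unname(sharp[1, ]), c(.7, .2, .1), tolerance = 1e-3)
})
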