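triangle_contrasts <- function(y_ab = 0.5, y_ac = 0.3, y_cb = 0.1,
                               v = 0.01) {
  tibble::tibble(
    study_id = c("s1", "s2", "s3"),
    treat1 = c("A", "A", "C"), treat2 = c("B", "C", "B"),
    y = c(y_ab, y_ac, y_cb), v = v, baseline = c("B", "C", "B")
  )
}

test_that("star networks have no estimable inconsistency", {
  star <- tibble::tibble(
    study_id = c("s1", "s2", "s3"),
    treat1 = c("SMR", "NSA", "OPI"), treat2 = "PLA",
    y = c(0.2, 0.4, 0.6), v = 0.04
  )
  res <- design_by_treatment_test(star, reference = "PLA")
  expect_equal(res$df, 0L)
  expect_false(res$estimable)
  expect_match(res$note, "no inconsistency estimable")
})

test_that("two-treatment networks give a degenerate global test, not a crash", {
  two <- tibble::tibble(study_id = c("s1", "s2"), treat1 = "SMR",
                        treat2 = "PLA", y = c(0.2, 0.3), v = 0.04)
  res <- design_by_treatment_test(two, reference = "PLA")
  expect_equal(res$df, 0L)
  expect_false(res$estimable)
})

test_that("an injected design offset is detected by the global test", {
  set.seed(451)
  cfg <- sim_config(treatments = c("PLA", "SMR", "NSA"),
                    true_d = c(0, 0.3, 0.6), tau = 0.05,
                    n_trials_per_design = 6, n_per_arm = 200,
                    inconsistency_offset = list(design = c("PLA", "SMR"),
                                                pair = c("SMR", "PLA"),
                                                offset = 1.0),
                    seed = 451)
  res <- design_by_treatment_test(simulate_contrasts(cfg), "PLA")
  expect_true(res$estimable)
  expect_lt(res$p_value, 0.01)
})

test_that("the worked loop example gives IF = 0.1, SE = 0.1732, p = 0.564", {
  res <- loop_inconsistency(triangle_contrasts(), c("A", "B", "C"))
  expect_equal(res$if_est, 0.1, tolerance = 1e-10)
  expect_equal(res$se_if, sqrt(0.03), tolerance = 1e-10)
  expect_equal(res$se_if, 0.1732, tolerance = 1e-3)
  expect_equal(res$p_value, 0.5637, tolerance = 1e-3)
  expect_equal(res$ci_low, 0)  # truncated at zero
})

test_that("a perfectly consistent loop has IF = 0", {
  res <- loop_inconsistency(triangle_contrasts(y_ab = 0.4, y_ac = 0.3,
                                               y_cb = 0.1),
                            c("A", "B", "C"))
  expect_equal(res$if_est, 0, tolerance = 1e-12)
})

test_that("loop records are direction-invariant and CI-truncated", {
  set.seed(452)
  for (i in 1:10) {
    ctr <- triangle_contrasts(rnorm(1, 0, 0.5), rnorm(1, 0, 0.5),
                              rnorm(1, 0, 0.5), v = runif(1, 0.005, 0.1))
    base <- loop_inconsistency(ctr, c("A", "B", "C"))
    for (perm in list(c("B", "C", "A"), c("C", "A", "B"), c("C", "B", "A"))) {
      alt <- loop_inconsistency(ctr, perm)
      expect_equal(alt$if_est, base$if_est, tolerance = 1e-12)
      expect_equal(alt$p_value, base$p_value, tolerance = 1e-12)
    }
    expect_gte(base$ci_low, 0)
  }
})

test_that("loops without full direct evidence are skipped with a reason", {
  ctr <- triangle_contrasts()[1:2, ]
  res <- loop_inconsistency(ctr, c("A", "B", "C"))
  expect_true(is.na(res$if_est))
  expect_match(res$note, "without direct evidence")
  all_loops <- loop_inconsistency_all(triangle_contrasts(), reference = "A")
  expect_equal(nrow(all_loops), 1)
})

test_that("node-splitting flags unsplittable comparisons", {
  star <- tibble::tibble(study_id = c("s1", "s2"),
                         treat1 = c("SMR", "NSA"), treat2 = "PLA",
                         y = c(0.2, 0.4), v = 0.04)
  res <- node_split(star, c("SMR", "PLA"), reference = "PLA")
  expect_false(res$splittable)
  expect_match(res$note, "not splittable")
  none <- node_split(star, c("SMR", "NSA"), reference = "PLA")
  expect_match(none$note, "no direct evidence")
})

test_that("node-splitting separates direct and indirect evidence", {
  mc <- nma_mcmc(n_chains = 2, n_iter = 2000, n_burnin = 800, seed = 9)
  # consistent triangle with several studies per edge
  cfg <- sim_config(treatments = c("PLA", "SMR", "NSA"),
                    true_d = c(0, 0.3, 0.6), tau = 0.1,
                    n_trials_per_design = 6, n_per_arm = 100, seed = 453)
  ctr <- simulate_contrasts(cfg)
  res <- node_split(ctr, c("SMR", "PLA"), "PLA", mcmc = mc)
  expect_true(res$splittable)
  expect_gt(res$bayes_p, 0.05)
  expect_equal(res$diff, res$direct - res$indirect, tolerance = 0.05)

  # a large offset on the split edge must be flagged
  cfg_off <- sim_config(treatments = c("PLA", "SMR", "NSA"),
                        true_d = c(0, 0.3, 0.6), tau = 0.05,
                        n_trials_per_design = 6, n_per_arm = 400,
                        inconsistency_offset = list(
                          design = c("PLA", "SMR"),
                          pair = c("SMR", "PLA"), offset = 1.0),
                        seed = 454)
  res_off <- node_split(simulate_contrasts(cfg_off), c("SMR", "PLA"), "PLA",
                        mcmc = mc)
  expect_lt(res_off$bayes_p, 0.05)
  expect_gt(res_off$diff, 0.5)
})

test_that("node-split direct evidence matches DL pooling when tau vanishes", {
  ctr <- dplyr::bind_rows(
    triangle_contrasts(y_ab = 0.45, y_ac = 0.3, y_cb = 0.1, v = 0.02),
    tibble::tibble(study_id = "s4", treat1 = "A", treat2 = "B",
                   y = 0.55, v = 0.02, baseline = "B")
  )
  res <- node_split(ctr, c("A", "B"), reference = "A",
                    priors = nma_priors(d_sd = 100, tau_upper = 1e-3),
                    mcmc = nma_mcmc(n_chains = 2, n_iter = 4000,
                                    n_burnin = 1000, seed = 10))
  direct_dl <- pool_random_effects(
    tibble::tibble(y = c(0.45, 0.55), v = c(0.02, 0.02)))
  expect_equal(res$direct, direct_dl$pooled, tolerance = 0.02)
})

test_that("the bundled report combines all three assessments", {
  ctr <- triangle_contrasts()
  rep <- inconsistency_report(ctr, reference = "A",
                              mcmc = nma_mcmc(n_chains = 2, n_iter = 1000,
                                              n_burnin = 400, seed = 11))
  expect_s3_class(rep, "nma_inconsistency")
  expect_equal(nrow(rep$loops), 1)
  expect_equal(nrow(rep$node_splits), 3)
  expect_true(all(rep$node_splits$splittable))
})
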