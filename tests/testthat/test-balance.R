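test_that("binary SMD matches hand-computed values and conventions", {
  expect_equal(smd_binary(0.37, 0.37), 0)
  expect_equal(smd_binary(0.2, 0.1), 0.1 / sqrt(0.125))  # ~0.2828
  # degenerate pooled variance with unequal proportions -> flagged non-finite
  expect_false(is.finite(smd_binary(1, 0)))
  expect_equal(smd_binary(0, 0), 0)
  expect_equal(smd_binary(1, 1), 0)
  expect_error(smd_binary(1.2, 0.5), "\\[0, 1\\]")
  # antisymmetry
  expect_equal(smd_binary(0.1, 0.2), -smd_binary(0.2, 0.1))
})

test_that("continuous SMD matches hand-computed values and conventions", {
  expect_equal(smd_continuous(10, 2, 8, 2), 1)
  expect_equal(smd_continuous(5, 3, 5, 3), 0)
  expect_equal(smd_continuous(5, 1, 5, 7), 0)    # equal means, unequal SDs
  expect_false(is.finite(smd_continuous(5, 0, 3, 0)))
  expect_error(smd_continuous(1, -1, 0, 1), "nonnegative")
  expect_equal(smd_continuous(8, 2, 10, 2), -1)
})

test_that("cohort comparison routes kinds, is antisymmetric and zero on self", {
  pop <- make_toy_population()
  s1 <- extract_covariates(toy_cohort(1:3, 960), pop, cohort_id = "a")
  s2 <- extract_covariates(toy_cohort(c(1L, 3L), 960), pop, cohort_id = "b")

  self <- compare_cohorts(s1, s1)
  expect_true(all(self$smd == 0))

  ab <- compare_cohorts(s1, s2, comparison_id = "ab")
  ba <- compare_cohorts(s2, s1, comparison_id = "ba")
  expect_equal(ab$smd, -ba$smd)
  expect_identical(unique(ab$comparison_id), "ab")
  # element-wise agreement with the scalar formulas
  bin <- ab[covariate_kind == "binary"]
  expect_equal(bin$smd, smd_binary(bin$stat_target, bin$stat_comparator))

  # mismatched universes are refused
  expect_error(compare_cohorts(s1, s2[covariate_id != "drug_4001"]), "mismatch")
})

test_that("imbalance counting applies the >= 0.1 rule with absolute values", {
  smds <- c(0.05, 0.09, 0.10, 0.15, 0.20)
  bal <- data.table(comparison_id = "x", window_name = "day0",
                    covariate_id = paste0("c", seq_along(smds)),
                    covariate_kind = "binary",
                    stat_target = 0.5, stat_comparator = 0.5, smd = smds)
  rep_gte <- count_imbalanced(bal, 0.1)
  expect_identical(rep_gte$n_imbalanced, 3L)  # balanced iff SMD < 0.1
  expect_identical(rep_gte$n_total, 5L)
  # strict > variant (the alternative reading) drops the boundary case
  expect_identical(count_imbalanced(bal, 0.1, rule = "gt")$n_imbalanced, 2L)

  bal$smd <- c(-0.2, 0.2, 0, 0, 0)
  expect_identical(count_imbalanced(bal, 0.1)$n_imbalanced, 2L)  # sign symmetry
  bal$smd <- rep(0, 5)
  expect_identical(count_imbalanced(bal, 0.1)$n_imbalanced, 0L)
  # non-finite SMDs count as imbalanced and are reported separately
  bal$smd <- c(Inf, 0, 0, 0, 0)
  r <- count_imbalanced(bal, 0.1)
  expect_identical(r$n_imbalanced, 1L)
  expect_identical(r$n_nonfinite, 1L)
})

test_that("imbalance counts are monotone nonincreasing in the threshold", {
  withr::with_seed(77, {
    bal <- data.table(comparison_id = "x", window_name = "w",
                      covariate_id = paste0("c", 1:200),
                      covariate_kind = "binary", stat_target = 0.5,
                      stat_comparator = 0.5, smd = rnorm(200, 0, 0.2))
  })
  counts <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.5),
                   function(th) count_imbalanced(bal, th)$n_imbalanced, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("adding a covariate absent in both cohorts leaves balance unchanged", {
  pop <- make_toy_population()
  cohort1 <- toy_cohort(1:3, 960)
  cohort2 <- toy_cohort(c(1L, 3L), 960)
  base <- count_imbalanced(compare_cohorts(
    extract_covariates(cohort1, pop, cohort_id = "a"),
    extract_covariates(cohort2, pop, cohort_id = "b"), "cmp"))
  aug <- pop
  # a concept recorded only for person 5 (not in either cohort): new universe
  # entry with proportion 0 in both
  aug$persons <- rbind(pop$persons,
                       data.table(person_id = 5L, sex = "F",
                                  age_at_start = 50L, latent_burden = 1))
  aug$visits <- rbind(pop$visits,
                      data.table(person_id = 5L, visit_date = toy_day(600)))
  aug$events <- rbind(pop$events,
                      data.table(person_id = 5L, event_date = toy_day(600),
                                 concept_id = 9009L, domain = "condition"))
  bal2 <- compare_cohorts(extract_covariates(cohort1, aug, cohort_id = "a"),
                          extract_covariates(cohort2, aug, cohort_id = "b"), "cmp")
  expect_true(all(bal2[covariate_id == "condition_9009"]$smd == 0))
  r2 <- count_imbalanced(bal2)
  expect_identical(r2$n_imbalanced, base$n_imbalanced)
  expect_identical(r2$n_total, base$n_total + 1L)  # one new covariate per window
})

test_that("scatter export is binary-only, diagonal on self-comparison", {
  pop <- make_toy_population()
  s1 <- extract_covariates(toy_cohort(1:3, 960), pop, cohort_id = "a")
  s2 <- extract_covariates(toy_cohort(c(1L, 3L), 960), pop, cohort_id = "b")
  sc_self <- export_scatter(s1, s1)
  expect_true(all(sc_self$proportion_target == sc_self$proportion_comparator))
  sc <- export_scatter(s1, s2)
  expect_identical(nrow(sc), 3L * 5L)  # n binary covariates x 5 windows
  expect_false("visit_count" %in% sc$covariate_id)
  one <- sc[covariate_id == "condition_1001" & window_name == "day0"]
  expect_equal(one$proportion_target, 1 / 3)
  expect_equal(one$proportion_comparator, 1 / 2)
})

test_that("imbalance matrix renders n/N (%) cells per comparison and window", {
  rep_tbl <- data.table(comparison_id = c("a", "a", "b", "b"),
                        window_name = c("day0", "long", "day0", "long"),
                        n_imbalanced = c(3L, 1L, 0L, 2L),
                        n_total = c(10L, 10L, 10L, 10L),
                        fraction = c(0.3, 0.1, 0, 0.2),
                        n_nonfinite = 0L)
  wide <- render_imbalance_matrix(rep_tbl)
  expect_identical(wide$day0, c("3/10 (30.0%)", "0/10 (0.0%)"))
  md <- render_imbalance_matrix(rep_tbl, markdown = TRUE)
  expect_match(md[1], "comparison_id")
  expect_length(md, 4L)
})
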