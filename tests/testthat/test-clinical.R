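test_that("dose-escalation decisions equal the hand-enumerated rule table", {
  # 3+3: 0/3 safe, 1/3 expand, >=2/3 exceeded; on 6: <=1 safe, >=2 exceeded
  oracle_33 <- function(n_dlt, n_eval) {
    if (n_eval == 3) {
      if (n_dlt == 0) "safe" else if (n_dlt == 1) "expand" else "exceeded"
    } else {
      if (n_dlt <= 1) "safe" else "exceeded"
    }
  }
  for (n_eval in c(3L, 6L)) {
    for (n_dlt in 0:n_eval) {
      expect_equal(dlt_decision(n_dlt, n_eval, "three_plus_three")$decision,
                   oracle_33(n_dlt, n_eval),
                   info = sprintf("3+3 %d/%d", n_dlt, n_eval))
    }
  }
  # modified 6+6 (documented interpretation): 0/6 safe, 1/6 expand,
  # >=2/6 exceeded; 7-12 evaluable follow the < 33% rule
  oracle_66 <- function(n_dlt, n_eval) {
    if (n_eval == 6) {
      if (n_dlt == 0) "safe" else if (n_dlt == 1) "expand" else "exceeded"
    } else {
      if (n_dlt / n_eval < 1 / 3) "safe" else "exceeded"
    }
  }
  for (n_eval in 6:12) {
    for (n_dlt in 0:n_eval) {
      expect_equal(dlt_decision(n_dlt, n_eval, "six_plus_six")$decision,
                   oracle_66(n_dlt, n_eval),
                   info = sprintf("6+6 %d/%d", n_dlt, n_eval))
    }
  }
  # the observed zero-DLT cohorts map to "safe"
  expect_equal(dlt_decision(0, 6, "three_plus_three")$decision, "safe")
  expect_equal(dlt_decision(0, 6, "six_plus_six")$decision, "safe")
  expect_equal(dlt_decision(0, 7, "six_plus_six")$decision, "safe")
  expect_error(dlt_decision(0, 2, "three_plus_three"), "at least 3")
  expect_error(dlt_decision(0, 4, "three_plus_three"), "3 or 6")
  expect_error(dlt_decision(0, 5, "six_plus_six"), "at least 6")
  expect_error(dlt_decision(4, 3, "three_plus_three"), "n_eval")
})

make_ae <- function(id, term = "fatigue", grade = 1, related = FALSE,
                    serious = FALSE, withdrawal = FALSE,
                    interruption = FALSE, immune = FALSE) {
  tibble::tibble(id = id, term = term, grade = as.integer(grade),
                 related = related, serious = serious,
                 withdrawal = withdrawal, interruption = interruption,
                 immune_related = immune)
}

test_that("AE summary counts subjects once per category with half-up percentages", {
  roster <- tibble::tibble(
    id = sprintf("P%02d", 1:34),
    part = c(rep("1", 21), rep("2A", 13)),
    group = c(rep("1 mg/kg", 6), rep("3 mg/kg", 3), rep("10 mg/kg", 12),
              rep("500 mg Q3W", 6), rep("1000 mg Q6W", 7)))
  # 12 subjects with a grade-3 event overall, 4 of them related;
  # a multi-event subject still counts once
  g3_ids <- sprintf("P%02d", c(1:10, 22, 23))
  rel_g3 <- sprintf("P%02d", c(1, 2, 22, 23))
  records <- dplyr::bind_rows(
    make_ae(g3_ids, term = "anemia", grade = 3,
            related = g3_ids %in% rel_g3),
    make_ae("P01", term = "dyspnea", grade = 4),   # duplicate g3 subject
    make_ae(sprintf("P%02d", 1:7), term = "fatigue", grade = 1,
            related = TRUE),
    make_ae(sprintf("P%02d", 22:26), term = "fatigue", grade = 1,
            related = TRUE))
  s <- summarize_aes(records, roster)
  cats <- s$categories
  pooled <- cats[cats$part == "All" & cats$group == "Total", ]
  expect_equal(pooled$pct[pooled$category == "Any grade >=3 AE"], 35.3)
  expect_equal(pooled$pct[pooled$category == "Related grade >=3 AE"], 11.8)
  p1_fat <- s$related_terms[s$related_terms$part == "1" &
                              s$related_terms$term == "fatigue", ]
  expect_equal(p1_fat$n, 7L)
  expect_equal(p1_fat$pct, 33.3)
  p2_fat <- s$related_terms[s$related_terms$part == "2A" &
                              s$related_terms$term == "fatigue", ]
  expect_equal(p2_fat$pct, 38.5)
  # empty record set gives all-zero counts
  s0 <- summarize_aes(records[0, ], roster)
  expect_true(all(s0$categories$n == 0))
  # records for unknown subjects are an error
  expect_error(summarize_aes(make_ae("ghost"), roster), "absent")
  expect_error(summarize_aes(make_ae("P01", grade = 7), roster), "grade")
})

test_that("per-term related incidence is filtered at the cutoff within a part", {
  roster <- tibble::tibble(id = sprintf("P%02d", 1:20), part = "1",
                           group = rep(c("a", "b"), each = 10))
  records <- dplyr::bind_rows(
    make_ae(c("P01", "P02"), term = "nausea", related = TRUE),  # 2/10 in a
    make_ae("P11", term = "pruritus", related = TRUE))          # 1/10 in b
  s <- summarize_aes(records, roster, term_incidence_cutoff = 0.15)
  expect_true("nausea" %in% s$related_terms$term)
  expect_false("pruritus" %in% s$related_terms$term)
})

test_that("confirmed best overall response follows the 4-week rule", {
  # a lone unconfirmed PR followed by progression is stable disease at best
  d1 <- tibble::tibble(id = "A", time = c(70, 140),
                       category = c("irPR", "irPD"))
  b1 <- best_overall_response(d1)
  expect_equal(b1$best_response, "irSD")
  # PR at day 90 confirmed at day 125 -> best irPR, time to response 90
  d2 <- tibble::tibble(id = "B", time = c(50, 90, 125, 250),
                       category = c("irSD", "irPR", "irPR", "irPD"))
  b2 <- best_overall_response(d2)
  expect_equal(b2$best_response, "irPR")
  expect_equal(b2$response_time_days, 90)
  expect_equal(b2$duration_days, 160)
  expect_true(b2$progression_observed)
  # a confirmation 27 days later is too early
  d3 <- tibble::tibble(id = "C", time = c(90, 117),
                       category = c("irPR", "irPR"))
  expect_equal(best_overall_response(d3)$best_response, "irSD")
  # CR confirmed by CR; PR-then-CR confirms the PR
  d4 <- tibble::tibble(id = "D", time = c(90, 150),
                       category = c("irPR", "irCR"))
  expect_equal(best_overall_response(d4)$best_response, "irPR")
  # progression alone
  d5 <- tibble::tibble(id = "E", time = c(70, 140),
                       category = c("irPD", "irPD"))
  expect_equal(best_overall_response(d5)$best_response, "irPD")
  # no evaluable assessment
  d6 <- tibble::tibble(id = "F", time = 70, category = "NE")
  expect_equal(best_overall_response(d6)$best_response, "NE")
  expect_error(best_overall_response(
    tibble::tibble(id = "G", time = 70, category = "PR")), "category")
})

test_that("response rates reproduce the count arithmetic with one-decimal rounding", {
  best <- c("irPR", "irPR", rep("irSD", 5), rep("irPD", 14))
  r <- response_rates(best)
  expect_equal(r$n_evaluable, 21)
  expect_equal(r$orr_pct, 9.5)
  expect_equal(r$dcr_pct, 33.3)
  expect_equal(response_rates(rep("irPD", 10))$orr_pct, 0)
  # ORR <= DCR <= 100 under random tabulations
  withr::with_seed(61, {
    for (i in 1:20) {
      b <- sample(c("irCR", "irPR", "irSD", "irPD", "NE"), 30, replace = TRUE)
      r <- response_rates(b)
      expect_lte(r$orr_pct, r$dcr_pct)
      expect_lte(r$dcr_pct, 100)
    }
  })
})

test_that("pipeline consistency: constructed cohort flows from assessments to rates", {
  # 2 confirmed PRs, 5 SDs, 14 PDs among 21
  visits <- c(70, 140, 210)
  mk <- function(id, cats) tibble::tibble(id = id,
                                          time = visits[seq_along(cats)],
                                          category = cats)
  d <- dplyr::bind_rows(
    purrr::map_dfr(1:2, function(i) mk(sprintf("pr%d", i),
                                       c("irPR", "irPR", "irPD"))),
    purrr::map_dfr(1:5, function(i) mk(sprintf("sd%d", i),
                                       c("irSD", "irSD", "irPD"))),
    purrr::map_dfr(1:14, function(i) mk(sprintf("pd%d", i),
                                        c("irPD", "irPD"))))
  bor <- best_overall_response(d)
  r <- response_rates(bor)
  expect_equal(r$n_pr, 2L)
  expect_equal(r$n_sd, 5L)
  expect_equal(r$orr_pct, 9.5)
  expect_equal(r$dcr_pct, 33.3)
})
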