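test_that("pattern fractions count over all classified patches", {
  expect_equal(compute_fractions(c("gp3", "gp3", "non_atypical", "gp4plus")),
               c(frac_gp3 = 0.5, frac_gp4plus = 0.25))
  expect_equal(compute_fractions(rep("non_atypical", 7)),
               c(frac_gp3 = 0, frac_gp4plus = 0))
  expect_error(compute_fractions(character(0)), "empty")
  expect_error(compute_fractions(c("gp3", "stroma")), "fused")
  # large random label set against an independent tally
  set.seed(12)
  lab <- sample(fused_classes(), 1000, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  fr <- compute_fractions(lab)
  expect_equal(unname(fr["frac_gp3"]), sum(lab == "gp3") / 1000)
  expect_equal(unname(fr["frac_gp4plus"]), sum(lab == "gp4plus") / 1000)
})

test_that("adjusted grade-group rule: doubling, threshold, majority/minority", {
  gg <- function(f3, f4, ...) {
    as.character(assign_adjusted_gg(f3, f4, ...)$adjusted_gg)
  }
  expect_equal(gg(0.60, 0.00), "1")   # GP3 doubled
  expect_equal(gg(0.10, 0.30), "3")   # GP>=4 majority + GP3
  expect_equal(gg(0.30, 0.10), "2")   # GP3 majority + GP>=4
  expect_equal(gg(0.02, 0.50), "4")   # GP3 under 4.5%: GP>=4 doubled
  expect_equal(gg(0.00, 0.00), "benign")
  expect_equal(gg(0.50, 0.50), "3")   # exact tie grades up: GP>=4 majority
  expect_equal(gg(0.045, 0.00), "1")  # threshold is inclusive
  expect_equal(gg(0.0449, 0.00), "benign")
  # majority/minority fields
  r <- assign_adjusted_gg(0.1, 0.3)
  expect_equal(r$majority, "gp4plus")
  expect_equal(r$minority, "gp3")
  r2 <- assign_adjusted_gg(0.6, 0)
  expect_equal(r2$majority, "gp3")
  expect_equal(r2$minority, "gp3")
  expect_true(is.na(assign_adjusted_gg(0, 0)$majority))
  expect_error(assign_adjusted_gg(0.7, 0.5), "sum")
  expect_error(assign_adjusted_gg(-0.1, 0.5), "fractions")
})

test_that("the full (majority, minority) mapping is reproduced", {
  cases <- list(
    list(f = c(0.40, 0.00), gg = "1"),  # 3+3
    list(f = c(0.40, 0.20), gg = "2"),  # 3 + >=4
    list(f = c(0.20, 0.40), gg = "3"),  # >=4 + 3
    list(f = c(0.00, 0.40), gg = "4")   # >=4 + >=4
  )
  for (cs in cases) {
    expect_equal(as.character(assign_adjusted_gg(cs$f[1], cs$f[2])$adjusted_gg),
                 cs$gg)
  }
})

test_that("threshold monotonicity and doubling at zero threshold", {
  # raising min_fraction can drop patterns but never flips majority/minority
  f3 <- 0.3; f4 <- 0.12
  for (thr in c(0, 0.045, 0.1, 0.2)) {
    r <- assign_adjusted_gg(f3, f4, grading_config(min_fraction = thr))
    if (!is.na(r$majority) && !is.na(r$minority) && r$majority != r$minority) {
      expect_equal(r$majority, "gp3")
      expect_equal(r$minority, "gp4plus")
    }
  }
  # any positive fraction fires the doubling rule at threshold 0
  r0 <- assign_adjusted_gg(0.001, 0, grading_config(min_fraction = 0))
  expect_equal(as.character(r0$adjusted_gg), "1")
})

test_that("cohort grading groups by biopsy and is duplication-invariant", {
  fused <- data.frame(
    biopsy_id = rep(c("a", "b", "c"), times = c(4, 4, 4)),
    fused_label = c("gp3", "gp3", "non_atypical", "gp4plus",
                    rep("non_atypical", 4),
                    c("gp4plus", "gp4plus", "gp3", "non_atypical"))
  )
  g <- grade_cohort(fused)
  expect_equal(g$biopsy_id, c("a", "b", "c"))
  expect_equal(as.character(g$adjusted_gg), c("2", "benign", "3"))
  # duplicating every row leaves all grades unchanged
  g2 <- grade_cohort(rbind(fused, fused))
  expect_equal(g2, g)
  # random cohort against a per-biopsy manual recomputation
  set.seed(8)
  rnd <- data.frame(
    biopsy_id = sample(sprintf("b%d", 1:5), 400, replace = TRUE),
    fused_label = sample(fused_classes(), 400, replace = TRUE)
  )
  gr <- grade_cohort(rnd)
  for (i in seq_len(nrow(gr))) {
    lab <- rnd$fused_label[rnd$biopsy_id == gr$biopsy_id[i]]
    expect_equal(gr$frac_gp3[i], mean(lab == "gp3"))
    expect_equal(gr$frac_gp4plus[i], mean(lab == "gp4plus"))
  }
})

test_that("reference grades from annotation areas match composition truth", {
  comp <- c(stroma = 0.3, benign_gland = 0.2, gp3 = 0.35, gp4plus = 0.15)
  g <- generate_slide(comp, size = c(600, 900), seed = 21, biopsy_id = "rg1")
  ref <- reference_grade_from_annotations(g$ann, 600, 900)
  expect_equal(ref$biopsy_id, "rg1")
  expect_equal(as.character(ref$adjusted_gg), "2")  # gp3 majority + gp4
  expect_equal(ref$frac_gp3, comp[["gp3"]], tolerance = 0.05)
  expect_equal(ref$frac_gp4plus, comp[["gp4plus"]], tolerance = 0.05)
})
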