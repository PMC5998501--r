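test_that("genetic values follow the coefficient coding", {
  m <- toy_model(effect_rows(list(class = "a", term = "L1", estimate = 2),
                             list(class = "d", term = "L1", estimate = 1)))
  expect_equal(genetic_value(c(L1 = 2L), m), 2)
  expect_equal(genetic_value(c(L1 = 1L), m), 1)
  expect_equal(genetic_value(c(L1 = 0L), m), -2)
  expect_equal(genetic_value(c(L1 = "QQ"), m), 2)
  # epistatic pair aa = 1: (QQ, QQ) adds +1, (QQ, qq) adds -1
  m2 <- toy_model(effect_rows(
    list(class = "a", term = "L1", estimate = 0),
    list(class = "a", term = "L2", estimate = 0),
    list(class = "aa", term = "L1 & L2", estimate = 1)))
  expect_equal(genetic_value(c(L1 = 2L, L2 = 2L), m2), 1)
  expect_equal(genetic_value(c(L1 = 2L, L2 = 0L), m2), -1)
  expect_error(genetic_value(c(L1 = 2L), m2), "incomplete")
})

test_that("genetic values agree with an independent evaluator on random models", {
  set.seed(11)
  loci <- paste0("L", 1:8)
  eff <- list()
  for (l in loci) {
    eff <- c(eff, list(list(class = "a", term = l,
                            estimate = round(stats::rnorm(1), 2)),
                       list(class = "d", term = l,
                            estimate = round(stats::rnorm(1), 2))))
  }
  prs <- c("L1 & L4", "L2 & L7", "L5 & L6")
  for (pr in prs)
    for (cl in c("aa", "ad", "da", "dd"))
      eff <- c(eff, list(list(class = cl, term = pr,
                              estimate = round(stats::rnorm(1), 2))))
  effects <- do.call(effect_rows, eff)
  m <- toy_model(effects)
  for (i in 1:100) {
    codes <- stats::setNames(sample(0:2, 8, replace = TRUE), loci)
    expect_equal(genetic_value(codes, m),
                 oracle_genetic_value(codes, effects))
  }
})

test_that("superior designs equal brute-force enumeration with epistasis", {
  set.seed(13)
  loci <- paste0("L", 1:10)
  eff <- list()
  for (l in loci)
    eff <- c(eff, list(list(class = "a", term = l,
                            estimate = round(stats::rnorm(1), 2)),
                       list(class = "d", term = l,
                            estimate = round(stats::rnorm(1), 2))))
  # two 3-locus epistatic components: {L1,L2,L3} and {L7,L8,L9}
  for (pr in c("L1 & L2", "L2 & L3", "L7 & L8", "L8 & L9"))
    for (cl in c("aa", "dd"))
      eff <- c(eff, list(list(class = cl, term = pr,
                              estimate = round(stats::rnorm(1), 2))))
  effects <- do.call(effect_rows, eff)
  m <- toy_model(effects)
  for (obj in c("max", "min")) {
    for (mode in c("GSH", "GSL")) {
      d <- design_superior(m, design_target(mode, obj))
      allowed <- if (mode == "GSL") c(2L, 0L) else c(2L, 1L, 0L)
      grid <- expand.grid(rep(list(allowed), 10))
      vals <- apply(grid, 1, function(r)
        oracle_genetic_value(stats::setNames(as.integer(r), loci), effects))
      best <- if (obj == "max") max(vals) else min(vals)
      expect_equal(d$value, best, tolerance = 1e-10)
    }
  }
  # min objective equals max on the sign-flipped model
  m_neg <- m
  m_neg$coef_table$estimate <- -m_neg$coef_table$estimate
  d_min <- design_superior(m, design_target("GSH", "min"))
  d_maxneg <- design_superior(m_neg, design_target("GSH", "max"))
  expect_equal(d_min$value, -d_maxneg$value, tolerance = 1e-10)
  expect_identical(d_min$assignment, d_maxneg$assignment)
})

test_that("hybrid space dominates line space and dominance favors heterozygotes", {
  m <- toy_model(effect_rows(list(class = "a", term = "L1", estimate = 2),
                             list(class = "d", term = "L1", estimate = 3)))
  gsl <- design_superior(m, design_target("GSL", "max"))
  gsh <- design_superior(m, design_target("GSH", "max"))
  expect_equal(unname(gsl$assignment["L1"]), 2L)   # QQ, value 2
  expect_equal(gsl$value, 2)
  expect_equal(unname(gsh$assignment["L1"]), 1L)   # Qq, value 3 (d > a)
  expect_equal(gsh$value, 3)
  expect_gte(gsh$value, gsl$value)
  # random feasible assignments never beat the optimum
  set.seed(17)
  effects <- effect_rows(
    list(class = "a", term = "L1", estimate = 1.2),
    list(class = "d", term = "L1", estimate = -0.5),
    list(class = "a", term = "L2", estimate = 0.3),
    list(class = "d", term = "L2", estimate = 0.8),
    list(class = "dd", term = "L1 & L2", estimate = 1.5))
  m2 <- toy_model(effects)
  opt <- design_superior(m2, design_target("GSH", "max"))$value
  for (i in 1:1000) {
    codes <- stats::setNames(sample(0:2, 2, replace = TRUE),
                             c("L1", "L2"))
    expect_lte(genetic_value(codes, m2), opt + 1e-12)
  }
})

test_that("environment-specific designs respond to GxE predictions only", {
  effects <- effect_rows(list(class = "a", term = "L1", estimate = 0.2))
  gxe <- data.frame(name = paste0("ae:L1"), class = "ae", term = "L1",
                    env = 1:3, estimate = c(-1, 0, 1))
  m <- toy_model(effects, gxe = gxe)
  # GSL ignores environments entirely
  gsl <- design_superior(m, design_target("GSL", "max"))
  expect_equal(unname(gsl$assignment["L1"]), 2L)
  # env 1: a + ae1 = -0.8 at QQ -> qq preferred; env 3: QQ preferred
  sl1 <- design_superior(m, design_target("SL", "max", environment = 1))
  sl3 <- design_superior(m, design_target("SL", "max", environment = 3))
  expect_equal(unname(sl1$assignment["L1"]), 0L)
  expect_equal(unname(sl3$assignment["L1"]), 2L)
  expect_equal(sl1$value, 0.8)
  # without GxE terms, SL matches GSL in every environment
  m0 <- toy_model(effects)
  expect_error(design_target("SL", "max"), "environment")
  expect_error(design_target("GSL", "max", environment = 2),
               "environment-independent")
})

test_that("pleiotropy conflicts are flagged exactly when optima disagree", {
  m_up <- toy_model(effect_rows(list(class = "a", term = "L1",
                                     estimate = 1)))
  m_down <- toy_model(effect_rows(list(class = "a", term = "L1",
                                       estimate = -1)))
  rep1 <- pleiotropy_conflict_report(list(t1 = m_up, t2 = m_down))
  expect_true(all(rep1$conflict))
  expect_setequal(rep1$code[rep1$trait == "t1"], 2L)
  expect_setequal(rep1$code[rep1$trait == "t2"], 0L)
  rep2 <- pleiotropy_conflict_report(list(t1 = m_up, t2 = m_up))
  expect_false(any(rep2$conflict))
  # three-trait toy against hand enumeration
  m3 <- toy_model(effect_rows(list(class = "a", term = "L1",
                                   estimate = 0.5),
                              list(class = "a", term = "L2",
                                   estimate = -2)))
  rep3 <- pleiotropy_conflict_report(list(t1 = m_up, t2 = m_down, t3 = m3))
  l1 <- rep3[rep3$qts == "L1", ]
  expect_equal(stats::setNames(l1$code, l1$trait),
               c(t1 = 2L, t2 = 0L, t3 = 2L))
  expect_true(all(l1$conflict))
  expect_false("L2" %in% rep3$qts)   # only shared QTSs are reported
  expect_error(pleiotropy_conflict_report(list(t1 = m_up)), ">= 2")
})
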