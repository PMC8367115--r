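# Helper: a complete 19-subject x 2x2x3 long table with additive effects.
make_table <- function(subj_sd = 1, noise_sd = 1, ev_effect = c(0, 0, 0),
                       seed = 1) {
  g <- condition_grid()
  tb <- merge(data.frame(label = 1:19), g)
  with_seed <- get("with_seed", asNamespace("pillchroma"))
  with_seed(seed, {
    subj <- rnorm(19, sd = subj_sd)
    tb$delta_e <- subj[tb$label] +
      ev_effect[match(tb$ev, c(-2, 0, 2))] +
      rnorm(nrow(tb), sd = noise_sd)
  })
  names(tb)[names(tb) == "name"] <- "condition"
  tb
}

test_that("summary statistics follow the mean/SD definitions", {
  rec <- data.frame(condition = rep(c("A", "B"), c(3, 2)),
                    delta_e = c(4, 4, 4, 10, 20))
  s <- delta_e_summary(rec)
  expect_equal(s$mean_delta_e[s$condition == "A"], 4)
  expect_equal(s$sd_delta_e[s$condition == "A"], 0)
  expect_equal(s$mean_delta_e[s$condition == "B"], 15)
  expect_equal(s$sd_delta_e[s$condition == "B"], sqrt(50), tolerance = 1e-12)
  one <- delta_e_summary(data.frame(condition = "C", delta_e = 3))
  expect_equal(one$mean_delta_e, 3)
  expect_true(is.na(one$sd_delta_e))
  expect_error(delta_e_summary(data.frame(condition = character(),
                                          delta_e = numeric())),
               class = "pillchroma_domain_error")
})

test_that("the three-way RM-ANOVA reports all seven within-subject effects", {
  tb <- make_table(seed = 2)
  res <- delta_e_rm_anova(tb)
  expect_setequal(res$effect,
                  c("background", "flash", "ev", "background:flash",
                    "background:ev", "flash:ev", "background:flash:ev"))
  expect_equal(res$df1[res$effect == "ev"], 2)
  expect_equal(res$df2[res$effect == "ev"], 36)
  expect_equal(res$df1[res$effect == "background"], 1)
  expect_true(all(res$F >= 0))
  expect_true(all(res$p >= 0 & res$p <= 1))
})

test_that("a constant response yields F near 0 and p near 1", {
  tb <- make_table(subj_sd = 0, noise_sd = 0, seed = 3)
  tb$delta_e <- 5 + 0.3 * tb$label  # subject offsets only, no condition effect
  res <- delta_e_rm_anova(tb)
  expect_true(all(res$F < 1e-10 | !is.finite(res$F)))
  expect_true(all(res$p > 0.999, na.rm = TRUE))
})

test_that("an incomplete crossing raises a design error naming the cell", {
  tb <- make_table(seed = 4)
  err <- tryCatch(delta_e_rm_anova(tb[-1, ]), error = identity)
  expect_s3_class(err, "pillchroma_design_error")
  expect_match(conditionMessage(err), "subject 1")
})

test_that("an injected EV effect is detected and survives the GG correction", {
  tb <- make_table(ev_effect = c(-2, 0, 2), seed = 5)
  res <- delta_e_rm_anova(tb, gg = TRUE)
  ev <- res[res$effect == "ev", ]
  expect_lt(ev$p, 0.001)
  expect_lt(ev$p_gg, 0.001)
  expect_true(ev$eps >= 0.5 && ev$eps <= 1)
  expect_gte(ev$p_gg, ev$p)  # fewer df can only raise the p-value
  # 1-df effects are sphericity-exempt
  expect_equal(res$eps[res$effect == "background"], 1)
})

test_that("contrast-based F statistics agree with aov", {
  tb <- make_table(ev_effect = c(-1, 0, 1), seed = 6)
  res <- delta_e_rm_anova(tb)
  ns <- asNamespace("pillchroma")
  Y <- get("cell_matrix", ns)(tb)
  for (eff in res$effect) {
    M <- get("effect_contrast", ns)(strsplit(eff, ":")[[1]], 3)
    st <- get("rm_effect_stats", ns)(Y, M)
    expect_equal(st$F, res$F[res$effect == eff], tolerance = 1e-8,
                 label = sprintf("F for %s", eff))
    expect_equal(st$df1, res$df1[res$effect == eff])
  }
})

test_that("stratified EV analysis tests each stratum with Bonferroni pairs", {
  tb <- make_table(ev_effect = c(-3, 0, 3), noise_sd = 0.5, seed = 7)
  out <- ev_strata_anova(tb)
  expect_equal(nrow(out$anova), 4)
  expect_equal(nrow(out$pairwise), 12)
  expect_true(all(out$anova$p < 0.01))
  expect_equal(out$pairwise$adjusted_p,
               pmin(1, out$pairwise$raw_p * 3))
  expect_true(all(out$pairwise$adjusted_p >= out$pairwise$raw_p))
  # extreme pair at least as significant as adjacent pairs in each stratum
  for (i in seq_len(4)) {
    sub <- out$pairwise[(3 * i - 2):(3 * i), ]
    extreme <- sub$adjusted_p[sub$ev1 == -2 & sub$ev2 == 2]
    expect_lte(extreme, min(sub$adjusted_p) + 1e-12)
  }
})

test_that("a null stratum stays non-significant", {
  tb <- make_table(ev_effect = c(0, 0, 0), seed = 8)
  out <- ev_strata_anova(tb)
  expect_true(all(out$anova$p > 0.01))
})

test_that("accuracy-vs-delta E association detects monotone structure", {
  conds <- condition_grid()$name
  de <- data.frame(condition = conds, mean_delta_e = seq(5, 60, length.out = 12))
  acc <- data.frame(condition = conds, k = 1,
                    accuracy = seq(0.9, 0.1, length.out = 12))
  out <- accuracy_delta_e_association(acc, de)
  expect_equal(out$correlations$spearman, -1)
  expect_equal(nrow(out$flagged), 0)

  # constant accuracy: correlation undefined by convention
  acc2 <- data.frame(condition = conds, k = 1, accuracy = 0.5)
  expect_true(is.na(accuracy_delta_e_association(acc2, de)$correlations$spearman))

  # one condition bucking the trend gets flagged
  acc3 <- acc
  acc3$accuracy[12] <- 0.95
  out3 <- accuracy_delta_e_association(acc3, de)
  expect_true(conds[12] %in% out3$flagged$condition)

  expect_error(accuracy_delta_e_association(acc[-1, ], de),
               class = "pillchroma_pairing_error")
})
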