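worked_groups <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(3, 4, 5))

test_that("one-way ANOVA matches the hand sum-of-squares oracle", {
  a <- one_way_anova(worked_groups)
  o <- oracle_anova(worked_groups)
  expect_equal(a$F, 3.0)
  expect_equal(a$df_between, 2)
  expect_equal(a$df_within, 6)
  expect_equal(a$mse, 1.0)
  expect_equal(a$p, o$p)
  # random group sets against the oracle
  set.seed(21)
  for (i in 1:15) {
    g <- lapply(1:sample(2:5, 1), function(j) rnorm(sample(3:9, 1), j * 0.3))
    a2 <- one_way_anova(g)
    o2 <- oracle_anova(g)
    expect_equal(a2$F, o2$F)
    expect_equal(a2$mse, o2$mse)
    expect_equal(a2$p, o2$p)
    expect_equal(c(a2$df_between, a2$df_within),
                 c(o2$df_between, o2$df_within))
  }
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(3)
  x <- rnorm(8); y <- rnorm(6, 0.5)
  a <- one_way_anova(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2)
  expect_equal(a$p, tt$p.value)
})

test_that("ANOVA degenerate and invalid inputs error as no-test", {
  expect_error(one_way_anova(list(a = c(1, 1), b = c(1, 1))), "degenerate")
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "at least 2")
  expect_error(one_way_anova(list(a = c(1, 2))), "at least 2")
  # identical means with equal spread: F = 0
  expect_equal(one_way_anova(list(a = c(1, 3), b = c(1, 3), c = c(1, 3)))$F, 0)
})

test_that("ANOVA F is invariant under affine transformations of the data", {
  set.seed(17)
  g <- list(a = rnorm(6), b = rnorm(6, 1), c = rnorm(6, 2))
  f0 <- one_way_anova(g)$F
  expect_equal(one_way_anova(lapply(g, function(v) v + 100))$F, f0)
  expect_equal(one_way_anova(lapply(g, function(v) v * 3.7))$F, f0)
  expect_equal(one_way_anova(lapply(g, function(v) v * -2 + 5))$F, f0)
})

test_that("Fisher's PLSD reproduces the worked pair and the pooled t-test", {
  a <- one_way_anova(worked_groups)
  pl <- fishers_plsd(worked_groups, a)
  row <- pl[pl$group1 == "g1" & pl$group2 == "g3", ]
  expect_equal(row$t, -2 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(row$df, 6)
  expect_equal(row$p, 2 * pt(-abs(2 / sqrt(2 / 3)), 6))
  # two groups: identical to the pooled-variance two-sample t-test
  set.seed(4)
  x <- rnorm(7); y <- rnorm(9, 0.8)
  pl2 <- fishers_plsd(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_lt(abs(pl2$p - tt$p.value), 1e-9)
  # equal means give t = 0, p = 1
  pl3 <- fishers_plsd(list(a = c(1, 2, 3), b = c(2, 2, 2), d = c(0, 2, 4)))
  eq <- pl3[pl3$group1 == "a" & pl3$group2 == "b", ]
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
})

test_that("PLSD agrees with pairwise.t.test using the pooled SD", {
  set.seed(31)
  g <- list(a = rnorm(8), b = rnorm(8, 0.6), c = rnorm(8, 1.1))
  pl <- fishers_plsd(g)
  ref <- pairwise.t.test(unlist(g), rep(names(g), lengths(g)),
                         p.adjust.method = "none", pool.sd = TRUE)$p.value
  for (k in seq_len(nrow(pl))) {
    want <- ref[pl$group2[k], pl$group1[k]]
    if (is.na(want)) want <- ref[pl$group1[k], pl$group2[k]]
    expect_equal(pl$p[k], unname(want), tolerance = 1e-12)
  }
})

test_that("missing culture values are dropped, not imputed", {
  g <- list(a = c(1, 2, NA, 3), b = c(2, 3, 4), c = c(NA, 3, 4, 5))
  a <- one_way_anova(g)
  expect_equal(a$n_dropped, 2)
  expect_equal(unname(a$ns), c(3L, 3L, 3L))
  expect_equal(a$F, 3.0)  # same as the worked example after dropping
})

test_that("the barcode decision rule maps every significance pattern correctly", {
  # (kd mean above both controls)
  expect_equal(classify_effect(0.01, 0.02, 0.50, 10, 5, 6), "increase")
  expect_equal(classify_effect(0.01, 0.20, 0.50, 10, 5, 6), "none")
  expect_equal(classify_effect(0.20, 0.02, 0.50, 10, 5, 6), "none")
  expect_equal(classify_effect(0.20, 0.30, 0.50, 10, 5, 6), "none")
  expect_equal(classify_effect(0.01, 0.02, 0.03, 10, 5, 6), "none")
  expect_equal(classify_effect(0.01, 0.20, 0.03, 10, 5, 6), "none")
  expect_equal(classify_effect(0.20, 0.02, 0.03, 10, 5, 6), "none")
  expect_equal(classify_effect(0.20, 0.30, 0.03, 10, 5, 6), "none")
  # mirrored for decreases
  expect_equal(classify_effect(0.01, 0.02, 0.50, 1, 5, 6), "decrease")
  expect_equal(classify_effect(0.01, 0.02, 0.03, 1, 5, 6), "none")
  # kd mean between the controls: significant but not consistent
  expect_equal(classify_effect(0.01, 0.02, 0.50, 5.5, 5, 6), "none")
  # boundary: p exactly alpha is not significant; controls at alpha are same
  expect_equal(classify_effect(0.05, 0.01, 0.50, 10, 5, 6), "none")
  expect_equal(classify_effect(0.01, 0.01, 0.05, 10, 5, 6), "increase")
  # missing p values log out as none
  expect_equal(classify_effect(NA, 0.01, 0.5, 10, 5, 6), "none")
})

test_that("build_barcode classifies per (parameter, DIV) cell", {
  set.seed(63)
  mk_table <- function(kd_shift) {
    rows <- list()
    for (cond in c("untransfected", "ntc", "kd")) {
      for (culture in 1:8) {
        for (d in c(7, 9)) {
          mu <- 10 + if (cond == "kd" && d == 9) kd_shift else 0
          rows[[length(rows) + 1L]] <- data.frame(
            condition = cond, culture_id = paste0(cond, culture), div = d,
            burst_rate = rnorm(1, mu, 0.5), stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  }
  bc <- build_barcode(mk_table(5), kd = "kd", parameters = "burst_rate")
  m <- as.matrix(bc)
  expect_equal(unname(m["burst_rate", "DIV9"]), "increase")
  expect_equal(unname(m["burst_rate", "DIV7"]), "none")
  bc2 <- build_barcode(mk_table(-5), kd = "kd", parameters = "burst_rate")
  expect_equal(unname(as.matrix(bc2)["burst_rate", "DIV9"]), "decrease")
  # degenerate all-identical data yields none everywhere
  tab <- mk_table(0)
  tab$burst_rate <- 1
  bc3 <- build_barcode(tab, kd = "kd", parameters = "burst_rate")
  expect_true(all(bc3$call == "none"))
  # missing values in one group drop out; with < 2 left the cell is none
  tab2 <- mk_table(5)
  tab2$burst_rate[tab2$condition == "kd" & tab2$div == 9][1:7] <- NA
  bc4 <- build_barcode(tab2, kd = "kd", parameters = "burst_rate")
  expect_equal(bc4$call[bc4$div == 9], "none")
  # single-DIV restriction
  bc5 <- build_barcode(mk_table(5), kd = "kd", parameters = "burst_rate",
                       divs = 9)
  expect_equal(nrow(bc5), 1)
})
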