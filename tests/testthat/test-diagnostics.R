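# Indicator- and test-level quality statistics.

test_that("CTT discrimination matches the direct rest-score correlation", {
  # hand 6-dyad table: verify against a spreadsheet-style computation
  m <- cbind(T1A01 = c(1, 0, 1, 1, 0, 0), T1A02 = c(1, 0, 1, 0, 0, 1),
             T1B01 = c(0, 0, 1, 1, 0, 1), T1G01 = c(1, 0, 1, 1, 1, 0))
  meta <- data.frame(name = colnames(m), level = c("A", "A", "B", "G"),
                     stringsAsFactors = FALSE)
  d <- ctt_discrimination(m, meta)
  expect_equal(unname(d["T1A01"]),
               cor(m[, 1], m[, 2] + m[, 4]))        # A: own dim + group
  expect_equal(unname(d["T1B01"]), cor(m[, 3], m[, 4]))
  expect_equal(unname(d["T1G01"]), cor(m[, 4], m[, 1] + m[, 2] + m[, 3]))
  # an indicator identical to its one-item rest score correlates 1
  m2 <- cbind(T1A01 = c(1, 0, 1, 0), T1A02 = c(1, 0, 1, 0))
  meta2 <- data.frame(name = colnames(m2), level = c("A", "A"))
  expect_equal(unname(ctt_discrimination(m2, meta2)["T1A01"]), 1)
  # independence: near-zero discrimination in a large sample
  set.seed(19)
  big <- cbind(matrix(rbinom(5000 * 9, 1, 0.5), 5000, 9),
               rbinom(5000, 1, 0.5))
  colnames(big) <- sprintf("T1A%02d", 1:10)
  metab <- data.frame(name = colnames(big), level = "A")
  expect_lt(abs(ctt_discrimination(big, metab)["T1A10"]), 0.05)
  mz <- cbind(T1A01 = rep(1, 6), T1A02 = c(1, 0, 1, 0, 1, 0))
  w <- capture_warnings(dz <- ctt_discrimination(mz, data.frame(
    name = colnames(mz), level = "A")))
  expect_match(w, "zero variance", all = TRUE)
  expect_true(is.na(dz["T1A01"]))
  expect_true(is.na(dz["T1A02"]))  # its rest-score is the constant item
})

test_that("infit flags overdispersion and is near 1 under the model", {
  set.seed(23)
  roster <- model_roster(6, 6, 4, delta_range = c(-1.5, 1.5))
  ab <- simulate_population(600, rho = 0.5)
  sc <- simulate_scores(ab, roster)
  fit <- fit_mml_em(sc, nodes = 21)
  inf <- infit_mnsq(sc, fit)
  expect_true(all(inf$mnsq > 0))
  expect_true(all(inf$ci_low < inf$ci_high))
  expect_equal(mean(inf$mnsq), 1, tolerance = 0.12)
  expect_equal(inf$n_obs, rep(600L, nrow(inf)))
  # overdispersed responses (mixture, not the model) inflate MNSQ
  contaminated <- sc$scores
  flip <- seq(1, 600, by = 2)
  contaminated[flip, 1] <- 1L - contaminated[flip, 1]  # item 1 now ~noise
  inf2 <- infit_mnsq(contaminated, fit)
  expect_gt(inf2$mnsq[1], 1)
  expect_gt(inf2$mnsq[1], inf$mnsq[1])
})

test_that("MNSQ interval and T follow the Wilson-Hilferty standardization", {
  r <- mnsq_interval_t(1.05, 0.01)
  expect_equal(unname(r["ci_low"]), 1 - 1.96 * 0.1)
  expect_equal(unname(r["ci_high"]), 1 + 1.96 * 0.1)
  # a null MNSQ of 1 standardizes to a small T
  expect_lt(abs(mnsq_interval_t(1, 0.05)["t"]), 0.2)
  # a 1.30 MNSQ with a tight interval is flagged (T > 2)
  expect_gt(mnsq_interval_t(1.30, 0.01)["t"], 2)
  # interval floor at 0 for huge q
  expect_equal(unname(mnsq_interval_t(1, 4)["ci_low"]), 0)
  expect_error(mnsq_interval_t(1, 0), "positive")
})

test_that("separation reliability discounts estimation error", {
  d <- c(-1, 0, 1, 2)
  expect_equal(item_separation_reliability(d, rep(0, 4)), 1)
  # difficulty variance 1, mean squared SE 0.25 -> 0.75
  d2 <- c(-1, 1) * sqrt(0.5)          # var exactly 1
  expect_equal(item_separation_reliability(d2, c(0.5, 0.5)), 0.75)
  expect_equal(item_separation_reliability(d, rep(10, 4)), 0)  # floor
  # monotone: shrinking SEs never lowers the reliability
  ses <- seq(1, 0.1, by = -0.1)
  rel <- vapply(ses, function(s)
    item_separation_reliability(d, rep(s, 4)), numeric(1))
  expect_true(all(diff(rel) >= 0))
  expect_warning(item_separation_reliability(c(1, 1), c(0.1, 0.1)),
                 "zero variance")
})

test_that("EAP reliability is the signal share of total variance", {
  v <- c(-1.2, -0.4, 0.4, 1.2)
  ab <- data.frame(group_id = as.character(1:4),
                   theta_A = v * sqrt(0.6) / sd(v),
                   theta_B = c(-1, 0, 0, 1),
                   sd_A = sqrt(0.2), sd_B = sqrt(0.2))
  # var(theta_A) = 0.6, mean posterior var 0.2 -> 0.75
  expect_equal(eap_reliability(ab, 1), 0.75)
  ab$sd_B <- 1e-9
  expect_equal(eap_reliability(ab, 2), 1, tolerance = 1e-6)
})

test_that("dimension correlation tracks the generating dependence", {
  ab <- data.frame(group_id = as.character(1:5),
                   theta_A = c(-1, 0, 0.5, 1, 2),
                   theta_B = c(-1, 0, 0.5, 1, 2),
                   sd_A = 0.3, sd_B = 0.3)
  expect_equal(dimension_correlation(ab), 1)
  set.seed(29)
  ind <- simulate_population(5000, rho = 0)
  ind$sd_A <- ind$sd_B <- 0.1
  expect_lt(abs(dimension_correlation(ind)), 0.05)
  const <- ab; const$theta_B <- 1
  expect_warning(r <- dimension_correlation(const), "zero variance")
  expect_true(is.na(r))
})

test_that("the retention filter drops by MNSQ band, discrimination and outcome sign", {
  fr <- data.frame(
    name = c("T1A01", "T1A02", "T1A03", "T1A04", "T1G01"),
    mnsq = c(1.00, 1.34, 0.98, 0.76, 1.05),
    discrimination = c(0.4, 0.5, -0.01, 0.3, 0.45),
    outcome_cor = c(0.2, 0.1, 0.3, 0.25, NA),
    stringsAsFactors = FALSE)
  res <- retention_filter(fr)
  expect_setequal(res$kept, c("T1A01", "T1G01"))
  expect_match(res$dropped$reason[res$dropped$name == "T1A02"],
               "MNSQ 1.340 out of \\[0.77, 1.33\\]")
  expect_match(res$dropped$reason[res$dropped$name == "T1A03"],
               "discrimination")
  # idempotence: filtering the kept set again drops nothing
  res2 <- retention_filter(fr[fr$name %in% res$kept, ])
  expect_equal(res2$kept, res$kept)
  expect_equal(nrow(res2$dropped), 0)
  # negative outcome correlation alone drops an indicator
  fr$outcome_cor[1] <- -0.2
  expect_false("T1A01" %in% retention_filter(fr)$kept)
})

test_that("Cohen's kappa matches its formula, labels and invariances", {
  x <- c(rep(1, 50), rep(0, 50))
  expect_equal(cohens_kappa(x, x)$kappa, 1)
  expect_equal(cohens_kappa(x, x)$magnitude, "excellent")
  # 2x2 agreement table (45, 5, 5, 45): p_o 0.9, p_e 0.5, kappa 0.8
  y <- c(rep(1, 45), rep(0, 5), rep(1, 5), rep(0, 45))
  k <- cohens_kappa(x, y)
  expect_equal(k$p_obs, 0.9)
  expect_equal(k$p_exp, 0.5)
  expect_equal(k$kappa, 0.8)
  # independent ratings: kappa near zero
  set.seed(37)
  a <- rbinom(5000, 1, 0.6); b <- rbinom(5000, 1, 0.4)
  expect_lt(abs(cohens_kappa(a, b)$kappa), 0.05)
  # relabeling both raters leaves kappa unchanged
  relab <- c(`0` = "no", `1` = "yes")
  expect_equal(cohens_kappa(relab[as.character(x)],
                            relab[as.character(y)])$kappa, k$kappa)
  expect_warning(kc <- cohens_kappa(rep(1, 10), rep(1, 10)), "2 categories")
  expect_true(is.na(kc$kappa))
  expect_equal(kappa_magnitude(c(0.76, 0.75, 0.4, 0.39)),
               c("excellent", "fair to good", "fair to good", "poor"))
})

test_that("the Wright map conserves counts and flags very easy indicators", {
  set.seed(41)
  roster <- model_roster(4, 4, 2, delta_range = c(-1, 1))
  sc <- simulate_scores(simulate_population(10, rho = 0.5), roster)
  fit <- fit_mml_em(sc$scores, build_matrices(
    data.frame(name = roster$name, level = roster$level, K = roster$K)),
    nodes = 15, max_iter = 60)
  eap <- estimate_abilities_eap(sc$scores, fit)
  wm <- wright_map(fit, eap, bin_width = 0.25)
  expect_equal(sum(wm$bins$count[wm$bins$dimension == 1]), 10)
  expect_equal(sum(wm$bins$count[wm$bins$dimension == 2]), 10)
  # an artificially easy indicator sits below every ability
  fit2 <- fit
  fit2$delta[1] <- min(eap$theta_A, eap$theta_B) - 2
  wm2 <- wright_map(fit2, eap)
  expect_true(wm2$items$below_all_abilities[1])
  # shifting all abilities translates occupied bins
  eap_shift <- eap
  eap_shift$theta_A <- eap$theta_A + 1
  eap_shift$theta_B <- eap$theta_B + 1
  wm3 <- wright_map(fit, eap_shift, bin_width = 0.25)
  occ <- function(w, d) sort(w$bins$mid[w$bins$dimension == d &
                                          w$bins$count > 0])
  expect_equal(occ(wm3, 1), occ(wm, 1) + 1, tolerance = 1e-8)
  expect_output(print(wm), "dim 1")
})

test_that("two-stage calibration filters and reports reliabilities", {
  set.seed(43)
  roster <- model_roster(5, 5, 2, delta_range = c(-1.2, 1.2))
  ab <- simulate_population(500, rho = 0.56)
  sc <- simulate_scores(ab, roster)
  # contaminate one indicator so it fails the filter
  noise <- rbinom(500, 1, 0.5)
  sc$scores[, "T1A03"] <- ifelse(rbinom(500, 1, 0.6) == 1, noise,
                                 sc$scores[, "T1A03"])
  sc$raw <- sc$scores
  cal <- calibrate(sc, nodes = 15)
  expect_s3_class(cal, "cps_calibration")
  expect_true(all(c("discrimination", "difficulty", "error", "mnsq",
                    "t") %in% names(cal$fit_records)))
  expect_true(nrow(cal$stage2$model$meta) <= nrow(cal$stage1$model$meta))
  expect_true(all(cal$report$separation_reliability >= 0 &
                    cal$report$separation_reliability <= 1))
  expect_true(abs(cal$report$dimension_correlation) <= 1)
  # when nothing is filtered, single- and two-stage agree
  sc2 <- simulate_scores(ab, roster)
  cal1 <- calibrate(sc2, two_stage = FALSE, nodes = 15)
  cal2 <- calibrate(sc2, two_stage = TRUE, nodes = 15)
  if (nrow(cal2$retention$dropped) == 0)
    expect_equal(cal2$stage2$delta, cal1$stage2$delta)
  # degenerate indicators are dropped with a warning before stage 1
  sc3 <- simulate_scores(ab, roster)
  sc3$scores[, 2] <- 0L
  sc3$raw <- sc3$scores
  expect_warning(cal3 <- calibrate(sc3, nodes = 15), "degenerate")
  expect_false(roster$name[2] %in% cal3$fit_records$name)
})
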