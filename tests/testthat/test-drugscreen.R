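test_that("4PL fit round-trips noiseless curves and censors flat data", {
  d <- dr_records(ic50 = 100)
  fit <- fit_4pl(d, "CMP", "CU")
  expect_true(fit$converged)
  expect_false(fit$censored)
  expect_lt(abs(fit$ic50 - 100) / 100, 0.01)
  expect_gt(fit$r_squared, 0.999)
  expect_true(fit$top >= fit$bottom)

  # flat viability = 1 at every dose: censored "> Cmax"-style report
  flat <- dr_records(ic50 = 100)
  flat$viability <- 1
  ffit <- fit_4pl(flat, "CMP", "CU")
  expect_true(ffit$censored)
  expect_equal(ffit$cmax, 1000)

  # true midpoint above the top tested dose: censored as well
  high <- dr_records(ic50 = 5000)
  expect_true(fit_4pl(high, "CMP", "CU")$censored)

  expect_error(fit_4pl(d[d$concentration_nM == 10, ], "CMP", "CU"),
               "2 distinct")
  expect_error(fit_4pl(d, "NOPE", "CU"), "no records")
})

test_that("IC50 recovery under screen noise; calls invariant to order", {
  set.seed(20)
  errs <- replicate(40, {
    ic <- 10^runif(1, 1, log10(500))
    d <- dr_records(ic50 = ic, noise_cv = 0.05)
    abs(fit_4pl(d, "CMP", "CU")$ic50 - ic) / ic
  })
  expect_lt(median(errs), 0.15)

  d <- dr_records(ic50 = 50, noise_cv = 0.05, seed = 9)
  f1 <- fit_4pl(d, "CMP", "CU")
  f2 <- fit_4pl(d[rev(seq_len(nrow(d))), ], "CMP", "CU")
  expect_equal(f1$ic50, f2$ic50, tolerance = 1e-6)
  expect_identical(call_efficacy(f1)$effective, call_efficacy(f2)$effective)
})

test_that("IC50 bias is small and bootstrap intervals cover (scaled study)", {
  # the full study is 200 curves; 40 curves with B = 80 keeps the default
  # test run fast while leaving the thresholds untouched
  set.seed(314)
  n_curve <- 40
  errs <- numeric(n_curve)
  cover <- logical(n_curve)
  for (i in seq_len(n_curve)) {
    d <- dr_records(ic50 = 100, noise_cv = 0.05)
    ci <- ic50_bootstrap_ci(d, "CMP", "CU", B = 80)
    f <- attr(ci, "fit")
    errs[i] <- (f$ic50 - 100) / 100
    cover[i] <- ci["lower"] <= 100 && 100 <= ci["upper"]
  }
  expect_lt(abs(median(errs)), 0.05)
  expect_gte(mean(cover), 0.90)
})

test_that("efficacy thresholds follow the screen reporting rules", {
  d <- dr_records(ic50 = 0.02, conc = c(0.001, 0.1, 10, 1000))
  f <- fit_4pl(d, "CMP", "CU")
  call <- call_efficacy(f)
  expect_true(call$effective)
  expect_gt(f$r_squared, 0.6)

  # censored IC50 is never effective
  flat <- dr_records(ic50 = 1e5)
  cflat <- call_efficacy(fit_4pl(flat, "CMP", "CU"))
  expect_false(cflat$effective)
  expect_identical(cflat$reason, "ic50_censored")

  # fabricate a mid-range fit with poor quality: reason is fit quality
  poor <- structure(list(compound = "X", culture = "Y", top = 1, bottom = 0,
                         hill = 1, ic50 = 500, r_squared = 0.5,
                         censored = FALSE, cmax = 1000, converged = TRUE),
                    class = "dose_response_fit")
  cp <- call_efficacy(poor)
  expect_false(cp$effective)
  expect_identical(cp$reason, "fit_quality")
})

test_that("median-effect fit recovers (m, Dm) and is scale-equivariant", {
  d <- me_records(Dm = 100, m = 1)
  fit <- median_effect_fit(d, "CMP", "CU")
  expect_equal(fit$m, 1, tolerance = 1e-6)
  expect_equal(fit$Dm, 100, tolerance = 1e-4)
  expect_equal(abs(fit$r), 1, tolerance = 1e-9)

  d2 <- d
  d2$concentration_nM <- d$concentration_nM * 2
  fit2 <- median_effect_fit(d2, "CMP", "CU")
  expect_equal(fit2$Dm, 200, tolerance = 1e-4)
  expect_equal(fit2$m, fit$m, tolerance = 1e-9)

  # identical fa everywhere: slope zero, Dm undefined
  dflat <- d
  dflat$viability <- 0.5
  expect_error(median_effect_fit(dflat, "CMP", "CU"), "slope")

  # fa outside (0,1) dropped with warning; too few points is an error
  dbad <- d
  dbad$viability[1] <- 1
  expect_warning(median_effect_fit(dbad, "CMP", "CU"), "dropped")
  dall <- d
  dall$viability <- 1
  expect_error(suppressWarnings(median_effect_fit(dall, "CMP", "CU")),
               "usable")
})

test_that("combination index identities and the worked example hold", {
  f <- median_effect_fit(me_records(Dm = 100, m = 1.3), "CMP", "CU")
  # self-combination at half the effective dose each: CI = 1 at any fa
  for (fa in c(0.2, 0.5, 0.8)) {
    Dx <- f$Dm * (fa / (1 - fa))^(1 / f$m)
    ci <- combination_index(f, f, Dx / 2, Dx / 2, fa)
    expect_equal(ci$CI, 1, tolerance = 1e-6)
  }

  # hand example: m1 = m2 = 1, Dm1 = 100, Dm2 = 200, fa = 0.5, d = (30, 50)
  f1 <- median_effect_fit(me_records(Dm = 100, m = 1, compound = "A"),
                          "A", "CU")
  f2 <- median_effect_fit(me_records(Dm = 200, m = 1, compound = "B"),
                          "B", "CU")
  ci <- combination_index(f1, f2, 30, 50, 0.5)
  expect_equal(ci$Dx1, 100, tolerance = 1e-6)
  expect_equal(ci$Dx2, 200, tolerance = 1e-6)
  expect_equal(ci$CI, 0.55, tolerance = 1e-6)
  expect_true(ci$synergy_call)

  # both drugs at their full single-agent dose: CI = 2 (antagonism region)
  ci2 <- combination_index(f1, f2, 100, 200, 0.5)
  expect_equal(ci2$CI, 2, tolerance = 1e-6)
  expect_false(ci2$synergy_call)

  expect_error(combination_index(f1, f2, 1, 1, 1), "inside")
  expect_error(combination_index(f1, f2, 1, 1, 0), "inside")
})

test_that("target deconvolution matches the hypergeometric oracle", {
  # 4 effective compounds, all hitting kinase A; A hit by exactly those 4
  # of a 40-compound panel
  cmp <- sprintf("C%02d", 1:40)
  tm <- matrix(0, 40, 3, dimnames = list(cmp, c("A", "B", "C")))
  tm[1:4, "A"] <- 90
  tm[, "C"] <- 100                      # hit by the whole panel
  tm[c(1, 9, 17), "B"] <- 80
  calls <- data.frame(compound = cmp, effective = c(rep(TRUE, 4),
                                                    rep(FALSE, 36)))
  ts <- target_deconvolution(calls, tm)
  # A and C tie on count 4; the smaller enrichment p puts A first
  expect_identical(ts$kinase[1], "A")
  a <- ts[ts$kinase == "A", ]
  expect_equal(a$n_effective_hitting, 4L)
  expect_equal(a$n_panel_hitting, 4L)
  expect_equal(a$enrichment_p, 1 / choose(40, 4), tolerance = 1e-12)
  expect_equal(a$enrichment_p, oracle_hyper_upper(40, 4, 4, 4),
               tolerance = 1e-12)
  # the uninformative kinase hit by every panel compound has p = 1
  expect_equal(ts$enrichment_p[ts$kinase == "C"], 1)
  # among equal counts, smaller p ranks first
  expect_lt(ts[ts$kinase == "A", "enrichment_p"],
            ts[ts$kinase == "C", "enrichment_p"])
  expect_identical(ts$kinase[order(-ts$n_effective_hitting,
                                   ts$enrichment_p)], ts$kinase)

  # zero effective compounds: all counts 0, all p = 1
  none <- data.frame(compound = cmp, effective = FALSE)
  ts0 <- target_deconvolution(none, tm)
  expect_true(all(ts0$n_effective_hitting == 0))
  expect_true(all(ts0$enrichment_p == 1))

  # effective compound absent from the matrix: skipped, not fatal
  extra <- rbind(calls, data.frame(compound = "GHOST", effective = TRUE))
  ts2 <- expect_silent(target_deconvolution(extra, tm))
  expect_identical(attr(ts2, "skipped"), "GHOST")
})

test_that("deconvolution p equals enumeration for random small panels", {
  set.seed(5)
  for (i in 1:10) {
    N <- sample(5:25, 1)
    tm <- matrix(ifelse(runif(N * 4) < 0.4, 80, 0), N, 4,
                 dimnames = list(sprintf("C%02d", 1:N), LETTERS[1:4]))
    eff <- sample(c(TRUE, FALSE), N, TRUE)
    calls <- data.frame(compound = rownames(tm), effective = eff)
    ts <- target_deconvolution(calls, tm)
    for (j in seq_len(nrow(ts))) {
      want <- oracle_hyper_upper(N, ts$n_panel_hitting[j],
                                 sum(eff), ts$n_effective_hitting[j])
      expect_equal(ts$enrichment_p[j], want, tolerance = 1e-10)
    }
  }
})
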