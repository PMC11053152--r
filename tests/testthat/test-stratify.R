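# small fitted forest shared by the curve tests
fit_curve_model <- function(seed = 1) {
  withr::with_seed(seed, {
    n <- 120
    a <- rnorm(n)
    cens <- runif(n, 42, 100)
    out <- simulate_survival(1.5 * a, 0.004, cens)
    d <- tibble::tibble(patient_id = sprintf("PT%03d", seq_len(n)),
                        time = out$time, event = out$event, a = a)
  })
  split <- split_train_test(d, seed = seed)
  train <- d[d$patient_id %in% split$train_ids, ]
  fit <- protrisk:::fit_rsf(train, "a", num_trees = 200, seed = seed)
  model <- structure(list(learner = "rsf", fit = fit, features = "a",
                          split = split),
                     class = "risk_model")
  list(model = model, data = d, train = train)
}

test_that("predicted survival curves are valid and identical for identical patients", {
  fx <- fit_curve_model()
  two <- fx$data[c(1, 1), ]
  two$patient_id <- c("A", "B")
  curves <- predict_survival_curve(fx$model, two)
  ca <- curves[curves$patient_id == "A", ]
  cb <- curves[curves$patient_id == "B", ]
  expect_identical(ca$surv, cb$surv)
  expect_equal(ca$surv[ca$time == 0], 1)
  expect_true(all(diff(ca$surv) <= 1e-12))
  expect_true(all(ca$surv >= 0 & ca$surv <= 1))
  expect_error(predict_survival_curve(fx$model, two[, "patient_id"]), "absent")
})

test_that("a higher Cox linear predictor gives a pointwise lower curve", {
  d <- binary_cox_data(300, beta = log(3), seed = 3)
  cox <- fit_cox(d, "x")
  model <- structure(list(learner = "coxph", fit = cox$fit, features = "x",
                          split = split_train_test(d, seed = 1)),
                     class = "risk_model")
  nd <- tibble::tibble(patient_id = c("lo", "hi"), x = c(0L, 1L))
  curves <- predict_survival_curve(model, nd)
  lo <- curves$surv[curves$patient_id == "lo" & curves$time > 0]
  hi <- curves$surv[curves$patient_id == "hi" & curves$time > 0]
  expect_true(all(hi <= lo + 1e-12))
  expect_true(any(hi < lo))
})

test_that("Crank equals horizon minus the trapezoid RMST on hand-built curves", {
  H <- 80
  flat <- tibble::tibble(patient_id = "p", time = c(0, H), surv = c(1, 1))
  expect_equal(compute_crank(flat, H)$crank, 0)

  drop0 <- tibble::tibble(patient_id = "p", time = c(0, 1e-9, H), surv = c(1, 0, 0))
  expect_equal(compute_crank(drop0, H)$crank, H, tolerance = 1e-6)

  # S = 1 until H/2 then 0, on a grid containing H/2
  step <- tibble::tibble(patient_id = "p",
                         time = c(0, H / 2 - 1e-9, H / 2, H),
                         surv = c(1, 1, 0, 0))
  expect_equal(compute_crank(step, H)$crank, H / 2, tolerance = 1e-6)

  # refinement invariance for a piecewise-constant curve whose jumps are
  # represented on both grids
  eps <- 1e-9
  coarse <- tibble::tibble(
    patient_id = "p",
    time = c(0, 20 - eps, 20, 40 - eps, 40, 80),
    surv = c(1, 1, 0.8, 0.8, 0.5, 0.5)
  )
  fine <- tibble::tibble(
    patient_id = "p",
    time = c(0, 10, 20 - eps, 20, 30, 40 - eps, 40, 55, 70, 80),
    surv = c(1, 1, 1, 0.8, 0.8, 0.8, 0.5, 0.5, 0.5, 0.5)
  )
  c1 <- compute_crank(coarse, 80)$crank
  c2 <- compute_crank(fine, 80)$crank
  expect_lt(abs(c1 - c2), 1e-3 * 80)
  expect_error(compute_crank(flat[0, ], 80), "empty")
})

test_that("the stratification threshold is the midpoint of group mean Cranks", {
  expect_equal(compute_threshold(c(5, 7, 1, 3), c(1, 1, 0, 0)), 4)
  expect_equal(compute_threshold(c(2, 4, 2, 4), c(1, 0, 1, 0)), 3)
  # affine equivariance
  cr <- c(5, 7, 1, 3); ev <- c(1, 1, 0, 0)
  expect_equal(compute_threshold(cr + 10, ev), compute_threshold(cr, ev) + 10)
  expect_error(compute_threshold(c(1, 2), c(0, 0)), "non-empty")
  # the LDA boundary reduces to the midpoint for balanced groups
  expect_equal(compute_threshold(c(5, 7, 1, 3), c(1, 1, 0, 0), method = "lda"), 4)
})

test_that("risk labels use the documented boundary and are order-invariant", {
  expect_equal(stratify_patients(c(3, 4, 5), 4), c("low", "high", "high"))
  expect_equal(stratify_patients(c(1, 2), 10), c("low", "low"))
  cr <- c(0.5, 2, 9); th <- 2
  mono <- function(z) log(z + 1)
  expect_equal(stratify_patients(mono(cr), mono(th)), stratify_patients(cr, th))
  expect_error(stratify_patients(1, Inf), "finite")
})

test_that("stratification evaluation computes the confusion matrix and KM split", {
  out <- tibble::tibble(time = c(10, 20, 30, 40), event = c(1L, 0L, 1L, 0L))
  ev <- evaluate_stratification(c("high", "low", "high", "low"), out)
  expect_equal(ev$accuracy, 1)
  expect_equal(unname(ev$confusion), c(2L, 0L, 2L, 0L))
  expect_warning(evaluate_stratification(rep("high", 4), out), "single risk class")
})

test_that("the threshold never reads test outcomes", {
  fx <- fit_curve_model(seed = 5)
  rs1 <- risk_stratify(fx$model, fx$data)
  shuffled <- fx$data
  test_rows <- shuffled$patient_id %in% fx$model$split$test_ids
  shuffled$event[test_rows] <- withr::with_seed(8, sample(shuffled$event[test_rows]))
  shuffled$time[test_rows] <- withr::with_seed(9, sample(shuffled$time[test_rows]))
  rs2 <- risk_stratify(fx$model, shuffled)
  expect_identical(rs1$threshold, rs2$threshold)
  expect_identical(rs1$cranks$crank, rs2$cranks$crank)
})

test_that("held-out stratification separates survival on a signal cohort", {
  fx <- fit_curve_model(seed = 6)
  rs <- risk_stratify(fx$model, fx$data)
  expect_true(all(c("train", "test") %in% rs$cranks$set))
  expect_lt(rs$evaluation$km$test$p, 0.05)
  expect_gt(rs$evaluation$accuracy, 0.6)
})
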