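test_that("epoch confusion handles the degenerate one-sided cases", {
  truth <- annotation_track(100, 200)
  # decisions identical to grid-aligned truth: perfect scores
  cm <- epoch_confusion(truth, truth, 400)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)
  # all-seizure decisions: SE 1, SP 0
  cm2 <- epoch_confusion(annotation_track(0, 400), truth, 400)
  expect_equal(cm2$sensitivity, 1)
  expect_equal(cm2$specificity, 0)
  # no truth of a class: metric undefined, not 0
  cm3 <- epoch_confusion(annotation_track(), annotation_track(), 400)
  expect_true(is.na(cm3$sensitivity))
  expect_equal(cm3$specificity, 1)
  cm4 <- epoch_confusion(annotation_track(), annotation_track(0, 400), 400)
  expect_true(is.na(cm4$specificity))
})

test_that("epoch confusion equals brute-force interval enumeration", {
  set.seed(101)
  for (i in 1:400) {
    dur <- sample(c(60, 100, 400), 1)
    truth <- random_events(dur)
    det <- random_events(dur)
    got <- epoch_confusion(det, truth, dur)
    want <- oracle_epoch_confusion(det, truth, dur)
    expect_equal(got$sensitivity, want$sensitivity, tolerance = 1e-9)
    expect_equal(got$specificity, want$specificity, tolerance = 1e-9)
  }
})

test_that("event metrics follow the any-overlap rule", {
  truth2 <- annotation_track(c(100, 200), c(150, 260))
  no_det <- annotation_track()
  em <- event_metrics(no_det, truth2, 3600)
  expect_equal(em$gdr, 0)
  expect_equal(em$fd_per_hour, 0)
  # one detection overlapping both adjoining seizures
  adjoin <- annotation_track(c(100, 150), c(150, 200))
  one <- annotation_track(140, 160)
  em2 <- event_metrics(one, adjoin, 3600)
  expect_equal(em2$gdr, 100)
  expect_equal(em2$n_false, 0)
  # 3 false events in a 10 h record
  falses <- annotation_track(c(0, 5000, 20000), c(10, 5010, 20010))
  em3 <- event_metrics(falses, annotation_track(30000, 30100), 36000)
  expect_equal(em3$fd_per_hour, 0.3)
  expect_error(event_metrics(no_det, truth2, 0), "positive")
})

test_that("event metrics equal brute-force enumeration on random cases", {
  set.seed(202)
  for (i in 1:400) {
    dur <- 200
    truth <- random_events(dur)
    det <- random_events(dur)
    got <- event_metrics(det, truth, dur)
    want <- oracle_event_metrics(det, truth, dur)
    expect_equal(got$gdr, want$gdr, tolerance = 1e-9)
    expect_equal(got$fd_per_hour, want$fd_per_hour, tolerance = 1e-9)
  }
})

# a metrics_table built directly from SE/SP matrices
direct_table <- function(SE, SP, thresholds) {
  structure(list(SE = SE, SP = SP, thresholds = thresholds,
                 patients = paste0("p", seq_len(ncol(SE))),
                 level = "epoch"),
            class = "metrics_table")
}

test_that("both AUC orders match hand trapezoid sums and collapse at M = 1", {
  th <- c(0.25, 0.5, 0.75)
  SE <- cbind(c(1.0, 0.8, 0.2), c(0.9, 0.5, 0.1))
  SP <- cbind(c(0.1, 0.6, 0.9), c(0.2, 0.7, 1.0))
  tab <- direct_table(SE, SP, th)
  want1 <- mean(c(oracle_trapezoid(SE[, 1], SP[, 1]),
                  oracle_trapezoid(SE[, 2], SP[, 2])))
  expect_equal(auc_per_patient_mean(tab), want1, tolerance = 1e-12)
  want2 <- oracle_trapezoid(rowMeans(SE), rowMeans(SP))
  expect_equal(auc_pooled_thresholds(tab), want2, tolerance = 1e-12)
  # single patient: the two orders coincide exactly
  tab1 <- direct_table(SE[, 1, drop = FALSE], SP[, 1, drop = FALSE], th)
  expect_equal(auc_per_patient_mean(tab1), auc_pooled_thresholds(tab1),
               tolerance = 1e-12)
  # identical patients: the two orders coincide
  tab_same <- direct_table(cbind(SE[, 1], SE[, 1]),
                           cbind(SP[, 1], SP[, 1]), th)
  expect_equal(auc_per_patient_mean(tab_same),
               auc_pooled_thresholds(tab_same), tolerance = 1e-12)
  expect_error(auc_per_patient_mean(
    direct_table(cbind(c(1, NA, 0)), SP[, 1, drop = FALSE], th)), "missing")
})

test_that("perfect separation gives AUC 1 and uninformative traces give 0.5", {
  # patient with probabilities perfectly separating grid-aligned truth
  p <- c(rep(0.1, 25), rep(0.9, 25), rep(0.1, 50))
  tr <- make_trace(matrix(p, 1))
  truth <- annotation_track(tr$times_s[26], tr$times_s[50] + 4)
  tab <- metrics_table(list(tr), list(truth), 4 + 100 * 4,
                       thresholds = seq(0, 1, 0.05))
  expect_equal(auc_per_patient_mean(tab), 1)
  expect_equal(auc_pooled_thresholds(tab), 1)
  # constant probabilities: chance line under endpoint augmentation
  tr_c <- make_trace(matrix(rep(0.4, 100), 1))
  tab_c <- metrics_table(list(tr_c), list(truth), 4 + 100 * 4,
                         thresholds = seq(0, 1, 0.05))
  expect_equal(auc_per_patient_mean(tab_c), 0.5)
})

test_that("pooled-threshold AUC is below mean per-patient AUC under calibration shifts", {
  # two patients whose traces separate seizure from background perfectly,
  # but at shifted operating levels
  set.seed(303)
  truth_idx <- 26:50
  dur <- 4 + 100 * 4
  for (i in 1:100) {
    shift <- runif(1, 0.05, 0.45)
    # patient 1 operates around 0.5, patient 2 around 0.1: the two
    # perfectly-separating traces share no common threshold
    p1 <- rep(0.5 - shift / 2, 100); p1[truth_idx] <- 0.5 + shift / 2
    p2 <- rep(0.05, 100); p2[truth_idx] <- 0.15
    tr1 <- make_trace(matrix(p1, 1)); tr2 <- make_trace(matrix(p2, 1))
    truth <- annotation_track(tr1$times_s[26], tr1$times_s[50] + 4)
    tab <- metrics_table(list(tr1, tr2), list(truth, truth), c(dur, dur),
                         thresholds = seq(0, 1, 0.02))
    a1 <- auc_per_patient_mean(tab)
    a2 <- auc_pooled_thresholds(tab)
    expect_equal(a1, 1)
    expect_lt(a2, a1)
  }
})

test_that("epoch-level SE is non-increasing and SP non-decreasing in the threshold", {
  set.seed(404)
  for (i in 1:5) {
    p <- pmin(pmax(stats::filter(runif(80), rep(1 / 5, 5),
                                 circular = TRUE), 0), 1)
    tr <- make_trace(matrix(as.numeric(p), 1))
    truth <- random_events(80 * 4)
    tab <- metrics_table(list(tr), list(truth), 4 + 80 * 4,
                         thresholds = seq(0, 1, 0.1))
    se <- tab$SE[, 1]; sp <- tab$SP[, 1]
    expect_true(all(diff(se[!is.na(se)]) <= 1e-12))
    expect_true(all(diff(sp[!is.na(sp)]) >= -1e-12))
  }
})

test_that("the threshold guide reports worst-case false-detection cost", {
  labs <- c("a", "b", "c")
  # three patients with isolated supra-threshold spikes and no true seizures
  spikes <- c(2, 3, 4)
  traces <- lapply(spikes, function(k) {
    p <- rep(0, 200)
    p[seq(10, by = 40, length.out = k)] <- 0.9
    make_trace(matrix(p, 1))
  })
  truths <- replicate(3, annotation_track(), simplify = FALSE)
  durs <- rep(200 * 4, 3)
  guide <- threshold_guide(traces, truths, durs,
                           thresholds = c(0.5, 0.95, 0.99),
                           collar_s = 0, n_boot = 500, seed = 9)
  hours <- 200 * 4 / 3600
  # beyond the max probability: nothing detected
  expect_equal(guide$mean_fd_per_hour[3], 0)
  expect_equal(guide$fd_per_hour_upper95[3], 0)
  expect_equal(guide$mean_fd_per_hour[1], mean(spikes / hours))
  # upper bound lies between the mean and the worst patient
  expect_gte(guide$fd_per_hour_upper95[1], guide$mean_fd_per_hour[1])
  expect_lte(guide$fd_per_hour_upper95[1], max(spikes / hours))
  # identical patients: degenerate CI equals the common value
  same <- threshold_guide(traces[c(1, 1)], truths[1:2], durs[1:2],
                          thresholds = c(0.5), collar_s = 0,
                          n_boot = 200, seed = 9)
  expect_equal(same$fd_per_hour_upper95, same$mean_fd_per_hour)
  # single patient: CI missing
  single <- threshold_guide(traces[1], truths[1], durs[1],
                            thresholds = c(0.5), collar_s = 0)
  expect_true(is.na(single$fd_per_hour_upper95))
})

test_that("the bootstrap FD/h bound approximates the analytic percentile", {
  set.seed(77)
  M <- 25
  fdh <- rnorm(M, mean = 1, sd = 0.2)
  # patients engineered so FD/h at theta 0.5 equals fdh (k spikes in k/fdh h)
  k <- 5
  durs <- k / fdh * 3600
  traces <- lapply(seq_len(M), function(j) {
    n_ep <- floor(durs[j] / 4) - 1
    p <- rep(0, n_ep)
    p[seq(10, by = 50, length.out = k)] <- 0.9
    make_trace(matrix(p, 1))
  })
  truths <- replicate(M, annotation_track(), simplify = FALSE)
  guide <- threshold_guide(traces, truths, durs, thresholds = c(0.5),
                           collar_s = 0, n_boot = 4000, seed = 5)
  analytic <- mean(fdh) + qnorm(0.975) * sd(fdh) * sqrt((M - 1) / M) / sqrt(M)
  expect_equal(guide$fd_per_hour_upper95, analytic, tolerance = 0.03)
})

test_that("tidy and glance summarise traces, decisions and tables", {
  tr <- make_trace(matrix(runif(2 * 10), 2), c("F3-C3", "F4-C4"))
  td <- tidy(tr)
  expect_setequal(unique(td$channel), c("F3-C3", "F4-C4", "fused"))
  dec <- binarize(tr, 0.1, 0)
  expect_equal(nrow(tidy(dec)), nrow(dec$events))
  expect_equal(glance(dec)$theta, 0.1)
  tab <- metrics_table(list(tr), list(annotation_track(8, 20)), 44,
                       thresholds = seq(0, 1, 0.25))
  g <- glance(tab)
  expect_true(all(c("auc_per_patient_mean", "auc_pooled_thresholds")
                  %in% names(g)))
  expect_equal(nrow(tidy(tab)), 5)
})
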