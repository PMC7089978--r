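# Photon data model and I/O

test_that("photon file round trip is lossless", {
  tr <- TTTRTrace(macrotimes = c(0, 3, 3, 40, 1e9 + 7),
                  microtimes = c(0, 24999, 512, 17, 2040),
                  channels = c(0L, 0L, 1L, 0L, 0L),
                  syncRate = 4e7, duration = 60,
                  metadata = list(dye = "Atto647N", concentration_nM = 100))
  path <- withr::local_tempfile(fileext = ".txt")
  writePhotonFile(tr, path)
  tr2 <- readPhotonFile(path)
  expect_identical(macrotimes(tr2), macrotimes(tr))
  expect_identical(microtimes(tr2), microtimes(tr))
  expect_identical(channels(tr2), channels(tr))
  expect_equal(syncRate(tr2), 4e7)
  expect_equal(acqDuration(tr2), 60)
  expect_equal(tr2@metadata$dye, "Atto647N")
  expect_equal(tr2@metadata$concentration_nM, 100)
})

test_that("hand-written records parse exactly, in order", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# sync_rate_hz=40000000",
               "0\t100\t0",
               "5\t20000\t1",
               "5\t3\t0",
               "123\t0\t0",
               "4000\t24999\t1"), path)
  tr <- readPhotonFile(path)
  expect_equal(nPhotons(tr), 5)
  expect_equal(macrotimes(tr), c(0, 5, 5, 123, 4000))
  expect_equal(microtimes(tr), c(100, 20000, 3, 0, 24999))
  expect_equal(channels(tr), c(0L, 1L, 0L, 0L, 1L))
})

test_that("empty container yields an empty, valid trace", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines("# sync_rate_hz=40000000", path)
  tr <- readPhotonFile(path)
  expect_equal(nPhotons(tr), 0)
  expect_equal(acqDuration(tr), 0)
  expect_true(validObject(tr))
})

test_that("malformed and invalid files raise pointed errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# sync_rate_hz=4e7", "0\t100\t0", "oops"), path)
  expect_error(readPhotonFile(path), "line 3")
  writeLines(c("# sync_rate_hz=4e7", "10\t100\t0", "5\t100\t0"), path)
  expect_error(readPhotonFile(path), "not non-decreasing")
  expect_error(readPhotonFile(path, formatHint = "hdf5"), "unsupported")
  expect_error(readPhotonFile(file.path(tempdir(), "nope.txt")), "no such")
})

test_that("trace validity enforces monotonicity and microtime range", {
  expect_error(TTTRTrace(c(5, 1), c(0, 0)), "non-decreasing")
  expect_error(TTTRTrace(c(1, 2), c(0, 25000)), "microtimes")
  expect_error(TTTRTrace(c(1, 2), c(0, -1)), "microtimes")
})

test_that("binning matches a brute-force histogram and conserves counts", {
  withr::local_seed(42)
  n <- 1e4
  t_s <- sort(runif(n, 0, 2))
  tr <- TTTRTrace(floor(t_s * 4e7), rep(0, n), duration = 2)
  it <- binIntensity(tr, 1e-3)
  # independent O(N * bins) count
  brute <- vapply(seq_along(counts(it)), function(k) {
    lo <- (k - 1) * 1e-3
    sum(arrivalTimes(tr) >= lo & arrivalTimes(tr) < lo + 1e-3)
  }, numeric(1))
  expect_equal(counts(it), brute)
  expect_equal(sum(counts(it)), n)
})

test_that("binning edge cases: empty trace, single cluster, bad width", {
  empty <- TTTRTrace(numeric(0), numeric(0), duration = 1)
  expect_true(all(counts(binIntensity(empty, 0.01)) == 0))
  clustered <- TTTRTrace(rep(1, 10), rep(0, 10), duration = 1)
  cnt <- counts(binIntensity(clustered, 0.5))
  expect_equal(cnt, c(10, 0))
  expect_error(binIntensity(clustered, 0), "positive")
  expect_error(binIntensity(clustered, -1), "positive")
})

test_that("TCSPC histogram matches brute-force binning; MLE recovers tau", {
  withr::local_seed(7)
  n <- 1e4
  tau_ps <- 4000
  micro <- floor(rexp(n, 1 / tau_ps)) %% 25000
  tr <- TTTRTrace(seq_len(n), micro, duration = 1)
  h <- buildTCSPCHistogram(tr, channelWidth = 16)
  brute <- tabulate(floor(micro / 16) + 1L, nbins = length(counts(h)))
  expect_equal(counts(h), as.numeric(brute))
  expect_equal(nPhotons(h), n)
  # closed-form MLE of the (wrapped) exponential mean on the raw microtimes:
  # wrap correction is analytic for the known period
  p <- 25000
  wrapped_mean <- function(tau) tau - p * exp(-p / tau) / (1 - exp(-p / tau))
  tau_hat <- uniroot(function(tt) wrapped_mean(tt) - mean(micro),
                     c(500, 20000))$root
  se <- tau_ps / sqrt(n)
  expect_lt(abs(tau_hat - tau_ps), 3 * se)
})

test_that("TCSPC histogram edge cases", {
  empty <- TTTRTrace(numeric(0), numeric(0), duration = 1)
  expect_true(all(counts(buildTCSPCHistogram(empty)) == 0))
  same <- TTTRTrace(1:50, rep(1234, 50), duration = 1)
  h <- buildTCSPCHistogram(same, 16)
  expect_equal(sum(counts(h) > 0), 1)
  expect_equal(max(counts(h)), 50)
  expect_error(buildTCSPCHistogram(same, 0), "positive")
})

test_that("histogram and correlation CSV round trips", {
  h <- new("TCSPCHistogram", channelWidth = 16,
           counts = as.numeric(rpois(1563, 10)), syncPeriod = 25000)
  path <- withr::local_tempfile(fileext = ".csv")
  writeHistogramCsv(h, path)
  h2 <- readHistogramCsv(path)
  expect_equal(counts(h2), counts(h))
  expect_equal(h2@channelWidth, 16)

  cv <- new("CorrelationCurve", lags = c(1e-6, 2e-6, 1e-5),
            g = c(1.5, 1.2, 0.3), weights = c(0.1, 0.1, 0.05),
            totalPhotons = 1e4, meanRate = 1700, binWidth = 1e-6)
  writeCorrelationCsv(cv, path)
  cv2 <- readCorrelationCsv(path)
  expect_equal(lags(cv2), lags(cv))
  expect_equal(gValues(cv2), gValues(cv))
  expect_equal(gWeights(cv2), gWeights(cv))
  expect_equal(meanRate(cv2), 1700)
})
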