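# Exact stochastic simulation: propensities, direct-method statistics,
# reproducibility, zero-order-hold trace evaluation.

test_that("propensity formulas", {
  sp <- data.frame(name = c("A", "B", "C"), init_conc = 0, role = "variable")
  ctx <- VolumeContext(1e-15)
  nav <- AVOGADRO * 1e-15
  net <- mkNetwork(sp, list(
    list(id = "uni", r = "A", p = "B", k = 2),
    list(id = "het", r = c("A", "B"), p = "C", k = 0.1 * nav),
    list(id = "hom", r = c("A", "A"), p = "C", k = 1 * nav / 2)))
  a <- propensities(c(5, 3, 0), net, ctx)
  expect_equal(unname(a["uni"]), 10)
  expect_equal(unname(a["het"]), 0.1 * 5 * 3)
  expect_equal(unname(a["hom"]), 1 * 5 * 4 / 2)
  # a homodimer needs two molecules
  expect_equal(unname(propensities(c(1, 0, 0), net, ctx)["hom"]), 0)
  expect_error(propensities(c(-1, 0, 0), net, ctx), "negative")
})

test_that("all-zero rates give an absorbing trace that persists to tEnd", {
  sp <- data.frame(name = "A", init_conc = 1e-6, role = "variable")
  net <- mkNetwork(sp, list(list(id = "r", r = "A", p = character(0), k = 0)))
  ctx <- VolumeContext(1e-15)
  tr <- simulateSSA(net, c(A = 10), ctx, tEnd = 5, seed = 1L)
  expect_length(tr@eventTimes, 0)
  expect_equal(traceValueAt(tr, "A", 5), 10)
})

test_that("linear death process matches its closed-form mean", {
  sp <- data.frame(name = "X", init_conc = 1e-6, role = "variable")
  net <- mkNetwork(sp, list(list(id = "d", r = "X", p = character(0), k = 1)))
  ctx <- VolumeContext(1e-15)
  set.seed(42)
  finals <- replicate(400, {
    tr <- simulateSSA(net, c(X = 1000), ctx, tEnd = 1)
    finalCounts(tr)[["X"]]
  })
  mu <- 1000 * exp(-1)        # E X(1) for X' -> death at rate 1
  se <- sqrt(1000 * exp(-1) * (1 - exp(-1)) / 400)
  expect_lt(abs(mean(finals) - mu), 3 * se)
})

test_that("immigration-death at stationarity is Poisson (mean ~ variance)", {
  ctx <- VolumeContext(1e-15)
  id <- immigrationDeathNetwork(kOut = 1, targetMean = 100, ctx = ctx)
  tr <- simulateSSA(id$network, id$init, ctx, tEnd = 400, seed = 11L)
  m <- timeWeightedMoments(tr, "X", 20, 400)
  expect_equal(m[["mean"]], 100, tolerance = 0.1)
  expect_equal(m[["sd"]]^2 / m[["mean"]], 1, tolerance = 0.15)
})

test_that("reversible isomerization matches its binomial stationary law", {
  iso <- isomerizationNetwork(kF = 2, kB = 1, nTotal = 50)
  ctx <- VolumeContext(1e-15)
  tr <- simulateSSA(iso$network, iso$init, ctx, tEnd = 600, seed = 5L)
  # sample x_A at well-separated times (relaxation time 1/(kF+kB) = 1/3 s)
  ts <- seq(50, 600, by = 2)
  xa <- traceValueAt(tr, "A", ts)
  p <- 1 / (2 + 1)                      # kB / (kF + kB)
  expect_equal(mean(xa), 50 * p, tolerance = 0.1)
  # goodness of fit against Binomial(50, 1/3) at alpha = 0.01
  brk <- c(-Inf, 11, 13, 15, 17, 19, 21, Inf)
  obs <- table(cut(xa, brk))
  pr <- diff(pbinom(c(-Inf, 11, 13, 15, 17, 19, 21, Inf), 50, p))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("identical seed paths give bit-identical traces", {
  ctx <- VolumeContext(1e-15)
  id <- immigrationDeathNetwork(kOut = 1, targetMean = 30, ctx = ctx)
  t1 <- simulateSSA(id$network, id$init, ctx, 20, seed = c(9L, 2L, 3L))
  t2 <- simulateSSA(id$network, id$init, ctx, 20, seed = c(9L, 2L, 3L))
  t3 <- simulateSSA(id$network, id$init, ctx, 20, seed = c(9L, 2L, 4L))
  expect_identical(t1@eventTimes, t2@eventTimes)
  expect_identical(t1@eventReaction, t2@eventReaction)
  expect_false(identical(t1@eventTimes, t3@eventTimes))
})

test_that("trace evaluation uses half-open plateaus", {
  sp <- data.frame(name = c("A", "B"), init_conc = c(1e-6, 0),
                   role = "variable")
  net <- mkNetwork(sp, list(list(id = "f", r = "A", p = "B", k = 1)))
  tr <- new("EventTrace", x0 = c(A = 5L, B = 0L),
            eventTimes = c(0.1, 0.12, 0.3),
            eventReaction = c(1L, 1L, 1L), t0 = 0, tEnd = 1,
            volume = 1e-15, seedPath = integer(0), network = net)
  expect_equal(traceValueAt(tr, "A", 0.05), 5)
  expect_equal(traceValueAt(tr, "A", 0.1), 4)   # post-event at event time
  expect_equal(traceValueAt(tr, "A", 0.2), 3)
  expect_equal(traceValueAt(tr, "A", 1), 2)     # holds to tEnd
  expect_error(traceValueAt(tr, "A", 1.5), "outside")
})

test_that("constant species never change during simulation", {
  ctx <- VolumeContext(1e-15)
  id <- immigrationDeathNetwork(kOut = 1, targetMean = 50, ctx = ctx)
  tr <- simulateSSA(id$network, id$init, ctx, 50, seed = 3L)
  expect_equal(finalCounts(tr)[["SRC"]], id$init[["SRC"]])
  expect_equal(frequencyOfChange(tr, "SRC"), 0)
})

test_that("ensemble mean of a first-order network follows the ODE solution", {
  # A -> B with k = 1: E A(t) = A0 exp(-t)
  sp <- data.frame(name = c("A", "B"), init_conc = c(1e-6, 0),
                   role = "variable")
  net <- mkNetwork(sp, list(list(id = "f", r = "A", p = "B", k = 1)))
  ctx <- VolumeContext(1e-15)
  set.seed(8)
  at <- replicate(300, {
    tr <- simulateSSA(net, c(A = 200, B = 0), ctx, tEnd = 0.7)
    traceValueAt(tr, "A", c(0.2, 0.5, 0.7))
  })
  for (i in seq_along(c(0.2, 0.5, 0.7))) {
    t <- c(0.2, 0.5, 0.7)[i]
    mu <- 200 * exp(-t)
    se <- sqrt(200 * exp(-t) * (1 - exp(-t)) / 300)
    expect_lt(abs(mean(at[i, ]) - mu), 3 * se)
  }
})

test_that("trace CSV round-trip", {
  ctx <- VolumeContext(1e-15)
  id <- immigrationDeathNetwork(kOut = 1, targetMean = 20, ctx = ctx)
  tr <- simulateSSA(id$network, id$init, ctx, 5, seed = 2L)
  f <- tempfile(fileext = ".csv")
  writeTrace(tr, f)
  tr2 <- readTrace(f, id$network)
  expect_equal(tr2@eventTimes, tr@eventTimes)
  expect_identical(tr2@eventReaction, tr@eventReaction)
  expect_identical(unname(tr2@x0), unname(tr@x0))
  expect_equal(tr2@tEnd, tr@tEnd)
})
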