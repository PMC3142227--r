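# Reaction-network model: parsing, validation, stoichiometry, unit
# conversions.

test_that("packaged signalling network has the documented composition", {
  net <- loadNetwork(packagedNetworkPath())
  expect_length(speciesNames(net), 66)
  expect_equal(nrow(reactions(net)), 110)
  expect_length(variableSpecies(net), 61)
  expect_setequal(constantSpecies(net),
                  c("APC", "tempPIP2", "Inositol", "PC", "PIP2"))
  ic <- initConc(net)
  expect_equal(unname(ic[c("APC", "tempPIP2", "Inositol", "PC", "PIP2")]),
               c(30e-6, 2.5e-6, 0, 0, 2.5e-6))
  # species named with embedded asterisks survive parsing verbatim
  expect_true(all(c("craf**deph", "cRaf1**", "G*GTP", "G*GDP", "MAPK*") %in%
                    speciesNames(net)))
})

test_that("parser rejects malformed files with the offending line", {
  base <- c("[species]", "A\t1e-6\tvariable", "B\t0\tvariable")
  expect_error(loadNetwork(writeTableFile(
    c(base, "[reactions]", "R1\tA -> C\t1\tkf"))), "line 5.*unknown species")
  expect_error(loadNetwork(writeTableFile(
    c("[species]", "A\t1e-6\tvariable", "A\t0\tvariable", "[reactions]",
      "R1\tA -> A\t1\tkf"))), "line 3.*duplicate")
  expect_error(loadNetwork(writeTableFile(
    c(base, "[reactions]", "R1\tA + A + B -> B\t1\tkf"))),
    "line 5.*order")
  expect_error(loadNetwork(writeTableFile(
    c(base, "[reactions]", "R1\tA -> B\t-2\tkf"))), "line 5.*negative")
  expect_error(loadNetwork(writeTableFile(c(base, "[reactions]"))),
               "empty reactions")
})

test_that("write/load round-trip reproduces the network", {
  net <- loadNetwork(packagedNetworkPath())
  f <- tempfile(fileext = ".tsv")
  writeNetwork(net, f)
  net2 <- loadNetwork(f)
  expect_equal(net2@species, net@species)
  expect_equal(net2@reactions$k, net@reactions$k)
  expect_identical(net2@reactions$reactants, net@reactions$reactants)
  expect_identical(net2@reactions$products, net@reactions$products)
})

test_that("stoichiometric matrix columns are products minus reactants", {
  sp <- data.frame(name = c("E", "S", "ES", "A", "B"),
                   init_conc = c(1e-6, 1e-6, 0, 1e-6, 0),
                   role = c("constant", rep("variable", 4)))
  net <- mkNetwork(sp, list(
    list(id = "conv", r = "A", p = "B", k = 1),
    list(id = "dim", r = c("A", "B"), p = "ES", k = 1),
    list(id = "bind", r = c("E", "S"), p = "ES", k = 1),
    list(id = "homo", r = c("A", "A"), p = "B", k = 1)))
  S <- stoichiometricMatrix(net)
  expect_identical(dim(S), c(5L, 4L))
  expect_equal(S[, "conv"], c(E = 0, S = 0, ES = 0, A = -1, B = 1),
               ignore_attr = FALSE)
  expect_equal(unname(S[, "dim"]), c(0, 0, 1, -1, -1))
  # constant species row forced to zero; substrate still consumed
  expect_equal(unname(S[, "bind"]), c(0, -1, 1, 0, 0))
  expect_equal(unname(S[, "homo"]), c(0, 0, 0, -2, 1))
  expect_true(all(S %in% -2:2))
})

test_that("concentration/count conversion uses N_A V with half-away rounding", {
  ctx <- VolumeContext(5e-16)
  expect_identical(concentrationsToCounts(2.5e-6, ctx), 753L)   # 752.77
  expect_identical(concentrationsToCounts(0, ctx), 0L)
  expect_identical(concentrationsToCounts(2.5e-6, VolumeContext(1e-13)),
                   150554L)                                     # 150553.5
  expect_error(concentrationsToCounts(-1e-9, ctx), "negative")
  # half-away rounding at exactly .5
  v <- 0.5 / (AVOGADRO * ctx@volume)
  expect_identical(concentrationsToCounts(v, ctx), 1L)
  # round trip bounded by half a molecule
  set.seed(1)
  conc <- runif(50, 0, 1e-5)
  back <- countsToConcentrations(concentrationsToCounts(conc, ctx), ctx)
  expect_true(all(abs(back - conc) <= 0.5 / (AVOGADRO * ctx@volume) + 1e-30))
})

test_that("stochastic rate constants follow the volume scaling laws", {
  sp <- data.frame(name = c("A", "B", "C"), init_conc = 1e-6,
                   role = "variable")
  net <- mkNetwork(sp, list(
    list(id = "uni", r = "A", p = "B", k = 1),
    list(id = "het", r = c("A", "B"), p = "C", k = 6.02214076e7),
    list(id = "hom", r = c("A", "A"), p = "C", k = 6.02214076e7)))
  ctx <- VolumeContext(1e-16)
  cj <- stochasticRateConstants(net, ctx)
  expect_equal(unname(cj["uni"]), 1)            # first order: identity
  expect_equal(unname(cj["het"]), 1)            # k / (N_A V) = 1
  expect_equal(unname(cj["hom"]), 2)            # homodimer factor 2
  cj2 <- stochasticRateConstants(net, VolumeContext(0.5e-16))
  expect_equal(unname(cj2[c("het", "hom")]), 2 * unname(cj[c("het", "hom")]))
  expect_equal(unname(cj2["uni"]), 1)
})
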