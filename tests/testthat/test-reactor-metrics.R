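# Derived reactor performance metrics: free ammonia, COD-balance
# efficiencies, first-order hydrolysis kinetics, differential indices.

test_that("free ammonia follows the NH3/NH4+ equilibrium closed form", {
  # independent recomputation, spelled out step by step
  fa_oracle <- function(TAN, pH, TC) {
    TK <- TC + 273.15
    ratio <- 10^(-pH) / 10^(-(0.09018 + 2729.92 / TK))
    1.214 * TAN * (1 + ratio)^(-1)
  }
  grid <- expand.grid(TAN = c(50, 93, 500, 1217),
                      pH = c(6.8, 7.0, 7.5, 8.2),
                      TC = c(22, 35, 52))
  expect_equal(free_ammonia(grid$TAN, grid$pH, grid$TC),
               fa_oracle(grid$TAN, grid$pH, grid$TC))
  expect_identical(free_ammonia(0, 7.2, 35), 0)
  # bounded by the fully un-ionised limit
  expect_true(all(free_ammonia(grid$TAN, grid$pH, grid$TC) <= 1.214 * grid$TAN))
})

test_that("free ammonia is monotone increasing in pH and temperature", {
  ph_grid <- seq(5, 9, by = 0.1)
  expect_true(all(diff(free_ammonia(100, ph_grid, 35)) > 0))
  t_grid <- seq(15, 60, by = 1)
  expect_true(all(diff(free_ammonia(100, 7.4, t_grid)) > 0))
  # scaling law: FA/TAN depends only on (pH, T)
  f1 <- free_ammonia(1, 7.3, 38)
  expect_equal(free_ammonia(c(10, 250, 4000), 7.3, 38), c(10, 250, 4000) * f1)
})

test_that("free ammonia rejects invalid inputs", {
  expect_error(free_ammonia(-1, 7, 35), "non-negative")
  expect_error(free_ammonia(100, 14.5, 35), "pH")
  expect_error(free_ammonia(NA_real_, 7, 35), "finite")
})

test_that("COD-balance efficiencies match direct arithmetic", {
  expect_equal(hydrolysis_efficiency(2, 1, 4, 10, 0), 0.5)
  expect_equal(hydrolysis_efficiency(1, 1, 0, 10, 2), 0)
  expect_equal(methanogenesis_efficiency(0, 10, 2), 0)
  # randomized spreadsheet-style oracle
  set.seed(11)
  for (i in 1:50) {
    tinf <- runif(1, 5, 40)
    teff <- runif(1, 0, tinf * 0.9)
    sinf <- runif(1, 0, tinf * 0.6)
    seff <- runif(1, 0, teff)
    ch4 <- runif(1, 0, tinf)
    expect_equal(hydrolysis_efficiency(seff, sinf, ch4, tinf, teff),
                 (seff - sinf + ch4) / (tinf - teff))
    expect_equal(methanogenesis_efficiency(ch4, tinf, teff),
                 ch4 / (tinf - teff))
    # algebraic identity: hyd - meth == (sCOD_eff - sCOD_inf)/(tCOD removed)
    expect_equal(hydrolysis_efficiency(seff, sinf, ch4, tinf, teff) -
                   methanogenesis_efficiency(ch4, tinf, teff),
                 (seff - sinf) / (tinf - teff))
  }
  expect_error(hydrolysis_efficiency(1, 1, 1, 5, 5), "tCOD_inf")
  expect_error(methanogenesis_efficiency(1, 4, 5), "tCOD_inf")
})

test_that("methanogenesis efficiency cannot exceed hydrolysis efficiency when
           soluble COD does not drop across the reactor", {
  set.seed(12)
  for (i in 1:25) {
    tinf <- runif(1, 5, 40); teff <- runif(1, 0, tinf * 0.9)
    sinf <- runif(1, 0, min(tinf, teff) * 0.5)
    seff <- runif(1, sinf, teff)   # effluent soluble >= influent soluble
    ch4 <- runif(1, 0, tinf)
    expect_gte(hydrolysis_efficiency(seff, sinf, ch4, tinf, teff),
               methanogenesis_efficiency(ch4, tinf, teff))
  }
})

test_that("hydrolysis rate constant inverts exact first-order series", {
  # 1 - e^-1 at Delta t = 5 days gives K_H = 0.2 / day
  k <- hydrolysis_rate_constant(times = c(0, 5, 30),
                                sCOD_t = c(0, 13.212, 20),
                                COD_CH4_t = c(0, 50, 80), t_index = 2)
  expect_equal(k, log(100 / 36.788) / 5, tolerance = 1e-12)
  expect_equal(k, 0.2, tolerance = 1e-4)

  # recovery of arbitrary k at every interior time point
  for (k_true in c(0.05, 0.2, 0.8)) {
    times <- c(0, 1, 2, 4, 8, 16, 1000)
    S_end <- 50
    pool <- S_end * (1 - exp(-k_true * times))   # hydrolysed COD
    scod <- 0.3 * pool
    ch4 <- 0.7 * pool
    for (ti in 2:6) {
      est <- hydrolysis_rate_constant(times, scod, ch4, t_index = ti)
      expect_equal(est, k_true, tolerance = 1e-9)
    }
    est_lsq <- hydrolysis_rate_constant(times, scod, ch4, method = "lsq")
    expect_equal(est_lsq, k_true, tolerance = 1e-9)
  }
})

test_that("hydrolysis rate constant recovers simulated noisy kinetics", {
  set.seed(21)
  k_true <- 0.25
  times <- c(0, seq(1, 12, by = 1), 60)
  pool <- 40 * (1 - exp(-k_true * times))
  reps <- replicate(40, {
    noisy <- pmax(pool + c(0, rnorm(length(times) - 2, sd = 0.3), 0), 0)
    noisy_scod <- 0.4 * noisy
    noisy_ch4 <- cummax(0.6 * noisy)
    hydrolysis_rate_constant(times, noisy_scod, noisy_ch4, method = "lsq")
  })
  expect_equal(mean(reps), k_true, tolerance = 0.05)
})

test_that("hydrolysis rate constant rejects degenerate series", {
  expect_error(hydrolysis_rate_constant(c(0, 0), c(0, 1), c(0, 1)),
               "strictly increasing")
  expect_error(hydrolysis_rate_constant(c(0, 1), c(0, 1), c(1, 0)),
               "non-decreasing")
  # degradation already complete at the requested point
  expect_error(hydrolysis_rate_constant(c(0, 5), c(0, 10), c(0, 10),
                                        t_index = 2),
               "complete")
})

test_that("differential efficiency and rate indices", {
  expect_equal(d_efficiency(0.5, 0.5), 0)
  expect_equal(d_efficiency(0.5, 0), 1)
  # Table-1-style stage means for the co-digestion condition
  expect_equal(d_efficiency(0.805, 0.771), 0.034 / 0.805)
  expect_equal(round(d_efficiency(0.805, 0.771), 4), 0.0422)
  expect_error(d_efficiency(0, 0.5), "undefined")
  expect_equal(d_rate(0.3, 0.3), 0)
  expect_equal(d_rate(0.3, 0), 1)
  set.seed(31)
  kh <- runif(20, 0.05, 1); sma <- runif(20, 0, 0.5)
  expect_equal(d_rate(kh, sma), (kh - sma) / kh)
  expect_error(d_rate(0, 0.1), "undefined")
})

test_that("derive_metrics assembles the tidy metric table", {
  chem <- data.frame(
    reactor_id = c("R1", "R2"), group = c("g1", "g2"),
    tCOD_inf = c(10, 30), tCOD_eff = c(2, 8),
    sCOD_inf = c(3, 5), sCOD_eff = c(1, 4),
    COD_CH4 = c(4, 15), TAN = c(100, 1200), pH = c(7.5, 7.0),
    temperature_C = c(35, 52), SMA_total = c(0.3, 0.2), K_H = c(0.2, 0.4))
  m <- derive_metrics(chem)
  expect_equal(m$hydrolysis_eff, c((1 - 3 + 4) / 8, (4 - 5 + 15) / 22))
  expect_equal(m$methanogenesis_eff, c(4 / 8, 15 / 22))
  expect_equal(m$pCOD_ratio, c(1 - 3 / 10, 1 - 5 / 30))
  expect_equal(m$FA, free_ammonia(chem$TAN, chem$pH, chem$temperature_C))
  expect_equal(m$D_rate, (chem$K_H - chem$SMA_total) / chem$K_H)
  expect_true(all(c("reactor_id", "group") %in% names(m)))
  expect_error(derive_metrics(chem[, -3]), "missing columns")
})

test_that("long-format chemistry round-trips through TSV", {
  chem_long <- expand.grid(reactor_id = c("A", "B"), stage = 1:2,
                           variable = c("tCOD_inf", "pH"),
                           stringsAsFactors = FALSE)
  chem_long$value <- seq_len(nrow(chem_long)) + 0.5
  chem_long$unit <- "g/L"
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(chem_long, f, sep = "\t", quote = FALSE, row.names = FALSE)
  wide <- read_chem_long(f)
  expect_setequal(names(wide), c("reactor_id", "stage", "tCOD_inf", "pH"))
  expect_equal(nrow(wide), 4)
  expect_equal(wide$tCOD_inf[wide$reactor_id == "A" & wide$stage == 1],
               chem_long$value[chem_long$reactor_id == "A" &
                                 chem_long$stage == 1 &
                                 chem_long$variable == "tCOD_inf"])
})
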