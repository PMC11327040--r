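test_that("total outlet resistance is the pressure-flow quotient", {
  expect_equal(total_outlet_resistance(124000, 83), 124000 / 83)
  expect_equal(total_outlet_resistance(0, 10), 0)
  expect_error(total_outlet_resistance(124000, 0), "positive")
})

test_that("Windkessel split follows the distal fraction", {
  m <- split_rcr(1000)
  expect_equal(m$Rp, 90)
  expect_equal(m$Rd, 910)
  even <- split_rcr(1000, distal_fraction = 0.5)
  expect_equal(even$Rp, even$Rd)
  expect_error(split_rcr(0), "positive")
  expect_error(split_rcr(1000, distal_fraction = 1), "\\(0, 1\\)")
})

test_that("compliance split follows the microcirculatory fraction", {
  cc <- split_compliance()
  expect_equal(cc$Ca, 1.1e-4)
  expect_equal(cc$Cim, 8.9e-4)
  even <- split_compliance(0.01, 0.5)
  expect_equal(even$Ca, even$Cim)
  expect_error(split_compliance(0), "positive")
  expect_error(split_compliance(0.001, 1.2), "\\(0, 1\\)")
})

test_that("outlet resistances are inversely proportional to target flows", {
  al <- allocate_outlet_resistances(1e5, c(a = 2, b = 1))
  expect_equal(al$R_total[2], 2 * al$R_total[1])
  # a single outlet carrying the whole flow reproduces the total resistance
  single <- allocate_outlet_resistances(1e5, c(all = 80))
  expect_equal(single$R_total, total_outlet_resistance(1e5, 80))
  # 4% coronary share means 25x the aorta-equivalent resistance
  both <- allocate_outlet_resistances(1e5, c(aorta = 80, cor = 0.04 * 80))
  expect_equal(both$R_total[2] / both$R_total[1], 25)
  expect_error(allocate_outlet_resistances(1e5, c(a = 0)), "positive")
})

test_that("RCR state derivative matches the closed-form RC response", {
  skip_if_not_installed("deSolve")
  m <- split_rcr(1000, C = 2e-3, Pref = 500)
  Q0 <- 3
  sol <- deSolve::lsoda(
    y = c(Pc = m$Pref), times = seq(0, 20, 0.05),
    func = function(t, y, p) list(rcr_state_derivative(m, y, Q0, t)$dstate),
    rtol = 1e-10, atol = 1e-8
  )
  tau <- m$Rd * m$C
  closed <- m$Pref + Q0 * m$Rd * (1 - exp(-sol[, "time"] / tau))
  expect_lt(max(abs(sol[, "Pc"] - closed)) / (Q0 * m$Rd), 0.005)
  # long-time interface pressure approaches Q0 (Rp + Rd) + Pref
  p_inf <- rcr_state_derivative(m, sol[nrow(sol), "Pc"], Q0)$P_in
  expect_equal(unname(p_inf), Q0 * (m$Rp + m$Rd) + m$Pref, tolerance = 1e-4)
  # equilibrium has zero state rate
  expect_equal(rcr_state_derivative(m, m$Pref, 0)$dstate, 0)
})

test_that("coronary circuit step response matches an eigenvalue closed form", {
  skip_if_not_installed("deSolve")
  m <- coronary_lpn(8e4, 5e-5, pim = make_pim_waveform(1, 0), Pv = 1000)
  Q0 <- 1.5
  # hand-derived linear system ds/dt = A s + b for s = (Pa, u), Pim = 0
  A <- rbind(
    c(-1 / (m$Ra_micro * m$Ca), 1 / (m$Ra_micro * m$Ca)),
    c(1 / (m$Ra_micro * m$Cim), -1 / (m$Ra_micro * m$Cim) - 1 / (m$Rv * m$Cim))
  )
  b <- c(Q0 / m$Ca, m$Pv / (m$Rv * m$Cim))
  s_inf <- solve(A, -b)
  eg <- eigen(A)
  tt <- seq(0, 30, 0.05)
  s0 <- c(0, 0)
  coef <- solve(eg$vectors, s0 - s_inf)
  closed <- t(vapply(tt, function(t) {
    Re(s_inf + eg$vectors %*% (coef * exp(eg$values * t)))
  }, numeric(2)))
  num <- deSolve::lsoda(
    y = c(Pa = 0, u = 0), times = tt,
    func = function(t, y, p) {
      list(coronary_lpn_state_derivative(m, y, Q0, t)$dstate)
    },
    rtol = 1e-10, atol = 1e-8
  )
  scale <- max(abs(s_inf))
  expect_lt(max(abs(num[, c("Pa", "u")] - closed)) / scale, 0.005)
  # resistive steady state of the interface pressure
  p_inf <- coronary_lpn_state_derivative(m, closed[length(tt), ], Q0)$P_in
  expect_equal(p_inf, Q0 * (m$Ra + m$Ra_micro + m$Rv) + m$Pv,
               tolerance = 1e-3)
})

test_that("intramyocardial pressure impedes systolic inflow", {
  skip_if_not_installed("deSolve")
  P_drive <- mmHg_to_dyne(93)
  run_lpn <- function(peak) {
    m <- coronary_lpn(9e4, 4e-5, pim = make_pim_waveform(1, peak, 0.35))
    f <- function(t, y, p) {
      Q_in <- (P_drive - y[1]) / m$Ra
      list(coronary_lpn_state_derivative(m, y, Q_in, t)$dstate)
    }
    out <- deSolve::lsoda(c(Pa = P_drive * 0.7, u = 0),
                          times = seq(0, 12, 0.002), f, rtol = 1e-8)
    last <- out[out[, "time"] >= 11, ]
    q <- (P_drive - last[, "Pa"]) / m$Ra
    ts <- last[, "time"] %% 1
    mean(q[ts <= 0.35])   # mean systolic inflow
  }
  expect_lt(run_lpn(mmHg_to_dyne(120)), run_lpn(0))
})

test_that("invalid circuit parameters are rejected", {
  expect_error(coronary_lpn(-1, 1e-4), "positive")
  expect_error(coronary_lpn(1e4, 1e-4, splits = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(coronary_lpn(1e4, 1e-4, pim = 5), "function")
})
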