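test_that("constant inflow into a Windkessel relaxes to the algebraic steady state", {
  rcr <- split_rcr(1000, C = 1e-5)   # fast time constant
  branches <- tibble::tibble(
    name = "b1", parent = "root", R = 10, L_inert = 0,
    sten = list(NULL), outlet = list(rcr)
  )
  net <- network_from_branches(branches, function(t) rep(2, length(t)))
  sol <- solve_transient(net, n_cycles = 3, steps_per_cycle = 200)
  expect_equal(sol$node_pressures[nrow(sol$node_pressures), "root"],
               2 * (10 + 1000), tolerance = 1e-3, ignore_attr = TRUE)
  expect_true(sol$converged)
})

test_that("outlet mean flows balance the inlet mean over the converged cycle", {
  sol <- solve_transient(assemble_network(), n_cycles = 12,
                         steps_per_cycle = 500)
  tt <- sol$time
  trap_mean <- function(v) {
    n <- length(tt)
    sum(diff(tt) * (v[-1] + v[-n]) / 2) / (tt[n] - tt[1])
  }
  outlet_sum <- sum(vapply(c("AO", "LAD", "LCX", "RCA"),
                           function(v) trap_mean(sol$flows[, v]), numeric(1)))
  inlet_mean <- trap_mean(sol$network$inlet(tt))
  expect_lt(abs(outlet_sum - inlet_mean) / inlet_mean, 0.005)
  # convergence metric decays over the last cycles
  m <- sol$convergence$metric
  expect_true(all(diff(tail(m, 3)) <= 1e-12))
})

test_that("junction mass conservation holds to solver precision", {
  sol <- solve_transient(assemble_network(list(stenosis_spec("LM", 0.5))),
                         n_cycles = 4, steps_per_cycle = 250)
  expect_lt(mass_conservation_residual(sol), 1e-6)
})

test_that("a zero-degree stenosis reproduces the healthy network exactly", {
  a <- solve_transient(assemble_network(), n_cycles = 3,
                       steps_per_cycle = 100)
  b <- solve_transient(assemble_network(list(stenosis_spec("LM", 0))),
                       n_cycles = 3, steps_per_cycle = 100)
  expect_identical(a$flows, b$flows)
  expect_identical(a$node_pressures, b$node_pressures)
})

test_that("halving the time step leaves mean pressures within 0.5%", {
  net <- assemble_network(list(stenosis_spec("LAD", 0.5)))
  coarse <- solve_transient(net, n_cycles = 8, steps_per_cycle = 250)
  fine <- solve_transient(net, n_cycles = 8, steps_per_cycle = 500)
  m <- function(sol, col) {
    tt <- sol$time; v <- sol$node_pressures[, col]; n <- length(tt)
    sum(diff(tt) * (v[-1] + v[-n]) / 2)
  }
  for (col in c("root", "LM_out")) {
    expect_lt(abs(m(coarse, col) - m(fine, col)) / abs(m(fine, col)), 0.005)
  }
})

test_that("mean vessel flow is non-increasing in the degree of stenosis", {
  means <- vapply(c(0, 0.3, 0.5, 0.7), function(ds) {
    net <- assemble_network(if (ds > 0) list(stenosis_spec("LM", ds))
                            else list())
    sol <- solve_transient(net, n_cycles = 6, steps_per_cycle = 250)
    mean(sol$flows[-nrow(sol$flows), "LM"])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("BDF2 matches an adaptive stiff integrator on a toy network", {
  skip_if_not_installed("deSolve")
  net <- toy_two_outlet_network()
  sol <- solve_transient(net, n_cycles = 12, steps_per_cycle = 500,
                         init = "zero")
  rcr <- net$branches$outlet[[1]]
  lpn <- net$branches$outlet[[2]]
  R1 <- 50 + rcr$Rp
  R2 <- 200 + lpn$Ra
  qin <- net$inlet
  f <- function(t, y, p) {
    Q1 <- (y[2] + lpn$pim(t) * 0 - y[1] + qin(t) * R2) / (R1 + R2)
    Q2 <- qin(t) - Q1
    Pb <- y[3] + lpn$pim(t)
    qab <- (y[2] - Pb) / lpn$Ra_micro
    list(c(
      (Q1 - (y[1] - rcr$Pref) / rcr$Rd) / rcr$C,
      (Q2 - qab) / lpn$Ca,
      (qab - (Pb - lpn$Pv) / lpn$Rv) / lpn$Cim
    ))
  }
  times <- c(0, 11 + sol$time)
  orc <- deSolve::lsoda(c(Pc = 0, Pa = 0, u = 0), times, f,
                        rtol = 1e-10, atol = 1e-8)
  orc <- orc[-1, , drop = FALSE]
  Q1 <- (orc[, "Pa"] - orc[, "Pc"] + qin(orc[, "time"]) * R2) / (R1 + R2)
  p_root_oracle <- orc[, "Pc"] + Q1 * R1
  err <- max(abs(sol$node_pressures[, "root"] - p_root_oracle)) /
    mean(abs(p_root_oracle))
  expect_lt(err, 0.005)
})

test_that("periodic initialisation yields charge-conserving cycles", {
  sol <- solve_transient(assemble_network(), n_cycles = 3,
                         steps_per_cycle = 500, init = "periodic")
  expect_lt(capacitor_current_ratio(sol), 1e-3)
  expect_true(sol$converged)
})

test_that("solution tidiers expose pressures and flows", {
  sol <- solve_transient(assemble_network(), n_cycles = 2,
                         steps_per_cycle = 100)
  long <- tidy(sol)
  expect_setequal(unique(long$kind),
                  c("pressure", "outlet_pressure", "flow"))
  g <- glance(sol)
  expect_equal(nrow(g), 1)
  # coarse 100-step grid: discretisation only
  expect_lt(abs(g$mean_inlet_flow - 5000 / 60) / (5000 / 60), 1e-3)
  expect_lt(g$mass_residual, 1e-6)
})
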