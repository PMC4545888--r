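test_that("heaviside is the right-continuous unit step", {
  expect_equal(heaviside(0), 1)
  expect_equal(heaviside(-0.001), 0)
  expect_equal(heaviside(5), 1)
  expect_equal(heaviside(c(-1, 0, 1)), c(0, 1, 1))
  expect_error(heaviside(NaN), "finite")
  expect_error(heaviside(Inf), "finite")
})

test_that("phi matches its limit at the singular point and its asymptotes", {
  # series limit at I = 0.384: 0.352u / (352u + 3.52u + O(u^2)) -> 0.352/355.52
  expect_equal(phi(0.384), 0.001 + 0.352 / 355.52, tolerance = 1e-12)
  # numerical continuity from both sides
  expect_equal(phi(0.384 + 1e-9), phi(0.384), tolerance = 1e-6)
  expect_equal(phi(0.384 - 1e-9), phi(0.384), tolerance = 1e-6)
  # asymptotes 0.001 and 0.101 (the upper one approached as 0.1/(3.52 I))
  expect_equal(phi(-50), 0.001, tolerance = 1e-9)
  expect_equal(phi(1e6), 0.101, tolerance = 1e-6)
})

test_that("phi is increasing and bounded on a dense grid", {
  # strictly increasing through the operating range and the singular point
  # (below I ~ 0.27 the increments fall under double precision against the
  # 0.001 offset, so strictness is only numerically testable above that)
  grid <- sort(unique(c(round(seq(0.28, 3, by = 0.001), 10), 0.384)))
  v <- phi(grid)
  expect_true(all(diff(v) > 0))
  # non-decreasing and bounded over a much wider range (the lower tail
  # saturates at exactly 0.001 once exp(-352 u) overflows)
  wide <- phi(seq(-100, 100, by = 0.1))
  expect_true(all(diff(wide) >= 0))
  expect_true(all(wide >= 0.001 & wide < 0.101))
})

test_that("the gate is piecewise linear with a strict threshold", {
  expect_equal(gate_input(0.5, 0.1), 0.4)
  expect_equal(gate_input(0.05, 0.1), 0)
  expect_equal(gate_input(0.3, 0.3), 0)
  expect_equal(gate_input(c(-1, 0, 2), 0.5), c(0, 0, 1.5))
})

test_that("input schedules follow the set-size, target and orientation rules", {
  s <- params_m11()$s_lip
  expect_equal(perceptual_input(2, "L1", s), s)
  expect_equal(perceptual_input(2, "L2", s), 0)
  expect_equal(perceptual_input(4, "R2", s), s)
  expect_equal(perceptual_input(4, "L3", s), 0)
  expect_equal(perceptual_input(6, "R3", s), s)
  expect_error(perceptual_input(4, "X1"), "arg")

  expect_equal(target_input("R1", "R1", 0.4), 0.4)
  expect_equal(target_input("R1", "L1", 0.4), 0)
  expect_equal(target_input("L2", "L2", 0.4), 0.4)

  expect_equal(orientation_input("E_right", "E_right", 1.2), 1.2)
  expect_equal(orientation_input("E_right", "E_left", 1.2), 0)
  expect_equal(orientation_input("E_left", "E_left", 1.2), 1.2)
})

test_that("motor inhibition is a symmetric weighted sum of motor activity", {
  expect_equal(motor_inhibition(c(0, 0), 11.02), 0)
  expect_equal(motor_inhibition(c(0.01, 0.02), 11.02), 0.3306)
  expect_equal(
    motor_inhibition(c(0.03, 0.07), 5),
    motor_inhibition(c(0.07, 0.03), 5)
  )
})

test_that("the LIP ring topology has the expected neighbour structure", {
  topo <- lip_topology()
  # symmetry
  rev_d <- topo$distance[match(
    paste(topo$to, topo$from),
    paste(topo$from, topo$to)
  )]
  expect_equal(topo$distance, rev_d)
  # each unit: two 1-step, two 2-step, one 3-step neighbours
  counts <- topo %>%
    dplyr::count(from, distance) %>%
    tidyr::pivot_wider(names_from = distance, values_from = n)
  expect_true(all(counts$`1` == 2 & counts$`2` == 2 & counts$`3` == 1))
  # the neighbour groupings of the six LIP equations
  groups <- function(u, d) sort(topo$to[topo$from == u & topo$distance == d])
  expect_equal(groups("L1", 1), c("L2", "R1"))
  expect_equal(groups("L1", 2), c("L3", "R2"))
  expect_equal(groups("L1", 3), "R3")
  expect_equal(groups("L2", 1), c("L1", "L3"))
  expect_equal(groups("L2", 2), c("R1", "R3"))
  expect_equal(groups("L2", 3), "R2")
  expect_equal(groups("L3", 1), c("L2", "R3"))
  expect_equal(groups("L3", 2), c("L1", "R2"))
  expect_equal(groups("L3", 3), "R1")
  expect_equal(groups("R1", 1), c("L1", "R2"))
  expect_equal(groups("R1", 2), c("L2", "R3"))
  expect_equal(groups("R1", 3), "L3")
  expect_equal(groups("R2", 1), c("R1", "R3"))
  expect_equal(groups("R2", 2), c("L1", "L3"))
  expect_equal(groups("R2", 3), "L2")
  expect_equal(groups("R3", 1), c("L3", "R2"))
  expect_equal(groups("R3", 2), c("L2", "R1"))
  expect_equal(groups("R3", 3), "L1")
})

test_that("drift at the origin: no input yet, LIP activity still rises via phi", {
  p <- update_params(params_m11(), s_back = 0)
  d <- lca_drift(network_state(), p, cond_cong4, t = 0)
  rho_idx <- grep("^rho_lip", names(d$drift))
  expect_equal(unname(d$drift[rho_idx]), rep(0, 6))
  lip_idx <- grep("^x_lip", names(d$drift))
  expect_equal(unname(d$drift[lip_idx]), rep(phi(0) / p$tau_lip, 6))
  expect_true(all(d$drift[lip_idx] > 0))
})

test_that("drift respects bilateral mirror symmetry", {
  p <- params_m11()
  mirror_state <- function(s) {
    m <- s
    swap <- function(a, b) {
      tmp <- m[a]
      m[a] <<- m[b]
      m[b] <<- tmp
    }
    for (i in 1:3) {
      swap(i, i + 3) # x_lip L<->R
      swap(i + 6, i + 9) # rho_lip
    }
    swap(13, 14) # x_it
    swap(15, 16) # rho_it
    swap(17, 18) # x_aip
    swap(19, 20) # x_m
    m
  }
  set.seed(11)
  for (rep in 1:5) {
    s <- setNames(runif(20, 0, 0.2), names(network_state()))
    cond <- trial_condition(4, sample(c("L1", "R1", "L2", "R2"), 1),
      sample(c("E_left", "E_right"), 1))
    t <- runif(1, 0, 400)
    d1 <- lca_drift(s, p, cond, t)$drift
    d2 <- lca_drift(mirror_state(s), p,
      covertsearch:::mirror_condition(cond), t)$drift
    expect_equal(unname(mirror_state(d1)), unname(d2), tolerance = 1e-12)
  }
})

test_that("L1 ring inhibition follows the distance-decay weighting", {
  p <- params_m11()
  set.seed(3)
  s <- setNames(runif(20, 0, 0.1), names(network_state()))
  s[19:20] <- 0 # no motor feedback
  s[17:18] <- 0 # no AIP terms
  x <- s[1:6]
  inhib <- p$eta_lip * (x[4] + x[2]) +
    p$eta_lip_decay1 * p$eta_lip * (x[5] + x[3]) +
    p$eta_lip_decay1 * p$eta_lip_decay2 * p$eta_lip * x[6]
  I_expected <- p$alpha_lip * x[1] - inhib + s[7]
  d <- lca_drift(s, p, cond_cong4, t = 0)
  expect_equal(
    unname(d$drift[["x_lip_L1"]]),
    (phi(unname(I_expected)) - unname(x[1])) / p$tau_lip
  )
})

test_that("with zero weights and inputs, IT/AIP/motor reduce to pure decay", {
  p <- update_params(params_m11(),
    eta_maipit = 0, w_itaip = 0, w_lipaip = 0, w_aipm = 0,
    beta_maip = 0, beta_mitlip = 0, s_ori = 0
  )
  set.seed(4)
  s <- setNames(runif(20, 0, 0.1), names(network_state()))
  s[15:16] <- 0 # IT inputs at rest
  d <- lca_drift(s, p, cond_cong4, t = 0)$drift
  expect_equal(unname(d[["x_aip_L"]]), -p$k_aip * unname(s[17]) / p$tau_aip)
  expect_equal(unname(d[["x_m_R"]]), -p$k_m * unname(s[20]) / p$tau_m)
  # IT decays toward its phi fixed point phi(0) when all coupling is off
  expect_equal(
    unname(d[["x_it_E_left"]]),
    (phi(0) - unname(s[13])) / p$tau_it
  )
})

test_that("compiled drift agrees with the R reference implementation", {
  p <- params_m11()
  opts <- covertsearch:::engine_opts(p)
  set.seed(5)
  for (rep in 1:8) {
    s <- setNames(runif(20, 0, 0.3), names(network_state()))
    cond <- trial_condition(
      sample(c(2, 4, 6), 1), "R1",
      sample(c("E_left", "E_right"), 1)
    )
    cc <- covertsearch:::condition_codes(cond)
    t <- runif(1, 0, 500)
    ref <- lca_drift(s, p, cond, t)
    cpp <- covertsearch:::cs_drift(
      unname(s), covertsearch:::param_vector(p),
      cc$set_size, cc$pos, cc$ori, t, opts
    )
    expect_equal(cpp$drift, unname(ref$drift), tolerance = 1e-12)
    expect_equal(cpp$noise, unname(ref$noise), tolerance = 1e-12)
  }
})

test_that("network state has exactly 20 variables", {
  expect_length(network_state(), 20)
})
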