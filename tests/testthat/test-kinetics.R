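test_that("ODE translation has one rate per non-pseudo edge", {
  sys <- preset_system("branched_endo_medium")
  model <- graph_to_ode(sys$graph)
  n_pseudo_edges <- sum(sys$graph$edges$kind == "pseudo")
  expect_identical(nrow(model$reactions),
                   nrow(sys$graph$edges) - n_pseudo_edges)
  expect_setequal(model$states, real_nodes(sys$graph)$id)
  # endo reactions feed both fragments from the same substrate
  endo <- model$reactions[model$reactions$kind == "endo", ]
  expect_true(all(!is.na(endo$target2)))
})

test_that("rate matrix balances exo flux and duplicates endo flux", {
  g <- degradation_graph("GAVLK")
  g <- add_endo_reaction(g, "GAVLK", 2L)$graph
  model <- graph_to_ode(g)
  k <- stats::setNames(0.4, model$reactions$param)
  A <- rate_matrix(model, k)
  expect_equal(A["GAVLK", "GAVLK"], -0.4)
  expect_equal(A["GA", "GAVLK"], 0.4)
  expect_equal(A["VLK", "GAVLK"], 0.4)
  expect_equal(sum(A[, "GAVLK"]), 0.4)  # one molecule becomes two
})

test_that("single-step decay matches the closed form", {
  g <- degradation_graph("GAVLK")
  res <- add_exo_reaction(g, "GAVLK", "AVLK")
  model <- graph_to_ode(res$graph)
  rates <- stats::setNames(0.5, res$edge_id)
  traj <- integrate_kinetics(model, rates, x0 = 1, times = c(1, 2.5, 5))
  expect_equal(traj$x[, "GAVLK"], exp(-0.5 * c(1, 2.5, 5)),
               tolerance = 1e-9)
  expect_equal(traj$x[, "AVLK"], 1 - exp(-0.5 * c(1, 2.5, 5)),
               tolerance = 1e-9)
  expect_equal(unname(traj$x[3, "GAVLK"]), exp(-2.5), tolerance = 1e-9)
})

test_that("three-step chain reproduces the Bateman closed form", {
  sys <- preset_system("fpa_chain")
  model <- graph_to_ode(sys$graph)
  k <- c(1.2, 0.6, 0.3)   # ordered along the chain
  times <- sample_times("study1")
  traj <- integrate_kinetics(model, sys$rates, x0 = 1, times = times)
  # independent oracle: explicit Bateman cascade for distinct rates
  bateman <- function(kvec, t) {
    n <- length(kvec)
    x <- matrix(0, length(t), n + 1)
    x[, 1] <- exp(-kvec[1] * t)
    for (m in 2:(n + 1)) {
      ## rates seen by species m: the production chain k_1..k_{m-1} plus
      ## its own loss rate (0 for the terminal product)
      km <- c(kvec, 0)[seq_len(m)]
      coef <- prod(kvec[seq_len(m - 1)])
      xm <- 0
      for (i in seq_len(m)) {
        denom <- prod(km[setdiff(seq_len(m), i)] - km[i])
        xm <- xm + exp(-km[i] * t) / denom
      }
      x[, m] <- coef * xm
    }
    x
  }
  chain <- c("DSGEGDFLAEGGGVR", "SGEGDFLAEGGGVR", "GEGDFLAEGGGVR",
             "EGDFLAEGGGVR")
  expect_lt(max(abs(traj$x[, chain] - bateman(k, times))), 1e-6)
})

test_that("all-zero rates freeze the system", {
  sys <- tiny_chain()
  model <- graph_to_ode(sys$graph)
  rates <- stats::setNames(rep(0, nrow(model$reactions)),
                           model$reactions$param)
  traj <- integrate_kinetics(model, rates, x0 = 3, times = 1:5)
  expect_equal(unname(traj$x[, model$seed]), rep(3, 5))
  expect_true(all(traj$x[, setdiff(model$states, model$seed)] == 0))
})

test_that("exo-only systems conserve total concentration", {
  sys <- preset_system("fpa_chain")
  model <- graph_to_ode(sys$graph)
  traj <- integrate_kinetics(model, sys$rates, x0 = 7,
                             times = sample_times("study1"))
  expect_equal(rowSums(traj$x), rep(7, length(traj$times)),
               tolerance = 1e-8)
})

test_that("one endo cut doubles molecules at the documented pace", {
  g <- degradation_graph("GAVLK")
  res <- add_endo_reaction(g, "GAVLK", 2L)
  model <- graph_to_ode(res$graph)
  k <- 0.6
  rates <- stats::setNames(k, reaction_edges(res$graph)$id)
  times <- c(0.5, 1, 2, 4)
  traj <- integrate_kinetics(model, rates, x0 = 1, times = times)
  expect_equal(rowSums(traj$x), 1 + (1 - exp(-k * times)),
               tolerance = 1e-8)
  # terminal endo siblings track each other exactly
  expect_equal(traj$x[, "GA"], traj$x[, "VLK"], tolerance = 1e-10)
})

test_that("seed concentration never increases", {
  sys <- preset_system("branched_endo_large")
  model <- graph_to_ode(sys$graph)
  traj <- integrate_kinetics(model, sys$rates, x0 = 10,
                             times = seq(0.1, 5, by = 0.1))
  expect_true(all(diff(traj$x[, model$seed]) <= 1e-12))
})

test_that("matrix-exponential and generic ODE paths agree to 1e-8", {
  for (name in c("fpa_chain", "branched_endo_medium")) {
    sys <- preset_system(name)
    model <- graph_to_ode(sys$graph)
    times <- sample_times("study1")
    t_auto <- integrate_kinetics(model, sys$rates, 10, times, "auto")
    t_expm <- integrate_kinetics(model, sys$rates, 10, times, "expm")
    t_ode <- integrate_kinetics(model, sys$rates, 10, times, "ode",
                                rtol = 1e-10)
    expect_lt(max(abs(t_auto$x - t_expm$x)), 1e-8)
    expect_lt(max(abs(t_auto$x - t_ode$x)), 1e-6 * 10)
  }
})

test_that("repeated-rate chains (defective systems) still integrate correctly", {
  sys <- tiny_chain(k1 = 0.5, k2 = 0.5)   # equal rates: defective matrix
  model <- graph_to_ode(sys$graph)
  times <- c(0.5, 1, 2)
  traj <- integrate_kinetics(model, sys$rates, 1, times)
  # closed form for equal-rate two-step chain: x2 = k t e^{-kt}
  expect_equal(unname(traj$x[, "AVLK"]), 0.5 * times * exp(-0.5 * times),
               tolerance = 1e-8)
})

test_that("concentration-to-intensity transformation is the documented linear map", {
  g <- degradation_graph("GAVLK")
  res <- add_exo_reaction(g, "GAVLK", "AVLK")
  model <- graph_to_ode(res$graph)
  traj <- structure(list(times = 1:2,
                         x = matrix(c(0.5, 0.25, 0.1, 0.2), 2, 2,
                                    dimnames = list(NULL, model$states))),
                    class = "concentration_trajectory")
  # no isobars here: every group holds exactly one peptide
  c_p <- stats::setNames(c(2, 1), model$states)
  P <- predict_intensities(traj, model, c_p)
  for (g in seq_along(model$groups$members)) {
    mem <- model$groups$members[[g]]
    expect_equal(unname(P[g, ]), unname(c_p[mem] * traj$x[, mem]))
  }
  # identity when all factors are 1
  P1 <- predict_intensities(traj, model, 1)
  expect_equal(sort(unname(P1[, 1])), sort(unname(traj$x[1, ])))
  expect_error(predict_intensities(traj, model,
                                   stats::setNames(c(-1, 1), model$states)),
               "> 0")
})

test_that("isobaric groups pool member intensities linearly", {
  g <- degradation_graph("IHPFHL")
  g <- add_exo_reaction(g, "IHPFHL", "IHPFH")$graph
  g <- add_exo_reaction(g, "IHPFHL", "HPFHL")$graph
  model <- graph_to_ode(g, group_tolerance = 0.01)
  iso <- which(vapply(model$groups$members, length, integer(1)) == 2L)
  expect_length(iso, 1L)
  mem <- model$groups$members[[iso]]
  x <- matrix(c(0.2, 0.1, 0.3), 1, 3,
              dimnames = list(NULL, model$states))
  traj <- structure(list(times = 1, x = x),
                    class = "concentration_trajectory")
  c_p <- stats::setNames(c(1, 3, 1), c(mem, setdiff(model$states, mem)))
  P <- predict_intensities(traj, model, c_p)
  expect_equal(unname(P[iso, 1]),
               sum(c(1, 3) * x[1, mem]))
})
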