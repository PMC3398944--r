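#' Options for kinetic parameter estimation
#'
#' @param weighting `"relative"` (default) weights each squared residual by
#'   `1 / max(I_obs, epsilon)^2` so that traces on different intensity
#'   scales contribute comparably; `"absolute"` uses unit weights.
#' @param epsilon_frac Relative-weight floor as a fraction of the maximum
#'   observed intensity (guards against division by tiny observations).
#' @param r_primary Initial rate (1/h) for the reaction on each node's
#'   shortest path to the root.
#' @param r_secondary Initial rate (1/h) for all other incoming reactions.
#' @param c_init Initial transformation factor.
#' @param max_iterations Levenberg-Marquardt iteration cap.
#' @param ftol,ptol Convergence tolerances passed to the optimizer.
#' @param x0_fixed If non-`NULL`, the seed initial concentration is pinned
#'   to this value instead of being estimated (this also fixes the scale
#'   gauge of the `c_p * x` transformation; with `x0` free the fit
#'   reports the gauge representative with `mean(c_p) = 1`).
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(weighting = c("relative", "absolute"),
                        epsilon_frac = 1e-6, r_primary = 1.0,
                        r_secondary = 0.01, c_init = 1.0,
                        max_iterations = 100L, ftol = 1e-10, ptol = 1e-10,
                        x0_fixed = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(epsilon_frac > 0, r_primary > r_secondary, r_secondary > 0,
            c_init > 0)
  structure(list(weighting = weighting, epsilon_frac = epsilon_frac,
                 r_primary = r_primary, r_secondary = r_secondary,
                 c_init = c_init, max_iterations = as.integer(max_iterations),
                 ftol = ftol, ptol = ptol, x0_fixed = x0_fixed),
            class = "fit_options")
}

#' Initial parameter values for the kinetic fit
#'
#' For every non-root peptide the incoming reaction that lies on a shortest
#' path (counted in reactions; the pseudo-node hop of an endo reaction is
#' part of that one reaction) to the root receives `r_primary`; all other
#' incoming reactions receive `r_secondary`. Primary-path reactions
#' dominate the early dynamics, which is what makes this a useful starting
#' point when nothing is known about the system. Ties between equally
#' short paths are broken lexicographically by reaction id, so the result
#' is deterministic. All transformation factors start at `c_init`.
#'
#' @param graph A `degradation_graph`.
#' @param options A `fit_options` object.
#' @return List with `rates` (named by reaction edge id) and `c_p` (named
#'   by peptide node id).
#' @export
initial_values <- function(graph, options = fit_options()) {
  model <- graph_to_ode(graph)
  rx <- model$reactions
  depth <- stats::setNames(rep(Inf, length(model$states)), model$states)
  depth[model$seed] <- 0
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(rx))) {
      d <- depth[rx$source[i]] + 1
      for (tgt in stats::na.omit(c(rx$target1[i], rx$target2[i]))) {
        if (d < depth[tgt]) {
          depth[tgt] <- d
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  rates <- stats::setNames(rep(options$r_secondary, nrow(rx)), rx$param)
  for (v in setdiff(model$states, model$seed)) {
    inc <- rx[rx$target1 == v | (!is.na(rx$target2) & rx$target2 == v), ,
              drop = FALSE]
    if (nrow(inc) == 0L) next
    pd <- depth[inc$source] + 1
    best <- inc$param[pd == min(pd)]
    rates[sort(best)[1L]] <- options$r_primary
  }
  list(rates = rates,
       c_p = stats::setNames(rep(options$c_init, length(model$states)),
                             model$states))
}

## Map model states onto rows of an observed intensity matrix: by sequence
## membership first, then by nearest mass within the matrix's tolerance.
.map_states <- function(model, observed) {
  row_of_seq <- new.env(parent = emptyenv())
  for (r in seq_along(observed$sequences)) {
    for (s in observed$sequences[[r]]) row_of_seq[[s]] <- r
  }
  vapply(model$states, function(s) {
    if (!is.null(row_of_seq[[s]])) return(row_of_seq[[s]])
    m <- compute_mass(s)
    d <- abs(observed$mass - m)
    r <- which.min(d)
    if (d[r] <= observed$tolerance) r else NA_integer_
  }, integer(1))
}

.weight_matrix <- function(observed, options) {
  vmax <- suppressWarnings(max(observed$values, na.rm = TRUE))
  if (!is.finite(vmax) || vmax <= 0) vmax <- 1
  if (options$weighting == "absolute") {
    w <- matrix(1, nrow(observed$values), ncol(observed$values))
  } else {
    eps <- options$epsilon_frac * vmax
    w <- 1 / pmax(observed$values, eps)^2
  }
  w[is.na(observed$values)] <- 0
  w
}

.predict_rows <- function(model, mapping, rates, c_p, x0, times,
                          n_rows) {
  traj <- integrate_kinetics(model, rates, x0, times)
  P <- matrix(NA_real_, n_rows, length(times))
  for (r in unique(mapping[!is.na(mapping)])) {
    mem <- model$states[!is.na(mapping) & mapping == r]
    P[r, ] <- as.numeric(traj$x[, mem, drop = FALSE] %*% c_p[mem])
  }
  P
}

#' Weighted least-squares objective of a parameter set
#'
#' `E = sum_m sum_j w(m, t_j) * (I_obs(m, t_j) - I_model(m, t_j))^2` over
#' all observed (non-missing) points of masses explained by the model;
#' missing observations contribute no term.
#'
#' @param model A `kinetic_model`.
#' @param rates Named rate vector.
#' @param c_p Named transformation-factor vector.
#' @param x0 Seed initial concentration.
#' @param observed An `intensity_matrix`.
#' @param options A `fit_options` object (controls the weighting).
#' @return The scalar objective E >= 0.
#' @export
objective_value <- function(model, rates, c_p, x0, observed,
                            options = fit_options()) {
  if (length(observed$times) != ncol(observed$values)) {
    stop("observed matrix dimensions inconsistent", call. = FALSE)
  }
  mapping <- .map_states(model, observed)
  W <- .weight_matrix(observed, options)
  P <- .predict_rows(model, mapping, rates, c_p, x0, observed$times,
                     nrow(observed$values))
  D <- observed$values - P
  idx <- !is.na(D) & W > 0 &
    row(D) %in% unique(mapping[!is.na(mapping)])
  sum(W[idx] * D[idx]^2)
}

#' Fit reaction rates, transformation factors and seed concentration
#'
#' Bounded Levenberg-Marquardt minimization of the weighted least-squares
#' objective, started from the [initial_values()] scheme. Because the
#' predicted intensities are linear in the transformation factors, the
#' fit uses variable projection: for every candidate rate vector the
#' optimal `c_p` of each observed mass group is solved in closed form by
#' weighted linear least squares (clipped to stay positive), and the
#' Levenberg-Marquardt iteration runs over the rates alone. This keeps
#' the search space small and removes the flat gauge direction
#' `(c_p / a, a * x0)` from the nonlinear step. Rates are bounded below
#' by 0. When `x0` is estimated (the default) the gauge is fixed by
#' reporting the solution with `mean(c_p) = 1`; pinning
#' `options$x0_fixed` reports factors on that scale instead. Optional
#' multi-start draws extra rate starting points from a seeded RNG and
#' keeps the best final objective. Non-convergence never raises: the
#' best parameters found so far are returned with `converged = FALSE`.
#'
#' @param graph A `degradation_graph` (the model structure to fit).
#' @param observed An `intensity_matrix` of observed traces (typically from
#'   [build_graph()] or the simulator).
#' @param options A `fit_options` object.
#' @param n_starts Number of optimizer starts (1 = deterministic scheme
#'   start only).
#' @param seed RNG seed for the extra starts (required if `n_starts > 1`).
#' @return Object of class `kinetic_fit`: rates, `c_p`, `x0`, `objective`
#'   (weighted SSE over data terms), `predicted` (matrix aligned with
#'   `observed$values`), `residuals`, `explained_rows`, `converged`,
#'   `status`, plus the model, mapping and options used.
#' @export
fit_kinetics <- function(graph, observed, options = fit_options(),
                         n_starts = 1L, seed = NULL) {
  model <- graph_to_ode(graph, group_tolerance = observed$tolerance)
  mapping <- .map_states(model, observed)
  W <- .weight_matrix(observed, options)
  sqw <- sqrt(W)
  obs <- observed$values
  times <- observed$times
  n_rows <- nrow(obs)
  explained <- sort(unique(mapping[!is.na(mapping)]))
  ## only masses the model explains contribute residual terms
  data_idx <- which(!is.na(obs) & W > 0 &
                      row(obs) %in% explained)

  init <- initial_values(graph, options)
  free_x0 <- is.null(options$x0_fixed)
  x0_internal <- if (free_x0) 1 else options$x0_fixed
  c_lb <- 1e-8

  obs_max <- suppressWarnings(max(obs, na.rm = TRUE))
  degenerate <- length(data_idx) == 0L || !is.finite(obs_max) ||
    obs_max <= 0

  ## rows explained by the model, with their member states (columns of the
  ## trajectory) resolved once
  row_members <- lapply(explained, function(r) {
    model$states[!is.na(mapping) & mapping == r]
  })
  names(row_members) <- as.character(explained)

  ## per-row constants of the variable-projection step, resolved once
  state_col <- stats::setNames(seq_along(model$states), model$states)
  row_pre <- lapply(seq_along(explained), function(rr) {
    r <- explained[rr]
    w <- W[r, ]
    o <- obs[r, ]
    use <- which(!is.na(o) & w > 0)
    list(mem = unname(state_col[row_members[[rr]]]), use = use,
         w = w[use], o = o[use], wo = w[use] * o[use])
  })

  ## variable projection: for a given trajectory, the weighted LS optimum
  ## of each group's transformation factors has a closed form (solved per
  ## row, clipped to stay positive); returns the stacked weighted
  ## residual vector and the per-state factors
  project_c <- function(X) {
    c_fit <- stats::setNames(rep(options$c_init, length(model$states)),
                             model$states)
    res <- vector("list", length(row_pre))
    for (rr in seq_along(row_pre)) {
      pre <- row_pre[[rr]]
      m <- length(pre$mem)
      if (length(pre$use) == 0L) {
        res[[rr]] <- numeric(0)
        next
      }
      G <- X[pre$use, pre$mem, drop = FALSE]
      if (m == 1L) {
        g <- G[, 1L]
        denom <- sum(pre$w * g * g)
        cc <- if (denom > 0) max(sum(pre$wo * g) / denom, c_lb)
              else options$c_init
      } else {
        Gw <- G * pre$w
        Amat <- crossprod(G, Gw)
        b <- crossprod(Gw, pre$o)
        diag(Amat) <- diag(Amat) + 1e-12
        sol <- tryCatch(solve(Amat, b), error = function(e) NULL)
        if (is.null(sol)) {
          cc <- rep(options$c_init, m)
        } else {
          cc <- pmax(as.numeric(sol), c_lb)
          ## one re-solve with clipped coordinates pinned keeps the rest
          ## optimal when the unconstrained optimum went negative
          low <- as.numeric(sol) < c_lb
          if (any(low) && !all(low)) {
            b2 <- b - Amat[, low, drop = FALSE] %*% rep(c_lb, sum(low))
            sol2 <- tryCatch(
              solve(Amat[!low, !low, drop = FALSE], b2[!low]),
              error = function(e) NULL)
            if (!is.null(sol2)) cc[!low] <- pmax(as.numeric(sol2), c_lb)
          }
        }
      }
      c_fit[pre$mem] <- cc
      pred <- as.numeric(G %*% cc)
      res[[rr]] <- sqrt(pre$w) * (pre$o - pred)
    }
    list(c_fit = c_fit, resid = unlist(res, use.names = FALSE))
  }
  traj_x <- function(k) {
    A <- rate_matrix(model, pmax(k, 0))
    x0v <- .expand_x0(model, x0_internal)
    .solve_linear(A, x0v, times)
  }
  eval_k <- function(k) project_c(traj_x(k))
  resid_fun <- function(k) {
    r <- eval_k(k)$resid
    r[!is.finite(r)] <- 1e6
    r
  }
  sse_of <- function(k) sum(resid_fun(k)^2)
  predict_rows_of <- function(k, c_fit) {
    X <- traj_x(k)
    P <- matrix(NA_real_, n_rows, length(times))
    for (rr in seq_along(row_pre)) {
      pre <- row_pre[[rr]]
      P[explained[rr], ] <- as.numeric(
        X[, pre$mem, drop = FALSE] %*% c_fit[pre$mem])
    }
    P
  }

  k0 <- init$rates
  if (degenerate) {
    sc <- eval_k(k0)
    P <- predict_rows_of(k0, sc$c_fit)
    return(structure(list(
      rates = k0, c_p = sc$c_fit, x0 = x0_internal, objective = 0,
      predicted = P, residuals = obs - P,
      explained_rows = explained, converged = FALSE,
      status = "non-identifiable: no usable signal", niter = 0L,
      model = model, mapping = mapping, options = options
    ), class = "kinetic_fit"))
  }

  starts <- list(k0)
  if (n_starts > 1L) {
    if (is.null(seed)) {
      stop("multi-start fitting needs an RNG seed", call. = FALSE)
    }
    rng <- .seeded_rng(seed)
    for (i in seq_len(n_starts - 1L)) {
      starts[[i + 1L]] <- k0 * exp(rng$rnorm(length(k0), sd = 0.5))
    }
  }

  best <- NULL
  for (kstart in starts) {
    res <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(
        par = kstart, lower = rep(0, length(kstart)), fn = resid_fun,
        control = minpack.lm::nls.lm.control(
          maxiter = options$max_iterations, ftol = options$ftol,
          ptol = options$ptol))),
      error = function(e) NULL)
    if (is.null(res)) next
    sse <- sse_of(res$par)
    if (is.null(best) || sse < best$sse) {
      best <- list(par = res$par, sse = sse, info = res$info,
                   message = res$message, niter = res$niter)
    }
  }

  init_sse <- sse_of(k0)
  if (is.null(best) || best$sse > init_sse + 1e-12) {
    ## the optimizer must never return something worse than its start
    best <- list(par = k0, sse = init_sse, info = 0L,
                 message = "kept initial values", niter = 0L)
  }

  k_hat <- stats::setNames(pmax(best$par, 0), names(k0))
  sc <- eval_k(k_hat)
  P <- predict_rows_of(k_hat, sc$c_fit)
  ## fix the scale gauge: with x0 free, report the representative with
  ## mean transformation factor 1
  if (free_x0) {
    mapped_states <- unlist(row_members, use.names = FALSE)
    x0_hat <- mean(sc$c_fit[mapped_states])
    if (!is.finite(x0_hat) || x0_hat <= 0) x0_hat <- 1
    c_hat <- sc$c_fit / x0_hat
  } else {
    x0_hat <- options$x0_fixed
    c_hat <- sc$c_fit
  }
  converged <- best$info %in% c(1L, 2L, 3L, 4L)
  structure(list(
    rates = k_hat, c_p = c_hat, x0 = x0_hat, objective = best$sse,
    predicted = P, residuals = obs - P,
    explained_rows = explained, converged = converged,
    status = if (converged) "converged"
             else paste0("not converged: ", best$message),
    niter = best$niter, model = model, mapping = mapping,
    options = options
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("kinetic fit: %d rate(s), E = %.6g (%s, %d iterations)\n",
              length(x$rates), x$objective, x$status, x$niter))
  cat(sprintf("x0 = %.6g\n", x$x0))
  invisible(x)
}
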