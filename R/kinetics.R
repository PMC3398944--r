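#' Derive the first-order kinetic model of a degradation graph
#'
#' Every proteolytic reaction is modelled as a first-order mass-action
#' reaction in the degraded peptide: an exo reaction u -> v with rate k
#' contributes -k*[u] to d[u]/dt and +k*[u] to d[v]/dt; an endo reaction
#' u -> (v, w) with rate k contributes -k*[u] to d[u]/dt and +k*[u] to both
#' products. The seed has a fixed starting concentration and no production
#' term (ex-vivo setting); saturation effects are neglected. The resulting
#' system is linear with constant coefficients, `dx/dt = A(k) x`.
#'
#' @param graph A validated `degradation_graph`.
#' @param group_tolerance Isobaric grouping tolerance used for the
#'   concentration-to-intensity transformation (Da).
#' @return Object of class `kinetic_model`: list with `states` (real node
#'   ids in topological order), `reactions` (data frame: `param`, `source`,
#'   `target1`, `target2`), `groups` (an `isobaric_groups` partition) and
#'   `seed` (the root state). The number of rate parameters equals the
#'   number of edges minus the number of pseudo-edges.
#' @export
graph_to_ode <- function(graph, group_tolerance = 0.1) {
  validate_graph(graph)
  states <- intersect(topological_order(graph),
                      real_nodes(graph)$id)
  re <- reaction_edges(graph)
  target1 <- character(nrow(re))
  target2 <- rep(NA_character_, nrow(re))
  for (i in seq_len(nrow(re))) {
    if (re$kind[i] == "endo") {
      kids <- graph$edges$target[graph$edges$source == re$target[i] &
                                   graph$edges$kind == "pseudo"]
      kids <- sort(unique(kids))
      target1[i] <- kids[1L]
      target2[i] <- if (length(kids) > 1L) kids[2L] else kids[1L]
    } else {
      target1[i] <- re$target[i]
    }
  }
  reactions <- data.frame(param = re$id, source = re$source,
                          kind = re$kind, target1 = target1,
                          target2 = target2, stringsAsFactors = FALSE)
  reactions <- reactions[order(reactions$param), , drop = FALSE]
  rownames(reactions) <- NULL
  state_idx <- stats::setNames(seq_along(states), states)
  structure(list(states = states, reactions = reactions,
                 groups = isobaric_groups(graph, group_tolerance),
                 seed = graph$root,
                 ## integer index images of the reaction table for fast
                 ## assembly of the rate matrix in the fitting hot path
                 rx_src = unname(state_idx[reactions$source]),
                 rx_tgt1 = unname(state_idx[reactions$target1]),
                 rx_tgt2 = ifelse(is.na(reactions$target2), NA_integer_,
                                  unname(state_idx[reactions$target2]))),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("kinetic model: %d state(s), %d rate parameter(s), %d mass group(s)\n",
              length(x$states), nrow(x$reactions), length(x$groups$mass)))
  invisible(x)
}

#' Rate matrix A(k) of a kinetic model
#'
#' @param model A `kinetic_model`.
#' @param rates Named numeric vector of non-negative rates; names are the
#'   reaction parameter ids (`model$reactions$param`).
#' @return The system matrix A with `dx/dt = A x`, states ordered as
#'   `model$states`.
#' @export
rate_matrix <- function(model, rates) {
  ns <- length(model$states)
  A <- matrix(0, ns, ns, dimnames = list(model$states, model$states))
  k <- rates[model$reactions$param]
  if (anyNA(k)) {
    stop(sprintf("missing rate for reaction '%s'",
                 model$reactions$param[which(is.na(k))[1L]]),
         call. = FALSE)
  }
  for (i in seq_along(k)) {
    s <- model$rx_src[i]
    A[s, s] <- A[s, s] - k[i]
    A[model$rx_tgt1[i], s] <- A[model$rx_tgt1[i], s] + k[i]
    if (!is.na(model$rx_tgt2[i])) {
      A[model$rx_tgt2[i], s] <- A[model$rx_tgt2[i], s] + k[i]
    }
  }
  A
}

#' Dump a kinetic model as JSON
#'
#' @param model A `kinetic_model`.
#' @param path Output path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_model_json <- function(model, path = NULL) {
  obj <- list(states = model$states, seed = model$seed,
              reactions = model$reactions,
              groups = list(mass = model$groups$mass,
                            members = model$groups$members))
  txt <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                          digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

.expand_x0 <- function(model, x0) {
  if (length(x0) == 1L && !(names(x0) %||% "") %in% model$states) {
    x <- stats::setNames(numeric(length(model$states)), model$states)
    x[model$seed] <- x0
    return(x)
  }
  x <- stats::setNames(numeric(length(model$states)), model$states)
  x[names(x0)] <- x0
  x
}

#' Integrate the kinetic model
#'
#' Solves `dx/dt = A(k) x` from `t = 0` and returns the concentrations at
#' the requested times. Because the system is linear with constant
#' coefficients, the default path uses the eigendecomposition of A
#' (the DAG structure makes A triangular in topological order); when A is
#' defective (repeated loss rates) the matrix exponential is used, and a
#' generic stiff ODE solver (`deSolve::lsoda`) is available as an
#' independent cross-check.
#'
#' @param model A `kinetic_model`.
#' @param rates Named non-negative rate vector.
#' @param x0 Initial concentrations: a single number (seed concentration,
#'   all products start at 0) or a named vector over states.
#' @param times Strictly increasing evaluation times (hours); need not
#'   include 0.
#' @param method `"auto"` (eigendecomposition with matrix-exponential
#'   fallback), `"expm"`, or `"ode"`.
#' @param rtol Relative tolerance for the `"ode"` method.
#' @return Object of class `concentration_trajectory`: list with `times`
#'   and `x` (times x states matrix).
#' @export
integrate_kinetics <- function(model, rates, x0, times,
                               method = c("auto", "expm", "ode"),
                               rtol = 1e-8) {
  method <- match.arg(method)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  A <- rate_matrix(model, rates)
  x0v <- .expand_x0(model, x0)
  X <- switch(method,
    auto = .solve_linear(A, x0v, times),
    expm = .solve_expm(A, x0v, times),
    ode = .solve_ode(A, x0v, times, rtol)
  )
  colnames(X) <- model$states
  structure(list(times = times, x = X),
            class = "concentration_trajectory")
}

.solve_linear <- function(A, x0, times) {
  ev <- tryCatch(eigen(A), error = function(e) NULL)
  ok <- !is.null(ev) && all(abs(Im(ev$values)) < 1e-12)
  if (ok) {
    vals <- Re(ev$values)
    V <- Re(ev$vectors)
    ## repeated eigenvalues are fine as long as A is diagonalizable
    ## (e.g. several terminal states all have eigenvalue 0); a defective
    ## A shows up as a numerically singular eigenvector matrix
    if (rcond(V) > 1e-7) {
      coef <- solve(V, x0)
      E <- exp(outer(times, vals))       # times x modes
      return(tcrossprod(sweep(E, 2L, coef, `*`), V))
    }
  }
  .solve_expm(A, x0, times)
}

## Stepwise propagation x(t_{j+1}) = expm(A dt_j) x(t_j), caching the
## matrix exponential per distinct step width (sampling schemes typically
## use very few), exact for a constant-coefficient linear system.
.solve_expm <- function(A, x0, times) {
  dts <- diff(c(0, times))
  keys <- as.character(signif(dts, 12))
  cache <- new.env(parent = emptyenv())
  X <- matrix(0, length(times), length(x0))
  x <- x0
  for (j in seq_along(times)) {
    key <- keys[j]
    if (is.null(cache[[key]])) {
      cache[[key]] <- as.matrix(Matrix::expm(A * dts[j]))
    }
    x <- as.numeric(cache[[key]] %*% x)
    X[j, ] <- x
  }
  X
}

.solve_ode <- function(A, x0, times, rtol) {
  has0 <- length(times) > 0 && abs(times[1L]) < 1e-15
  tt <- if (has0) times else c(0, times)
  sol <- deSolve::lsoda(
    y = x0, times = tt,
    func = function(t, y, parms) list(as.numeric(A %*% y)),
    rtol = rtol, atol = rtol * max(abs(x0), 1) * 1e-2)
  if (attr(sol, "istate")[1L] < 0) {
    stop(sprintf(
      "ODE solver failed (istate=%d); rates=[%s]",
      attr(sol, "istate")[1L],
      paste(signif(diag(A), 3), collapse = ", ")), call. = FALSE)
  }
  out <- unname(sol[, -1L, drop = FALSE])
  if (!has0) out <- out[-1L, , drop = FALSE]
  out
}

#' Transform concentrations into predicted spectrum intensities
#'
#' Assumes the standard linear intensity-concentration relationship: the
#' predicted intensity of a mass group is the linear combination of its
#' member peptide concentrations weighted by the per-peptide
#' transformation factors, `I(m, t) = sum_p c_p * x_p(t)`.
#'
#' @param trajectory A `concentration_trajectory`.
#' @param model The `kinetic_model` that produced it.
#' @param c_p Named vector of positive transformation factors (one per
#'   state); a single number is recycled.
#' @return Matrix of predicted intensities, mass groups x times, with the
#'   group representative masses as rownames.
#' @export
predict_intensities <- function(trajectory, model, c_p = 1) {
  if (length(c_p) == 1L && is.null(names(c_p))) {
    c_p <- stats::setNames(rep(c_p, length(model$states)), model$states)
  }
  if (!all(model$states %in% names(c_p))) {
    stop("c_p must provide a factor for every state", call. = FALSE)
  }
  if (any(c_p[model$states] <= 0)) {
    stop("transformation factors must be > 0", call. = FALSE)
  }
  nt <- length(trajectory$times)
  res <- vapply(model$groups$members, function(mem) {
    as.numeric(trajectory$x[, mem, drop = FALSE] %*% c_p[mem])
  }, numeric(nt))
  out <- if (nt == 1L) matrix(res, ncol = 1L) else t(res)
  rownames(out) <- sprintf("m%.4f", model$groups$mass)
  out
}
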