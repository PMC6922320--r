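#' Mean absolute log10 error between two relative-abundance profiles
#'
#' The fitting objective: the mean over species of
#' `|log10(max(p, floor)) - log10(max(m, floor))|`. The floor keeps species
#' predicted at exactly zero (unreachable from any intake) from producing an
#' infinite error.
#'
#' @param predicted,observed named numeric vectors over the same species
#'   key set.
#' @param floor positive lower bound applied before taking logs.
#' @return non-negative scalar.
#' @export
abundance_log_error <- function(predicted, observed, floor = 1e-6) {
  stopifnot(floor > 0)
  if (!length(observed)) stop("empty species set")
  if (is.null(names(predicted)) || is.null(names(observed)) ||
      !setequal(names(predicted), names(observed))) {
    stop("predicted and observed must be named over the same species set")
  }
  p <- predicted[names(observed)]
  mean(abs(log10(pmax(p, floor)) - log10(pmax(observed, floor))))
}

# Residual vector and analytic Jacobian of the log10 abundance error for a
# linear biomass response Rb: p = Rb c / sum(Rb c). Floored components have a
# zero Jacobian row (the objective is locally flat there).
log_residual_fun <- function(Rb, log_m, floor) {
  csum <- colSums(Rb)
  function(x) {
    B <- drop(Rb %*% x)
    s <- sum(B)
    p <- if (s > 0) B / s else B
    log10(pmax(p, floor)) - log_m
  }
}

log_jacobian_fun <- function(Rb, floor) {
  csum <- colSums(Rb)
  function(x) {
    B <- drop(Rb %*% x)
    s <- sum(B)
    p <- if (s > 0) B / s else B
    J <- matrix(0, nrow(Rb), ncol(Rb))
    act <- p > floor & B > 0
    if (any(act) && s > 0) {
      J[act, ] <- (Rb[act, , drop = FALSE] / B[act] -
                     matrix(csum / s, sum(act), ncol(Rb), byrow = TRUE)) /
        log(10)
    }
    J
  }
}

#' Infer the nutrient intake that best explains observed abundances
#'
#' Fits the per-sample intake vector over a configured list of candidate
#' intake metabolites by bounded (non-negative) nonlinear least squares on
#' the per-species log10 abundance residuals, using Levenberg-Marquardt
#' (`minpack.lm::nls.lm`, the analog of MATLAB's `lsqnonlin`). Each restart
#' starts from amounts drawn uniformly on (0, 1) and normalized to sum 1;
#' the best restart is kept. Because predicted relative profiles are
#' invariant under rescaling of the intake, the fitted vector is
#' renormalized onto the simplex.
#'
#' Observed species that do not resolve in the network must be removed (and
#' abundances renormalized) before calling, e.g. via [map_taxa()].
#'
#' @param net a `cross_feeding_network`.
#' @param sample a `community_sample`.
#' @param params a `flow_parameters` object (fixed f and level count).
#' @param intake_metabolites character vector of candidate intake
#'   metabolite ids.
#' @param n_restarts number of random restarts (default 10).
#' @param seed integer RNG seed; refits with the same seed are
#'   bit-reproducible.
#' @param floor log floor shared with [abundance_log_error()].
#' @param tol `ftol` passed to the optimizer.
#' @param max_iter maximum optimizer iterations per restart.
#' @return object of class `intake_fit`: `intake` (named simplex vector),
#'   `objective` (mean absolute log10 error at the optimum), `sse`
#'   (sum of squared residuals), `restart_objectives`, `converged`, `seed`,
#'   `n_species`.
#' @export
fit_intake <- function(net, sample, params, intake_metabolites,
                       n_restarts = 10L, seed = 1L, floor = 1e-6,
                       tol = 1e-12, max_iter = 300L) {
  stopifnot(length(intake_metabolites) >= 1L)
  sp <- names(sample$abundances)
  if (!length(intersect(sp, net$species))) {
    stop("no overlap between sample species and network species")
  }
  resp <- intake_response(net, sample, params, intake_metabolites)
  fit_intake_response(resp, sample$abundances, n_restarts = n_restarts,
                      seed = seed, floor = floor, tol = tol,
                      max_iter = max_iter)
}

# Fitting core against a precomputed intake_response(); exported for the
# calibration grid, which reuses responses across scoring steps.
#' @rdname fit_intake
#' @param response a precomputed [intake_response()].
#' @param observed named observed relative abundances.
#' @export
fit_intake_response <- function(response, observed, n_restarts = 10L,
                                seed = 1L, floor = 1e-6, tol = 1e-12,
                                max_iter = 300L) {
  Rb <- response$biomass
  m <- observed[rownames(Rb)]
  stopifnot(!anyNA(m))
  m <- m / sum(m)
  K <- ncol(Rb)
  log_m <- log10(pmax(m, floor))
  if (K == 1L) {
    intake <- stats::setNames(1, colnames(Rb))
    r <- log_residual_fun(Rb, log_m, floor)(1)
    return(structure(
      list(intake = intake, objective = mean(abs(r)), sse = sum(r^2),
           restart_objectives = mean(abs(r)), converged = TRUE, seed = seed,
           n_species = nrow(Rb)),
      class = "intake_fit"))
  }
  fn0 <- log_residual_fun(Rb, log_m, floor)
  jac0 <- log_jacobian_fun(Rb, floor)
  # Levenberg-Marquardt needs at least as many residuals as parameters;
  # zero-pad when the sample has fewer species than intake candidates
  pad <- max(0L, K - nrow(Rb) + 1L)
  fn <- if (pad) function(x) c(fn0(x), numeric(pad)) else fn0
  jac <- if (pad) function(x) rbind(jac0(x), matrix(0, pad, K)) else jac0
  set.seed(seed)
  best <- NULL
  restart_obj <- numeric(n_restarts)
  restart_init_sse <- numeric(n_restarts)
  conv <- logical(n_restarts)
  for (r_i in seq_len(n_restarts)) {
    x0 <- stats::runif(K)
    x0 <- x0 / sum(x0)
    restart_init_sse[r_i] <- sum(fn0(x0)^2)
    fit <- minpack.lm::nls.lm(
      par = x0, lower = rep(0, K), upper = rep(Inf, K),
      fn = fn, jac = jac,
      control = minpack.lm::nls.lm.control(ftol = tol, ptol = tol,
                                           maxiter = max_iter)
    )
    fvec <- fit$fvec[seq_len(nrow(Rb))]
    sse <- sum(fvec^2)
    if (!is.finite(sse)) next
    restart_obj[r_i] <- mean(abs(fvec))
    conv[r_i] <- fit$info %in% 1:4
    if (is.null(best) || sse < best$sse) {
      best <- list(par = fit$par, sse = sse, fvec = fvec,
                   converged = conv[r_i])
    }
  }
  if (is.null(best)) stop("all restarts failed to produce a finite objective")
  x <- pmax(best$par, 0)
  s <- sum(x)
  intake <- stats::setNames(if (s > 0) x / s else rep(1 / K, K), colnames(Rb))
  structure(
    list(intake = intake, objective = mean(abs(best$fvec)), sse = best$sse,
         restart_objectives = restart_obj,
         restart_initial_sse = restart_init_sse, converged = best$converged,
         seed = seed, n_species = nrow(Rb)),
    class = "intake_fit"
  )
}

#' @export
print.intake_fit <- function(x, ...) {
  cat("Intake fit over", length(x$intake), "metabolites,", x$n_species,
      "species: objective", format(x$objective, digits = 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  top <- sort(x$intake, decreasing = TRUE)
  top <- top[top > 0][seq_len(min(5L, sum(x$intake > 0)))]
  cat("  top intakes:", paste(sprintf("%s=%.3f", names(top), top),
                              collapse = ", "), "\n")
  invisible(x)
}
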