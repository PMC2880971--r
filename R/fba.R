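#' Flux bounds for linear-programming flux determination
#'
#' Defaults follow the usual convention for small models in arbitrary
#' units: reversible reactions bounded \[-10, 10\], irreversible \[0, 10\];
#' the substrate uptake is fixed to 1 inside [fba_fluxes()] so all fluxes
#' are per unit substrate.
#'
#' @param model A [stoich_model()].
#' @param overrides Optional data frame `reaction, lower, upper` overriding
#'   the default bounds for selected reactions.
#' @return A tibble `reaction, lower, upper`.
#' @export
default_bounds <- function(model, overrides = NULL) {
  b <- tibble::tibble(
    reaction = model$reactions$id,
    lower = ifelse(model$reactions$reversible, -10, 0),
    upper = 10
  )
  if (!is.null(overrides)) {
    ov <- tibble::as_tibble(overrides)
    i <- match(ov$reaction, b$reaction)
    b$lower[i[!is.na(i)]] <- ov$lower[!is.na(i)]
    b$upper[i[!is.na(i)]] <- ov$upper[!is.na(i)]
  }
  if (any(b$lower > b$upper)) stop("lower bound exceeds upper bound",
                                   call. = FALSE)
  b
}

#' Flux balance analysis: LP flux determination
#'
#' Maximizes the flux of an objective reaction (by default the biomass
#' reaction) subject to the steady-state balance `S v = 0` on internal
#' metabolites and flux bounds, with substrate uptake fixed to 1 so the
#' optimum is directly a per-substrate yield. Reversible reactions are
#' split into nonnegative forward/backward parts for the simplex solver
#' ([boot::simplex()]) and folded back to net fluxes.
#'
#' With uptake fixed and non-binding capacity bounds, the optimum equals the
#' best per-substrate yield over the elementary modes (the LP optimum is
#' attained on an extreme ray of the flux cone).
#'
#' @param model A [stoich_model()].
#' @param objective_rxn Reaction id to maximize (default biomass).
#' @param bounds A bounds tibble from [default_bounds()].
#' @param substrate_flux Fixed substrate uptake (default 1).
#' @return A list of class `fba_result`: `fluxes` (tibble `reaction, flux`),
#'   `objective_value`, `status` (`"optimal"`). An infeasible or unsolved LP
#'   raises an error carrying the solver status rather than returning zeros.
#' @export
fba_fluxes <- function(model, objective_rxn = model$biomass_rxn,
                       bounds = default_bounds(model), substrate_flux = 1) {
  objective_absent <- !objective_rxn %in% model$reactions$id
  sp <- split_reversible(model)
  S <- sp$S
  n_split <- ncol(S)
  bl <- bounds$lower[sp$col_rxn]
  bu <- bounds$upper[sp$col_rxn]
  # split-variable capacity: forward part limited by upper bound,
  # backward part by -lower bound
  ub <- ifelse(sp$col_dir == 1L, pmax(0, bu), pmax(0, -bl))
  lb <- ifelse(sp$col_dir == 1L, pmax(0, bl), pmax(0, -bu))
  # on reversible reactions the net flux is fwd - bwd; per-part lower
  # bounds only apply to irreversible reactions
  lb[model$reactions$reversible[sp$col_rxn]] <- 0

  obj <- if (objective_absent) rep(0, n_split) else {
    as.numeric(sp$col_rxn == match(objective_rxn, model$reactions$id)) *
      sp$col_dir
  }
  sub_row <- as.numeric(sp$col_rxn == match(model$substrate_rxn,
                                            model$reactions$id)) * sp$col_dir

  A1 <- diag(n_split); b1 <- ub
  A3 <- rbind(S, sub_row); b3 <- c(rep(0, nrow(S)), substrate_flux)
  has_lb <- lb > 0
  A2 <- if (any(has_lb)) diag(n_split)[has_lb, , drop = FALSE] else NULL
  b2 <- if (any(has_lb)) lb[has_lb] else NULL

  sol <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                       A3 = A3, b3 = b3, maxi = TRUE,
                       n.iter = 100 * (n_split + nrow(A3)), eps = 1e-10)
  if (is.na(sol$solved) || sol$solved != 1L) {
    status <- if (!is.na(sol$solved) && sol$solved == -1L) "infeasible"
              else "not converged"
    stop("FBA linear program ", status, " (solver code ", sol$solved, ")",
         call. = FALSE)
  }
  x <- sol$soln
  v <- stats::setNames(rep(0, nrow(model$reactions)), model$reactions$id)
  for (j in seq_len(n_split)) {
    v[sp$col_rxn[j]] <- v[sp$col_rxn[j]] + sp$col_dir[j] * x[j]
  }
  structure(
    list(fluxes = tibble::tibble(reaction = names(v), flux = unname(v)),
         objective_value = if (objective_absent) 0 else unname(sol$value),
         objective_rxn = objective_rxn,
         status = if (objective_absent) "objective absent" else "optimal"),
    class = "fba_result"
  )
}

#' @export
print.fba_result <- function(x, ...) {
  cat("<fba_result> objective ", x$objective_rxn, " = ",
      format(x$objective_value, digits = 6), " (", x$status, ")\n", sep = "")
  invisible(x)
}
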