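#' @keywords internal
#' Split reversible reactions into irreversible forward/backward pairs.
#' Returns the internal stoichiometric matrix over split columns plus the
#' column -> (reaction, direction) mapping.
split_reversible <- function(model) {
  S <- stoich_matrix(model)
  rev_flag <- model$reactions$reversible
  n <- ncol(S)
  back <- which(rev_flag)
  S_split <- cbind(S, -S[, back, drop = FALSE])
  col_rxn <- c(seq_len(n), back)
  col_dir <- c(rep(1L, n), rep(-1L, length(back)))
  colnames(S_split) <- paste0(model$reactions$id[col_rxn],
                              ifelse(col_dir == 1L, "", "_rev"))
  list(S = S_split, col_rxn = col_rxn, col_dir = col_dir, n_rxn = n)
}

# Nearest rational p/q with q <= max_den (continued fractions); snaps
# float artefacts like 0.333333331 back to 1/3 before normalization.
snap_rational <- function(x, max_den = 1e6, tol = 1e-8) {
  vapply(x, function(v) {
    if (!is.finite(v) || v == 0) return(v)
    sign_v <- sign(v)
    v <- abs(v)
    p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
    r <- v
    for (i in 1:40) {
      a <- floor(r)
      p2 <- a * p1 + p0; q2 <- a * q1 + q0
      if (q2 > max_den) break
      p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
      if (abs(v - p1 / q1) < tol * max(1, v)) break
      if (abs(r - a) < 1e-12) break
      r <- 1 / (r - a)
    }
    cand <- p1 / q1
    if (abs(cand - v) < tol * max(1, v)) sign_v * cand else sign_v * v
  }, 0)
}

normalize_mode <- function(v, substrate_idx, tol = 1e-9) {
  v <- snap_rational(v)
  s <- v[substrate_idx]
  if (length(s) == 1 && is.finite(s) && s > tol) v <- v / s
  else v <- v / max(abs(v))
  snap_rational(v)
}

new_emset <- function(M, model) {
  rownames(M) <- model$reactions$id
  supports <- lapply(seq_len(ncol(M)), function(j) {
    model$reactions$id[abs(M[, j]) > 1e-9]
  })
  structure(list(M = M, reaction_ids = model$reactions$id,
                 model_name = model$name, supports = supports),
            class = "emset")
}

#' @export
print.emset <- function(x, ...) {
  cat("<emset> ", ncol(x$M), " elementary modes over ",
      nrow(x$M), " reactions (model: ", x$model_name, ")\n", sep = "")
  invisible(x)
}

#' Number of elementary modes in an EM set
#' @param ems An `emset`.
#' @return Integer count.
#' @export
n_modes <- function(ems) ncol(ems$M)

# Deterministic mode order: lexicographic on the support index pattern.
order_modes <- function(M, tol = 1e-9) {
  keys <- apply(abs(M) > tol, 2, function(s) {
    paste(sprintf("%04d", which(s)), collapse = ",")
  })
  order(keys)
}

#' Enumerate all elementary flux modes of a model
#'
#' Elementary modes (EMs) are the support-minimal steady-state flux vectors
#' of the network: `S v = 0` over internal metabolites, `v >= 0` on
#' irreversible reactions, and no other steady-state vector has a support
#' that is a proper subset. They are the extreme rays of the flux cone once
#' reversible reactions are split into forward/backward irreversible pairs.
#'
#' The implementation is the classical double-description (tableau) scheme:
#' internal metabolites are processed one at a time, rays violating the new
#' balance are combined pairwise across signs, and non-minimal supports are
#' discarded at each step. Spurious forward+backward 2-cycles of reversible
#' reactions are removed at the end and surviving modes are folded back to
#' signed coefficients on the original reactions.
#'
#' Each mode is normalized to unit substrate uptake when it consumes
#' substrate, otherwise to a maximum absolute coefficient of 1.
#'
#' @param model A [stoich_model()].
#' @param tol Numerical tolerance for zero tests.
#' @param max_rays Safety cap on intermediate ray counts.
#' @return An `emset`: modes are the columns of matrix `M` (reactions x
#'   modes), in deterministic support-lexicographic order.
#' @seealso [brute_force_efms()] for the exhaustive oracle used in testing.
#' @export
enumerate_efms <- function(model, tol = 1e-9, max_rays = 2e5) {
  sp <- split_reversible(model)
  S <- sp$S
  m <- nrow(S); n <- ncol(S)
  if (m < 1L) stop("model has no internal metabolite", call. = FALSE)

  R <- diag(n)                # rays as rows over split reactions
  A <- t(S)                   # residual balances: A[i, k] = S[k, ] %*% R[i, ]
  for (k in seq_len(m)) {
    vals <- A[, k]
    zero <- abs(vals) <= tol
    pos <- which(!zero & vals > 0)
    neg <- which(!zero & vals < 0)
    keep_R <- R[zero, , drop = FALSE]
    keep_A <- A[zero, , drop = FALSE]
    if (length(pos) && length(neg)) {
      n_new <- length(pos) * length(neg)
      if (n_new + nrow(keep_R) > max_rays) {
        stop("intermediate ray count exceeds max_rays = ", max_rays,
             call. = FALSE)
      }
      pi <- rep(pos, times = length(neg))
      ni <- rep(neg, each = length(pos))
      w_p <- -vals[ni]         # positive multipliers
      w_n <- vals[pi]
      new_R <- R[pi, , drop = FALSE] * w_p + R[ni, , drop = FALSE] * w_n
      new_A <- A[pi, , drop = FALSE] * w_p + A[ni, , drop = FALSE] * w_n
      sc <- apply(abs(new_R), 1, max)
      new_R <- new_R / sc
      new_A <- new_A / sc
      new_R[abs(new_R) <= tol] <- 0
      new_A[, seq_len(k)] <- 0

      cand_R <- rbind(keep_R, new_R)
      supp <- cand_R > tol
      sizes <- rowSums(supp)
      # outside[j, i] = #elements of supp_j not in supp_i; j subset i iff 0
      outside <- supp %*% (1 - t(supp))
      n_keep <- nrow(keep_R)
      drop <- rep(FALSE, nrow(cand_R))
      for (i in seq_len(nrow(cand_R))) {
        if (i <= n_keep) next  # previously minimal rays stay
        subs <- which(outside[, i] == 0)
        subs <- subs[subs != i]
        if (any(sizes[subs] < sizes[i])) { drop[i] <- TRUE; next }
        dups <- subs[sizes[subs] == sizes[i]]
        if (any(dups < i)) drop[i] <- TRUE
      }
      R <- cand_R[!drop, , drop = FALSE]
      A <- rbind(keep_A, new_A)[!drop, , drop = FALSE]
    } else if (length(pos) || length(neg)) {
      R <- keep_R; A <- keep_A
    } else {
      R <- rbind(keep_R); A <- rbind(keep_A)
    }
    if (nrow(R) == 0L) break
  }

  fold_split_modes(R, sp, model, tol)
}

# Drop 2-cycles, fold split columns back to signed coefficients, normalize,
# order deterministically and wrap as an emset.
fold_split_modes <- function(R, sp, model, tol = 1e-9) {
  n_rxn <- sp$n_rxn
  sub_idx <- match(model$substrate_rxn, model$reactions$id)
  if (nrow(R) == 0L) {
    return(new_emset(matrix(0, n_rxn, 0), model))
  }
  keep <- rep(TRUE, nrow(R))
  folded <- matrix(0, nrow(R), n_rxn)
  for (i in seq_len(nrow(R))) {
    v <- numeric(n_rxn)
    for (j in seq_along(sp$col_rxn)) {
      v[sp$col_rxn[j]] <- v[sp$col_rxn[j]] + sp$col_dir[j] * R[i, j]
    }
    supp_split <- which(R[i, ] > tol)
    rxns_used <- sp$col_rxn[supp_split]
    if (anyDuplicated(rxns_used)) {
      # both directions of a reversible reaction: either the spurious
      # 2-cycle or a non-elementary combination; neither is a mode
      keep[i] <- FALSE
      next
    }
    if (all(abs(v) <= tol)) { keep[i] <- FALSE; next }
    folded[i, ] <- normalize_mode(v, sub_idx, tol)
  }
  M <- t(folded[keep, , drop = FALSE])
  # dedupe identical supports (can arise from fold-back of equivalent rays)
  if (ncol(M) > 1L) {
    keys <- apply(abs(M) > tol, 2, function(s) paste(which(s), collapse = ","))
    M <- M[, !duplicated(keys), drop = FALSE]
  }
  M <- M[, order_modes(M, tol), drop = FALSE]
  new_emset(M, model)
}

#' Brute-force elementary mode enumeration (testing oracle)
#'
#' Exhaustively checks every candidate support set of the split network:
#' a support is an elementary mode iff the nullspace of the stoichiometric
#' matrix restricted to those columns is one-dimensional, its generator is
#' strictly nonzero with a single sign on all support columns, and no kept
#' support is a proper subset. Exponential in the number of reactions, hence
#' the hard size guard; intended as an independent oracle for
#' [enumerate_efms()], not for real models.
#'
#' @param model A [stoich_model()].
#' @param max_split Refuse models with more than this many reactions after
#'   reversible splitting (default 18).
#' @param tol Numerical tolerance.
#' @return An `emset`, support-identical to [enumerate_efms()].
#' @export
brute_force_efms <- function(model, max_split = 18, tol = 1e-9) {
  sp <- split_reversible(model)
  S <- sp$S
  n <- ncol(S)
  if (n > max_split) {
    stop("brute_force_efms refuses models with more than ", max_split,
         " reactions after reversible splitting (got ", n, ")", call. = FALSE)
  }
  kept_masks <- numeric(0)
  kept_rows <- list()
  for (size in seq_len(n)[-1]) {
    combs <- utils::combn(n, size)
    for (ci in seq_len(ncol(combs))) {
      T_idx <- combs[, ci]
      mask <- sum(2^(T_idx - 1))
      # minimality: skip supersets of an already-kept support
      if (length(kept_masks) &&
          any(bitwAnd(mask, kept_masks) == kept_masks)) next
      sub <- S[, T_idx, drop = FALSE]
      # each internal metabolite must be producible and consumable (or
      # untouched) within the support
      pos_r <- rowSums(sub > 0); neg_r <- rowSums(sub < 0)
      if (any(xor(pos_r > 0, neg_r > 0))) next
      ns <- nullspace_basis(sub, tol)
      if (ncol(ns) != 1L) next
      g <- ns[, 1]
      if (any(abs(g) <= tol * max(abs(g)))) next
      if (sign(g[1]) < 0) g <- -g
      if (any(g < 0)) next
      kept_masks <- c(kept_masks, mask)
      row <- numeric(n); row[T_idx] <- g
      kept_rows[[length(kept_rows) + 1L]] <- row
    }
  }
  R <- if (length(kept_rows)) do.call(rbind, kept_rows) else matrix(0, 0, n)
  fold_split_modes(R, sp, model, tol)
}

# Orthonormal nullspace basis via SVD; ncol = nullity at tolerance.
nullspace_basis <- function(A, tol = 1e-9) {
  n <- ncol(A)
  if (n == 0L) return(matrix(0, 0, 0))
  if (nrow(A) == 0L) return(diag(n))
  sv <- svd(A, nu = 0, nv = n)
  rank <- sum(sv$d > tol * max(sv$d, 1))
  if (rank == n) matrix(0, n, 0) else sv$v[, (rank + 1):n, drop = FALSE]
}

#' Support sets of an EM set
#' @param ems An `emset`.
#' @return List of character vectors of reaction ids, in mode order.
#' @export
mode_supports <- function(ems) ems$supports

# --- classification and yields ------------------------------------------

# Species carrying the substrate/product mass: the external metabolite
# consumed by the substrate reaction / produced by the product reaction.
designated_species <- function(model, role = c("substrate", "product")) {
  role <- match.arg(role)
  rxn_id <- if (role == "substrate") model$substrate_rxn else model$product_rxn
  st <- model$reactions$stoichiometry[[match(rxn_id, model$reactions$id)]]
  ext <- model$metabolites$id[!model$metabolites$is_internal]
  want <- if (role == "substrate") st < 0 else st > 0
  hit <- intersect(names(st)[want], ext)
  if (length(hit) == 0L) hit <- names(st)[want]
  if (length(hit) == 0L) {
    stop("cannot identify the ", role, " species of reaction ", rxn_id,
         call. = FALSE)
  }
  hit[1]
}

species_mw <- function(model, role) {
  sp <- designated_species(model, role)
  mw <- unname(c(model$mw, NA_real_)[sp])
  if (is.na(mw)) mw <- unname(c(model$mw, NA_real_)[sub("_ext$", "", sp)])
  if (is.null(mw) || is.na(mw)) {
    stop("no molecular weight supplied for ", role, " species '", sp, "'",
         call. = FALSE)
  }
  mw
}

# Flux of a designated reaction in each mode (0 if knocked out of model).
designated_flux <- function(M, reaction_ids, rxn_id) {
  i <- match(rxn_id, reaction_ids)
  if (is.na(i)) rep(0, ncol(M)) else M[i, ]
}

#' Per-mode substrate, product and biomass yields
#'
#' Product yield is a mass yield, `(product flux x MW_product) /
#' (substrate flux x MW_substrate)` (g/g); biomass is reported as the
#' biomass-reaction flux per unit substrate flux. Modes with zero substrate
#' uptake (internal cycles) have both yields 0 by convention.
#'
#' @param ems An `emset`.
#' @param model The source [stoich_model()] (provides designations and
#'   molecular weights).
#' @param tol Zero tolerance on fluxes.
#' @return A tibble with one row per mode: `mode`, `substrate_flux`,
#'   `product_flux`, `biomass_flux`, `product_yield_mass`,
#'   `biomass_per_substrate`, `n_support`.
#' @export
mode_yields <- function(ems, model, tol = 1e-9) {
  M <- ems$M
  nm <- ncol(M)
  sub_f <- designated_flux(M, ems$reaction_ids, model$substrate_rxn)
  prod_f <- designated_flux(M, ems$reaction_ids, model$product_rxn)
  bio_f <- designated_flux(M, ems$reaction_ids, model$biomass_rxn)
  has_sub <- sub_f > tol
  py <- rep(0, nm); by <- rep(0, nm)
  if (any(has_sub) && nm > 0) {
    mw_s <- species_mw(model, "substrate")
    mw_p <- species_mw(model, "product")
    py[has_sub] <- pmax(0, prod_f[has_sub]) * mw_p / (sub_f[has_sub] * mw_s)
    by[has_sub] <- pmax(0, bio_f[has_sub]) / sub_f[has_sub]
  }
  tibble::tibble(
    mode = seq_len(nm),
    substrate_flux = sub_f,
    product_flux = prod_f,
    biomass_flux = bio_f,
    product_yield_mass = py,
    biomass_per_substrate = by,
    n_support = vapply(ems$supports, length, 0L)
  )
}

#' Census of product- and biomass-forming modes
#'
#' A mode "produces" a species when its coefficient on the designated
#' reaction exceeds the tolerance.
#'
#' @param ems An `emset`.
#' @param model The source [stoich_model()].
#' @param tol Production tolerance (default 1e-9 on normalized modes).
#' @return A one-row tibble: `n_total`, `n_product`, `n_biomass`, `n_both`
#'   and the corresponding percentages (reported to 0.1%).
#' @export
classify_modes <- function(ems, model, tol = 1e-9) {
  M <- ems$M
  prod_f <- designated_flux(M, ems$reaction_ids, model$product_rxn)
  bio_f <- designated_flux(M, ems$reaction_ids, model$biomass_rxn)
  n <- ncol(M)
  np <- sum(prod_f > tol); nb <- sum(bio_f > tol)
  nboth <- sum(prod_f > tol & bio_f > tol)
  pct <- function(k) if (n > 0) round(100 * k / n, 1) else NA_real_
  tibble::tibble(
    n_total = n, n_product = np, n_biomass = nb, n_both = nboth,
    pct_product = pct(np), pct_biomass = pct(nb), pct_both = pct(nboth)
  )
}

#' Maximum (theoretical) yield over an EM set
#'
#' The theoretical yield of product (or biomass) on substrate is the maximum
#' per-mode yield over all elementary modes of the model. Also reports how
#' many modes attain it (relative tolerance 1e-6) and, for each attaining
#' mode, the number of reactions outside its support — i.e. the reaction
#' removals needed to isolate that mode as the only route.
#'
#' @param ems An `emset`.
#' @param model The source [stoich_model()].
#' @param target `"product"` (mass yield, g/g) or `"biomass"`
#'   (flux per unit substrate).
#' @param rel_tol Relative tolerance for "attains the maximum".
#' @return A list with `value`, `n_modes_attaining`, `attaining_modes`
#'   (indices) and `knockouts_to_isolate` (integer vector, one per attaining
#'   mode). An empty EM set gives `value = 0`, `n_modes_attaining = 0`.
#' @export
max_yield <- function(ems, model, target = c("product", "biomass"),
                      rel_tol = 1e-6) {
  target <- match.arg(target)
  if (n_modes(ems) == 0L) {
    return(list(value = 0, n_modes_attaining = 0L,
                attaining_modes = integer(), knockouts_to_isolate = integer()))
  }
  ym <- mode_yields(ems, model)
  y <- if (target == "product") ym$product_yield_mass else ym$biomass_per_substrate
  val <- max(y)
  if (val <= 0) {
    return(list(value = 0, n_modes_attaining = 0L,
                attaining_modes = integer(), knockouts_to_isolate = integer()))
  }
  att <- which(y >= val * (1 - rel_tol))
  ko <- vapply(att, function(i) {
    length(ems$reaction_ids) - length(ems$supports[[i]])
  }, 0L)
  list(value = val, n_modes_attaining = length(att),
       attaining_modes = att, knockouts_to_isolate = ko)
}

#' Select the parent modes surviving a set of reaction knockouts
#'
#' The EM set of a deletion strain is exactly the subset of the parent's
#' modes whose supports avoid every removed reaction (knockout-subset
#' property), so no re-enumeration is needed.
#'
#' @param ems Parent `emset`.
#' @param removed Character vector of removed reaction ids.
#' @return An `emset` restricted to the surviving modes (same reaction rows).
#' @export
surviving_modes <- function(ems, removed) {
  if (length(removed) == 0L) return(ems)
  keep <- !vapply(ems$supports, function(s) any(s %in% removed), TRUE)
  out <- ems
  out$M <- ems$M[, keep, drop = FALSE]
  out$supports <- ems$supports[keep]
  out
}

# --- EM set I/O ----------------------------------------------------------

#' Write / read an EM matrix as wide CSV
#'
#' Rows are reactions, columns modes (`em1`, `em2`, ...). The reader attaches
#' the matrix to a model so externally computed EM sets can be cross-checked.
#'
#' @param ems An `emset`.
#' @param path CSV path.
#' @return `path` invisibly (writer); an `emset` (reader).
#' @export
write_emset <- function(ems, path) {
  df <- as.data.frame(ems$M)
  if (ncol(df) > 0) colnames(df) <- paste0("em", seq_len(ncol(df)))
  df <- cbind(reaction = ems$reaction_ids, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emset
#' @param model The [stoich_model()] the matrix belongs to.
#' @export
read_emset <- function(path, model) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  colnames(M) <- NULL
  idx <- match(model$reactions$id, df$reaction)
  if (anyNA(idx)) stop("EM CSV is missing reactions present in the model",
                       call. = FALSE)
  M <- M[idx, , drop = FALSE]
  new_emset(M, model)
}
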