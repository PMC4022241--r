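# Reversibility models: rev_j = v_reverse / v_net (Eq-5-style exchange
# parameterization), constant or time-varying.

#' Evaluate a reversibility model
#'
#' Kinds: `constant` (rev), `hyperbolic` (rev0 / (t + eps), the decreasing
#' pyruvate-transport form) and `exponential` (alpha * exp(beta t), the
#' increasing alanine-transport form). Time in hours.
#'
#' @param model list with `kind` and its parameters
#' @param t time (h), vectorized
#' @export
rev_value <- function(model, t) {
  v <- switch(model$kind,
    constant = rep_len(model$rev, length(t)),
    hyperbolic = model$rev0 / (t + model$eps),
    exponential = model$alpha * exp(model$beta * t),
    stop("unknown reversibility kind: ", model$kind))
  if (any(v < 0)) stop("reversibility model evaluates negative at t = ",
                       t[which(v < 0)[1]])
  v
}

#' Expand net fluxes into absolute forward/reverse fluxes
#'
#' For a reversible reaction with net flux v and reversibility rev(t):
#' forward = |v| (1 + rev), reverse = |v| rev, with the roles of the two
#' directions swapped when the net flux is negative. Irreversible reactions
#' get (v, 0).
#'
#' @param v_net named net-flux vector
#' @param rev_models named list (reaction id -> reversibility model or NULL)
#' @param t time (h)
#' @return data.frame reaction, net, fwd, rev where fwd/rev are the absolute
#'   fluxes in the reaction's written / opposite direction
#' @export
expand_reversibilities <- function(v_net, rev_models, t = 0) {
  stopifnot(length(t) == 1L)
  fwd <- rev <- numeric(length(v_net))
  for (i in seq_along(v_net)) {
    id <- names(v_net)[i]
    m <- rev_models[[id]]
    v <- v_net[[i]]
    if (is.null(m)) {
      if (v < 0) stop("negative net flux on irreversible reaction ", id)
      fwd[i] <- v; rev[i] <- 0
    } else {
      rv <- rev_value(m, t)
      fwd[i] <- max(v, 0) + abs(v) * rv
      rev[i] <- max(-v, 0) + abs(v) * rv
    }
  }
  data.frame(reaction = names(v_net), net = as.numeric(v_net),
             fwd = fwd, rev = rev, row.names = NULL)
}

# Map reaction id -> its reversibility model (from network + parameter
# overrides); NULL for irreversible reactions.
reaction_rev_models <- function(network, rev_params = NULL) {
  out <- list()
  for (r in network$reactions) {
    if (!r$reversible) { out[r$id] <- list(NULL); next }
    m <- if (!is.na(r$rev_model)) network$rev_models[[r$rev_model]]
         else list(kind = "constant", rev = 0, id = paste0("REV_", r$id))
    if (!is.null(rev_params)) {
      # overrides are named by rev-model parameter, e.g. REV_LDH1.rev,
      # REV_PYRT.rev0, REV_ALAT.alpha
      for (p in setdiff(names(m), c("kind", "id"))) {
        key <- paste0(m$id, ".", p)
        if (key %in% names(rev_params)) m[[p]] <- rev_params[[key]]
      }
    }
    out[[r$id]] <- m
  }
  out
}
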