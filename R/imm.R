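# Isotopomer distribution vectors (IDVs) and isotopomer mapping matrices
# (IMMs). An n-carbon pool has 2^n positional labeling states; state s has
# carbon k labeled iff bit (k-1) of s is set.

#' IDV of independently labeled carbons
#'
#' @param n number of carbons
#' @param p labeling probability per carbon (scalar or length-n vector)
#' @return vector of length 2^n over binary labeling states
#' @export
bernoulli_idv <- function(n, p) {
  if (n == 0L) return(1)
  p <- rep_len(p, n)
  idv <- 1
  for (k in seq_len(n)) idv <- c(idv * (1 - p[k]), idv * p[k])
  # bit (k-1) varies fastest for carbon k: build with carbon n as the
  # slowest bit so that state index bit k-1 corresponds to carbon k
  idv
}

#' Natural-abundance IDV
#' @inheritParams bernoulli_idv
#' @param p_nat natural 13C fraction (default 1.1%)
#' @export
natural_idv <- function(n, p_nat = 0.011) bernoulli_idv(n, p_nat)

popcount <- function(x) {
  n <- 0L
  while (any(x > 0)) { n <- n + (x %% 2L); x <- x %/% 2L }
  n
}

#' Collapse an IDV to its mass isotopomer distribution
#'
#' @param idv isotopomer distribution vector (length 2^n)
#' @return MID vector of length n + 1
#' @export
idv_to_mid <- function(idv) {
  n <- as.integer(round(log2(length(idv))))
  stopifnot(2^n == length(idv))
  pc <- popcount(seq_len(length(idv)) - 1L)
  as.numeric(tapply(idv, factor(pc, levels = 0:n), sum))
}

#' Initial IDVs for all labeled pools
#'
#' Unlabeled pools start at the natural 13C abundance (independent
#' per-carbon Bernoulli); the tracer substrate starts at its positional
#' atom purity (0.99 for the [U-13C6] glucose employed).
#'
#' @param network an `instcho_network`
#' @param tracer list with `substrate` (pool id), `enrichment` (per-carbon
#'   13C fraction) and `natural` (13C fraction of unlabeled pools)
#' @return named list of IDVs for every pool that carries carbon
#' @export
initial_idvs <- function(network, tracer = tracer_spec()) {
  out <- list()
  for (m in network$metabolites) {
    if (m$role %in% c("sink", "gas") || m$n_carbons == 0L) next
    p <- if (identical(m$id, tracer$substrate)) tracer$enrichment else tracer$natural
    out[[m$id]] <- bernoulli_idv(m$n_carbons, p)
  }
  out
}

#' Tracer specification
#'
#' @param substrate labeled substrate pool id
#' @param enrichment positional 13C enrichment (atom purity)
#' @param natural natural 13C abundance of unlabeled pools
#' @export
tracer_spec <- function(substrate = "GLC_ex", enrichment = 0.99,
                        natural = 0.011) {
  stopifnot(enrichment >= 0, enrichment <= 1, natural >= 0, natural <= 1)
  list(substrate = substrate, enrichment = enrichment, natural = natural)
}

# Letter lookup for the mapped substrate instances of a reaction:
# letter -> (instance index among mapped substrates, carbon bit)
letter_table <- function(sub_instances) {
  tab <- list()
  for (i in seq_along(sub_instances)) {
    chars <- strsplit(sub_instances[[i]]$map[1], "")[[1]]
    for (k in seq_along(chars)) tab[[chars[k]]] <- c(i, k - 1L)
  }
  tab
}

#' Isotopomer mapping matrices of a reaction
#'
#' For each product pool of the (possibly reversed) reaction, builds the
#' linear operator taking the joint isotopomer distribution of the mapped
#' substrate pools to the product-isotopomer contribution. Condensation
#' products drawing carbon from two substrate molecules get a matrix over
#' the Kronecker product of the substrate IDVs (first listed substrate
#' varies slowest). Product carbons marked `*` are drawn from an unlabeled
#' source at natural abundance; scrambled alternatives (`|`) contribute
#' with equal weight.
#'
#' @param reaction a reaction from an `instcho_network`
#' @param metabolites the network's metabolite list
#' @param direction "forward" or "reverse" (reverse requires an invertible
#'   atom map: every substrate carbon recoverable from the products)
#' @param p_unlabeled 13C fraction of `*` carbons
#' @return list of terms: each with `product` (pool id), `inputs`
#'   (character vector of substrate pool ids, possibly empty), `w`
#'   (stoichiometric weight = coefficient / scale) and `M` (matrix of
#'   dimension 2^n_product x prod(2^n_inputs))
#' @export
build_mapping_matrices <- function(reaction, metabolites,
                                   direction = c("forward", "reverse"),
                                   p_unlabeled = 0.011) {
  direction <- match.arg(direction)
  r <- reaction
  if (direction == "reverse") r <- reverse_reaction(r, metabolites)
  has_map <- function(x) !is.null(x$map)
  subs <- Filter(has_map, r$substrates)
  prods <- Filter(has_map, r$products)
  if (length(prods) == 0L)
    stop("reaction ", r$id, ": no atom map; cannot build mapping matrices")
  ltab <- letter_table(subs)
  sub_n <- vapply(subs, function(s) metabolites[[s$id]]$n_carbons, 0L)

  terms <- list()
  for (p in prods) {
    role <- metabolites[[p$id]]$role
    if (role %in% c("sink", "gas")) next
    np <- metabolites[[p$id]]$n_carbons
    alts <- lapply(p$map, function(m) strsplit(m, "")[[1]])
    used <- sort(unique(unlist(lapply(alts, function(a) {
      vapply(setdiff(a, "*"), function(ch) ltab[[ch]][1], 0)
    }))))
    dims <- if (length(used)) 2^sub_n[used] else 1L
    M <- matrix(0, 2^np, prod(dims))
    for (a in alts) {
      w_alt <- 1 / length(alts)
      stars <- which(a == "*")
      # mapped carbon sources: (which used-instance slot, bit)
      src <- lapply(seq_along(a), function(k) {
        if (a[k] == "*") NULL else {
          e <- ltab[[a[k]]]
          c(match(e[1], used), e[2])
        }
      })
      for (instate in 0:(prod(dims) - 1L)) {
        # decode mixed-radix input state: slot 1 is the lowest block
        bits <- integer(length(used))
        rem <- instate
        for (s in seq_along(used)) {
          bits[s] <- rem %% dims[s]
          rem <- rem %/% dims[s]
        }
        base <- 0L
        for (k in seq_along(a)) {
          if (is.null(src[[k]])) next
          e <- src[[k]]
          if (bitwAnd(bits[e[1]], bitwShiftL(1L, e[2])) != 0L)
            base <- base + bitwShiftL(1L, k - 1L)
        }
        if (length(stars) == 0L) {
          M[base + 1L, instate + 1L] <- M[base + 1L, instate + 1L] + w_alt
        } else {
          for (sub in 0:(2^length(stars) - 1L)) {
            st <- base
            wb <- w_alt
            for (q in seq_along(stars)) {
              if (bitwAnd(sub, bitwShiftL(1L, q - 1L)) != 0L) {
                st <- st + bitwShiftL(1L, stars[q] - 1L)
                wb <- wb * p_unlabeled
              } else wb <- wb * (1 - p_unlabeled)
            }
            M[st + 1L, instate + 1L] <- M[st + 1L, instate + 1L] + wb
          }
        }
      }
    }
    terms[[length(terms) + 1L]] <- list(
      product = p$id,
      inputs = vapply(subs[used], function(s) s$id, ""),
      w = p$coef / r$scale,
      M = M
    )
  }
  terms
}

# Swap substrates and products to obtain the reverse atom map. Substrate
# instances of role "gas" on the original product side become unlabeled
# feeds ('*'); sink products block reversal.
reverse_reaction <- function(r, metabolites) {
  for (p in r$products) {
    role <- metabolites[[p$id]]$role
    if (role == "sink" && !is.null(p$map))
      stop("reaction ", r$id, ": cannot reverse a map with a sink product")
    if (!is.null(p$map) && length(p$map) > 1L)
      stop("reaction ", r$id, ": cannot reverse scrambled alternatives")
  }
  subs <- lapply(r$products, function(p) {
    if (!is.null(p$map) && metabolites[[p$id]]$role == "gas") {
      # letters stay known to the letter table but the pool is unlabeled:
      # replace downstream occurrences by '*' instead (handled below)
      p$gas <- TRUE
    }
    p
  })
  gas_letters <- unlist(lapply(Filter(function(p) isTRUE(p$gas), subs),
                               function(p) strsplit(p$map[1], "")[[1]]))
  subs <- Filter(function(p) !isTRUE(p$gas), subs)
  prods <- lapply(r$substrates, function(s) {
    if (!is.null(s$map) && length(gas_letters)) {
      chars <- strsplit(s$map[1], "")[[1]]
      chars[chars %in% gas_letters] <- "*"
      s$map <- paste(chars, collapse = "")
    }
    s
  })
  list(id = paste0(r$id, "_rev"), substrates = subs, products = prods,
       scale = r$scale, reversible = TRUE, rev_model = r$rev_model)
}
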