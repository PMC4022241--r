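# GC-MS mass-isotopomer data handling: fragment definitions, correction of
# raw spectra for naturally occurring isotopes, measurement covariance.

# Natural isotope abundances (fraction of the +1/+2 heavy species per atom).
ISOTOPE_ABUNDANCE <- list(
  C  = c(`0` = 0.989, `1` = 0.011),
  H  = c(`0` = 0.999885, `1` = 0.000115),
  N  = c(`0` = 0.99636, `1` = 0.00364),
  O  = c(`0` = 0.99757, `1` = 0.00038, `2` = 0.00205),
  Si = c(`0` = 0.92223, `1` = 0.04685, `2` = 0.03092)
)

#' Default GC-MS fragment table for the CHO-K1 labeling experiment
#'
#' The eight SIM fragments carrying the complete carbon skeleton of the
#' measured extracellular metabolites: pyruvate m/z 174 (methoxyamine-TMS),
#' lactate 261, alanine 260, glycine 246, serine 390, aspartate 418,
#' glutamate 432 and glutamine 431 (TBDMS derivatives, [M-57] type ions;
#' pyruvate is the [M-15] ion). Elemental compositions are derived from the
#' named derivatives (the published work gives only m/z values) and are
#' editable: pass your own table with the same columns anywhere a fragment
#' table is accepted.
#'
#' @return data.frame with columns fragment, metabolite, mz, n_backbone and
#'   atom counts C, H, N, O, Si of the derivatized fragment ion
#' @export
default_fragments <- function() {
  data.frame(
    fragment   = c("PYR174", "LAC261", "ALA260", "GLY246", "SER390",
                   "ASP418", "GLU432", "GLN431"),
    metabolite = c("PYR", "LAC", "ALA", "GLY", "SER", "ASP", "GLU", "GLN"),
    mz         = c(174L, 261L, 260L, 246L, 390L, 418L, 432L, 431L),
    n_backbone = c(3L, 3L, 3L, 2L, 3L, 4L, 5L, 5L),
    C  = c(6L, 11L, 11L, 10L, 17L, 18L, 19L, 19L),
    H  = c(12L, 25L, 26L, 24L, 40L, 40L, 42L, 43L),
    N  = c(1L, 0L, 1L, 1L, 1L, 1L, 1L, 2L),
    O  = c(3L, 3L, 2L, 2L, 3L, 4L, 4L, 3L),
    Si = c(1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L),
    stringsAsFactors = FALSE
  )
}

# Convolve two mass-shift distributions, truncating at n_max shifts.
conv_trunc <- function(a, b, n_max) {
  out <- numeric(n_max)
  for (i in seq_along(a)) {
    jmax <- min(length(b), n_max - i + 1L)
    if (jmax >= 1L)
      out[i:(i + jmax - 1L)] <- out[i:(i + jmax - 1L)] + a[i] * b[1:jmax]
  }
  out
}

# Mass-shift distribution contributed by the non-backbone atoms of a
# derivatized fragment (all H, N, O, Si plus derivatization carbons).
derivatization_shift <- function(frag, n_max) {
  d <- c(1, rep(0, n_max - 1L))
  counts <- list(C = frag$C - frag$n_backbone, H = frag$H, N = frag$N,
                 O = frag$O, Si = frag$Si)
  for (el in names(counts)) {
    k <- counts[[el]]
    if (is.na(k) || k <= 0) next
    single <- ISOTOPE_ABUNDANCE[[el]]
    for (i in seq_len(k)) d <- conv_trunc(d, single, n_max)
  }
  d
}

#' Isotope-convolution (correction) matrix of a fragment
#'
#' Column j (tracer labeling state M+(j-1)) holds the expected measured
#' mass-shift distribution: the binomial natural-abundance contribution of
#' the remaining unlabeled backbone carbons convolved with the shift
#' distribution of the derivatization atoms. The raw spectrum then satisfies
#' raw = CM %*% corrected.
#'
#' @param frag one row of a fragment table (list or 1-row data.frame)
#' @param n_raw number of measured masses (rows), >= n_backbone + 1
#' @param backbone include natural abundance of unlabeled backbone carbons
#' @return n_raw x (n_backbone + 1) matrix
#' @export
correction_matrix <- function(frag, n_raw = NULL, backbone = TRUE) {
  frag <- as.list(frag)
  nb <- frag$n_backbone
  if (is.null(n_raw)) n_raw <- nb + 1L
  stopifnot(n_raw >= nb + 1L)
  D <- derivatization_shift(frag, n_raw)
  CM <- matrix(0, n_raw, nb + 1L)
  pC <- ISOTOPE_ABUNDANCE$C["1"]
  for (j in 0:nb) {
    n_unlab <- nb - j
    shift <- if (backbone && n_unlab > 0)
      stats::dbinom(0:n_unlab, n_unlab, pC) else 1
    # shift by j for the tracer carbons themselves
    full <- numeric(n_raw)
    base <- conv_trunc(shift, D, n_raw)
    idx <- (j + 1L):n_raw
    full[idx] <- base[seq_along(idx)]
    CM[, j + 1L] <- full
  }
  CM
}

#' Correct a raw MID for naturally occurring isotopes
#'
#' Solves raw = CM %*% corrected by least squares, clips negative fractions
#' to zero and renormalizes to a simplex vector (the constrained-solve
#' alternative is available via `method = "nnls"`, a simple active-set
#' non-negative solve).
#'
#' @param raw_mid numeric vector of measured mass fractions (length >= n+1)
#' @param frag fragment row (see [default_fragments()])
#' @param backbone correct backbone-carbon natural abundance as well
#' @param method "clip" (default) or "nnls"
#' @return corrected MID of length n_backbone + 1 summing to 1
#' @export
correct_natural_abundance <- function(raw_mid, frag, backbone = TRUE,
                                      method = c("clip", "nnls")) {
  method <- match.arg(method)
  frag <- as.list(frag)
  nb <- frag$n_backbone
  if (length(raw_mid) < nb + 1L)
    stop("raw MID has ", length(raw_mid), " masses; fragment needs >= ", nb + 1L)
  s <- sum(raw_mid)
  if (abs(s - 1) > 0.05)
    warning("raw MID sums to ", signif(s, 4), ", more than 5% from 1")
  CM <- correction_matrix(frag, n_raw = length(raw_mid), backbone = backbone)
  if (rcond_est(crossprod(CM)) < 1e-12)
    stop("correction matrix is numerically singular for fragment ", frag$fragment)
  x <- qr.coef(qr(CM), raw_mid)
  if (method == "nnls" && any(x < 0)) x <- nnls_solve(CM, raw_mid)
  x[x < 0] <- 0
  if (sum(x) <= 0) stop("corrected MID degenerate (all mass removed)")
  x / sum(x)
}

rcond_est <- function(M) {
  d <- svd(M, nu = 0, nv = 0)$d
  if (max(d) == 0) 0 else min(d) / max(d)
}

# Minimal active-set non-negative least squares (Lawson-Hanson style).
nnls_solve <- function(A, b, tol = 1e-12) {
  n <- ncol(A)
  passive <- logical(n)
  x <- numeric(n)
  for (iter in seq_len(10L * n)) {
    w <- crossprod(A, b - A %*% x)
    w[passive] <- -Inf
    if (max(w) <= tol) break
    passive[which.max(w)] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & (z <= tol)
      alpha <- min(x[neg] / (x[neg] - z[neg]), na.rm = TRUE)
      x <- x + alpha * (z - x)
      passive[passive & (x <= tol)] <- FALSE
      x[!passive] <- 0
    }
  }
  x
}

#' Forward-convolve a corrected MID with natural abundance
#'
#' The exact inverse operation of [correct_natural_abundance()]: produces
#' the raw spectrum a GC-MS would measure for a given tracer-labeling MID.
#'
#' @inheritParams correct_natural_abundance
#' @param mid corrected MID (length n_backbone + 1)
#' @param n_raw number of masses to emit
#' @export
convolve_natural_abundance <- function(mid, frag, n_raw = NULL, backbone = TRUE) {
  frag <- as.list(frag)
  if (is.null(n_raw)) n_raw <- frag$n_backbone + 1L
  CM <- correction_matrix(frag, n_raw = n_raw, backbone = backbone)
  as.numeric(CM %*% mid)
}

#' Measurement covariance with the 0.005 standard-deviation floor
#'
#' Diagonal covariance over all MID data points with entries
#' max(sd, 0.005)^2; the floor prevents near-zero replicate standard
#' deviations from dominating the weighted objective.
#'
#' @param sds vector of per-data-point standard deviations
#' @param floor minimum standard deviation (default 0.005)
#' @return diagonal covariance matrix (0 x 0 for empty input)
#' @export
build_covariance <- function(sds, floor = 0.005) {
  sds <- as.numeric(sds)
  if (!length(sds)) return(matrix(0, 0, 0))
  diag(pmax(sds, floor)^2, nrow = length(sds))
}

#' Number of mass-isotopomer data points
#'
#' @param fragments fragment table (needs column n_backbone)
#' @param n_timepoints number of sampling times
#' @return sum over fragments of (n_backbone + 1) * n_timepoints
#' @export
count_mid_datapoints <- function(fragments, n_timepoints) {
  if (is.null(fragments) || nrow(fragments) == 0L) return(0L)
  as.integer(sum(fragments$n_backbone + 1L) * n_timepoints)
}

#' Read / write MID measurement tables
#'
#' Layout: columns fragment, time_h, m0..m6, sd0..sd6 (NA beyond the
#' fragment's mass count).
#'
#' @param path CSV path
#' @return data.frame in the layout above
#' @export
read_mid_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("fragment", "time_h", "m0")
  if (!all(need %in% names(df)))
    stop("MID CSV must have columns fragment, time_h, m0..")
  df
}

#' @rdname read_mid_csv
#' @param df MID data.frame
#' @export
write_mid_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Long-format accessor: named list fragment -> list(time, mid matrix, sd matrix)
mid_table_to_list <- function(df, fragments = default_fragments()) {
  out <- list()
  for (fr in unique(df$fragment)) {
    nb <- fragments$n_backbone[match(fr, fragments$fragment)]
    if (is.na(nb)) stop("unknown fragment in MID table: ", fr)
    sub <- df[df$fragment == fr, , drop = FALSE]
    sub <- sub[order(sub$time_h), , drop = FALSE]
    mcols <- paste0("m", 0:nb)
    scols <- paste0("sd", 0:nb)
    out[[fr]] <- list(
      time = sub$time_h,
      mid = as.matrix(sub[, mcols, drop = FALSE]),
      sd = if (all(scols %in% names(sub))) as.matrix(sub[, scols, drop = FALSE]) else NULL
    )
  }
  out
}
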