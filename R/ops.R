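#' Position-specific convolution
#'
#' Applies a filter bank in which every sequence position has its own
#' weights: for position `i` and filter `p`,
#' `g[i,p] = sum_k sum_j f[i,p,k,j] * d[i - floor(K/2) + k - 1, j]`,
#' with zero padding of `floor(K/2)` rows at both ends of `D`. Passing a
#' 3-d bank (`F x K x M`) applies the same filters at every position
#' (standard shared cross-correlation).
#'
#' @param D Numeric matrix, `L x M` (positions x channels).
#' @param bank Numeric array `L x F x K x M` (position-specific) or
#'   `F x K x M` (shared).
#' @return Numeric matrix `L x F`.
#' @examples
#' D <- matrix(c(1, 2), 2, 1)
#' bank <- array(0, c(2, 1, 3, 1))
#' bank[1, 1, , 1] <- c(1, 1, 1)
#' positionSpecificConv(D, bank)[1, 1]  # 0*1 + 1*1 + 2*1 = 3
#' @export
positionSpecificConv <- function(D, bank) {
  D <- as.matrix(D)
  L <- nrow(D); M <- ncol(D)
  dm <- dim(bank)
  if (length(dm) == 4L) {
    if (dm[1] != L || dm[4] != M)
      stopf("bank dimensions (%s) do not match D (%d x %d)",
            paste(dm, collapse = " x "), L, M)
    K <- dm[3]
    if (K %% 2L == 0L) stopf("filter window K must be odd")
    w <- aperm(bank, c(4, 3, 2, 1))        # M, K, F, L
    dim(w) <- c(M * K, dm[2], L)
    cpp_position_conv(D, w, K, FALSE)
  } else if (length(dm) == 3L) {
    if (dm[3] != M)
      stopf("bank channel dimension %d does not match D (%d channels)", dm[3], M)
    K <- dm[2]
    if (K %% 2L == 0L) stopf("filter window K must be odd")
    w <- aperm(bank, c(3, 2, 1))           # M, K, F
    dim(w) <- c(M * K, dm[1], 1L)
    cpp_position_conv(D, w, K, TRUE)
  } else stopf("bank must be a 3-d (shared) or 4-d (position-specific) array")
}

#' Zero-order-hold discretization
#'
#' Converts the continuous-time state parameters to their discrete forms
#' for one timestep: `Abar = exp(delta * A)` elementwise and
#' `Bbar = delta * B` (the customary first-order simplification of the
#' input term).
#'
#' @param A State matrix diagonal (length-S vector), entries typically <= 0.
#' @param delta Positive scalar step size.
#' @param B Input vector (length S).
#' @return List with `Abar` and `Bbar`.
#' @examples
#' discretizeZoh(-1, log(2), 1)$Abar  # exp(-log 2) = 0.5
#' @export
discretizeZoh <- function(A, delta, B) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stopf("delta must be a positive scalar")
  list(Abar = exp(delta * A), Bbar = delta * B)
}

#' Selective state-space scan
#'
#' Runs the per-channel linear recurrence
#' `h_t = Abar_t (.) h_{t-1} + Bbar_t * g_{t,p}`, `z_{t,p} = <C_t, h_t>`
#' with `h_0 = 0`. The state is updated with the current input before
#' emission, so `z_t` depends on inputs `1..t` only (causal).
#'
#' @param G Numeric matrix `L x F` of scan inputs.
#' @param Abar,Bbar,C Numeric matrices `L x S` of per-timestep discretized
#'   parameters (rows are timesteps). Vectors are accepted for `S = 1`.
#' @return Numeric matrix `L x F` of outputs.
#' @examples
#' # integrator limit: Abar = Bbar = C = 1 turns the scan into a cumsum
#' selectiveScan(matrix(1, 3, 1), rep(1, 3), rep(1, 3), rep(1, 3))
#' @export
selectiveScan <- function(G, Abar, Bbar, C) {
  G <- as.matrix(G)
  Abar <- as.matrix(Abar); Bbar <- as.matrix(Bbar); C <- as.matrix(C)
  if (nrow(Abar) != nrow(G) || !all(dim(Abar) == dim(Bbar)) ||
      !all(dim(Abar) == dim(C)))
    stopf("Abar, Bbar and C must all be L x S with L matching G")
  cpp_selective_scan(G, Abar, Bbar, C)
}

#' Fuse multi-scale feature matrices
#'
#' Implements the softmax fusion of the scale branches: weight matrices
#' `W_k = Q_k (.) Z_k` (queries broadcast along positions) are normalized
#' across the scale axis by a per-cell softmax and used as convex
#' combination weights: `Z = sum_k W'_k (.) Z_k`.
#'
#' @param zList List of equal-dimension `L x N` feature matrices, one per
#'   scale.
#' @param qList List of length-`N` query vectors, same length as `zList`.
#' @return List with the fused matrix `Z` and the list of normalized weight
#'   matrices `weights` (summing to 1 across scales at every cell).
#' @export
fuseScales <- function(zList, qList) {
  if (length(zList) != length(qList) || length(zList) < 2L)
    stopf("need matching lists of at least two scales")
  d <- dim(zList[[1]])
  for (z in zList) if (!all(dim(z) == d)) stopf("scale matrices differ in shape")
  W <- Map(function(z, q) sweep(z, 2, q, "*"), zList, qList)
  mx <- Reduce(pmax, W)
  E <- lapply(W, function(w) exp(w - mx))
  s <- Reduce(`+`, E)
  Wn <- lapply(E, function(e) e / s)
  Z <- Reduce(`+`, Map(`*`, Wn, zList))
  list(Z = Z, weights = Wn)
}

#' Embed an encoded batch
#'
#' Looks up one embedding row per base index.
#'
#' @param indices Integer matrix (windows x L) with entries in 0..3.
#' @param table Numeric `4 x N` embedding table (rows A, C, G, T).
#' @return Numeric array windows x L x N.
#' @export
embedBatch <- function(indices, table) {
  if (any(indices < 0L | indices > 3L)) stopf("indices must lie in 0..3")
  res <- table[as.vector(indices) + 1L, , drop = FALSE]
  array(res, c(nrow(indices), ncol(indices), ncol(table)))
}
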