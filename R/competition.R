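#' Parameters for the initiation-competition (Lodish-style) model
#'
#' mRNAs compete for a limiting pool of 43S preinitiation complexes (PICs).
#' Each mRNA i initiates at a saturable, Michaelis-type flux
#' \deqn{J_i(P) = Jmax_i \frac{K1_i P}{K1_i P + Jmax_i}}
#' where `P` is the free-PIC level, `K1` the mRNA's overall initiation rate
#' constant (the second-order rate of assembling an 80S initiation complex
#' from mRNA and PIC), and `Jmax` the elongation-limited packing flux the
#' transcript can sustain. At low `P` the flux is ~`K1*P` (weak mRNAs lose
#' proportionally); as `P` grows it saturates at `Jmax` (strong mRNAs are
#' buffered). Free PICs obey the conservation closure
#' `P + sum(m_i * L_i * J_i(P)) = R_total`, with `m` the mRNA abundance and
#' `L` the seconds of PIC occupancy each initiation sequesters.
#'
#' @param K1 per-mRNA initiation rate constants (> 0), per PIC per second.
#' @param m per-mRNA abundances (molecules, > 0).
#' @param Jmax per-mRNA maximal initiation fluxes (initiations/s, > 0);
#'   scalar recycled.
#' @param R_total total 43S-competent pool (molecules, > 0).
#' @param L per-mRNA PIC occupancy per initiation (seconds, >= 0); scalar
#'   recycled; used only by the conservation solver.
#' @return a `competition_params` list.
#' @export
competition_params <- function(K1, m = rep(1, length(K1)), Jmax = 10,
                               R_total = length(K1), L = 1) {
  n <- length(K1)
  Jmax <- rep_len(Jmax, n); m <- rep_len(m, n); L <- rep_len(L, n)
  if (n == 0L) stop("need at least one mRNA")
  if (any(K1 <= 0) || any(m <= 0) || any(Jmax <= 0)) {
    stop("K1, m and Jmax must be positive")
  }
  if (any(L < 0)) stop("L must be non-negative")
  if (R_total <= 0) stop("R_total must be positive")
  structure(list(K1 = K1, m = m, Jmax = Jmax, R_total = R_total, L = L),
            class = "competition_params")
}

#' Per-mRNA initiation flux at a given free-PIC level
#'
#' @param params a `competition_params` object.
#' @param P_free free 43S PIC level (> 0).
#' @return numeric vector of fluxes `J_i`, each strictly below `Jmax_i` and
#'   strictly increasing in `P_free`.
#' @export
flux_at <- function(params, P_free) {
  if (!is.numeric(P_free) || length(P_free) != 1L || P_free <= 0) {
    stop("P_free must be a single positive number")
  }
  a <- params$K1 * P_free
  params$Jmax * a / (a + params$Jmax)
}

#' Solve the free-PIC conservation fixed point
#'
#' Finds the unique `P_free` in `(0, R_total]` with
#' `P_free + sum(m * L * J(P_free)) = R_total` by bisection: the left side is
#' continuous and strictly increasing from 0, so a root always exists and is
#' unique. Iterates until the residual is below `1e-10 * R_total`.
#'
#' @param params a `competition_params` object.
#' @return a `competition_state` list: `P_free`, per-mRNA flux `J`,
#'   `TE_model` (flux per mRNA molecule, = `J`), and `relTE` (`TE_model`
#'   divided by its abundance-weighted mean, so that the abundance-weighted
#'   mean of `relTE` is exactly 1).
#' @export
solve_free_pool <- function(params) {
  R <- params$R_total
  occupied <- function(P) sum(params$m * params$L * flux_at(params, P))
  f <- function(P) P + occupied(P) - R
  lo <- R * .Machine$double.eps
  hi <- R
  tol <- 1e-10 * R
  if (f(hi) <= tol) {
    P <- R  # no sequestration (e.g. L == 0): pool stays free
  } else {
    # run bisection to floating-point exhaustion; the slope >= 1 then
    # guarantees the residual bound
    for (iter in seq_len(200L)) {
      P <- (lo + hi) / 2
      if (P <= lo || P >= hi) break
      if (f(P) > 0) hi <- P else lo <- P
    }
    P <- (lo + hi) / 2
    if (abs(f(P)) >= tol) stop("conservation solve failed to reach tolerance")
  }
  J <- flux_at(params, P)
  TE_model <- J
  relTE <- TE_model / stats::weighted.mean(TE_model, params$m)
  structure(list(P_free = P, J = J, TE_model = TE_model, relTE = relTE),
            class = "competition_state")
}

#' Relative-TE change under a change in the free 43S pool
#'
#' Solves the model at a reference and a perturbed total pool size and
#' returns the per-mRNA change in log2 relative TE. Because relative TE is
#' normalized to the (abundance-weighted) average mRNA, a uniform loss of
#' initiation cancels: only differences in `K1` (and `Jmax`) reprogram
#' relative TE. With uniform `Jmax` and a shrunken pool the change is a
#' strictly increasing function of `K1`: weak mRNAs lose, strong mRNAs gain.
#'
#' @param params a `competition_params` object (its `R_total` is ignored).
#' @param R_total_reference,R_total_perturbed pool sizes (> 0).
#' @return numeric vector `log2(relTE_perturbed) - log2(relTE_reference)`.
#' @export
relative_te_change <- function(params, R_total_reference, R_total_perturbed) {
  if (R_total_reference <= 0 || R_total_perturbed <= 0) {
    stop("pool sizes must be positive")
  }
  p_ref <- params; p_ref$R_total <- R_total_reference
  p_per <- params; p_per$R_total <- R_total_perturbed
  s_ref <- solve_free_pool(p_ref)
  s_per <- solve_free_pool(p_per)
  log2(s_per$relTE) - log2(s_ref$relTE)
}

#' @export
print.competition_state <- function(x, ...) {
  cat("competition_state: n =", length(x$J),
      " P_free =", format(x$P_free), "\n")
  invisible(x)
}
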