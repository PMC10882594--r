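# FOD-M: the environment-modified hydrophobicity field.  A non-aqueous
# environment (membrane, cofactor, local field) is represented by mixing the
# aqueous Gaussian field T with its complement (T_max - T_i), in proportion
# K, then renormalizing.

#' Environment-modified distribution M
#'
#' `M_i` is proportional to `T_i + K (T_max - T_i)` with `T_max` the maximum
#' of the (normalized) theoretical distribution of the unit under analysis,
#' renormalized to unit sum.  `K = 0` reproduces T exactly (pure aqueous
#' field); large K approaches the complement field, which vanishes at the
#' Gaussian peak.
#'
#' @param T normalized theoretical distribution.
#' @param K environment participation coefficient, `K >= 0`.
#' @return normalized numeric vector `M`.
#' @export
m_profile <- function(T, K) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K < 0)
    stop("K must be a single non-negative number")
  m <- T + K * (max(T) - T)
  s <- sum(m)
  if (s <= 0) return(rep(1 / length(T), length(T)))  # uniform T, K arbitrary
  m / s
}

#' Select the environment parameter K
#'
#' Evaluates `D_KL(O | M(K))` over a grid of K values and returns the
#' minimizing K (ties broken toward smaller K, i.e. the least environmental
#' modification).  The default grid spans 0 to 2 in steps of 0.1, matching
#' the one-decimal resolution at which K is conventionally reported; when
#' the minimum lands on the upper grid boundary the grid is extended to 3
#' with a warning.
#'
#' @param profile a `hydro_profile`.
#' @param k_grid increasing numeric grid of candidate K values.
#' @param auto_extend extend the grid (step preserved, up to `extend_to`)
#'   when the optimum falls on its upper boundary.
#' @param extend_to upper bound for automatic extension.
#' @return object of class `fodm_result`: list with `k_opt`, `k_grid`,
#'   `dkl_OM` (the divergence curve, bits), `M_opt` (the optimal M
#'   distribution) and `dkl_OT` (= curve value at K = 0 when on the grid).
#' @export
scan_k <- function(profile, k_grid = seq(0, 2, by = 0.1),
                   auto_extend = TRUE, extend_to = 3) {
  stopifnot(inherits(profile, "hydro_profile"))
  if (!length(k_grid)) stop("empty K grid")
  k_grid <- sort(unique(as.numeric(k_grid)))
  curve <- vapply(k_grid, function(k)
    kl_divergence(profile$O, m_profile(profile$T, k)), numeric(1L))
  if (auto_extend && length(k_grid) > 1L) {
    step <- min(diff(k_grid))
    while (which.min(curve) == length(k_grid) &&
           max(k_grid) + step <= extend_to + 1e-9) {
      warning("D_KL(O|M) minimum on grid boundary; extending K grid")
      k_new <- seq(max(k_grid) + step, extend_to, by = step)
      curve <- c(curve, vapply(k_new, function(k)
        kl_divergence(profile$O, m_profile(profile$T, k)), numeric(1L)))
      k_grid <- c(k_grid, k_new)
    }
  }
  i <- which.min(curve)                  # first minimum = smallest K on ties
  k_opt <- k_grid[i]
  structure(list(k_opt = k_opt, k_grid = k_grid, dkl_OM = curve,
                 M_opt = m_profile(profile$T, k_opt),
                 dkl_OT = if (any(k_grid == 0)) curve[k_grid == 0][1L]
                          else NA_real_),
            class = "fodm_result")
}

#' @export
print.fodm_result <- function(x, ...) {
  cat(sprintf("FOD-M scan: K_opt = %.2f, D_KL(O|M) = %.4f bits (grid %g..%g)\n",
              x$k_opt, min(x$dkl_OM), min(x$k_grid), max(x$k_grid)))
  invisible(x)
}

#' Write the K-scan divergence curve
#'
#' TSV with columns `K` and `dkl_OM` (bits).
#'
#' @param fodm a `fodm_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kscan_tsv <- function(fodm, path) {
  utils::write.table(data.frame(K = fodm$k_grid, dkl_OM = fodm$dkl_OM),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
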